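# Internal helpers: classed error conditions and small validators.
#
# Error taxonomy (mirrored by CLI exit codes):
#   imgchain_config_error   -- bad configuration / unknown algorithm (exit 2)
#   imgchain_data_error     -- unreadable or malformed input data     (exit 3)
#   imgchain_contract_error -- violated module contract               (exit 4)

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("imgchain_config_error", "imgchain_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("imgchain_data_error", "imgchain_error")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("imgchain_contract_error", "imgchain_error")))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Population variance (divide by N).  Used for per-run accuracy spread and
# object statistics, where a single observation must give 0, not NA.
pop_var <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
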