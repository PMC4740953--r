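# structured error conditions so callers (and the CLI) can map error kinds
# to exit codes
abort_hlba <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hlba_error")))
}
abort_param <- function(msg) abort_hlba(msg, "hlba_param_error")
abort_data <- function(msg) abort_hlba(msg, "hlba_data_error")
abort_config <- function(msg) abort_hlba(msg, "hlba_config_error")
abort_lookup <- function(msg) abort_hlba(msg, "hlba_lookup_error")
abort_consistency <- function(msg) abort_hlba(msg, "hlba_consistency_error")
abort_sampler <- function(msg) abort_hlba(msg, "hlba_sampler_error")
abort_numeric <- function(msg) abort_hlba(msg, "hlba_numeric_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == floor(x)

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort_param(sprintf("'%s' must be a finite numeric scalar", name))
}
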