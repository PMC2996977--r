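# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "dreamtdmr_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "dreamtdmr_error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name, class = "dreamtdmr_validation_error")
  if (x < min || (strict_min && x <= min) || x > max)
    stopf("'%s' = %g out of range [%g, %g]", name, x, min, max,
          class = "dreamtdmr_validation_error")
  invisible(x)
}

assert_fraction <- function(x, name) assert_scalar_number(x, name, 0, 1)

assert_count <- function(x, name) {
  assert_scalar_number(x, name, min = 1)
  if (x != as.integer(x))
    stopf("'%s' must be an integer count", name, class = "dreamtdmr_validation_error")
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s is missing column(s): %s", what, paste(missing, collapse = ", "),
          class = "dreamtdmr_schema_error")
  invisible(df)
}

# tissue labels of sample columns named "<tissue>_<replicate>"
sample_tissues <- function(sample_names) sub("_[^_]+$", "", sample_names)

# deterministic seed streams: every simulate_* sets its own substream so that
# regenerating any one artifact from the same config is byte-identical
sim_seed <- function(config, offset) {
  s <- (as.integer(config$seed) + 97L * as.integer(offset)) %% 2147483647L
  if (s == 0L) s <- 1L
  s
}
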