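`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.msgf <- function(fmt, ...) message(sprintf(fmt, ...))

# scalar integer-ish check
.check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    .stopf("'%s' must be a single integer", name)
  if (positive && x <= 0) .stopf("'%s' must be positive", name)
  as.integer(x)
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopf("'%s' must be a single value in [0, 1]", name)
  as.numeric(x)
}
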