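# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_infinite = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_infinite && !is.finite(x)))
    stop2("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop2("'%s' = %s outside allowed range [%s, %s]", name,
          format(x), format(lower), format(upper))
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) stop2("'%s' must be an integer", name)
  invisible(as.integer(x))
}

# sample-sd per row, vectorised (n - 1 denominator)
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}
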