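## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

.assert_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x),
          "%s must be a single finite number", name)
  if (strict) {
    .assert(x > lower, "%s must be > %g", name, lower)
  } else {
    .assert(x >= lower, "%s must be >= %g", name, lower)
  }
  invisible(x)
}

## product categories are a fixed triple throughout
.products <- c("rice", "wheat_flour", "other")

## truncate (not round) at `digits` decimals; reproduces printed shares
## such as 16/22 -> 72.72
.trunc_percent <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 1e-9) / f
}

## key used to join (province, product) pairs without separator collisions
.pair_key <- function(a, b) paste(a, b, sep = "\x1f")
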