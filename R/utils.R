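# Internal helpers shared across modules.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive `n` child seeds from one parent seed, all below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single finite %s number, got %s",
                 name, if (strict) "positive" else "non-negative",
                 deparse(substitute(x))), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bilinear interpolation of matrix `img` at fractional pixel coordinates
# (row, col), 1-based. Points must lie inside [1, nrow] x [1, ncol].
bilinear <- function(img, row, col) {
  r0 <- pmin(floor(row), nrow(img) - 1L)
  c0 <- pmin(floor(col), ncol(img) - 1L)
  fr <- row - r0
  fc <- col - c0
  i00 <- img[cbind(r0, c0)]
  i01 <- img[cbind(r0, c0 + 1L)]
  i10 <- img[cbind(r0 + 1L, c0)]
  i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}
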