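#' Autocovariance of fractional Gaussian noise increments
#'
#' Covariance at integer lag `k` of the per-axis displacement increments of a
#' fractional Brownian motion whose per-axis MSD is `2 D t^alpha` (so the 2D
#' MSD is `4 D t^alpha`), sampled at interval `dt`:
#' `gamma(k) = D dt^alpha (|k+1|^alpha - 2|k|^alpha + |k-1|^alpha)`.
#' At `k = 0` this is the increment variance `2 D dt^alpha`; for `alpha < 1`
#' lagged covariances are negative (anti-persistent, subdiffusive motion),
#' for `alpha > 1` positive (persistent).
#'
#' @param k integer lag(s), `>= 0`.
#' @param alpha anomalous exponent in `(0, 2]`.
#' @param D diffusion coefficient (um^2/s), `>= 0`.
#' @param dt sampling interval (s), `> 0`.
#' @return numeric vector of covariances (um^2).
#' @export
fgn_acvf <- function(k, alpha, D, dt) {
  D * dt^alpha * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

# Davies-Harte circulant embedding: exact simulation of n stationary Gaussian
# increments with autocovariance gamma(0..n). Returns NULL when the circulant
# eigenvalues are materially negative (embedding infeasible); the caller then
# falls back to a Cholesky factorisation of the covariance matrix.
fgn_davies_harte <- function(n, gamma) {
  if (n == 1L) return(rnorm(1L, sd = sqrt(gamma[1L])))
  m <- 2L * n
  g <- c(gamma[1:(n + 1L)], rev(gamma[2:n]))
  lam <- Re(fft(g))
  if (min(lam) < -1e-8 * max(abs(lam))) return(NULL)
  lam[lam < 0] <- 0
  v <- complex(m)
  v[1L] <- sqrt(lam[1L]) * rnorm(1L)
  v[n + 1L] <- sqrt(lam[n + 1L]) * rnorm(1L)
  if (n > 1L) {
    a <- rnorm(n - 1L)
    b <- rnorm(n - 1L)
    v[2:n] <- sqrt(lam[2:n] / 2) * complex(real = a, imaginary = b)
    v[m:(n + 2L)] <- Conj(v[2:n])
  }
  Re(fft(v))[1:n] / sqrt(m)
}

# Exact-covariance fallback: O(n^3) but always correct for a positive
# semi-definite Toeplitz covariance.
fgn_cholesky <- function(n, gamma) {
  G <- toeplitz(gamma[1:n])
  L <- chol(G)
  drop(rnorm(n) %*% L)
}

#' Simulate fractional Gaussian noise increments
#'
#' Draws one realisation of `n` per-axis displacement increments of a
#' fractional Brownian motion with per-axis MSD `2 D t^alpha` (Hurst exponent
#' `H = alpha / 2`), sampled at interval `dt`. Uses Davies-Harte circulant
#' embedding (O(n log n), exact) with a Cholesky fallback for the rare
#' lengths where the embedding is infeasible.
#'
#' @inheritParams fgn_acvf
#' @param n number of increments, `>= 1`.
#' @return numeric vector of `n` increments (um). The cumulative sum is a
#'   discretely sampled fBm path started at 0.
#' @export
fgn_sim <- function(n, alpha, D, dt) {
  stopifnot(n >= 1L)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 2)) {
    stop("`alpha` must lie in (0, 2]: the fGn covariance is not positive ",
         "semi-definite outside this range", call. = FALSE)
  }
  stop_if_not_scalar_pos(D, "D", strict = FALSE)
  stop_if_not_scalar_pos(dt, "dt")
  if (D == 0) return(numeric(n))
  gamma <- fgn_acvf(0:n, alpha, D, dt)
  x <- fgn_davies_harte(n, gamma)
  if (is.null(x)) x <- fgn_cholesky(n, gamma)
  x
}
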