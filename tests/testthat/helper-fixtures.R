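# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# Noise-free Gaussian intensity profile centred on 0.
gaussian_profile <- function(sigma_um, pixel_size = 0.1, half_length = 2,
                             peak = 1, background = 0) {
  offsets <- seq(-half_length, half_length, by = pixel_size)
  list(offsets = offsets,
       intensities = background + peak * exp(-offsets^2 / (2 * sigma_um^2)),
       background = background)
}

# Exact power-law MSD curve, for fit-exactness checks.
power_law_curve <- function(D, alpha, lags) {
  structure(data.frame(lag = lags, msd = 4 * D * lags^alpha,
                       n_pairs = rep(1L, length(lags))),
            class = c("msd_curve", "data.frame"),
            track_id = "exact", frame_interval = diff(lags[1:2]))
}

# Hand-built trajectory from coordinate vectors.
make_track <- function(x, y, dt = 0.5, id = "t1") {
  trajectory(id, seq_along(x) - 1L, x, y, dt)
}

# Brute-force time-averaged MSD: the double-loop oracle.
msd_oracle <- function(track, max_lag_fraction = 0.25) {
  n <- nrow(track)
  K <- max(1L, floor(max_lag_fraction * n))
  vapply(seq_len(K), function(k) {
    tot <- 0
    for (i in seq_len(n - k)) {
      tot <- tot + (track$x[i + k] - track$x[i])^2 +
        (track$y[i + k] - track$y[i])^2
    }
    tot / (n - k)
  }, numeric(1L))
}

# Brute-force FWHM: upsample the profile 100x by linear interpolation and
# scan for the half-max crossings nearest the peak.
fwhm_oracle <- function(profile, factor = 100L) {
  off <- profile$offsets
  fine <- seq(min(off), max(off), length.out = factor * (length(off) - 1L) + 1L)
  ii <- approx(off, profile$intensities, xout = fine)$y
  bg <- profile$background
  ipk <- which.max(ii)
  level <- bg + (ii[ipk] - bg) / 2
  left <- max(which(ii[seq_len(ipk)] <= level))
  right <- ipk - 1L + min(which(ii[ipk:length(ii)] <= level))
  fine[right] - fine[left]
}

# Brute-force gated assignment: enumerate all one-to-one matchings between
# rows of a and b (with unmatched allowed) and minimise
# sum(d^2) + gate^2 * (#unmatched_a + #unmatched_b) -- the same objective
# the LAP formulation optimises.
assignment_oracle <- function(a, b, gate) {
  n1 <- nrow(a)
  n2 <- nrow(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  best <- NULL
  best_cost <- Inf
  # enumerate injective partial maps a -> b
  assign_next <- function(i, link, used) {
    if (i > n1) {
      cost <- 0
      for (j in seq_len(n1)) {
        cost <- cost + if (link[j] == 0L) gate^2 else d2[j, link[j]]
      }
      cost <- cost + gate^2 * sum(!seq_len(n2) %in% link)
      if (cost < best_cost) {
        best_cost <<- cost
        best <<- link
      }
      return(invisible())
    }
    assign_next(i + 1L, c(link, 0L), used)
    for (j in seq_len(n2)) {
      if (!used[j] && d2[i, j] <= gate^2) {
        used[j] <- TRUE
        assign_next(i + 1L, c(link, j), used)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, integer(0), logical(n2))
  list(link = best, cost = best_cost)
}
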