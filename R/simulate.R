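#' Configuration for trajectory simulation
#'
#' Defaults follow the live-cell acquisition this package models: 300 frames
#' at 0.5 s intervals, and population parameters of the order measured for
#' ER aggregate (Russell body) mobility, `D = 0.0045` um^2/s and
#' `alpha = 0.74` (subdiffusive, constrained motion).
#'
#' @param D diffusion coefficient (um^2/s), prefactor of `MSD = 4 D t^alpha`.
#' @param alpha anomalous exponent in `(0, 2]`; 1 is Brownian, < 1
#'   subdiffusive, 2 ballistic.
#' @param n_frames number of time points, `>= 2`.
#' @param frame_interval acquisition interval (s).
#' @param drift_velocity `(vx, vy)` deterministic drift (um/s), modelling
#'   directionally moving clusters.
#' @param loc_noise_sd static localisation error, per axis (um). Adds a
#'   constant `4 * loc_noise_sd^2` to the expected 2D MSD at every positive
#'   lag.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a list of class `"track_sim_config"`.
#' @export
track_sim_config <- function(D = 0.0045, alpha = 0.74, n_frames = 300L,
                             frame_interval = 0.5,
                             drift_velocity = c(0, 0),
                             loc_noise_sd = 0, seed = NULL) {
  stop_if_not_scalar_pos(D, "D", strict = FALSE)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 2)) {
    stop("`alpha` must lie in (0, 2]", call. = FALSE)
  }
  if (!(length(n_frames) == 1L && n_frames >= 2)) {
    stop("`n_frames` must be >= 2", call. = FALSE)
  }
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  if (length(drift_velocity) != 2L || any(!is.finite(drift_velocity))) {
    stop("`drift_velocity` must be a finite (vx, vy) pair", call. = FALSE)
  }
  stop_if_not_scalar_pos(loc_noise_sd, "loc_noise_sd", strict = FALSE)
  structure(list(D = D, alpha = alpha, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 drift_velocity = as.numeric(drift_velocity),
                 loc_noise_sd = loc_noise_sd, seed = seed),
            class = "track_sim_config")
}

#' Simulate one trajectory
#'
#' Realises the anomalous-diffusion model `MSD = 4 D t^alpha` as a 2D
#' fractional Brownian motion: independent per-axis fractional Gaussian
#' increments with Hurst exponent `H = alpha / 2` and per-axis MSD
#' `2 D t^alpha`, plus optional deterministic drift and static localisation
#' noise added to the observed positions. The same configuration (including
#' seed) always yields the identical trajectory.
#'
#' @param cfg a [track_sim_config()].
#' @param track_id identifier for the output trajectory.
#' @param condition optional condition label attached to the trajectory.
#' @return a [trajectory()] of `cfg$n_frames` points starting at the origin
#'   (before noise).
#' @export
simulate_track <- function(cfg, track_id = "sim", condition = NA_character_) {
  stopifnot(inherits(cfg, "track_sim_config"))
  n <- cfg$n_frames
  tt <- (seq_len(n) - 1L) * cfg$frame_interval
  with_seed(cfg$seed, {
    dx <- fgn_sim(n - 1L, cfg$alpha, cfg$D, cfg$frame_interval)
    dy <- fgn_sim(n - 1L, cfg$alpha, cfg$D, cfg$frame_interval)
    x <- c(0, cumsum(dx)) + cfg$drift_velocity[1L] * tt
    y <- c(0, cumsum(dy)) + cfg$drift_velocity[2L] * tt
    if (cfg$loc_noise_sd > 0) {
      x <- x + rnorm(n, sd = cfg$loc_noise_sd)
      y <- y + rnorm(n, sd = cfg$loc_noise_sd)
    }
    trajectory(track_id, frame = 0:(n - 1L), x = x, y = y,
               frame_interval = cfg$frame_interval, condition = condition)
  })
}

#' Simulate a population of independent trajectories
#'
#' Child seeds are derived deterministically from `seed`, so the population
#' is reproducible as a whole and each member equals `simulate_track` run
#' with its derived seed.
#'
#' @param cfg a [track_sim_config()]; its own `seed` field is ignored in
#'   favour of the derived per-track seeds.
#' @param n_tracks number of trajectories, `>= 1`.
#' @param seed integer seed for the population.
#' @param condition optional condition label for all tracks.
#' @return list of [trajectory()] objects with ids `"track_1"`, ...
#' @export
simulate_population <- function(cfg, n_tracks, seed,
                                condition = NA_character_) {
  stopifnot(inherits(cfg, "track_sim_config"), n_tracks >= 1L)
  seeds <- derive_seeds(seed, n_tracks)
  lapply(seq_len(n_tracks), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- seeds[i]
    simulate_track(cfg_i, track_id = paste0("track_", i),
                   condition = condition)
  })
}
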