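# Trajectory and image generators: determinism, degenerate limits, and the
# statistical properties of the fractional-Gaussian-noise engine.

test_that("degenerate track limits are exact", {
  # zero diffusion: frozen at the origin
  cfg <- track_sim_config(D = 0, alpha = 0.74, n_frames = 50L, seed = 1L)
  tr <- simulate_track(cfg)
  expect_equal(tr$x, rep(0, 50))
  expect_equal(tr$y, rep(0, 50))

  # ballistic limit: pure drift at 1 um/s sampled every 0.5 s
  cfg <- track_sim_config(D = 0, drift_velocity = c(1, 0), n_frames = 5L,
                          frame_interval = 0.5, seed = 1L)
  tr <- simulate_track(cfg)
  expect_equal(tr$x, c(0, 0.5, 1, 1.5, 2))
  expect_equal(tr$y, rep(0, 5))
})

test_that("same seed reproduces trajectories bitwise; populations too", {
  cfg <- track_sim_config(n_frames = 40L, seed = 99L)
  expect_identical(simulate_track(cfg), simulate_track(cfg))

  p1 <- simulate_population(track_sim_config(n_frames = 30L), 5L, seed = 3L)
  p2 <- simulate_population(track_sim_config(n_frames = 30L), 5L, seed = 3L)
  expect_identical(p1, p2)
  expect_length(p1, 5L)

  # singleton population equals simulate_track under the derived seed
  p <- simulate_population(track_sim_config(n_frames = 30L), 1L, seed = 11L)
  cfg1 <- track_sim_config(n_frames = 30L,
                           seed = rbtrack:::derive_seeds(11L, 1L))
  one <- simulate_track(cfg1, track_id = "track_1")
  expect_equal(p[[1L]]$x, one$x)
  expect_equal(p[[1L]]$y, one$y)
})

test_that("alpha outside (0, 2] is rejected", {
  expect_error(track_sim_config(alpha = 0), "alpha")
  expect_error(track_sim_config(alpha = 2.3), "alpha")
  expect_error(fgn_sim(10L, alpha = -1, D = 1, dt = 1), "alpha")
})

test_that("Brownian ensemble MSD matches the closed form and increments are uncorrelated", {
  # alpha = 1, D = 0.01: E|dr|^2 at lag 1 frame = 4 D dt = 0.02 um^2
  withr::with_seed(42L, {
    n_tracks <- 2000L
    sq <- vapply(seq_len(n_tracks), function(i) {
      dx <- fgn_sim(49L, 1, 0.01, 0.5)
      dy <- fgn_sim(49L, 1, 0.01, 0.5)
      mean(dx^2 + dy^2)
    }, numeric(1L))
    m <- mean(sq)
    se <- sd(sq) / sqrt(n_tracks)
    expect_lt(abs(m - 0.02), 3 * se)

    # increment autocorrelation at lag >= 1 vanishes for Brownian motion
    x <- fgn_sim(20000L, 1, 0.01, 0.5)
    ac <- acf(x, lag.max = 3, plot = FALSE)$acf[-1L]
    expect_lt(max(abs(ac)), 3 / sqrt(20000))
  })
})

test_that("simulated increments reproduce the fGn autocovariance", {
  # gamma(k) = D dt^alpha (|k+1|^a - 2|k|^a + |k-1|^a), checked by sample
  # autocovariance over >= 1e4 increments for each alpha. The Monte-Carlo
  # error is estimated from the scatter across independent replicate series
  # (important for alpha > 1, where long-range dependence slows convergence).
  withr::with_seed(7L, {
    for (alpha in c(0.5, 0.74, 1.0, 1.5)) {
      reps <- 50L
      est <- vapply(seq_len(reps), function(r) {
        x <- fgn_sim(2000L, alpha, 0.0045, 0.5)
        acf(x, lag.max = 5, type = "covariance", demean = FALSE,
            plot = FALSE)$acf[, 1L, 1L]
      }, numeric(6L))
      theo <- fgn_acvf(0:5, alpha, 0.0045, 0.5)
      emp <- rowMeans(est)
      se <- apply(est, 1L, sd) / sqrt(reps)
      expect_true(all(abs(emp - theo) < 4 * se),
                  label = sprintf("autocovariance match at alpha = %g", alpha))
    }
  })
})

test_that("ensemble MSD converges to 4 D t^alpha for subdiffusion", {
  withr::with_seed(13L, {
    D <- 0.0045; alpha <- 0.74; dt <- 0.5
    n_tracks <- 500L
    lags <- c(1L, 4L, 10L)
    acc <- matrix(0, n_tracks, length(lags))
    for (i in seq_len(n_tracks)) {
      dx <- cumsum(fgn_sim(20L, alpha, D, dt))
      dy <- cumsum(fgn_sim(20L, alpha, D, dt))
      x <- c(0, dx); y <- c(0, dy)
      acc[i, ] <- (x[1L + lags] - x[1L])^2 + (y[1L + lags] - y[1L])^2
    }
    for (j in seq_along(lags)) {
      expected <- 4 * D * (lags[j] * dt)^alpha
      se <- sd(acc[, j]) / sqrt(n_tracks)
      expect_lt(abs(mean(acc[, j]) - expected), 3.5 * se)
    }
  })
})

test_that("localization noise adds 4 sigma^2 to the ensemble 2D MSD", {
  withr::with_seed(21L, {
    sd_loc <- 0.03
    cfg0 <- track_sim_config(D = 0.002, alpha = 1, n_frames = 2L,
                             frame_interval = 0.5)
    disp2 <- function(loc_sd, n = 4000L) {
      cfg <- cfg0; cfg$loc_noise_sd <- loc_sd
      seeds <- rbtrack:::derive_seeds(5L, n)
      vapply(seq_len(n), function(i) {
        cfg$seed <- seeds[i]
        tr <- simulate_track(cfg)
        (tr$x[2L] - tr$x[1L])^2 + (tr$y[2L] - tr$y[1L])^2
      }, numeric(1L))
    }
    clean <- disp2(0)
    noisy <- disp2(sd_loc)
    delta <- mean(noisy) - mean(clean)
    se <- sqrt(var(noisy) / length(noisy) + var(clean) / length(clean))
    expect_lt(abs(delta - 4 * sd_loc^2), 3.5 * se)
  })
})

test_that("Cholesky fallback agrees with the embedding in law", {
  # same covariance target: compare sample variance of lag-0 increments
  withr::with_seed(31L, {
    gamma <- fgn_acvf(0:50, 0.74, 0.0045, 0.5)
    x_dh <- replicate(400L, rbtrack:::fgn_davies_harte(50L, gamma)[1L])
    x_ch <- replicate(400L, rbtrack:::fgn_cholesky(50L, gamma)[1L])
    expect_lt(abs(var(x_dh) - gamma[1L]), 4 * gamma[1L] / sqrt(200))
    expect_lt(abs(var(x_ch) - gamma[1L]), 4 * gamma[1L] / sqrt(200))
  })
})

test_that("cluster-pair rendering honours geometry, linearity and bounds", {
  # zero growth, no noise: channels identical
  cfg <- image_sim_config(shell_growth_fraction = 0, noise_model = "none")
  pair <- render_cluster_pair(cfg)
  expect_equal(pair$image$red, pair$image$green)
  expect_equal(pair$truth$rel_increase, 0)

  # ground truth carries the configured growth exactly
  cfg <- image_sim_config(shell_growth_fraction = 0.16, noise_model = "none")
  pair <- render_cluster_pair(cfg)
  expect_equal(pair$truth$rel_increase, 0.16)
  expect_equal(pair$truth$d_g_um, pair$truth$d_r_um * 1.16)

  # dark config renders an all-zero image
  cfg0 <- image_sim_config(peak_intensity = 0, background = 0,
                           noise_model = "none")
  pair0 <- render_cluster_pair(cfg0)
  expect_true(all(pair0$image$red == 0) && all(pair0$image$green == 0))

  # doubling peak intensity doubles every pixel above background
  cfg1 <- image_sim_config(peak_intensity = 500, background = 7,
                           noise_model = "none")
  cfg2 <- image_sim_config(peak_intensity = 1000, background = 7,
                           noise_model = "none")
  r1 <- render_cluster_pair(cfg1)$image$red - 7
  r2 <- render_cluster_pair(cfg2)$image$red - 7
  expect_equal(r2, 2 * r1, tolerance = 1e-12)

  # out-of-bounds cluster errors, naming the margin
  expect_error(render_cluster_pair(cfg, center = c(0.3, 3)), "margin")
})

test_that("movie rendering matches its ground truth", {
  # stationary track, no noise: identical frames
  still <- make_track(rep(2, 10), rep(2, 10))
  cfg <- image_sim_config(image_shape = c(40L, 40L), noise_model = "none",
                          core_diameter = 0.6)
  mv <- render_movie(list(still), cfg)
  expect_length(mv$stack$frames, 10L)
  for (f in mv$stack$frames) expect_equal(f, mv$stack$frames[[1L]])

  # drifting well-separated tracks: brightest pixel within 1 px of truth
  tracks <- lapply(1:4, function(i) {
    x0 <- 1.5 + 2 * ((i - 1) %% 2)
    y0 <- 1.5 + 2 * ((i - 1) %/% 2)
    make_track(x0 + 0.04 * (0:9), y0 + 0.02 * (0:9), id = paste0("d", i))
  })
  cfg <- image_sim_config(image_shape = c(60L, 60L), noise_model = "none",
                          core_diameter = 0.5)
  mv <- render_movie(tracks, cfg)
  for (f in seq_len(10L)) {
    fr <- mv$stack$frames[[f]]
    truth_f <- mv$truth[mv$truth$frame == f - 1L, ]
    for (i in seq_len(nrow(truth_f))) {
      rc <- round(c(truth_f$y_um[i], truth_f$x_um[i]) / cfg$pixel_size) + 1L
      win <- fr[(rc[1L] - 1L):(rc[1L] + 1L), (rc[2L] - 1L):(rc[2L] + 1L)]
      # truth pixel is the local brightest within 1 px
      expect_gte(max(win), max(fr[rc[1L] + c(-3L, 3L), rc[2L]]))
    }
  }

  # empty track list: background-only stack
  mv0 <- render_movie(list(), cfg)
  expect_length(mv0$stack$frames, 1L)
  expect_true(all(mv0$stack$frames[[1L]] == cfg$background))

  # overlapping tracks are flagged in the ground truth
  t1 <- make_track(c(2, 2.01), c(2, 2))
  t2 <- make_track(c(2.2, 2.2), c(2, 2), id = "t2")
  expect_warning(mvo <- render_movie(list(t1, t2), cfg), "overlap")
  expect_gt(nrow(attr(mvo$truth, "overlaps")), 0L)
})

test_that("image and track I/O round-trip", {
  cfg <- image_sim_config(seed = 5L)
  pair <- render_cluster_pair(cfg)
  tmp <- tempfile(fileext = ".tif")
  write_two_channel_tiff(pair$image, tmp)
  back <- read_two_channel_tiff(tmp, cfg$pixel_size)
  # 16-bit storage: photon counts round-trip to within half a count
  expect_lt(max(abs(back$red - round(pair$image$red))), 0.51)

  tracks <- simulate_population(track_sim_config(n_frames = 20L), 3L,
                                seed = 2L)
  csv <- tempfile(fileext = ".csv")
  write_track_table(tracks, csv)
  back <- read_track_table(csv, frame_interval = 0.5)
  for (i in seq_along(tracks)) {
    id <- attr(tracks[[i]], "track_id")
    expect_equal(back[[id]]$x, tracks[[i]]$x, tolerance = 1e-6)
    expect_equal(back[[id]]$y, tracks[[i]]$y, tolerance = 1e-6)
  }
  unlink(c(tmp, csv))
})
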