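# MSD computation, the anomalous-diffusion fit, and population statistics.

test_that("MSD closed forms: stationary and ballistic tracks", {
  still <- make_track(rep(1, 20), rep(2, 20))
  cv <- compute_msd(still)
  expect_equal(cv$msd, rep(0, nrow(cv)))
  expect_equal(cv$n_pairs, 20L - seq_len(nrow(cv)))

  # pure drift 1 um/s at dt = 0.5: MSD(k dt) = (0.5 k)^2 exactly
  drift <- make_track(0.5 * (0:39), rep(0, 40))
  cv <- compute_msd(drift)
  expect_equal(cv$msd, (0.5 * seq_len(nrow(cv)))^2, tolerance = 1e-12)
})

test_that("fast MSD equals the brute-force double loop", {
  withr::with_seed(19L, {
    for (rep in 1:20) {
      n <- sample(10:100, 1L)
      tr <- make_track(cumsum(rnorm(n)), cumsum(rnorm(n)))
      expect_equal(compute_msd(tr)$msd, msd_oracle(tr), tolerance = 1e-12)
    }
  })
})

test_that("MSD rejects too-short and gappy tracks", {
  expect_error(compute_msd(make_track(1:2, 1:2)), "too short")
  gappy <- trajectory("g", c(0L, 1L, 3L, 4L), 1:4, 1:4, 0.5)
  expect_error(compute_msd(gappy), "gap")
})

test_that("fit is exact on noiseless power laws", {
  lags <- seq(0.5, 10, by = 0.5)
  for (D in 10^seq(-4, -1)) {
    for (alpha in c(0.3, 0.74, 1, 1.5, 2)) {
      fit <- suppressWarnings(fit_anomalous(power_law_curve(D, alpha, lags)))
      expect_equal(unname(coef(fit)["D"]), D, tolerance = 1e-10)
      expect_equal(unname(coef(fit)["alpha"]), alpha, tolerance = 1e-10)
    }
  }
  # headline scenario: the exact 0.74 / 0.0045 curve
  fit <- suppressWarnings(
    fit_anomalous(power_law_curve(0.0045, 0.74, lags)))
  expect_equal(unname(coef(fit)), c(0.0045, 0.74), tolerance = 1e-12)
  # Brownian case
  fit1 <- suppressWarnings(fit_anomalous(power_law_curve(0.01, 1, lags)))
  expect_equal(unname(coef(fit1)["alpha"]), 1, tolerance = 1e-12)
})

test_that("fit guards: window size, non-positive values, superdiffusive flag", {
  lags <- seq(0.5, 10, by = 0.5)
  short <- power_law_curve(0.01, 1, lags[1:5])
  expect_error(fit_anomalous(short, n_points = 20L), "only 5 lags")
  bad <- power_law_curve(0.01, 1, lags)
  bad$msd[3L] <- 0
  expect_error(fit_anomalous(bad), "log-fit undefined")
  ball <- suppressWarnings(fit_anomalous(power_law_curve(0.01, 2, lags)))
  expect_true(ball$superdiffusive)
})

test_that("fitted D is invariant to pixel vs micrometre representation", {
  withr::with_seed(23L, {
    tr <- simulate_track(track_sim_config(n_frames = 120L, seed = 8L))
    fit_um <- fit_anomalous(compute_msd(tr))
    px <- tr
    px$x <- tr$x / 0.1
    px$y <- tr$y / 0.1
    # re-express in pixels, convert back via pixel_size on ingest
    tmp <- tempfile(fileext = ".csv")
    write.csv(data.frame(track_id = "t", frame = px$frame, x = px$x,
                         y = px$y), tmp, row.names = FALSE)
    tr2 <- read_track_table(tmp, 0.5, pixel_size = 0.1)[["t"]]
    fit_px <- fit_anomalous(compute_msd(tr2))
    expect_equal(coef(fit_px), coef(fit_um), tolerance = 1e-9)
    unlink(tmp)
  })
})

test_that("msd_fit methods are coherent", {
  lags <- seq(0.5, 10, by = 0.5)
  fit <- fit_anomalous(power_law_curve(0.0045, 0.74, lags))
  expect_equal(predict(fit, 1), 4 * 0.0045, tolerance = 1e-10)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
  expect_output(print(fit), "alpha")
  s <- summary(fit)
  expect_match(s$regime, "subdiffusive")
  expect_output(print(s), "power-law")
  sims <- simulate(fit, nsim = 2L, seed = 4L, n_frames = 50L)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1L]]), 50L)
})

test_that("population summary matches a direct recomputation", {
  lags <- seq(0.5, 10, by = 0.5)
  f1 <- fit_anomalous(power_law_curve(0.004, 0.7, lags))
  f2 <- fit_anomalous(power_law_curve(0.005, 0.8, lags))
  s <- summarize_population(list(f1, f2), condition = "untreated")
  expect_equal(s$mean_alpha, 0.75, tolerance = 1e-9)
  expect_equal(s$sem_alpha, 0.05, tolerance = 1e-9)
  expect_equal(s$mean_D, 0.0045, tolerance = 1e-9)
  expect_equal(s$n_tracks, 2L)

  sid <- summarize_population(list(f1, f1, f1))
  expect_equal(sid$sem_alpha, 0, tolerance = 1e-12)
  expect_error(summarize_population(list()), "no fits")

  withr::with_seed(3L, {
    pop <- simulate_population(track_sim_config(n_frames = 100L), 40L,
                               seed = 17L)
    fits <- fit_population(pop)
    s <- summarize_population(fits)
    a <- vapply(fits, function(f) unname(coef(f)["alpha"]), numeric(1L))
    expect_equal(s$mean_alpha, mean(a))
    expect_equal(s$sem_alpha, sd(a) / sqrt(length(a)))
  })
})

test_that("parameter recovery at the study's sampling scale", {
  withr::with_seed(29L, {
    pop <- simulate_population(
      track_sim_config(D = 0.0045, alpha = 0.74, n_frames = 300L,
                       frame_interval = 0.5), 115L, seed = 41L)
    fits <- fit_population(pop, n_points = 20L)
    s <- summarize_population(fits)
    expect_lt(abs(s$mean_alpha - 0.74), 0.05)
    expect_lt(abs(s$mean_D - 0.0045) / 0.0045, 0.25)
  })
})

test_that("localization noise biases fitted alpha downward, monotonically", {
  withr::with_seed(37L, {
    mean_alpha <- vapply(c(0, 0.02, 0.05), function(sig) {
      pop <- simulate_population(
        track_sim_config(D = 0.0045, alpha = 0.74, n_frames = 200L,
                         loc_noise_sd = sig), 40L, seed = 19L)
      summarize_population(fit_population(pop))$mean_alpha
    }, numeric(1L))
    expect_true(all(diff(mean_alpha) < 0))
    expect_lt(mean_alpha[3L], mean_alpha[1L] - 0.05)
  })
})

test_that("size-mobility relation flags the inverse D-diameter trend", {
  lags <- seq(0.5, 10, by = 0.5)
  d <- seq(0.5, 2.5, length.out = 12L)
  fits <- lapply(0.004 / d, function(D) {
    fit_anomalous(power_law_curve(D, 0.74, lags))
  })
  rel <- size_mobility_relation(fits, d)
  expect_equal(rel$rho[rel$parameter == "D"], -1, tolerance = 1e-9)

  # constant alpha: degenerate ranks error path
  expect_error(size_mobility_relation(fits, rep(1, 12L)), "degenerate")

  withr::with_seed(43L, {
    d <- runif(100L, 0.5, 2.5)
    fits <- lapply(0.004 / d * exp(rnorm(100L, sd = 0.3)), function(D) {
      fit_anomalous(power_law_curve(D, 0.74, lags))
    })
    rel <- size_mobility_relation(fits, d)
    expect_lt(rel$rho[rel$parameter == "D"], 0)
    expect_lt(rel$p_value[rel$parameter == "D"], 0.05)
  })
})

test_that("condition comparison isolates a halved diffusion coefficient", {
  withr::with_seed(47L, {
    base <- track_sim_config(D = 0.0045, alpha = 0.74, n_frames = 150L)
    slow <- base; slow$D <- base$D / 2
    fits_a <- fit_population(simulate_population(base, 50L, seed = 1L))
    fits_b <- fit_population(simulate_population(slow, 50L, seed = 2L))
    cmp <- compare_conditions(fits_a, fits_b,
                              labels = c("untreated", "nocodazole"))
    expect_lt(cmp$p_value[cmp$parameter == "D"], 0.01)
    expect_gt(cmp$p_value[cmp$parameter == "alpha"], 0.05)
    expect_lt(abs(cmp$ratio_of_means[cmp$parameter == "D"] - 0.5), 0.1)
    expect_output(print(cmp), "Mann-Whitney")
  })
  expect_error(compare_conditions(list(), list()), "at least 3")
})
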