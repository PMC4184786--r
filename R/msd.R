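#' Time-averaged mean-square displacement of a trajectory
#'
#' `MSD(k dt) = mean_i |r(i + k) - r(i)|^2` over all overlapping
#' displacement pairs of the track (overlapping pairs give the
#' lowest-variance time average). Lags run up to
#' `floor(max_lag_fraction * n_points)`; at larger lags the time average is
#' dominated by a handful of pairs and is statistically unreliable.
#'
#' @param track a [trajectory()] with at least 3 points. Frames must be
#'   gap-free (consecutive).
#' @param max_lag_fraction fraction of the track length up to which lags are
#'   computed, in `(0, 1]`.
#' @return an object of class `"msd_curve"`: data frame with `lag` (s),
#'   `msd` (um^2), `n_pairs`; attributes `track_id`, `frame_interval`.
#' @export
compute_msd <- function(track, max_lag_fraction = 0.25) {
  stopifnot(is_trajectory(track))
  n <- nrow(track)
  if (n < 3L) stop("track too short for an MSD curve (need >= 3 points)",
                   call. = FALSE)
  if (!(max_lag_fraction > 0 && max_lag_fraction <= 1)) {
    stop("`max_lag_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (any(diff(track$frame) != 1L)) {
    stop(sprintf("track '%s' has frame gaps; time-averaged MSD assumes ",
                 attr(track, "track_id")),
         "consecutive frames", call. = FALSE)
  }
  dt <- attr(track, "frame_interval")
  K <- max(1L, floor(max_lag_fraction * n))
  msd <- numeric(K)
  n_pairs <- integer(K)
  x <- track$x
  y <- track$y
  for (k in seq_len(K)) {
    dx <- x[(1L + k):n] - x[1:(n - k)]
    dy <- y[(1L + k):n] - y[1:(n - k)]
    msd[k] <- mean(dx^2 + dy^2)
    n_pairs[k] <- n - k
  }
  structure(data.frame(lag = seq_len(K) * dt, msd = msd, n_pairs = n_pairs),
            class = c("msd_curve", "data.frame"),
            track_id = attr(track, "track_id"), frame_interval = dt)
}

#' Fit the anomalous-diffusion model to an MSD curve
#'
#' Fits `MSD(t) = 4 D t^alpha` to the first `n_points` lags of the curve.
#' The default estimator is ordinary least squares of `log(MSD)` on
#' `log(t)`: `alpha` is the slope and `D = exp(intercept) / 4`. On a
#' noiseless power law this recovers the generating parameters exactly, and
#' the estimate is invariant to the units the track was recorded in.
#' `method = "nls"` refits by nonlinear least squares on the linear scale
#' (initialised from the log-log fit), which weights large lags more
#' heavily.
#'
#' The model has no constant offset, so static localisation error is a
#' documented downward bias on `alpha` at short lags, not a fitted
#' parameter. Fits at or above the ballistic exponent 2 are flagged
#' superdiffusive (directed motion); values above 2.5 additionally trigger a
#' warning.
#'
#' @param curve an `"msd_curve"` from [compute_msd()].
#' @param n_points number of leading lags to fit (default 20).
#' @param method `"loglog"` (default) or `"nls"`.
#' @return an object of class `"msd_fit"`: list with `coefficients`
#'   (`D` um^2/s, `alpha`), `r_squared` (of the log-log fit),
#'   `n_points_fit`, `superdiffusive`, `track_id`, `method`, and the fitted
#'   window (`lag`, `msd`).
#' @export
fit_anomalous <- function(curve, n_points = 20L, method = c("loglog", "nls")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "msd_curve"))
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  if (nrow(curve) < n_points) {
    stop(sprintf("MSD curve has only %d lags; %d requested for the fit",
                 nrow(curve), n_points), call. = FALSE)
  }
  lag <- curve$lag[seq_len(n_points)]
  msd <- curve$msd[seq_len(n_points)]
  if (any(msd <= 0)) {
    stop("log-fit undefined: non-positive MSD value inside the fit window",
         call. = FALSE)
  }
  fit <- lm(log(msd) ~ log(lag))
  alpha <- unname(coef(fit)[2L])
  D <- exp(unname(coef(fit)[1L])) / 4
  tss <- sum((log(msd) - mean(log(msd)))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1
  if (method == "nls") {
    nfit <- tryCatch(
      nls(msd ~ 4 * D * lag^alpha, start = list(D = D, alpha = alpha),
          control = list(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(nfit)) {
      D <- unname(coef(nfit)["D"])
      alpha <- unname(coef(nfit)["alpha"])
    }
  }
  if (alpha > 2.5) {
    warning(sprintf("fitted alpha = %.2f exceeds 2.5 (ballistic limit is 2);",
                    alpha), " check the track for artefacts", call. = FALSE)
  }
  structure(list(coefficients = c(D = D, alpha = alpha),
                 r_squared = r2, n_points_fit = as.integer(n_points),
                 # at (or numerically at) the ballistic value 2 the motion
                 # is directed, not diffusive
                 superdiffusive = alpha > 2 - sqrt(.Machine$double.eps),
                 track_id = attr(curve, "track_id"), method = method,
                 lag = lag, msd = msd),
            class = "msd_fit")
}

#' @export
coef.msd_fit <- function(object, ...) object$coefficients

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("Anomalous-diffusion fit (MSD = 4 D t^alpha), track '%s'\n",
              x$track_id))
  cat(sprintf("  D     = %.4g um^2/s\n  alpha = %.3f%s\n  R^2   = %.4f  (%d lags, %s)\n",
              x$coefficients["D"], x$coefficients["alpha"],
              if (x$superdiffusive) "  [superdiffusive]" else "",
              x$r_squared, x$n_points_fit, x$method))
  invisible(x)
}

#' @export
summary.msd_fit <- function(object, ...) {
  regime <- if (object$superdiffusive) "superdiffusive (directed)"
            else if (object$coefficients["alpha"] < 0.9) "subdiffusive (constrained)"
            else if (object$coefficients["alpha"] <= 1.1) "approximately Brownian"
            else "mildly superdiffusive"
  out <- c(unclass(object)[c("coefficients", "r_squared", "n_points_fit",
                             "track_id", "method")],
           list(regime = regime,
                residuals = log(object$msd) -
                  log(4 * object$coefficients["D"] *
                        object$lag^object$coefficients["alpha"])))
  class(out) <- "summary.msd_fit"
  out
}

#' @export
print.summary.msd_fit <- function(x, ...) {
  cat(sprintf("MSD power-law fit for track '%s': %s\n", x$track_id, x$regime))
  cat(sprintf("  D = %.4g um^2/s, alpha = %.3f, R^2 = %.4f over %d lags\n",
              x$coefficients["D"], x$coefficients["alpha"], x$r_squared,
              x$n_points_fit))
  cat(sprintf("  log-residual range: [%.3g, %.3g]\n",
              min(x$residuals), max(x$residuals)))
  invisible(x)
}

#' @export
predict.msd_fit <- function(object, lag = NULL, ...) {
  if (is.null(lag)) lag <- object$lag
  unname(4 * object$coefficients["D"] * lag^object$coefficients["alpha"])
}

#' @export
residuals.msd_fit <- function(object, type = c("log", "linear"), ...) {
  type <- match.arg(type)
  fit <- predict(object)
  if (type == "log") log(object$msd) - log(fit) else object$msd - fit
}

#' @export
plot.msd_fit <- function(x, ...) {
  plot(x$lag, x$msd, log = "xy", xlab = "lag time (s)",
       ylab = expression(MSD ~ (mu * m^2)),
       main = sprintf("track '%s': D = %.3g, alpha = %.2f", x$track_id,
                      x$coefficients["D"], x$coefficients["alpha"]), ...)
  lag_fine <- exp(seq(log(min(x$lag)), log(max(x$lag)), length.out = 100L))
  lines(lag_fine, predict(x, lag_fine), col = "red3")
  invisible(x)
}

#' Simulate trajectories from a fitted mobility model
#'
#' Draws new fractional-Brownian-motion tracks with the fitted `D` and
#' `alpha`, e.g. for parametric-bootstrap checks of the estimator.
#'
#' @param object an `"msd_fit"`.
#' @param nsim number of tracks.
#' @param seed integer seed.
#' @param n_frames,frame_interval sampling of the simulated tracks.
#' @param ... unused.
#' @return list of [trajectory()] objects.
#' @export
simulate.msd_fit <- function(object, nsim = 1L, seed = NULL,
                             n_frames = 300L, frame_interval = 0.5, ...) {
  cfg <- track_sim_config(D = unname(object$coefficients["D"]),
                          alpha = min(unname(object$coefficients["alpha"]), 2),
                          n_frames = n_frames,
                          frame_interval = frame_interval)
  simulate_population(cfg, nsim, seed %||% sample.int(2^31 - 1, 1L))
}

#' Fit every track of a population
#'
#' Convenience wrapper: MSD curve plus power-law fit per track. Tracks whose
#' fit fails (e.g. a non-positive MSD value inside the window) are dropped
#' and counted, not imputed.
#'
#' @param tracks list of [trajectory()] objects.
#' @param n_points,method passed to [fit_anomalous()].
#' @param max_lag_fraction passed to [compute_msd()].
#' @return list of `"msd_fit"` objects with attribute `n_dropped`.
#' @export
fit_population <- function(tracks, n_points = 20L, max_lag_fraction = 0.25,
                           method = "loglog") {
  fits <- lapply(tracks, function(tr) {
    tryCatch(fit_anomalous(compute_msd(tr, max_lag_fraction), n_points,
                           method),
             error = function(e) NULL)
  })
  dropped <- sum(vapply(fits, is.null, logical(1L)))
  structure(Filter(Negate(is.null), fits), n_dropped = dropped)
}

#' Population summary of diffusion fits
#'
#' Means and standard errors of `D` and `alpha` over tracks (the track is
#' the sampling unit: uncertainties are SD / sqrt(n_tracks)).
#'
#' @param fits list of `"msd_fit"` objects.
#' @param condition label carried into the summary.
#' @return list of class `"population_summary"`.
#' @export
summarize_population <- function(fits, condition = NA_character_) {
  if (length(fits) < 1L) stop("no fits to summarise", call. = FALSE)
  D <- vapply(fits, function(f) unname(f$coefficients["D"]), numeric(1L))
  a <- vapply(fits, function(f) unname(f$coefficients["alpha"]), numeric(1L))
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  structure(list(mean_D = mean(D), sem_D = sem(D),
                 mean_alpha = mean(a), sem_alpha = sem(a),
                 n_tracks = length(fits), condition = condition),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population mobility (%d tracks%s):\n", x$n_tracks,
              if (is.na(x$condition)) ""
              else paste0(", ", x$condition)))
  cat(sprintf("  D     = %.4g +/- %.2g um^2/s (mean +/- SEM)\n",
              x$mean_D, x$sem_D))
  cat(sprintf("  alpha = %.3f +/- %.3f\n", x$mean_alpha, x$sem_alpha))
  invisible(x)
}

#' Correlation of mobility parameters with cluster size
#'
#' Spearman rank correlation of the fitted `D` and `alpha` against cluster
#' diameter. Rank-based because `D` is right-skewed and the expected
#' relation (larger clusters diffuse more slowly) is monotone, not linear.
#'
#' @param fits list of `"msd_fit"` objects.
#' @param diameters cluster diameters (um), one per fit.
#' @return data frame with one row per parameter: `parameter`, `rho`,
#'   `p_value`, `n`.
#' @export
size_mobility_relation <- function(fits, diameters) {
  if (length(fits) != length(diameters) || length(fits) < 3L) {
    stop("need paired fits and diameters for at least 3 tracks",
         call. = FALSE)
  }
  if (length(unique(diameters)) < 2L) {
    stop("degenerate ranks: diameters are all tied", call. = FALSE)
  }
  D <- vapply(fits, function(f) unname(f$coefficients["D"]), numeric(1L))
  a <- vapply(fits, function(f) unname(f$coefficients["alpha"]), numeric(1L))
  one <- function(v, nm) {
    if (length(unique(v)) < 2L) {
      stop(sprintf("degenerate ranks: %s values are all tied", nm),
           call. = FALSE)
    }
    ct <- suppressWarnings(cor.test(v, diameters, method = "spearman"))
    data.frame(parameter = nm, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(v))
  }
  rbind(one(D, "D"), one(a, "alpha"))
}

#' Compare mobility between two conditions
#'
#' Per-parameter two-sided Mann-Whitney (Wilcoxon rank-sum) tests between
#' two groups of tracks — rank-based because `D` is right-skewed. A Welch
#' t-test is available via `test = "welch"`. The effect size is reported
#' both as the ratio of group means and as the ratio of group medians (the
#' two natural readings of "x-fold smaller on average").
#'
#' @param fits_a,fits_b lists of `"msd_fit"` objects (>= 3 tracks each),
#'   e.g. untreated vs. drug-treated.
#' @param diameters_a,diameters_b optional cluster diameters (um) per group,
#'   compared the same way.
#' @param test `"wilcox"` (default) or `"welch"`.
#' @param labels group labels for printing.
#' @return object of class `"condition_comparison"`: data frame with one
#'   row per parameter: `parameter`, `mean_a`, `mean_b`, `ratio_of_means`
#'   (b/a), `ratio_of_medians`, `statistic`, `p_value`.
#' @export
compare_conditions <- function(fits_a, fits_b, diameters_a = NULL,
                               diameters_b = NULL,
                               test = c("wilcox", "welch"),
                               labels = c("a", "b")) {
  test <- match.arg(test)
  if (length(fits_a) < 3L || length(fits_b) < 3L) {
    stop("each condition needs at least 3 tracks", call. = FALSE)
  }
  pull <- function(fits, what) {
    vapply(fits, function(f) unname(f$coefficients[what]), numeric(1L))
  }
  one <- function(va, vb, nm) {
    ht <- if (test == "wilcox") {
      suppressWarnings(wilcox.test(va, vb, alternative = "two.sided"))
    } else {
      t.test(va, vb)
    }
    data.frame(parameter = nm, mean_a = mean(va), mean_b = mean(vb),
               ratio_of_means = mean(vb) / mean(va),
               ratio_of_medians = median(vb) / median(va),
               statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  out <- rbind(one(pull(fits_a, "D"), pull(fits_b, "D"), "D"),
               one(pull(fits_a, "alpha"), pull(fits_b, "alpha"), "alpha"))
  if (!is.null(diameters_a) && !is.null(diameters_b)) {
    out <- rbind(out, one(diameters_a, diameters_b, "diameter"))
  }
  structure(out, class = c("condition_comparison", "data.frame"),
            labels = labels, test = test,
            n = c(length(fits_a), length(fits_b)))
}

#' @export
print.condition_comparison <- function(x, ...) {
  lb <- attr(x, "labels")
  n <- attr(x, "n")
  cat(sprintf("Condition comparison ('%s' n = %d vs '%s' n = %d, %s test)\n",
              lb[1L], n[1L], lb[2L], n[2L],
              if (attr(x, "test") == "wilcox") "Mann-Whitney" else "Welch"))
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, 3L)
  df$flag <- ifelse(df$p_value < 0.01, "**",
                    ifelse(df$p_value < 0.05, "*", ""))
  print(df, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' Plot a family of MSD curves with their average
#'
#' Individual per-track curves as thin lines with the pointwise average
#' overlaid as a thick line, optionally for two conditions.
#'
#' @param curves list of `"msd_curve"` objects.
#' @param col line colour for the individual curves.
#' @param add add to an existing plot.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the matrix of aligned MSD values (lags x tracks).
#' @export
plot_msd_curves <- function(curves, col = "orange", add = FALSE, ...) {
  K <- min(vapply(curves, nrow, integer(1L)))
  lag <- curves[[1L]]$lag[seq_len(K)]
  M <- vapply(curves, function(cv) cv$msd[seq_len(K)], numeric(K))
  M <- matrix(M, nrow = K)
  if (!add) {
    plot(NA, xlim = range(lag), ylim = range(M), xlab = "lag time (s)",
         ylab = expression(MSD ~ (mu * m^2)), ...)
  }
  matlines(lag, M, lty = 1L, col = adjustcolor(col, 0.35))
  lines(lag, rowMeans(M), lwd = 3L, col = col)
  invisible(M)
}
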