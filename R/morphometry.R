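#' Extract an intensity profile along a line through a cluster
#'
#' Samples the image by bilinear interpolation at pixel pitch along a line
#' of half-length `half_length` through `center` at angle `angle`. The
#' profile's background is the median of the outer 10% of samples at each
#' end, a local estimate robust to neighbouring clusters.
#'
#' @param image single-channel numeric matrix.
#' @param pixel_size um per pixel.
#' @param center `(x, y)` line centre (um).
#' @param angle line direction (radians; 0 is along +x).
#' @param half_length half the line length (um).
#' @return an object of class `"intensity_profile"`: list with `offsets`
#'   (um, centred on 0, uniformly spaced at pixel pitch), `intensities`,
#'   and `background`.
#' @export
extract_profile <- function(image, pixel_size, center, angle, half_length) {
  stopifnot(is.matrix(image))
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(half_length, "half_length")
  offsets <- seq(-half_length, half_length, by = pixel_size)
  xs <- center[1L] + offsets * cos(angle)
  ys <- center[2L] + offsets * sin(angle)
  rows <- ys / pixel_size + 1
  cols <- xs / pixel_size + 1
  if (any(rows < 1 | rows > nrow(image) | cols < 1 | cols > ncol(image))) {
    stop("sampling line exits the image; shorten `half_length` or move the ",
         "center", call. = FALSE)
  }
  intensities <- bilinear(image, rows, cols)
  if (max(intensities) - min(intensities) <= 0) {
    stop("flat profile: no intensity variation along the sampling line",
         call. = FALSE)
  }
  n_edge <- max(1L, floor(0.1 * length(offsets)))
  background <- median(c(head(intensities, n_edge),
                         tail(intensities, n_edge)))
  structure(list(offsets = offsets, intensities = intensities,
                 background = background),
            class = "intensity_profile")
}

#' Full width at half maximum of an intensity profile
#'
#' The cluster diameter measure: the half-maximum level is
#' `background + (peak - background) / 2`; the two crossings nearest the
#' peak (one on each side) are located by linear interpolation between the
#' bracketing samples, and their distance is returned. Taking the crossings
#' nearest the peak makes the measure robust to neighbouring structures that
#' put additional crossings further out on the line.
#'
#' @param profile an `"intensity_profile"` from [extract_profile()], or any
#'   list with `offsets`, `intensities` and optionally `background` (default
#'   0).
#' @return the FWHM (um).
#' @export
fwhm <- function(profile) {
  off <- profile$offsets
  ii <- profile$intensities
  bg <- profile$background %||% 0
  ipk <- which.max(ii)
  peak <- ii[ipk]
  if (peak <= bg) {
    stop("peak intensity does not exceed background", call. = FALSE)
  }
  level <- bg + (peak - bg) / 2

  cross_at <- function(i) {
    # linear interpolation of the level crossing between samples i and i+1
    off[i] + (level - ii[i]) / (ii[i + 1L] - ii[i]) * (off[i + 1L] - off[i])
  }
  left <- NA_real_
  for (i in seq(ipk - 1L, 1L, length.out = max(ipk - 1L, 0L))) {
    if (ii[i] <= level && ii[i + 1L] > level) { left <- cross_at(i); break }
  }
  right <- NA_real_
  for (i in seq(ipk, length(ii) - 1L,
                length.out = max(length(ii) - ipk, 0L))) {
    if (ii[i] > level && ii[i + 1L] <= level) { right <- cross_at(i); break }
  }
  if (is.na(left) || is.na(right)) {
    stop("unbounded peak: fewer than two half-maximum crossings (peak at ",
         "profile edge?)", call. = FALSE)
  }
  right - left
}

#' Measure one cluster's two-channel FWHM diameters
#'
#' For a red-core / green-shell cluster, measures the FWHM diameter in each
#' channel on the same sampling lines and computes the relative size
#' increase `(d_g - d_r) / d_r`. The manual step of picking a diameter by
#' eye is automated as the mean FWHM over `n_angles` evenly spaced line
#' directions through the intensity-weighted centroid (unbiased for round
#' clusters); set `n_angles = 1` and `angle` for a single fixed direction.
#'
#' @param image a [two_channel_image()].
#' @param center approximate `(x, y)` cluster centre (um).
#' @param half_length profile half-length (um); must comfortably exceed the
#'   cluster radius.
#' @param n_angles number of evenly spaced diameter directions (over pi).
#' @param angle first direction (radians).
#' @param refine_center if `TRUE`, replace `center` by the red-channel
#'   intensity-weighted centroid within `half_length` of it.
#' @param cluster_id,cell_id identifiers carried into the record.
#' @return one-row data frame: `cluster_id`, `cell_id`, `d_r_um`, `d_g_um`,
#'   `rel_increase`.
#' @export
measure_cluster <- function(image, center, half_length, n_angles = 8L,
                            angle = 0, refine_center = TRUE,
                            cluster_id = "cluster_1", cell_id = "cell_1") {
  stopifnot(inherits(image, "two_channel_image"))
  ps <- image$pixel_size
  if (refine_center) {
    center <- centroid_refine(image$red, ps, center, half_length)
  }
  angles <- angle + seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  mean_fwhm <- function(channel) {
    vals <- vapply(angles, function(a) {
      fwhm(extract_profile(channel, ps, center, a, half_length))
    }, numeric(1L))
    mean(vals)
  }
  d_r <- tryCatch(mean_fwhm(image$red),
                  error = function(e) stop("red channel: ",
                                           conditionMessage(e), call. = FALSE))
  d_g <- tryCatch(mean_fwhm(image$green),
                  error = function(e) stop("green channel: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  data.frame(cluster_id = cluster_id, cell_id = cell_id,
             d_r_um = d_r, d_g_um = d_g,
             rel_increase = (d_g - d_r) / d_r)
}

# Intensity-weighted centroid of the background-subtracted window of
# half-width `half_length` around `center` (um in, um out).
centroid_refine <- function(channel, pixel_size, center, half_length) {
  h <- ceiling(half_length / pixel_size)
  r0 <- max(1L, round(center[2L] / pixel_size + 1) - h)
  r1 <- min(nrow(channel), round(center[2L] / pixel_size + 1) + h)
  c0 <- max(1L, round(center[1L] / pixel_size + 1) - h)
  c1 <- min(ncol(channel), round(center[1L] / pixel_size + 1) + h)
  win <- channel[r0:r1, c0:c1, drop = FALSE]
  w <- pmax(win - median(win), 0)
  if (sum(w) == 0) return(center)
  rows <- r0:r1
  cols <- c0:c1
  rc <- sum(rowSums(w) * rows) / sum(w)
  cc <- sum(colSums(w) * cols) / sum(w)
  c((cc - 1) * pixel_size, (rc - 1) * pixel_size)
}

#' Measure many clusters from a centers table
#'
#' @param image a [two_channel_image()].
#' @param centers data frame with columns `cluster_id`, `cell_id`, `x_um`,
#'   `y_um` (the schema of a detection table or a hand-picked CSV).
#' @param ... passed to [measure_cluster()].
#' @return data frame of growth records, one row per measurable cluster;
#'   clusters whose measurement fails are dropped with a warning and counted
#'   in the `"n_failed"` attribute.
#' @export
measure_clusters <- function(image, centers, ...) {
  needed <- c("cluster_id", "cell_id", "x_um", "y_um")
  if (!all(needed %in% names(centers))) {
    stop("`centers` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  rows <- vector("list", nrow(centers))
  failed <- 0L
  for (i in seq_len(nrow(centers))) {
    rows[[i]] <- tryCatch(
      measure_cluster(image, c(centers$x_um[i], centers$y_um[i]), ...,
                      cluster_id = centers$cluster_id[i],
                      cell_id = centers$cell_id[i]),
      error = function(e) {
        warning(sprintf("cluster '%s' dropped: %s", centers$cluster_id[i],
                        conditionMessage(e)), call. = FALSE)
        failed <<- failed + 1L
        NULL
      })
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cluster_id = character(),
                                      cell_id = character(),
                                      d_r_um = numeric(), d_g_um = numeric(),
                                      rel_increase = numeric())
  attr(out, "n_failed") <- failed
  out
}

#' Summarise relative cluster growth
#'
#' Mean and standard error of the relative size increase
#' `(d_g - d_r) / d_r`. The SEM is computed over clusters by default
#' (`n` = number of clusters); `by = "cell"` first averages within each cell
#' and reports the SEM over cells — both units are meaningful when several
#' clusters per cell are measured.
#'
#' @param records growth-record data frame from [measure_clusters()].
#' @param by unit for the SEM: `"cluster"` or `"cell"`.
#' @return list of class `"growth_summary"`: `mean_rel_increase`,
#'   `sem_rel_increase`, `n_clusters`, `n_cells`, `by`.
#' @export
summarize_growth <- function(records, by = c("cluster", "cell")) {
  by <- match.arg(by)
  if (is.null(records) || nrow(records) < 1L) {
    stop("no growth records to summarise", call. = FALSE)
  }
  vals <- if (by == "cluster") records$rel_increase
          else tapply(records$rel_increase, records$cell_id, mean)
  m <- mean(vals)
  sem <- if (length(vals) > 1L) sd(vals) / sqrt(length(vals)) else 0
  structure(list(mean_rel_increase = m, sem_rel_increase = sem,
                 n_clusters = nrow(records),
                 n_cells = length(unique(records$cell_id)), by = by),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf(paste0("Relative cluster size increase: %.1f%% +/- %.1f%% ",
                     "(SEM over %ss)\n  %d clusters in %d cells\n"),
              100 * x$mean_rel_increase, 100 * x$sem_rel_increase, x$by,
              x$n_clusters, x$n_cells))
  invisible(x)
}
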