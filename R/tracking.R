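# Spot detection and frame-to-frame linking.

# Scale-normalised Laplacian-of-Gaussian kernel (sign-flipped so bright
# blobs give positive responses).
log_kernel <- function(sigma_px) {
  h <- max(2L, ceiling(4 * sigma_px))
  g <- seq(-h, h)
  d2 <- outer(g^2, g^2, "+")
  k <- (d2 / sigma_px^2 - 2) * exp(-d2 / (2 * sigma_px^2))
  k <- -(k - mean(k))                      # zero-sum, bright-positive
  k / sum(k[k > 0])
}

#' Detect cluster positions in one frame
#'
#' Laplacian-of-Gaussian blob detection at a scale matched to the expected
#' cluster diameter, followed by non-maximum suppression (no two detections
#' closer than `expected_diameter / 2`) and sub-pixel refinement by a
#' three-point quadratic fit to the response peak along each axis.
#'
#' @param frame single-channel numeric matrix.
#' @param pixel_size um per pixel.
#' @param expected_diameter expected cluster diameter (um); must be at least
#'   2 pixels.
#' @param quality_threshold minimum detector response; `NULL` uses a robust
#'   automatic threshold, `median(response) + 5 * mad(response)`, with a
#'   floor at 2% of the maximum response to reject faint sidelobe maxima in
#'   low-noise frames.
#' @return data frame of spots sorted by quality descending: `x`, `y` (um),
#'   `intensity` (image value at the peak), `quality` (LoG response). Empty
#'   data frame when nothing is found.
#' @export
detect_spots <- function(frame, pixel_size, expected_diameter,
                         quality_threshold = NULL) {
  stopifnot(is.matrix(frame))
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  if (expected_diameter < 2 * pixel_size) {
    stop("`expected_diameter` must span at least 2 pixels", call. = FALSE)
  }
  sigma_px <- expected_diameter / pixel_size / (2 * sqrt(2))
  resp <- EBImage::filter2(frame, log_kernel(sigma_px))
  if (is.null(quality_threshold)) {
    # robust noise floor plus a small relative floor that rejects faint
    # sidelobe maxima in low-noise frames
    quality_threshold <- max(median(resp) + 5 * mad(resp),
                             0.02 * max(resp), .Machine$double.eps)
  }

  nr <- nrow(resp); nc <- ncol(resp)
  core <- resp[2:(nr - 1L), 2:(nc - 1L)]
  is_max <- core > quality_threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & (core >= resp[2:(nr - 1L) + dr, 2:(nc - 1L) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(x = numeric(), y = numeric(), intensity = numeric(),
                      quality = numeric()))
  }
  rows <- idx[, 1L] + 1L
  cols <- idx[, 2L] + 1L
  quality <- resp[cbind(rows, cols)]

  # sub-pixel: 1D parabola through the three samples along each axis
  para <- function(m, p, q) {
    den <- m - 2 * p + q
    ifelse(abs(den) < .Machine$double.eps, 0,
           pmin(pmax(0.5 * (m - q) / den, -0.5), 0.5))
  }
  drow <- para(resp[cbind(rows - 1L, cols)], quality,
               resp[cbind(rows + 1L, cols)])
  dcol <- para(resp[cbind(rows, cols - 1L)], quality,
               resp[cbind(rows, cols + 1L)])

  ord <- order(quality, decreasing = TRUE)
  spots <- data.frame(x = (cols[ord] + dcol[ord] - 1) * pixel_size,
                      y = (rows[ord] + drow[ord] - 1) * pixel_size,
                      intensity = frame[cbind(rows, cols)][ord],
                      quality = quality[ord])

  # non-maximum suppression: greedy by quality
  min_sep <- expected_diameter / 2
  keep <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    ki <- which(keep)
    if (!length(ki) ||
        all((spots$x[ki] - spots$x[i])^2 + (spots$y[ki] - spots$y[i])^2 >=
              min_sep^2)) {
      keep[i] <- TRUE
    }
  }
  spots[keep, , drop = FALSE]
}

#' Detect spots in every frame of a stack
#'
#' @param stack an `"image_stack"`.
#' @inheritParams detect_spots
#' @return list (one per frame) of spot data frames with an added `frame`
#'   column (0-based).
#' @export
detect_spots_stack <- function(stack, expected_diameter,
                               quality_threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  lapply(seq_along(stack$frames), function(f) {
    s <- detect_spots(stack$frames[[f]], stack$pixel_size, expected_diameter,
                      quality_threshold)
    if (nrow(s)) s$frame <- f - 1L else s$frame <- integer()
    s
  })
}

# Minimum-cost one-to-one matching between previous-frame track ends and
# current-frame spots, with a gate: candidates further apart than
# `max_displacement` can never link. Solved as a square linear assignment
# problem with auxiliary rows/columns for track termination and track birth
# (cost `gate^2` each), the standard LAP formulation for frame-to-frame
# linking.
match_frames <- function(prev_xy, cur_xy, max_displacement) {
  n1 <- nrow(prev_xy)
  n2 <- nrow(cur_xy)
  if (n1 == 0L || n2 == 0L) {
    return(list(link = integer(n1)))      # 0 = unlinked
  }
  b <- max_displacement^2
  big <- 1e6 * (b + 1)
  n <- n1 + n2
  cost <- matrix(big, n, n)
  d2 <- outer(prev_xy[, 1L], cur_xy[, 1L], "-")^2 +
        outer(prev_xy[, 2L], cur_xy[, 2L], "-")^2
  d2[d2 > b] <- big
  cost[seq_len(n1), seq_len(n2)] <- d2
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- b       # end a track
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- b       # start a track
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0         # dummy-dummy
  sol <- as.integer(clue::solve_LSAP(cost))
  link <- sol[seq_len(n1)]
  link[link > n2] <- 0L
  # safety: a gated pair must never be forced through
  for (i in seq_len(n1)) {
    if (link[i] > 0L && d2[i, link[i]] >= big) link[i] <- 0L
  }
  list(link = link)
}

#' Link detected spots into trajectories
#'
#' Frame-to-frame linking by optimal bipartite assignment (Hungarian
#' algorithm) minimising total squared displacement, gated at
#' `max_displacement`; deterministic and invariant to spot order within a
#' frame. No gap closing: a spot that disappears terminates its track, and a
#' spot with no match starts a new one. Tracks with `min_track_length` or
#' fewer points are discarded (the default keeps tracks *longer than* 150
#' frames).
#'
#' @param spots_by_frame list of per-frame spot data frames (columns `x`,
#'   `y` in um, optionally `frame`), e.g. from [detect_spots_stack()];
#'   consecutive list elements are consecutive frames.
#' @param max_displacement linking gate (um per frame).
#' @param min_track_length tracks must have strictly more points than this.
#' @param frame_interval s between frames, attached to the trajectories.
#' @return list of [trajectory()] objects, with attributes `n_total` (tracks
#'   before length filtering) and `n_dropped`.
#' @export
link_tracks <- function(spots_by_frame, max_displacement,
                        min_track_length = 150L, frame_interval = 0.5) {
  stop_if_not_scalar_pos(max_displacement, "max_displacement")
  n_frames <- length(spots_by_frame)
  tracks <- list()        # each: list(frame =, x =, y =)
  active <- integer(0)    # indices into `tracks` alive at the last frame
  for (f in seq_len(n_frames)) {
    sp <- spots_by_frame[[f]]
    cur <- if (is.null(sp) || nrow(sp) == 0L) {
      matrix(numeric(), 0L, 2L)
    } else {
      cbind(sp$x, sp$y)
    }
    prev <- if (length(active)) {
      t(vapply(tracks[active],
               function(tr) c(tr$x[length(tr$x)], tr$y[length(tr$y)]),
               numeric(2L)))
    } else {
      matrix(numeric(), 0L, 2L)
    }
    link <- if (nrow(cur)) match_frames(prev, cur, max_displacement)$link
            else integer(nrow(prev))
    taken <- logical(nrow(cur))
    new_active <- integer(0)
    for (i in seq_along(active)) {
      j <- link[i]
      if (j > 0L) {
        ti <- active[i]
        tracks[[ti]]$frame <- c(tracks[[ti]]$frame, f - 1L)
        tracks[[ti]]$x <- c(tracks[[ti]]$x, cur[j, 1L])
        tracks[[ti]]$y <- c(tracks[[ti]]$y, cur[j, 2L])
        taken[j] <- TRUE
        new_active <- c(new_active, ti)
      }
    }
    for (j in which(!taken)) {
      tracks[[length(tracks) + 1L]] <-
        list(frame = f - 1L, x = cur[j, 1L], y = cur[j, 2L])
      new_active <- c(new_active, length(tracks))
    }
    active <- new_active
  }
  n_total <- length(tracks)
  keep <- vapply(tracks, function(tr) length(tr$frame) > min_track_length,
                 logical(1L))
  out <- lapply(which(keep), function(i) {
    trajectory(paste0("track_", i), tracks[[i]]$frame, tracks[[i]]$x,
               tracks[[i]]$y, frame_interval)
  })
  structure(out, n_total = n_total, n_dropped = n_total - length(out))
}

#' Read / write track tables
#'
#' CSV interchange for trajectories. `write_track_table` writes columns
#' `track_id`, `frame`, `t_s`, `x_um`, `y_um` (a column subset compatible
#' with common spot-export tables). `read_track_table` accepts coordinates
#' as `x_um`/`y_um` (micrometres) or `x`/`y`; plain `x`/`y` are treated as
#' micrometres unless `pixel_size` is given, in which case they are pixels
#' and are converted by multiplication.
#'
#' @param tracks list of [trajectory()] objects.
#' @param path CSV file path.
#' @return `write_track_table`: `path`, invisibly. `read_track_table`: list
#'   of trajectories.
#' @export
write_track_table <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(track_id = attr(tr, "track_id"), frame = tr$frame,
               t_s = tr$t, x_um = tr$x, y_um = tr$y,
               condition = attr(tr, "condition"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_table
#' @param frame_interval s between frames (required on read: the table
#'   stores frame indices).
#' @param pixel_size if given, plain `x`/`y` columns are pixels and are
#'   converted to um.
#' @export
read_track_table <- function(path, frame_interval, pixel_size = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("track_id", "frame") %in% names(tab))) {
    stop("track table must have columns `track_id` and `frame`",
         call. = FALSE)
  }
  if (all(c("x_um", "y_um") %in% names(tab))) {
    tab$..x <- tab$x_um
    tab$..y <- tab$y_um
  } else if (all(c("x", "y") %in% names(tab))) {
    s <- if (is.null(pixel_size)) 1 else pixel_size
    tab$..x <- tab$x * s
    tab$..y <- tab$y * s
  } else {
    stop("track table must have coordinate columns `x_um`/`y_um` or `x`/`y`",
         call. = FALSE)
  }
  has_cond <- "condition" %in% names(tab)
  lapply(split(tab, tab$track_id), function(d) {
    if (any(diff(d$frame) <= 0)) {
      stop(sprintf(
        "track '%s': frames must be strictly increasing within the track",
        d$track_id[1L]), call. = FALSE)
    }
    trajectory(d$track_id[1L], d$frame, d$..x, d$..y, frame_interval,
               condition = if (has_cond) d$condition[1L] else NA_character_)
  })
}
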