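#' Construct a trajectory
#'
#' A trajectory is one cluster's time-ordered 2D positions in physical units
#' (micrometres), with its acquisition interval and an optional condition
#' label (e.g. `"untreated"`, `"nocodazole"`) and cluster diameter.
#'
#' @param track_id identifier (coerced to character).
#' @param frame integer frame indices, strictly increasing, starting anywhere
#'   `>= 0`.
#' @param x,y positions (um), same length as `frame`.
#' @param frame_interval time between consecutive frames (s).
#' @param condition optional condition label.
#' @param diameter optional cluster diameter (um), e.g. from morphometry.
#' @return an object of class `"trajectory"`: a data frame with columns
#'   `frame`, `t`, `x`, `y` and attributes `track_id`, `frame_interval`,
#'   `condition`, `diameter`.
#' @export
trajectory <- function(track_id, frame, x, y, frame_interval,
                       condition = NA_character_, diameter = NA_real_) {
  frame <- as.integer(frame)
  if (length(frame) < 2L) stop("a trajectory needs at least 2 points", call. = FALSE)
  if (any(diff(frame) <= 0L)) {
    stop(sprintf("track '%s': frames must be strictly increasing", track_id),
         call. = FALSE)
  }
  if (length(x) != length(frame) || length(y) != length(frame)) {
    stop("`x`, `y` and `frame` must have equal length", call. = FALSE)
  }
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  out <- data.frame(frame = frame, t = frame * frame_interval,
                    x = as.numeric(x), y = as.numeric(y))
  structure(out, class = c("trajectory", "data.frame"),
            track_id = as.character(track_id),
            frame_interval = frame_interval,
            condition = condition, diameter = diameter)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'> %d points, dt = %g s%s\n",
              attr(x, "track_id"), nrow(x), attr(x, "frame_interval"),
              if (is.na(attr(x, "condition"))) ""
              else paste0(", condition = ", attr(x, "condition"))))
  print(head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

is_trajectory <- function(x) inherits(x, "trajectory")
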