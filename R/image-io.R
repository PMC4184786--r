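# TIFF and sidecar I/O. Images are stored as 16-bit greyscale TIFF pages
# (photon counts clipped to [0, 65535] and rounded), which is lossless for
# the photon ranges the renderer produces.

tiff_encode <- function(mat) pmin(pmax(mat, 0), 65535) / 65535
tiff_decode <- function(mat) mat * 65535

#' Write / read a time series as a multi-page TIFF
#'
#' @param stack an `"image_stack"` (list of frame matrices, `pixel_size`,
#'   `frame_interval`), as produced by [render_movie()].
#' @param path output file.
#' @return `write_image_stack` returns `path` invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(lapply(stack$frames, tiff_encode), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @param pixel_size,frame_interval calibration to attach on read (TIFF
#'   pages carry no physical units here).
#' @return `read_image_stack` returns an `"image_stack"`.
#' @export
read_image_stack <- function(path, pixel_size, frame_interval) {
  pages <- tiff::readTIFF(path, all = TRUE)
  structure(list(frames = lapply(pages, tiff_decode),
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "image_stack")
}

#' Write / read a two-channel image as a two-page TIFF (red, green)
#'
#' @param image a [two_channel_image()].
#' @param path file path.
#' @return `write_two_channel_tiff` returns `path` invisibly;
#'   `read_two_channel_tiff` a [two_channel_image()].
#' @export
write_two_channel_tiff <- function(image, path) {
  stopifnot(inherits(image, "two_channel_image"))
  tiff::writeTIFF(list(tiff_encode(image$red), tiff_encode(image$green)),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_two_channel_tiff
#' @param pixel_size um per pixel to attach on read.
#' @export
read_two_channel_tiff <- function(path, pixel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L) {
    stop(sprintf("expected a 2-page TIFF (red, green), found %d page(s)",
                 length(pages)), call. = FALSE)
  }
  two_channel_image(tiff_decode(pages[[1L]]), tiff_decode(pages[[2L]]),
                    pixel_size)
}

#' Write simulation ground truth and its configuration sidecar
#'
#' The ground-truth table goes to CSV and the full configuration (including
#' the seed) to a JSON sidecar next to it, so any rendered dataset can be
#' regenerated bit-for-bit.
#'
#' @param truth ground-truth data frame.
#' @param cfg the `track_sim_config` / `image_sim_config` that produced it.
#' @param path CSV output path; the sidecar is `paste0(path, ".json")`.
#' @return `path` invisibly.
#' @export
write_ground_truth <- function(truth, cfg, path) {
  write.csv(truth, path, row.names = FALSE)
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
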