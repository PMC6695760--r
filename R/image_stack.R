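#' Time-lapse image stack
#'
#' Container for a time-ordered stack of 2D grayscale frames together with
#' the physical calibration needed by all downstream analyses: the pixel
#' size (micrometres per pixel) and the frame interval (seconds).
#'
#' Pixel coordinate convention: pixel centres sit at integer coordinates,
#' origin at the top-left pixel, `x` runs along columns and `y` along rows
#' (so `frame[y, x]` addresses the pixel whose centre is at `(x, y)` px).
#' Physical positions are `x_um = x * pixel_size_um`.
#'
#' @param frames numeric 3D array `[ny, nx, n_frames]`, or a list of equally
#'   sized matrices (converted).
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param frame_interval_s time between consecutive frames in seconds.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_s) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must have identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a [ny, nx, n_frames] array or a list of matrices")
  stopifnot(pixel_size_um > 0, frame_interval_s > 0)
  structure(
    list(frames = frames,
         pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "image_stack: %d frame(s) of %d x %d px, %.4g um/px, dt = %.4g s\n",
    d[3L], d[1L], d[2L], x$pixel_size_um, x$frame_interval_s))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack an `image_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3L]

#' @export
plot.image_stack <- function(x, frame = 1L, ...) {
  f <- x$frames[, , frame]
  graphics::image(t(f)[, nrow(f):1], col = grDevices::gray.colors(256),
                  asp = nrow(f) / ncol(f), axes = FALSE,
                  main = sprintf("frame %d", frame), ...)
  invisible(x)
}

# 16-bit scale used for TIFF round-trips (counts are stored as counts/65535)
.tiff_max <- 65535

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Pixel counts are clipped to `[0, 65535]` and stored as 16-bit samples.
#' Calibration (pixel size, frame interval) is written both in an
#' ImageJ-style description tag and in a JSON sidecar `<path>.json`, because
#' baseline TIFF has no standard slot for them.
#'
#' @param stack an `image_stack`.
#' @param path output file path (`.tif`).
#' @param sidecar write the JSON calibration sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, sidecar = TRUE) {
  fr <- stack$frames
  fr[fr < 0] <- 0
  fr[fr > .tiff_max] <- .tiff_max
  pages <- lapply(seq_len(dim(fr)[3L]), function(i) fr[, , i] / .tiff_max)
  desc <- sprintf(
    "ImageJ=1.53t\nimages=%d\nframes=%d\nfinterval=%g\nunit=um",
    length(pages), length(pages), stack$frame_interval_s)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                            description = desc),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (sidecar) {
    jsonlite::write_json(
      list(pixel_size_um = stack$pixel_size_um,
           frame_interval_s = stack$frame_interval_s,
           n_frames = dim(fr)[3L]),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' Calibration is taken from the JSON sidecar when present, otherwise from
#' the arguments.
#'
#' @param path TIFF file path.
#' @param pixel_size_um,frame_interval_s calibration fallbacks used when no
#'   sidecar is found.
#' @return an `image_stack` with integer counts restored.
#' @export
read_stack_tiff <- function(path, pixel_size_um = 0.1, frame_interval_s = 0.15) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    pixel_size_um <- meta$pixel_size_um
    frame_interval_s <- meta$frame_interval_s
  }
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # collapse any palette channel
    round(p * .tiff_max)
  })
  image_stack(frames, pixel_size_um, frame_interval_s)
}
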