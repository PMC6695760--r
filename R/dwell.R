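#' Build a kymograph along a line through a movie
#'
#' For every frame, samples intensity by bilinear interpolation at 1-px
#' spacing along the line and averages over `width_px` parallel offsets
#' perpendicular to it; the samples form one kymograph column, so the
#' result is a position-by-time image of membrane residence.
#'
#' @param stack an [image_stack].
#' @param line numeric `c(x0, y0, x1, y1)` endpoints in px (pixel centres
#'   at integers); must lie inside the field.
#' @param width_px number of perpendicular offsets averaged (odd; 1 = the
#'   bare line).
#' @return a `kymograph`: `intensity` matrix `[n_samples, n_frames]`,
#'   `line`, `width_px`, `frame_interval_s`, `sample_spacing_px`.
#' @export
build_kymograph <- function(stack, line, width_px = 1L) {
  stopifnot(inherits(stack, "image_stack"), length(line) == 4L,
            width_px >= 1L)
  ny <- dim(stack$frames)[1L]; nx <- dim(stack$frames)[2L]
  x0 <- line[1L]; y0 <- line[2L]; x1 <- line[3L]; y1 <- line[4L]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len == 0) stop("zero-length line")
  if (min(x0, x1) < 1 || max(x0, x1) > nx || min(y0, y1) < 1 ||
      max(y0, y1) > ny)
    stop("line endpoints must lie inside the field")
  ns <- ceiling(len) + 1L
  tt <- seq(0, 1, length.out = ns)
  sx <- x0 + tt * (x1 - x0)
  sy <- y0 + tt * (y1 - y0)
  # unit normal for the width averaging
  ux <- -(y1 - y0) / len; uy <- (x1 - x0) / len
  offs <- seq_len(width_px) - (width_px + 1) / 2
  nf <- n_frames(stack)
  kymo <- matrix(0, ns, nf)
  for (f in seq_len(nf)) {
    img <- stack$frames[, , f]
    acc <- numeric(ns)
    for (o in offs)
      acc <- acc + .bilinear(img, sx + o * ux, sy + o * uy)
    kymo[, f] <- acc / length(offs)
  }
  structure(list(intensity = kymo, line = line, width_px = width_px,
                 frame_interval_s = stack$frame_interval_s,
                 sample_spacing_px = len / (ns - 1L)),
            class = "kymograph")
}

# bilinear interpolation at (x, y) vectors; out-of-field samples clamp to edge
.bilinear <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1L)
  i10 <- cbind(y0 + 1L, x0); i11 <- cbind(y0 + 1L, x0 + 1L)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d position(s) x %d frame(s), dt = %g s, width %d px\n",
              nrow(x$intensity), ncol(x$intensity), x$frame_interval_s,
              x$width_px))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(seq_len(ncol(x$intensity)) * x$frame_interval_s,
                  seq_len(nrow(x$intensity)),
                  t(x$intensity), col = grDevices::gray.colors(256),
                  xlab = "time (s)", ylab = "position (px)", ...)
  invisible(x)
}

#' Membrane dwell time from one fluorescence trace
#'
#' Normalizes a background-subtracted intensity trace to its maximum and
#' measures the longest contiguous run of frames above `threshold_frac`
#' (half-maximum by default); dwell time is run length times the frame
#' interval. The estimate is invariant to positive scaling of the trace. A
#' run touching the first or last frame is flagged censored (the particle
#' was already, or still, present outside the recording).
#'
#' @param trace numeric per-frame intensity of one tracked particle,
#'   background-subtracted.
#' @param frame_interval_s frame interval (s).
#' @param threshold_frac presence threshold as a fraction of the trace
#'   maximum, default 0.5.
#' @return a `dwell_record` list: `dwell_s`, `n_frames`, `start_frame`,
#'   `end_frame`, `censored`, `trace_norm`.
#' @export
dwell_time <- function(trace, frame_interval_s, threshold_frac = 0.5) {
  stopifnot(is.numeric(trace), length(trace) >= 1L, frame_interval_s > 0,
            threshold_frac > 0, threshold_frac < 1)
  m <- max(trace)
  if (!is.finite(m) || m <= 0)
    stop("dwell refused: trace has no positive signal")
  tn <- trace / m
  above <- tn >= threshold_frac
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  n_run <- r$lengths[best]
  s <- starts[best]; e <- ends[best]
  structure(list(dwell_s = n_run * frame_interval_s, n_frames = n_run,
                 start_frame = s, end_frame = e,
                 censored = s == 1L || e == length(trace),
                 trace_norm = tn),
            class = "dwell_record")
}

#' @export
print.dwell_record <- function(x, ...) {
  cat(sprintf("dwell_record: %.3g s (%d frames, frames %d-%d%s)\n",
              x$dwell_s, x$n_frames, x$start_frame, x$end_frame,
              if (x$censored) ", censored" else ""))
  invisible(x)
}

#' Dwell records for a matrix of traces
#'
#' @param traces matrix `[n_particles, n_frames]` of background-subtracted
#'   intensity traces (e.g. from [simulate_particle_traces()]).
#' @param frame_interval_s frame interval (s).
#' @param threshold_frac presence threshold, see [dwell_time()].
#' @return data.frame: `id`, `dwell_s`, `n_frames`, `censored`.
#' @export
dwell_records <- function(traces, frame_interval_s, threshold_frac = 0.5) {
  stopifnot(is.matrix(traces))
  rows <- lapply(seq_len(nrow(traces)), function(i) {
    r <- tryCatch(dwell_time(traces[i, ], frame_interval_s, threshold_frac),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(id = i, dwell_s = r$dwell_s, n_frames = r$n_frames,
               censored = r$censored)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(id = integer(0), dwell_s = numeric(0),
                      n_frames = integer(0), censored = logical(0)))
  do.call(rbind, rows)
}

#' Dwell records from tracked trajectories
#'
#' Uses each trajectory's observed lifetime (first to last linked frame)
#' directly: the kymograph band a human would measure is exactly the
#' particle's presence interval, which the tracker already gives. Tracks
#' touching the first or last movie frame are censored.
#'
#' @param traj a `trajectories` data.frame.
#' @param n_movie_frames total frames in the movie (for right-censoring).
#' @return data.frame: `id`, `dwell_s`, `n_frames`, `censored`.
#' @export
dwell_from_trajectories <- function(traj, n_movie_frames) {
  dt <- attr(traj, "frame_interval_s")
  tracks <- split_trajectories(traj)
  if (!length(tracks))
    return(data.frame(id = integer(0), dwell_s = numeric(0),
                      n_frames = integer(0), censored = logical(0)))
  out <- do.call(rbind, lapply(names(tracks), function(id) {
    fr <- tracks[[id]]$frame
    data.frame(id = as.integer(id),
               dwell_s = (max(fr) - min(fr) + 1L) * dt,
               n_frames = max(fr) - min(fr) + 1L,
               censored = min(fr) == 1L || max(fr) == n_movie_frames)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize dwell records for one condition
#'
#' Censored records are excluded from the mean/SD and counted separately.
#'
#' @param records data.frame with `dwell_s` and `censored` columns.
#' @param condition_label label carried in the summary.
#' @return a `dwell_summary` list: `condition`, `mean_s`, `sd_s`, `n`,
#'   `n_censored`.
#' @export
summarize_dwell <- function(records, condition_label = "condition") {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("dwell_s", "censored") %in% names(records)))
  ok <- !records$censored
  structure(list(condition = condition_label,
                 mean_s = if (any(ok)) mean(records$dwell_s[ok]) else NA_real_,
                 sd_s = if (sum(ok) > 1L) stats::sd(records$dwell_s[ok])
                 else NA_real_,
                 n = sum(ok), n_censored = sum(!ok)),
            class = "dwell_summary")
}

#' @export
print.dwell_summary <- function(x, ...) {
  cat(sprintf("dwell [%s]: %.3g +/- %.3g s (n = %d, %d censored excluded)\n",
              x$condition, x$mean_s, x$sd_s, x$n, x$n_censored))
  invisible(x)
}
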