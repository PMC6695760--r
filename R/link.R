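#' Link per-frame spot detections into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame assignment with gap closing:
#' candidate (track end, detection) pairs are gated at
#' `max_disp_px * g` for a `g`-frame step (so a track missing for one frame
#' may reconnect at up to twice the single-frame gate), sorted by distance
#' with deterministic tie-breaking (distance, then track id, then detection
#' id), and assigned greedily so each detection joins at most one
#' trajectory. Tracks unmatched for more than `max_gap_frames` frames are
#' closed. Trajectories shorter than `min_length` detections are discarded.
#'
#' The assignment is invariant to the ordering of detections within a
#' frame.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (px) and
#'   optionally `intensity`; e.g. from [detect_spots_stack()].
#' @param max_disp_px maximum displacement per frame step (px).
#' @param max_gap_frames maximum number of consecutive missed frames that
#'   can be bridged (0 = no gap closing).
#' @param min_length minimum number of detections per kept trajectory.
#' @param pixel_size_um pixel size used to export positions in um.
#' @param frame_interval_s frame interval attached to the result (s).
#' @return a `trajectories` data.frame: `id`, `frame`, `x_um`, `y_um`,
#'   `intensity`, with `pixel_size_um` and `frame_interval_s` attributes.
#' @export
link_spots <- function(detections, max_disp_px, max_gap_frames = 1L,
                       min_length = 5L, pixel_size_um = 0.1,
                       frame_interval_s = 0.15) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y") %in% names(detections)),
            max_disp_px > 0, max_gap_frames >= 0, min_length >= 1)
  if (!"intensity" %in% names(detections)) detections$intensity <- NA_real_
  if (!nrow(detections)) return(.empty_trajectories(pixel_size_um,
                                                    frame_interval_s))
  # canonical within-frame order so input permutations cannot matter
  detections <- detections[order(detections$frame, detections$x,
                                 detections$y), , drop = FALSE]

  tracks <- list()       # each: list(rows = data.frame, last_frame)
  open <- integer(0)     # indices of open tracks
  for (f in sort(unique(detections$frame))) {
    det <- detections[detections$frame == f, , drop = FALSE]
    nd <- nrow(det)
    # close tracks that fell out of the gap window
    if (length(open)) {
      last <- vapply(tracks[open], `[[`, numeric(1), "last_frame")
      open <- open[f - last <= max_gap_frames + 1L]
    }
    assigned_det <- rep(FALSE, nd)
    if (length(open) && nd) {
      last <- vapply(tracks[open], `[[`, numeric(1), "last_frame")
      lx <- vapply(tracks[open], function(t) t$last_x, numeric(1))
      ly <- vapply(tracks[open], function(t) t$last_y, numeric(1))
      g <- f - last
      dmat <- sqrt(outer(lx, det$x, `-`)^2 + outer(ly, det$y, `-`)^2)
      gate <- matrix(max_disp_px * g, nrow = length(open), ncol = nd)
      ok <- which(dmat <= gate, arr.ind = TRUE)
      if (nrow(ok)) {
        ord <- order(dmat[ok], open[ok[, 1L]], ok[, 2L])
        used_tr <- rep(FALSE, length(open))
        for (k in ord) {
          ti <- ok[k, 1L]; di <- ok[k, 2L]
          if (used_tr[ti] || assigned_det[di]) next
          used_tr[ti] <- TRUE
          assigned_det[di] <- TRUE
          idx <- open[ti]
          tracks[[idx]]$rows <- rbind(tracks[[idx]]$rows, det[di, ])
          tracks[[idx]]$last_frame <- f
          tracks[[idx]]$last_x <- det$x[di]
          tracks[[idx]]$last_y <- det$y[di]
        }
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- list(rows = det[di, ], last_frame = f,
                                            last_x = det$x[di],
                                            last_y = det$y[di])
      open <- c(open, length(tracks))
    }
  }

  keep <- vapply(tracks, function(t) nrow(t$rows) >= min_length, logical(1))
  tracks <- tracks[keep]
  if (!length(tracks)) return(.empty_trajectories(pixel_size_um,
                                                  frame_interval_s))
  res <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    r <- tracks[[i]]$rows
    data.frame(id = i, frame = r$frame, x_um = r$x * pixel_size_um,
               y_um = r$y * pixel_size_um, intensity = r$intensity)
  }))
  rownames(res) <- NULL
  attr(res, "pixel_size_um") <- pixel_size_um
  attr(res, "frame_interval_s") <- frame_interval_s
  class(res) <- c("trajectories", "data.frame")
  res
}

.empty_trajectories <- function(pixel_size_um, frame_interval_s) {
  res <- data.frame(id = integer(0), frame = integer(0), x_um = numeric(0),
                    y_um = numeric(0), intensity = numeric(0))
  attr(res, "pixel_size_um") <- pixel_size_um
  attr(res, "frame_interval_s") <- frame_interval_s
  class(res) <- c("trajectories", "data.frame")
  res
}

#' @export
print.trajectories <- function(x, ...) {
  cat(sprintf("trajectories: %d track(s), %d localization(s), dt = %g s\n",
              length(unique(x$id)), nrow(x),
              attr(x, "frame_interval_s")))
  invisible(x)
}

#' Split a trajectories table into a per-track list
#' @param traj a `trajectories` data.frame.
#' @return named list of per-track data.frames (frame, x_um, y_um,
#'   intensity), each carrying the `frame_interval_s` attribute.
#' @export
split_trajectories <- function(traj) {
  dt <- attr(traj, "frame_interval_s")
  out <- split(as.data.frame(traj)[c("frame", "x_um", "y_um", "intensity")],
               traj$id)
  lapply(out, function(d) { attr(d, "frame_interval_s") <- dt; d })
}

#' Track a movie: detect in every frame, then link
#'
#' Convenience wrapper running [detect_spots_stack()] then [link_spots()]
#' with the stack's own calibration.
#'
#' @param stack an [image_stack].
#' @param psf_sigma_px PSF standard deviation (px).
#' @param snr_threshold minimum spot SNR.
#' @param max_disp_px linking gate per frame step (px).
#' @param max_gap_frames gap-closing window (frames).
#' @param min_length minimum trajectory length (detections).
#' @return a `trajectories` data.frame.
#' @export
track_movie <- function(stack, psf_sigma_px = 1.2, snr_threshold = 5,
                        max_disp_px = 4, max_gap_frames = 1L,
                        min_length = 5L) {
  det <- detect_spots_stack(stack, psf_sigma_px, snr_threshold)
  link_spots(det, max_disp_px = max_disp_px,
             max_gap_frames = max_gap_frames, min_length = min_length,
             pixel_size_um = stack$pixel_size_um,
             frame_interval_s = stack$frame_interval_s)
}

#' Write trajectories to the interchange CSV
#' @param traj a `trajectories` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = attr(traj, "pixel_size_um"),
         frame_interval_s = attr(traj, "frame_interval_s")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read trajectories from the interchange CSV
#' @param path CSV path written by [write_trajectories_csv()].
#' @param pixel_size_um,frame_interval_s fallbacks when no sidecar exists.
#' @return a `trajectories` data.frame.
#' @export
read_trajectories_csv <- function(path, pixel_size_um = 0.1,
                                  frame_interval_s = 0.15) {
  d <- utils::read.csv(path)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    pixel_size_um <- meta$pixel_size_um
    frame_interval_s <- meta$frame_interval_s
  }
  attr(d, "pixel_size_um") <- pixel_size_um
  attr(d, "frame_interval_s") <- frame_interval_s
  class(d) <- c("trajectories", "data.frame")
  d
}

#' Convert simulator ground truth to trajectories
#'
#' Lets every downstream analysis run on noise-free true positions, which
#' isolates tracking error from estimator error in recovery studies.
#'
#' @param truth a `tirf_ground_truth` from [simulate_tirf_movie()].
#' @param min_length minimum trajectory length (detections).
#' @return a `trajectories` data.frame.
#' @export
truth_trajectories <- function(truth, min_length = 5L) {
  stopifnot(inherits(truth, "tirf_ground_truth"))
  pos <- truth$positions
  n_per <- table(pos$id)
  keep <- as.integer(names(n_per)[n_per >= min_length])
  pos <- pos[pos$id %in% keep, , drop = FALSE]
  res <- data.frame(id = pos$id, frame = pos$frame, x_um = pos$x_um,
                    y_um = pos$y_um, intensity = NA_real_)
  attr(res, "pixel_size_um") <- truth$params$pixel_size_um
  attr(res, "frame_interval_s") <- truth$params$frame_interval_s
  class(res) <- c("trajectories", "data.frame")
  res
}
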