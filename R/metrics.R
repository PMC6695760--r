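#' Detection precision and recall against simulator ground truth
#'
#' Matches detections to true particle positions frame by frame: pairs
#' within `radius_px` are assigned greedily by increasing distance, one to
#' one. Precision = matched detections / all detections; recall = matched
#' true positions / all true positions.
#'
#' @param detections data.frame with `frame`, `x`, `y` in px (from
#'   [detect_spots_stack()]).
#' @param truth a `tirf_ground_truth` (positions in um).
#' @param radius_px match radius (px), default 1.
#' @return list: `precision`, `recall`, `n_detections`, `n_truth`,
#'   `n_matched`, `rmse_px` (localization error of matched pairs).
#' @export
detection_metrics <- function(detections, truth, radius_px = 1) {
  stopifnot(inherits(truth, "tirf_ground_truth"))
  px <- truth$params$pixel_size_um
  tp <- truth$positions
  n_match <- 0L
  sq_err <- numeric(0)
  for (f in unique(tp$frame)) {
    tf <- tp[tp$frame == f, , drop = FALSE]
    df <- detections[detections$frame == f, , drop = FALSE]
    if (!nrow(df)) next
    d <- sqrt(outer(tf$x_um / px, df$x, `-`)^2 +
                outer(tf$y_um / px, df$y, `-`)^2)
    ok <- which(d <= radius_px, arr.ind = TRUE)
    if (!nrow(ok)) next
    ord <- order(d[ok])
    used_t <- rep(FALSE, nrow(tf)); used_d <- rep(FALSE, nrow(df))
    for (k in ord) {
      ti <- ok[k, 1L]; di <- ok[k, 2L]
      if (used_t[ti] || used_d[di]) next
      used_t[ti] <- TRUE; used_d[di] <- TRUE
      n_match <- n_match + 1L
      sq_err <- c(sq_err, d[ti, di]^2)
    }
  }
  list(precision = if (nrow(detections)) n_match / nrow(detections) else NA,
       recall = if (nrow(tp)) n_match / nrow(tp) else NA,
       n_detections = nrow(detections), n_truth = nrow(tp),
       n_matched = n_match,
       rmse_px = if (length(sq_err)) sqrt(mean(sq_err)) else NA_real_)
}

#' Trajectory purity against simulator ground truth
#'
#' Assigns every localization of every recovered trajectory to the nearest
#' true particle within `radius_px` in its frame. A trajectory is pure when
#' all its assigned localizations belong to one true particle (no merges /
#' identity swaps).
#'
#' @param traj a `trajectories` data.frame (positions in um).
#' @param truth a `tirf_ground_truth`.
#' @param radius_px assignment radius (px).
#' @return list: `purity` (fraction of pure trajectories),
#'   `n_trajectories`, `n_pure`.
#' @export
trajectory_purity <- function(traj, truth, radius_px = 2) {
  stopifnot(inherits(truth, "tirf_ground_truth"))
  px <- truth$params$pixel_size_um
  tp <- truth$positions
  tracks <- split_trajectories(traj)
  pure <- vapply(tracks, function(tr) {
    ids <- integer(0)
    for (r in seq_len(nrow(tr))) {
      tf <- tp[tp$frame == tr$frame[r], , drop = FALSE]
      if (!nrow(tf)) next
      d <- sqrt((tf$x_um - tr$x_um[r])^2 + (tf$y_um - tr$y_um[r])^2) / px
      if (min(d) <= radius_px) ids <- c(ids, tf$id[which.min(d)])
    }
    length(ids) > 0L && length(unique(ids)) == 1L
  }, logical(1))
  list(purity = if (length(pure)) mean(pure) else NA_real_,
       n_trajectories = length(pure), n_pure = sum(pure))
}
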