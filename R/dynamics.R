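#' Time-averaged mean square displacement of one trajectory
#'
#' For lag `k`, averages the squared Euclidean displacement over every pair
#' of localizations exactly `k` frames apart within the trajectory
#' (time-averaged, within-particle MSD). Pairs spanning gap-closed missing
#' frames are simply absent because pairing is on true frame numbers.
#'
#' @param traj one trajectory: data.frame with `frame`, `x_um`, `y_um`
#'   (e.g. an element of [split_trajectories()]).
#' @param max_lag largest lag in frames; truncated (with a warning) to the
#'   trajectory span.
#' @param frame_interval_s frame interval (s); default taken from the
#'   trajectory's attribute.
#' @return an `msd_curve`: data.frame `lag_frames`, `lag_s`, `msd_um2`,
#'   `n_pairs`, keeping only lags with at least one pair.
#' @export
compute_msd <- function(traj, max_lag = 10L,
                        frame_interval_s = attr(traj, "frame_interval_s")) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 2L,
            all(c("frame", "x_um", "y_um") %in% names(traj)))
  if (is.null(frame_interval_s))
    stop("frame_interval_s missing: pass it or attach it as an attribute")
  o <- order(traj$frame)
  fr <- traj$frame[o]; x <- traj$x_um[o]; y <- traj$y_um[o]
  if (anyDuplicated(fr)) stop("trajectory has duplicated frames")
  span <- max(fr) - min(fr)
  if (max_lag >= span + 1L) {
    warning("max_lag exceeds trajectory span; truncating")
    max_lag <- span
  }
  lags <- seq_len(max_lag)
  msd <- rep(NA_real_, max_lag)
  npair <- integer(max_lag)
  n <- length(fr)
  for (i in seq_len(n - 1L)) {
    dk <- fr[(i + 1L):n] - fr[i]
    sel <- dk <= max_lag
    if (!any(sel)) next
    j <- which(sel)
    d2 <- (x[i + j] - x[i])^2 + (y[i + j] - y[i])^2
    for (m in seq_along(j)) {
      k <- dk[j[m]]
      npair[k] <- npair[k] + 1L
      msd[k] <- if (npair[k] == 1L) d2[m] else msd[k] + (d2[m] - msd[k]) / npair[k]
    }
  }
  keep <- npair > 0L
  res <- data.frame(lag_frames = lags[keep],
                    lag_s = lags[keep] * frame_interval_s,
                    msd_um2 = msd[keep], n_pairs = npair[keep])
  class(res) <- c("msd_curve", "data.frame")
  res
}

#' Diffusion coefficient from the short-lag MSD slope
#'
#' Ordinary least-squares line through the first `n_lags` MSD points
#' (including the implicit origin is NOT assumed: intercept is free and
#' retained as a localization-noise estimate). For free 2D diffusion
#' `MSD(t) = 4 D t`, so `D = slope / 4`. A negative slope is clamped to
#' `D = 0` and flagged rather than dropped, keeping population counts
#' interpretable.
#'
#' @param msd an `msd_curve` from [compute_msd()].
#' @param n_lags number of leading lags to fit (>= 2).
#' @return a `diffusion_estimate` list: `D_um2_s`, `intercept_um2`, `r2`,
#'   `n_lags_used`, `clamped` (TRUE when the raw slope was negative).
#' @export
fit_diffusion <- function(msd, n_lags = 2L) {
  stopifnot(inherits(msd, "msd_curve") || is.data.frame(msd))
  if (n_lags < 2L) stop("n_lags must be >= 2")
  use <- utils::head(msd, n_lags)
  if (nrow(use) < 2L)
    stop("fewer than 2 usable lags: diffusion fit refused")
  fit <- stats::lm(msd_um2 ~ lag_s, data = use)
  sl <- unname(stats::coef(fit)[2L])
  # r^2 by hand: summary.lm warns on exact lines, which are a valid input
  ss_tot <- sum((use$msd_um2 - mean(use$msd_um2))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(D_um2_s = max(sl, 0) / 4,
                 intercept_um2 = unname(stats::coef(fit)[1L]),
                 r2 = r2, n_lags_used = nrow(use), clamped = sl < 0),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g um^2/s (intercept %.4g um^2, r^2 = %.3f, %d lags%s)\n",
              x$D_um2_s, x$intercept_um2, x$r2, x$n_lags_used,
              if (x$clamped) ", slope clamped at 0" else ""))
  invisible(x)
}

#' Motion range of a trajectory
#'
#' The largest Euclidean distance between any two positions the particle
#' visited during its membrane lifetime.
#'
#' @param traj one trajectory (data.frame with `x_um`, `y_um`, >= 2 rows).
#' @return length in um.
#' @export
motion_range <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("x_um", "y_um") %in% names(traj)))
  if (nrow(traj) < 2L)
    stop("motion range undefined for a single-point trajectory")
  max(stats::dist(cbind(traj$x_um, traj$y_um)))
}

#' Per-trajectory dynamics table
#'
#' Runs [compute_msd()] + [fit_diffusion()] and [motion_range()] on every
#' trajectory of a tracking result.
#'
#' @param traj a `trajectories` data.frame.
#' @param n_lags lags used for the diffusion fit.
#' @param max_lag lags computed per MSD curve.
#' @return data.frame: `id`, `n_frames`, `D_um2_s`, `intercept_um2`, `r2`,
#'   `clamped`, `motion_range_um`, `duration_s`.
#' @export
trajectory_dynamics <- function(traj, n_lags = 2L, max_lag = 10L) {
  tracks <- split_trajectories(traj)
  dt <- attr(traj, "frame_interval_s")
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    if (nrow(tr) < max(2L, n_lags)) return(NULL)
    est <- tryCatch({
      m <- suppressWarnings(compute_msd(tr, max_lag = max_lag,
                                        frame_interval_s = dt))
      fit_diffusion(m, n_lags = min(n_lags, nrow(m)))
    }, error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(id = as.integer(id), n_frames = nrow(tr),
               D_um2_s = est$D_um2_s, intercept_um2 = est$intercept_um2,
               r2 = est$r2, clamped = est$clamped,
               motion_range_um = motion_range(tr),
               duration_s = (max(tr$frame) - min(tr$frame)) * dt)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(id = integer(0), n_frames = integer(0),
                      D_um2_s = numeric(0), intercept_um2 = numeric(0),
                      r2 = numeric(0), clamped = logical(0),
                      motion_range_um = numeric(0), duration_s = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaussian-fitted histogram peak of a per-trajectory statistic
#'
#' Histograms the values (Freedman-Diaconis binning by default), fits a
#' single Gaussian `A * exp(-(x - mu)^2 / (2 * sd^2))` to the bin
#' centre/count pairs by least squares, and reports the fitted peak
#' position — the population summary used for motion-range and
#' diffusion-coefficient distributions.
#'
#' Multimodality is not modelled: the fit describes a single population and
#' its RMSE is returned so a poor single-Gaussian description is visible.
#'
#' @param values numeric vector of a per-trajectory statistic.
#' @param statistic_name label stored with the fit
#'   (e.g. "diffusion_coefficient", "motion_range").
#' @param bins number of histogram bins, or `"FD"` for Freedman-Diaconis.
#' @param min_values refuse the fit below this many values.
#' @return a `population_fit`: `statistic`, `breaks`, `counts`, `mids`,
#'   `amplitude`, `peak` (the fitted mean), `width` (fitted SD),
#'   `rmse`, `n`.
#' @export
fit_population_peak <- function(values, statistic_name = "statistic",
                                bins = "FD", min_values = 50L) {
  values <- values[is.finite(values)]
  if (length(values) < min_values)
    stop(sprintf("population fit refused: %d values < floor of %d",
                 length(values), min_values))
  if (stats::sd(values) == 0)
    stop("population fit refused: zero-width distribution")
  h <- if (identical(bins, "FD")) graphics::hist(values, breaks = "FD",
                                                 plot = FALSE)
  else graphics::hist(values, breaks = bins, plot = FALSE)
  if (length(h$mids) < 4L)
    h <- graphics::hist(values, breaks = 8L, plot = FALSE)
  df <- data.frame(x = h$mids, n = h$counts)
  mu0 <- stats::weighted.mean(df$x, df$n)
  sd0 <- sqrt(stats::weighted.mean((df$x - mu0)^2, df$n))
  a0 <- max(df$n)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    n ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
    start = list(A = a0, mu = mu0, s = sd0),
    lower = c(A = 0, mu = min(df$x), s = 1e-12 + diff(range(df$x)) / 1e6),
    upper = c(A = Inf, mu = max(df$x), s = diff(range(df$x))),
    control = minpack.lm::nls.lm.control(maxiter = 100))), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("population fit refused: Gaussian fit did not converge (",
         attr(fit, "condition")$message, ")")
  p <- stats::coef(fit)
  structure(list(statistic = statistic_name, breaks = h$breaks,
                 counts = h$counts, mids = h$mids,
                 amplitude = unname(p[["A"]]), peak = unname(p[["mu"]]),
                 width = abs(unname(p[["s"]])),
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(values)),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf(
    "population_fit (%s): peak = %.4g, width = %.4g, n = %d, fit RMSE = %.3g\n",
    x$statistic, x$peak, x$width, x$n, x$rmse))
  invisible(x)
}

#' @export
plot.population_fit <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h", lwd = 3, col = "grey60",
                 xlab = x$statistic, ylab = "count",
                 main = sprintf("peak = %.3g", x$peak), ...)
  xx <- seq(min(x$breaks), max(x$breaks), length.out = 200)
  graphics::lines(xx, x$amplitude * exp(-(xx - x$peak)^2 / (2 * x$width^2)),
                  col = "firebrick", lwd = 2)
  invisible(x)
}
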