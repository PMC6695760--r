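#' Maximum-likelihood monoexponential lifetime from one decay histogram
#'
#' Fits a single-exponential decay to a binned photon-arrival histogram by
#' maximizing the multinomial likelihood of the bin counts under an
#' exponential truncated to the acquisition window. Both the binning and
#' the truncation are part of the model, so no instrument-response or
#' tail-start heuristics are needed: the estimator is unbiased for
#' window >> tau and corrects the downward bias of the naive
#' mean-arrival-time estimate (see [naive_lifetime()]).
#'
#' @param histogram integer vector of photon counts per arrival-time bin.
#' @param bin_width_ns bin width (ns).
#' @param min_photons refuse the fit below this total count (default 100).
#' @param method `"ml"` (default) or `"ls"`, unweighted least squares on
#'   log-counts of non-empty bins (fast, biased at low counts; kept as a
#'   cross-check).
#' @return fitted lifetime tau (ns).
#' @export
fit_pixel_lifetime <- function(histogram, bin_width_ns, min_photons = 100L,
                               method = c("ml", "ls")) {
  method <- match.arg(method)
  stopifnot(is.numeric(histogram), all(histogram >= 0), bin_width_ns > 0)
  total <- sum(histogram)
  if (total < min_photons)
    stop(sprintf("lifetime fit refused: %d photons < floor of %d",
                 total, min_photons))
  nb <- length(histogram)
  W <- nb * bin_width_ns
  edges <- seq(0, W, length.out = nb + 1L)
  if (method == "ls") {
    mids <- edges[-1L] - bin_width_ns / 2
    pos <- histogram > 0
    if (sum(pos) < 2L) stop("lifetime fit refused: fewer than 2 occupied bins")
    fit <- stats::lm(log(histogram[pos]) ~ mids[pos])
    sl <- unname(stats::coef(fit)[2L])
    if (sl >= 0) stop("lifetime fit refused: non-decaying histogram")
    return(-1 / sl)
  }
  lo <- edges[-(nb + 1L)]
  nll <- function(tau) {
    # bin probabilities of the truncated exponential
    p <- (exp(-lo / tau) - exp(-edges[-1L] / tau)) / (1 - exp(-W / tau))
    p <- pmax(p, 1e-300)
    -sum(histogram * log(p))
  }
  stats::optimize(nll, interval = c(bin_width_ns / 20, 10 * W))$minimum
}

#' Naive lifetime estimate: mean photon-arrival time
#'
#' The empirical mean of the binned arrival times (bin midpoints). For a
#' truncated exponential this systematically underestimates tau by
#' `W * exp(-W/tau) / (1 - exp(-W/tau))` (see [truncated_exp_mean()]);
#' exposed for comparison against the ML estimator.
#'
#' @inheritParams fit_pixel_lifetime
#' @return mean arrival time (ns).
#' @export
naive_lifetime <- function(histogram, bin_width_ns) {
  stopifnot(sum(histogram) > 0)
  mids <- (seq_along(histogram) - 0.5) * bin_width_ns
  sum(histogram * mids) / sum(histogram)
}

#' Fit a per-pixel lifetime map
#'
#' Runs [fit_pixel_lifetime()] on every pixel of a FLIM acquisition.
#' Pixels under the photon floor are flagged unfit (`NA` lifetime) rather
#' than erroring.
#'
#' @param flim a [flim_data()] object.
#' @param min_photons per-pixel photon floor (default 100).
#' @param method estimator passed through to [fit_pixel_lifetime()].
#' @return a `lifetime_map`: `tau_ns` matrix (NA where unfit), `photons`
#'   matrix, `fitted` logical matrix.
#' @export
fit_lifetime_map <- function(flim, min_photons = 100L, method = "ml") {
  stopifnot(inherits(flim, "flim_data"))
  d <- dim(flim$counts)
  tau <- matrix(NA_real_, d[1L], d[2L])
  photons <- matrix(0, d[1L], d[2L])
  for (j in seq_len(d[2L])) {
    for (i in seq_len(d[1L])) {
      h <- flim$counts[i, j, ]
      photons[i, j] <- sum(h)
      if (photons[i, j] >= min_photons)
        tau[i, j] <- fit_pixel_lifetime(h, flim$bin_width_ns,
                                        min_photons = min_photons,
                                        method = method)
    }
  }
  structure(list(tau_ns = tau, photons = photons, fitted = !is.na(tau),
                 bin_width_ns = flim$bin_width_ns,
                 window_ns = flim$window_ns),
            class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  cat(sprintf(
    "lifetime_map: %d x %d px, %d fitted; tau %.3g-%.3g ns (median %.3g)\n",
    nrow(x$tau_ns), ncol(x$tau_ns), sum(x$fitted),
    min(x$tau_ns, na.rm = TRUE), max(x$tau_ns, na.rm = TRUE),
    stats::median(x$tau_ns, na.rm = TRUE)))
  invisible(x)
}

#' Photon-weighted ROI lifetime
#'
#' Average lifetime across a region of interest, weighting each fitted
#' pixel by its photon count so dim, noisy pixels do not dominate.
#'
#' @param map a `lifetime_map`.
#' @param roi_mask logical matrix selecting the ROI; `NULL` = whole field.
#' @return list: `mean_ns`, `sd_ns` (photon-weighted), `n_pixels`,
#'   `photons`.
#' @export
roi_lifetime <- function(map, roi_mask = NULL) {
  stopifnot(inherits(map, "lifetime_map"))
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(map$tau_ns),
                                            ncol(map$tau_ns))
  sel <- roi_mask & map$fitted
  if (!any(sel))
    stop("ROI contains no successfully fitted pixel")
  tau <- map$tau_ns[sel]
  w <- map$photons[sel]
  m <- stats::weighted.mean(tau, w)
  v <- stats::weighted.mean((tau - m)^2, w)
  list(mean_ns = m, sd_ns = sqrt(v), n_pixels = sum(sel),
       photons = sum(w))
}

#' Render a lifetime map on the fixed rainbow scale
#'
#' Absolute linear color scale from navy (2.1 ns) to red (2.7 ns):
#' the same lifetime always maps to the same color regardless of the map's
#' own range. Out-of-range lifetimes clamp to the scale ends; unfit pixels
#' are black.
#'
#' @param map a `lifetime_map`.
#' @param tau_min_ns,tau_max_ns scale endpoints (ns), defaults 2.1 / 2.7.
#' @param path optional PNG output path.
#' @return RGB array `[ny, nx, 3]` in `[0, 1]`, invisibly when written.
#' @export
render_lifetime_map <- function(map, tau_min_ns = 2.1, tau_max_ns = 2.7,
                                path = NULL) {
  stopifnot(inherits(map, "lifetime_map"), tau_max_ns > tau_min_ns)
  u <- (map$tau_ns - tau_min_ns) / (tau_max_ns - tau_min_ns)
  u <- pmin(pmax(u, 0), 1)
  # hue 2/3 (navy-blue) down to 0 (red)
  hue <- (1 - u) * 2 / 3
  col <- grDevices::hsv(ifelse(is.na(hue), 0, hue), s = 1,
                        v = ifelse(is.na(hue), 0, 1))
  rgb <- grDevices::col2rgb(col) / 255
  arr <- array(0, dim = c(nrow(u), ncol(u), 3L))
  arr[, , 1L] <- matrix(rgb[1L, ], nrow(u))
  arr[, , 2L] <- matrix(rgb[2L, ], nrow(u))
  arr[, , 3L] <- matrix(rgb[3L, ], nrow(u))
  if (!is.null(path)) {
    png::writePNG(arr, path)
    return(invisible(arr))
  }
  arr
}

#' FRET efficiency from donor and donor+acceptor lifetimes
#'
#' `E = (1 - tau_DA / tau_D) * 100` percent: the fractional shortening of
#' the donor lifetime when the acceptor opens a transfer pathway. A
#' negative value (tau_DA exceeding tau_D) is returned as such — it is
#' diagnostic, not an error.
#'
#' @param tau_donor_ns donor-alone lifetime (ns), > 0.
#' @param tau_da_ns donor lifetime in presence of the acceptor (ns), > 0.
#' @return efficiency in percent.
#' @export
fret_efficiency <- function(tau_donor_ns, tau_da_ns) {
  if (any(tau_donor_ns <= 0) || any(tau_da_ns <= 0))
    stop("lifetimes must be strictly positive")
  (1 - tau_da_ns / tau_donor_ns) * 100
}
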