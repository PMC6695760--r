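#' Detect diffraction-limited spots in one frame
#'
#' Band-passes the frame with a Laplacian-of-Gaussian (LoG) filter at scale
#' `psf_sigma_px`, takes strict local maxima of the (sign-flipped) response,
#' and refines every candidate by least-squares 2D Gaussian fitting in a
#' `(4*sigma+1)^2` window (amplitude, subpixel centre, width, local
#' offset). A candidate is kept when the fit converges, stays inside the
#' image, and its amplitude-over-residual-noise ratio reaches
#' `snr_threshold`.
#'
#' @param frame_image numeric matrix (one movie frame, counts).
#' @param psf_sigma_px expected PSF standard deviation (px).
#' @param snr_threshold minimum fitted amplitude over local noise SD.
#' @return data.frame of class `spot_detections` with columns
#'   `x`, `y` (subpixel px, pixel centres at integers), `intensity`
#'   (fitted amplitude), `sigma` (fitted width, px), `snr`, `offset`.
#'   Zero rows when nothing is found; never an error on a blank frame.
#' @export
detect_spots <- function(frame_image, psf_sigma_px, snr_threshold = 5) {
  if (!is.matrix(frame_image) || !is.numeric(frame_image))
    stop("frame_image must be a numeric matrix")
  if (any(!is.finite(frame_image)))
    stop("frame_image contains non-finite pixels")
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be strictly positive")
  empty <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
                      sigma = numeric(0), snr = numeric(0), offset = numeric(0))
  class(empty) <- c("spot_detections", "data.frame")
  if (stats::sd(frame_image) == 0) return(empty)

  resp <- .log_response(frame_image, psf_sigma_px)
  noise <- stats::mad(resp)
  if (noise == 0) noise <- stats::sd(resp)
  if (noise == 0) return(empty)

  # candidate gate on the band-passed response; at matched filter scale a
  # real spot responds several-fold above this, so the gate removes noise
  # maxima without costing recall, and the Gaussian-fit SNR decides the rest
  cand <- .local_maxima(resp, resp > snr_threshold * noise)
  if (!nrow(cand)) return(empty)
  cand <- cand[order(-cand$value), , drop = FALSE]

  half <- ceiling(2 * psf_sigma_px)
  out <- vector("list", nrow(cand))
  kept_xy <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    fit <- .fit_gaussian_spot(frame_image, cand$x[i], cand$y[i], half,
                              psf_sigma_px)
    if (is.null(fit)) next
    if (fit$snr < snr_threshold) next
    # drop refits of an already-accepted spot
    if (nrow(kept_xy) &&
        any((kept_xy[, 1] - fit$x)^2 + (kept_xy[, 2] - fit$y)^2 <
            (2 * psf_sigma_px)^2)) next
    kept_xy <- rbind(kept_xy, c(fit$x, fit$y))
    out[[i]] <- as.data.frame(fit)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else empty
  class(res) <- c("spot_detections", "data.frame")
  res
}

# sign-flipped LoG filter response: bright Gaussian spots become positive peaks
.log_response <- function(img, sigma) {
  half <- max(2L, ceiling(4 * sigma))
  ax <- -half:half
  g <- exp(-ax^2 / (2 * sigma^2))
  # scale-normalized LoG kernel, negated
  k <- -sigma^2 * (outer(ax^2, ax^2, `+`) / sigma^4 - 2 / sigma^2) *
    outer(g, g)
  k <- k - mean(k)                 # zero-sum: removes flat background
  EBImage::filter2(img, k / sum(abs(k)))
}

# strict 8-neighbour local maxima among pixels passing `mask`
.local_maxima <- function(resp, mask) {
  ny <- nrow(resp); nx <- ncol(resp)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- resp
  ctr <- pad[2:(ny + 1L), 2:(nx + 1L)]
  is_max <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
    is_max <- is_max & (ctr > nb | (ctr == nb & (dy < 0 | (dy == 0 & dx < 0))))
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(y = idx[, 1L], x = idx[, 2L], value = resp[idx])
}

# least-squares Gaussian fit around (cx, cy); NULL when the fit is unusable
.fit_gaussian_spot <- function(img, cx, cy, half, sigma0) {
  ny <- nrow(img); nx <- ncol(img)
  xs <- max(1L, cx - half):min(nx, cx + half)
  ys <- max(1L, cy - half):min(ny, cy + half)
  if (length(xs) < 4L || length(ys) < 4L) return(NULL)
  z <- img[ys, xs]
  df <- data.frame(x = rep(xs, each = length(ys)),
                   y = rep(ys, times = length(xs)),
                   z = as.vector(z))
  off0 <- stats::median(df$z)
  a0 <- max(df$z) - off0
  if (a0 <= 0) return(NULL)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    z ~ off + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
    data = df,
    start = list(off = off0, A = a0, x0 = cx, y0 = cy, s = sigma0),
    lower = c(off = -Inf, A = 0, x0 = min(xs) - 1, y0 = min(ys) - 1,
              s = 0.3 * sigma0),
    upper = c(off = Inf, A = Inf, x0 = max(xs) + 1, y0 = max(ys) + 1,
              s = 3 * sigma0),
    control = minpack.lm::nls.lm.control(maxiter = 60))),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  p <- stats::coef(fit)
  # a real diffraction-limited spot fits near the PSF scale; single-pixel
  # noise spikes collapse to the narrow bound and are rejected here
  if (p[["s"]] < 0.78 * sigma0 || p[["s"]] > 1.5 * sigma0) return(NULL)
  # reject fits that ran away from the candidate or out of the image
  if (abs(p[["x0"]] - cx) > half || abs(p[["y0"]] - cy) > half) return(NULL)
  if (p[["x0"]] < 0.5 || p[["x0"]] > nx + 0.5 ||
      p[["y0"]] < 0.5 || p[["y0"]] > ny + 0.5) return(NULL)
  # background noise from annulus pixels (> 2 sigma from the centre), so a
  # spot's own shot noise does not deflate its SNR
  r2 <- (df$x - p[["x0"]])^2 + (df$y - p[["y0"]])^2
  far <- r2 > (2 * sigma0)^2
  res <- stats::residuals(fit)
  # MAD, not SD: a neighbouring spot clipping the window corner must not
  # masquerade as background noise
  res_sd <- if (sum(far) >= 8) stats::mad(res[far]) else stats::mad(res)
  if (res_sd == 0) res_sd <- stats::sd(res)
  if (!is.finite(res_sd) || res_sd <= 0) return(NULL)
  list(x = unname(p[["x0"]]), y = unname(p[["y0"]]),
       intensity = unname(p[["A"]]), sigma = unname(p[["s"]]),
       snr = unname(p[["A"]]) / res_sd, offset = unname(p[["off"]]))
}

#' Detect spots in every frame of a stack
#'
#' @param stack an [image_stack].
#' @param psf_sigma_px PSF standard deviation (px).
#' @param snr_threshold minimum spot SNR, see [detect_spots()].
#' @return data.frame with a `frame` column prepended to the per-frame
#'   [detect_spots()] output.
#' @export
detect_spots_stack <- function(stack, psf_sigma_px, snr_threshold = 5) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    d <- detect_spots(stack$frames[, , f], psf_sigma_px, snr_threshold)
    if (nrow(d)) res[[f]] <- cbind(frame = f, as.data.frame(d))
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0), sigma = numeric(0),
                      snr = numeric(0), offset = numeric(0)))
  do.call(rbind, res)
}
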