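#' Parameters for the synthetic TIRF movie simulator
#'
#' Bundles and validates everything [simulate_tirf_movie()] needs. The
#' defaults emulate single membrane-receptor particles imaged by
#' variable-angle TIRF: slow 2D Brownian diffusion (D about 2e-3 um^2/s),
#' exponential membrane dwell times of about 2 s, 0.15 s frame interval,
#' diffraction-limited Gaussian spots on a Poisson background with additive
#' camera read noise.
#'
#' @param field_size_px integer vector `c(ny, nx)`, frame size in pixels.
#' @param pixel_size_um pixel size (um/px). Default 0.1.
#' @param frame_interval_s frame interval (s). Default 0.15.
#' @param n_frames number of frames (>= 2).
#' @param diffusion_um2_s diffusion coefficient D (um^2/s).
#' @param dwell_mean_s mean membrane dwell time (s); lifetimes are
#'   exponential with this mean. `Inf` disables particle death.
#' @param birth_rate_per_frame expected number of newly appearing particles
#'   per frame (Poisson). May be 0.
#' @param n_initial particles present in frame 1; `NULL` uses the
#'   steady-state expectation `birth_rate_per_frame * dwell_mean_s /
#'   frame_interval_s`.
#' @param psf_sigma_px Gaussian PSF standard deviation (px).
#' @param photons_per_spot expected photons per particle per frame.
#' @param background_photons expected background photons per pixel per frame.
#' @param read_noise_sd camera read noise SD (counts).
#' @param seed RNG seed; all randomness of one simulation flows from it.
#' @return a validated list of class `tirf_sim_params`.
#' @export
tirf_sim_params <- function(field_size_px = c(128L, 128L),
                            pixel_size_um = 0.1,
                            frame_interval_s = 0.15,
                            n_frames = 100L,
                            diffusion_um2_s = 2e-3,
                            dwell_mean_s = 2.0,
                            birth_rate_per_frame = 2,
                            n_initial = NULL,
                            psf_sigma_px = 1.2,
                            photons_per_spot = 400,
                            background_photons = 10,
                            read_noise_sd = 2,
                            seed = 1L) {
  p <- list(field_size_px = as.integer(field_size_px),
            pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s,
            n_frames = as.integer(n_frames),
            diffusion_um2_s = diffusion_um2_s,
            dwell_mean_s = dwell_mean_s,
            birth_rate_per_frame = birth_rate_per_frame,
            n_initial = n_initial,
            psf_sigma_px = psf_sigma_px,
            photons_per_spot = photons_per_spot,
            background_photons = background_photons,
            read_noise_sd = read_noise_sd,
            seed = as.integer(seed))
  .check_positive(p, c("pixel_size_um", "frame_interval_s", "psf_sigma_px",
                       "dwell_mean_s"))
  .check_nonneg(p, c("diffusion_um2_s", "birth_rate_per_frame",
                     "photons_per_spot", "background_photons",
                     "read_noise_sd"))
  if (any(p$field_size_px < 8L))
    stop("field_size_px: each dimension must be >= 8 px")
  if (p$n_frames < 2L) stop("n_frames: must be >= 2")
  class(p) <- "tirf_sim_params"
  p
}

.check_positive <- function(p, fields) {
  for (f in fields)
    if (!is.finite(p[[f]]) && !identical(p[[f]], Inf) || p[[f]] <= 0)
      stop(sprintf("%s: must be strictly positive", f))
  invisible(TRUE)
}

.check_nonneg <- function(p, fields) {
  for (f in fields)
    if (!is.finite(p[[f]]) || p[[f]] < 0)
      stop(sprintf("%s: must be finite and non-negative", f))
  invisible(TRUE)
}

#' Simulate a TIRF movie of diffusing membrane particles
#'
#' Particles appear via a memoryless (Poisson) birth process, live for
#' exponentially distributed dwell times with mean `dwell_mean_s`, and move
#' by 2D Brownian steps with per-axis variance `2 * D * dt`. A particle that
#' steps outside the field is killed there (recorded as a death, not
#' reflected). Each live particle is rendered as a pixel-integrated Gaussian
#' PSF carrying `photons_per_spot` expected photons; the camera model is
#' `Poisson(signal + background) + Normal(0, read_noise_sd)`, clipped at 0
#' and quantized to 16-bit.
#'
#' @param params a [tirf_sim_params()] object.
#' @param return_noiseless also return the expected (noise-free) photon map
#'   per frame; used by conservation checks.
#' @return list with elements
#'   \describe{
#'     \item{stack}{[image_stack] of quantized counts.}
#'     \item{truth}{`tirf_ground_truth`: `positions` data.frame (id, frame,
#'       x_um, y_um), `particles` data.frame (id, birth_frame, death_frame,
#'       lifetime_s with the continuous exponential draw), and the params.}
#'     \item{noiseless}{optional `[ny, nx, n_frames]` expectation array.}
#'   }
#' @export
simulate_tirf_movie <- function(params, return_noiseless = FALSE) {
  stopifnot(inherits(params, "tirf_sim_params"))
  set.seed(params$seed)
  ny <- params$field_size_px[1L]; nx <- params$field_size_px[2L]
  dt <- params$frame_interval_s
  nf <- params$n_frames
  px <- params$pixel_size_um
  step_sd_um <- sqrt(2 * params$diffusion_um2_s * dt)

  n0 <- params$n_initial
  if (is.null(n0)) {
    n0 <- if (is.finite(params$dwell_mean_s))
      round(params$birth_rate_per_frame * params$dwell_mean_s / dt)
    else round(params$birth_rate_per_frame * nf)
  }
  n0 <- as.integer(n0)

  births <- c(rep.int(1L, n0),
              rep(seq_len(nf), stats::rpois(nf, params$birth_rate_per_frame)))
  n_part <- length(births)

  pos_list <- vector("list", n_part)
  rec <- data.frame(id = integer(0), birth_frame = integer(0),
                    death_frame = integer(0), lifetime_s = numeric(0))
  xmax_um <- nx * px; ymax_um <- ny * px
  for (i in seq_len(n_part)) {
    b <- births[i]
    life <- if (is.finite(params$dwell_mean_s))
      stats::rexp(1L, rate = 1 / params$dwell_mean_s) else Inf
    n_alive <- if (is.finite(life)) max(1L, ceiling(life / dt)) else nf
    d <- min(b + n_alive - 1L, nf)
    n_fr <- d - b + 1L
    x <- numeric(n_fr); y <- numeric(n_fr)
    x[1L] <- stats::runif(1L, 0.5 * px, xmax_um)
    y[1L] <- stats::runif(1L, 0.5 * px, ymax_um)
    if (n_fr > 1L) {
      sx <- stats::rnorm(n_fr - 1L, 0, step_sd_um)
      sy <- stats::rnorm(n_fr - 1L, 0, step_sd_um)
      x[-1L] <- x[1L] + cumsum(sx)
      y[-1L] <- y[1L] + cumsum(sy)
    }
    inside <- x > 0 & x <= xmax_um & y > 0 & y <= ymax_um
    first_out <- which(!inside)[1L]
    if (!is.na(first_out)) {        # killed at the boundary
      if (first_out == 1L) next     # born outside margin: drop silently
      x <- x[seq_len(first_out - 1L)]
      y <- y[seq_len(first_out - 1L)]
      d <- b + first_out - 2L
      n_fr <- first_out - 1L
    }
    id <- nrow(rec) + 1L
    rec <- rbind(rec, data.frame(id = id, birth_frame = b, death_frame = d,
                                 lifetime_s = life))
    pos_list[[id]] <- data.frame(id = id, frame = b:d, x_um = x, y_um = y)
  }
  positions <- if (nrow(rec)) do.call(rbind, pos_list[seq_len(nrow(rec))])
  else data.frame(id = integer(0), frame = integer(0),
                  x_um = numeric(0), y_um = numeric(0))

  lam0 <- matrix(params$background_photons, ny, nx)
  frames <- array(0, dim = c(ny, nx, nf))
  noiseless <- if (return_noiseless) array(0, dim = c(ny, nx, nf)) else NULL
  by_frame <- split(positions, positions$frame)
  for (f in seq_len(nf)) {
    lam <- lam0
    pf <- by_frame[[as.character(f)]]
    if (!is.null(pf) && nrow(pf) && params$photons_per_spot > 0) {
      for (j in seq_len(nrow(pf))) {
        lam <- .add_gaussian_spot(lam, pf$x_um[j] / px, pf$y_um[j] / px,
                                  params$psf_sigma_px,
                                  params$photons_per_spot)
      }
    }
    if (return_noiseless) noiseless[, , f] <- lam
    img <- stats::rpois(length(lam), lam) +
      stats::rnorm(length(lam), 0, params$read_noise_sd)
    img <- round(pmin(pmax(img, 0), .tiff_max))
    frames[, , f] <- img
  }

  truth <- structure(
    list(positions = positions, particles = rec, params = params),
    class = "tirf_ground_truth")
  out <- list(stack = image_stack(frames, px, dt), truth = truth)
  if (return_noiseless) out$noiseless <- noiseless
  out
}

# Add a pixel-integrated Gaussian of `photons` total expected photons at
# (x_px, y_px) (pixel-centre-at-integer convention) into intensity map lam.
.add_gaussian_spot <- function(lam, x_px, y_px, sigma, photons) {
  ny <- nrow(lam); nx <- ncol(lam)
  w <- ceiling(4 * sigma + 1)
  cx <- round(x_px); cy <- round(y_px)
  xs <- max(1L, cx - w):min(nx, cx + w)
  ys <- max(1L, cy - w):min(ny, cy + w)
  if (!length(xs) || !length(ys)) return(lam)
  # integral of the Gaussian over each pixel via normal CDF differences
  gx <- stats::pnorm(xs + 0.5, x_px, sigma) - stats::pnorm(xs - 0.5, x_px, sigma)
  gy <- stats::pnorm(ys + 0.5, y_px, sigma) - stats::pnorm(ys - 0.5, y_px, sigma)
  lam[ys, xs] <- lam[ys, xs] + photons * outer(gy, gx)
  lam
}

#' @export
print.tirf_ground_truth <- function(x, ...) {
  cat(sprintf(
    "tirf_ground_truth: %d particle(s), %d position record(s)\n",
    nrow(x$particles), nrow(x$positions)))
  cat(sprintf("  true D = %g um^2/s, mean dwell = %g s\n",
              x$params$diffusion_um2_s, x$params$dwell_mean_s))
  invisible(x)
}

#' Write ground truth as CSV (+ JSON sidecar of parameters)
#'
#' One row per particle per frame: id, frame, x_um, y_um.
#'
#' @param truth a `tirf_ground_truth`.
#' @param path output CSV path; params go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth$positions, path, row.names = FALSE)
  jsonlite::write_json(unclass(truth$params), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Simulate per-particle fluorescence time traces
#'
#' Generates the background-subtracted intensity trace of `n` membrane
#' particles over a movie of `n_frames` frames: each particle is born at a
#' uniformly random frame, lives for an exponential dwell time (mean
#' `dwell_mean_s`), emits `peak_intensity` expected counts per frame while
#' present, and every frame carries additive Gaussian noise of SD
#' `peak_intensity / snr`. This is the trace-level counterpart of
#' [simulate_tirf_movie()] used to exercise dwell-time measurement at large
#' n without rendering images.
#'
#' @param n number of particles.
#' @param dwell_mean_s mean membrane dwell time (s).
#' @param frame_interval_s frame interval (s).
#' @param n_frames movie length in frames.
#' @param peak_intensity expected in-spot intensity (counts).
#' @param snr peak intensity over noise SD.
#' @param seed RNG seed.
#' @return list: `traces` matrix `[n, n_frames]`, `truth` data.frame
#'   (id, birth_frame, death_frame, lifetime_s, censored).
#' @export
simulate_particle_traces <- function(n, dwell_mean_s = 2.0,
                                     frame_interval_s = 0.15,
                                     n_frames = 400L,
                                     peak_intensity = 100,
                                     snr = 8,
                                     seed = 1L) {
  stopifnot(n >= 1, dwell_mean_s > 0, frame_interval_s > 0, n_frames >= 2,
            peak_intensity > 0, snr > 0)
  set.seed(as.integer(seed))
  noise_sd <- peak_intensity / snr
  births <- sample.int(n_frames, n, replace = TRUE)
  life <- stats::rexp(n, rate = 1 / dwell_mean_s)
  n_alive <- pmax(1L, ceiling(life / frame_interval_s))
  deaths <- pmin(births + n_alive - 1L, n_frames)
  censored <- (births + n_alive - 1L) > n_frames
  traces <- matrix(stats::rnorm(n * n_frames, 0, noise_sd), n, n_frames)
  for (i in seq_len(n))
    traces[i, births[i]:deaths[i]] <-
      traces[i, births[i]:deaths[i]] + peak_intensity
  list(traces = traces,
       truth = data.frame(id = seq_len(n), birth_frame = births,
                          death_frame = deaths, lifetime_s = life,
                          censored = censored))
}
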