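#' Parameters for the synthetic FLIM (TCSPC) simulator
#'
#' Emulates time-correlated single-photon counting: each pixel has a true
#' monoexponential fluorescence lifetime, photons arrive with exponential
#' delay truncated to the acquisition window and are binned into a
#' per-pixel arrival-time histogram. No instrument response function is
#' modelled; the truncation is the only departure from a pure exponential
#' and is handled analytically by the fitting side.
#'
#' @param lifetime_map_ns numeric matrix of true per-pixel lifetimes (ns);
#'   a scalar is expanded to a `map_size_px` uniform map.
#' @param map_size_px size used when `lifetime_map_ns` is scalar.
#' @param photons_per_pixel expected photon count per pixel (Poisson).
#' @param window_ns acquisition window (ns); must exceed every lifetime.
#' @param n_bins histogram bins across the window.
#' @param seed RNG seed.
#' @return a validated list of class `flim_sim_params`.
#' @export
flim_sim_params <- function(lifetime_map_ns = 2.53,
                            map_size_px = c(32L, 32L),
                            photons_per_pixel = 1e4,
                            window_ns = 25,
                            n_bins = 250L,
                            seed = 1L) {
  if (!is.matrix(lifetime_map_ns))
    lifetime_map_ns <- matrix(lifetime_map_ns, map_size_px[1L], map_size_px[2L])
  if (any(lifetime_map_ns <= 0))
    stop("lifetime_map_ns: all lifetimes must be strictly positive")
  if (window_ns <= 0) stop("window_ns: must be strictly positive")
  if (window_ns <= max(lifetime_map_ns))
    stop("window_ns: must exceed the largest lifetime")
  if (photons_per_pixel < 0)
    stop("photons_per_pixel: must be non-negative")
  if (n_bins < 2L) stop("n_bins: must be >= 2")
  structure(list(lifetime_map_ns = lifetime_map_ns,
                 photons_per_pixel = photons_per_pixel,
                 window_ns = window_ns, n_bins = as.integer(n_bins),
                 seed = as.integer(seed)),
            class = "flim_sim_params")
}

#' Simulate per-pixel TCSPC photon-arrival histograms
#'
#' Photon counts per pixel are Poisson with mean `photons_per_pixel`;
#' arrival times are exponential with the pixel's true lifetime, truncated
#' to the window by inverse-CDF sampling, then binned.
#'
#' @param params a [flim_sim_params()] object.
#' @return a `flim_data` object: `counts` array `[ny, nx, n_bins]`,
#'   `bin_width_ns`, `window_ns`.
#' @export
simulate_flim <- function(params) {
  stopifnot(inherits(params, "flim_sim_params"))
  set.seed(params$seed)
  tau_map <- params$lifetime_map_ns
  ny <- nrow(tau_map); nx <- ncol(tau_map)
  W <- params$window_ns; nb <- params$n_bins
  bw <- W / nb
  counts <- array(0L, dim = c(ny, nx, nb))
  edges <- seq(0, W, length.out = nb + 1L)
  for (j in seq_len(nx)) {
    for (i in seq_len(ny)) {
      n <- stats::rpois(1L, params$photons_per_pixel)
      if (n == 0L) next
      tau <- tau_map[i, j]
      # inverse CDF of the exponential truncated to [0, W]
      u <- stats::runif(n)
      t <- -tau * log(1 - u * (1 - exp(-W / tau)))
      counts[i, j, ] <- tabulate(findInterval(t, edges,
                                              rightmost.closed = TRUE),
                                 nbins = nb)
    }
  }
  flim_data(counts, bin_width_ns = bw)
}

#' Construct a FLIM data object
#'
#' @param counts integer array `[ny, nx, n_bins]` of photon counts per
#'   arrival-time bin, or a matrix `[n_bins]` vector for a single pixel.
#' @param bin_width_ns width of one arrival-time bin (ns).
#' @return object of class `flim_data` with fields `counts`,
#'   `bin_width_ns`, `window_ns = n_bins * bin_width_ns`.
#' @export
flim_data <- function(counts, bin_width_ns) {
  if (is.vector(counts)) counts <- array(counts, dim = c(1L, 1L, length(counts)))
  stopifnot(length(dim(counts)) == 3L, bin_width_ns > 0, all(counts >= 0))
  structure(list(counts = counts, bin_width_ns = bin_width_ns,
                 window_ns = dim(counts)[3L] * bin_width_ns),
            class = "flim_data")
}

#' @export
print.flim_data <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "flim_data: %d x %d px, %d bins of %.4g ns (window %.4g ns), %.3g photons total\n",
    d[1L], d[2L], d[3L], x$bin_width_ns, x$window_ns, sum(x$counts)))
  invisible(x)
}

#' Mean arrival time of a truncated exponential decay
#'
#' Closed form `E[T | T < W] = tau - W * exp(-W/tau) / (1 - exp(-W/tau))`.
#' Exposed because it is the bias the maximum-likelihood lifetime fit
#' corrects relative to the naive mean-arrival-time estimate.
#'
#' @param tau_ns lifetime (ns).
#' @param window_ns acquisition window (ns).
#' @return expected arrival time (ns).
#' @export
truncated_exp_mean <- function(tau_ns, window_ns) {
  stopifnot(tau_ns > 0, window_ns > 0)
  tau_ns - window_ns * exp(-window_ns / tau_ns) / (1 - exp(-window_ns / tau_ns))
}
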