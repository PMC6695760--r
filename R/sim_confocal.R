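#' Parameters for the synthetic confocal Z-stack simulator
#'
#' Defines a simplified epidermal-cell geometry for internalization
#' measurements: a cylindrical cell whose wall is a bright plasma-membrane
#' (PM) ring in every optical section, plus cytoplasmic puncta (endosome-like
#' vesicles) carrying the internalized signal. The fluorescence budget is
#' split so that a fraction `internal_fraction` of the total noiseless
#' signal — in the whole volume and in every individual body slice — lies in
#' the cytoplasm; this is the ground truth the analysis must recover.
#'
#' Puncta are kept `pm_thickness_px + 12` px clear of the wall so that,
#' after optical blur, membrane and cytoplasmic photons remain spatially
#' separable (as they are in real cells, where endosomes sit well inside
#' the cortex at this resolution).
#'
#' @param slice_size_px integer `c(ny, nx)` per slice.
#' @param n_slices number of optical sections (>= 2).
#' @param z_step_um z spacing (um), default 0.5.
#' @param pixel_size_um lateral pixel size (um/px).
#' @param cell_radius_px radius of the cylindrical cell (px).
#' @param pm_thickness_px thickness of the PM wall ring (px).
#' @param internal_fraction fraction of total signal in the cytoplasm, in
#'   `[0, 1]`.
#' @param n_puncta cytoplasmic puncta per slice.
#' @param total_photons expected total signal photons per slice.
#' @param background_photons expected background photons per pixel.
#' @param read_noise_sd camera noise SD (counts).
#' @param blur_sigma_px optical blur applied to the noiseless slice (px);
#'   0 disables blurring.
#' @param seed RNG seed.
#' @return a validated list of class `confocal_sim_params`.
#' @export
confocal_sim_params <- function(slice_size_px = c(96L, 96L),
                                n_slices = 10L,
                                z_step_um = 0.5,
                                pixel_size_um = 0.1,
                                cell_radius_px = 36,
                                pm_thickness_px = 2,
                                internal_fraction = 0.25,
                                n_puncta = 60L,
                                total_photons = 4e5,
                                background_photons = 5,
                                read_noise_sd = 2,
                                blur_sigma_px = 0.8,
                                seed = 1L) {
  if (internal_fraction < 0 || internal_fraction > 1)
    stop("internal_fraction: must lie in [0, 1]")
  p <- list(slice_size_px = as.integer(slice_size_px),
            n_slices = as.integer(n_slices), z_step_um = z_step_um,
            pixel_size_um = pixel_size_um, cell_radius_px = cell_radius_px,
            pm_thickness_px = pm_thickness_px,
            internal_fraction = internal_fraction,
            n_puncta = as.integer(n_puncta), total_photons = total_photons,
            background_photons = background_photons,
            read_noise_sd = read_noise_sd, blur_sigma_px = blur_sigma_px,
            seed = as.integer(seed))
  .check_positive(p, c("z_step_um", "pixel_size_um", "cell_radius_px",
                       "pm_thickness_px", "total_photons"))
  .check_nonneg(p, c("background_photons", "read_noise_sd", "blur_sigma_px"))
  if (p$n_slices < 2L) stop("n_slices: must be >= 2")
  if (p$cell_radius_px >= min(p$slice_size_px) / 2 - 4)
    stop("cell_radius_px: cell (plus blur margin) must fit inside the slice")
  class(p) <- "confocal_sim_params"
  p
}

#' Simulate a confocal Z-stack of a cell with controllable internalization
#'
#' Slice 1 is dark mounting medium above the cell (so apical-surface
#' detection has something to detect); slices 2..n are cell-body sections,
#' each with a PM wall ring and, when `internal_fraction > 0`, bright
#' cytoplasmic puncta. Membrane and cytoplasm components are rendered and
#' blurred separately, so the recorded noiseless truth fraction
#' `sum(cyto component) / sum(both)` equals `internal_fraction` up to edge
#' losses of the blur kernel (well below 1e-3 for the default geometry).
#'
#' @param params a [confocal_sim_params()] object.
#' @param return_noiseless also return the per-component noiseless arrays.
#' @return list:
#'   \describe{
#'     \item{stack}{a `z_stack` (slices array `[ny, nx, n]`, `z_step_um`,
#'       `pixel_size_um`).}
#'     \item{truth}{`confocal_ground_truth`: `internal_fraction` (noiseless),
#'       geometry masks `cell_mask` / `pm_mask` / `cyto_mask` (blur-dilated
#'       cell outline), apical slice index, params.}
#'     \item{noiseless_pm, noiseless_cyto}{optional component arrays.}
#'   }
#' @export
simulate_confocal_stack <- function(params, return_noiseless = FALSE) {
  stopifnot(inherits(params, "confocal_sim_params"))
  set.seed(params$seed)
  ny <- params$slice_size_px[1L]; nx <- params$slice_size_px[2L]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  r <- sqrt(outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`))
  R <- params$cell_radius_px
  wall <- r <= R & r > (R - params$pm_thickness_px)
  interior <- r <= (R - params$pm_thickness_px - 12)

  # analysis-facing geometry masks: cell outline dilated by the blur extent
  # so that blurred membrane photons stay inside the whole-cell mask
  pad <- ceiling(3 * params$blur_sigma_px)
  cell_mask <- r <= (R + pad)
  pm_mask <- cell_mask & r > (R - params$pm_thickness_px - pad)

  f <- params$internal_fraction
  n <- params$n_slices
  pm_arr <- array(0, dim = c(ny, nx, n))
  cy_arr <- array(0, dim = c(ny, nx, n))
  for (k in 2:n) {
    pm_sl <- matrix(0, ny, nx)
    pm_sl[wall] <- params$total_photons * (1 - f) / sum(wall)
    cy_sl <- matrix(0, ny, nx)
    if (f > 0) {
      idx <- which(interior)
      pick <- sample(idx, min(params$n_puncta, length(idx)))
      cy_sl[pick] <- params$total_photons * f / length(pick)
    }
    if (params$blur_sigma_px > 0) {
      pm_sl <- .gaussian_blur(pm_sl, params$blur_sigma_px)
      cy_sl <- .gaussian_blur(cy_sl, params$blur_sigma_px)
    }
    pm_arr[, , k] <- pm_sl
    cy_arr[, , k] <- cy_sl
  }
  signal <- pm_arr + cy_arr
  total <- sum(signal)
  truth_frac <- if (total > 0) sum(cy_arr) / total else f

  # FFT blur can leave tiny negative ringing; clamp before Poisson draws
  lambda <- pmax(signal + params$background_photons, 0)
  noisy <- array(
    round(pmax(stats::rpois(length(lambda), lambda) +
                 stats::rnorm(length(signal), 0, params$read_noise_sd), 0)),
    dim = dim(signal))

  stack <- structure(
    list(slices = noisy, z_step_um = params$z_step_um,
         pixel_size_um = params$pixel_size_um),
    class = "z_stack")
  truth <- structure(
    list(internal_fraction = truth_frac,
         cell_mask = cell_mask, pm_mask = pm_mask,
         cyto_mask = cell_mask & !pm_mask,
         apical_slice = 2L, params = params),
    class = "confocal_ground_truth")
  out <- list(stack = stack, truth = truth)
  if (return_noiseless) {
    out$noiseless_pm <- pm_arr
    out$noiseless_cyto <- cy_arr
  }
  out
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("z_stack: %d slice(s) of %d x %d px, dz = %g um, %g um/px\n",
              d[3L], d[1L], d[2L], x$z_step_um, x$pixel_size_um))
  invisible(x)
}

# separable Gaussian blur; mass-preserving away from edges
.gaussian_blur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, 0, sigma)
  k <- k / sum(k)
  EBImage::filter2(img, outer(k, k))
}

#' Write a Z-stack as multi-page TIFF
#' @param stack a `z_stack`.
#' @param path output path; calibration sidecar at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_zstack_tiff <- function(stack, path) {
  fr <- stack$slices
  fr[fr < 0] <- 0; fr[fr > .tiff_max] <- .tiff_max
  pages <- lapply(seq_len(dim(fr)[3L]), function(i) fr[, , i] / .tiff_max)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(z_step_um = stack$z_step_um, pixel_size_um = stack$pixel_size_um,
         n_slices = dim(fr)[3L]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Z-stack TIFF written by [write_zstack_tiff()]
#' @param path TIFF path.
#' @param z_step_um,pixel_size_um fallbacks when no sidecar exists.
#' @return a `z_stack`.
#' @export
read_zstack_tiff <- function(path, z_step_um = 0.5, pixel_size_um = 0.1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    z_step_um <- meta$z_step_um; pixel_size_um <- meta$pixel_size_um
  }
  arr <- array(unlist(lapply(pages, function(p) round(p * .tiff_max))),
               dim = c(dim(pages[[1L]])[1:2], length(pages)))
  structure(list(slices = arr, z_step_um = z_step_um,
                 pixel_size_um = pixel_size_um), class = "z_stack")
}
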