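#' Select analysis slices at a depth below the apical surface
#'
#' The apical surface is the first slice whose mean intensity exceeds the
#' stack's background level (the dimmest slice) by `background_factor`.
#' Returns the slices whose depth below that surface falls inside
#' `depth_range_um`, the optical window used for internalization
#' quantification.
#'
#' @param stack a `z_stack`.
#' @param depth_range_um numeric `c(min, max)` depth below the apical
#'   surface (um); default `c(2, 3)`.
#' @param background_factor apical detection factor (default 1.5).
#' @return a `z_stack` containing only the selected slices, with
#'   attributes `slice_indices` (into the input stack) and `apical_slice`.
#' @export
select_analysis_slices <- function(stack, depth_range_um = c(2, 3),
                                   background_factor = 1.5) {
  stopifnot(inherits(stack, "z_stack"), length(depth_range_um) == 2L,
            depth_range_um[1L] <= depth_range_um[2L],
            depth_range_um[1L] >= 0)
  n <- dim(stack$slices)[3L]
  means <- vapply(seq_len(n), function(k) mean(stack$slices[, , k]),
                  numeric(1))
  bg <- min(means)
  apical <- which(means > background_factor * bg)[1L]
  if (is.na(apical))
    stop("no slice exceeds background: cannot locate the apical surface")
  depth <- (seq_len(n) - apical) * stack$z_step_um
  sel <- which(depth >= depth_range_um[1L] & depth <= depth_range_um[2L])
  if (!length(sel))
    stop(sprintf(
      "no slice in depth range [%g, %g] um below apical slice %d (stack reaches %g um)",
      depth_range_um[1L], depth_range_um[2L], apical, max(depth)))
  sub <- structure(list(slices = stack$slices[, , sel, drop = FALSE],
                        z_step_um = stack$z_step_um,
                        pixel_size_um = stack$pixel_size_um),
                   class = "z_stack")
  attr(sub, "slice_indices") <- sel
  attr(sub, "apical_slice") <- apical
  sub
}

#' Segment the cell and its plasma-membrane ring
#'
#' Otsu threshold on the maximum projection, morphological closing (to
#' bridge puncta and membrane into one region), hole filling, then a small
#' dilation so the PSF-blurred membrane stays inside the cell mask. The PM
#' mask is the ring of `ring_thickness_px` at the cell boundary (cell mask
#' minus its erosion); the cytoplasm is the rest of the cell.
#'
#' `ring_thickness_px` defaults to 8 px so the ring covers a few-pixel
#' membrane plus its blur tails at typical confocal sampling; narrow rings
#' misattribute blurred membrane photons to the cytoplasm.
#'
#' @param stack a `z_stack` (typically the [select_analysis_slices()]
#'   output).
#' @param ring_thickness_px PM ring thickness (px).
#' @param close_radius_px closing structuring-element radius (px).
#' @return list of logical matrices: `cell_mask`, `pm_mask`, `cyto_mask`.
#' @export
segment_cell <- function(stack, ring_thickness_px = 8L,
                         close_radius_px = 5L) {
  stopifnot(inherits(stack, "z_stack"))
  proj <- apply(stack$slices, c(1L, 2L), max)
  norm <- proj / max(proj)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  brush <- EBImage::makeBrush(2L * close_radius_px + 1L, shape = "disc")
  m <- EBImage::closing(EBImage::Image(mask * 1), brush)
  m <- EBImage::fillHull(m)
  m <- EBImage::dilate(m, EBImage::makeBrush(5L, shape = "disc"))
  cell <- EBImage::imageData(m) > 0.5
  er <- EBImage::erode(EBImage::Image(cell * 1),
                       EBImage::makeBrush(2L * ring_thickness_px + 1L,
                                          shape = "disc"))
  inner <- EBImage::imageData(er) > 0.5
  list(cell_mask = cell, pm_mask = cell & !inner, cyto_mask = inner)
}

#' Internalized fraction from a confocal sub-stack
#'
#' The fraction of a PM protein's signal that has been internalized,
#' measured as background-subtracted cytoplasm intensity over whole-cell
#' intensity. Per-slice ratios are averaged by default (so each optical
#' section weighs equally); pooled summation over slices is available via
#' `average = "pooled"`. The per-slice background is the mode of the
#' pixels outside the cell mask, which is robust to sparse bright debris.
#'
#' @param stack a `z_stack` of the analysis slices.
#' @param cell_mask,pm_mask logical matrices; when NULL both are taken from
#'   [segment_cell()]. `cell_mask` must contain `pm_mask`.
#' @param ring_thickness_px ring width used when segmenting internally.
#' @param average `"slices"` (mean of per-slice ratios) or `"pooled"`.
#' @return an `internalization_result`: `fraction` (clamped to `[0, 1]`),
#'   `per_slice` fractions, `n_slices`, `method`, and the masks used.
#' @export
internalized_fraction <- function(stack, cell_mask = NULL, pm_mask = NULL,
                                  ring_thickness_px = 8L,
                                  average = c("slices", "pooled")) {
  stopifnot(inherits(stack, "z_stack"))
  average <- match.arg(average)
  if (is.null(cell_mask) || is.null(pm_mask)) {
    seg <- segment_cell(stack, ring_thickness_px = ring_thickness_px)
    cell_mask <- seg$cell_mask
    pm_mask <- seg$pm_mask
  }
  stopifnot(is.logical(cell_mask), is.logical(pm_mask),
            all(dim(cell_mask) == dim(stack$slices)[1:2]),
            all(dim(pm_mask) == dim(cell_mask)))
  if (any(pm_mask & !cell_mask))
    stop("pm_mask must be contained in cell_mask")
  cyto <- cell_mask & !pm_mask
  n <- dim(stack$slices)[3L]
  cyto_sum <- numeric(n); cell_sum <- numeric(n)
  for (k in seq_len(n)) {
    sl <- stack$slices[, , k]
    bg <- .pixel_mode(sl[!cell_mask])
    slb <- sl - bg
    cyto_sum[k] <- sum(slb[cyto])
    cell_sum[k] <- sum(slb[cell_mask])
  }
  if (average == "slices") {
    if (any(cell_sum <= 0))
      stop("whole-cell intensity non-positive after background subtraction")
    per_slice <- cyto_sum / cell_sum
    frac <- mean(per_slice)
  } else {
    if (sum(cell_sum) <= 0)
      stop("whole-cell intensity non-positive after background subtraction")
    per_slice <- cyto_sum / cell_sum
    frac <- sum(cyto_sum) / sum(cell_sum)
  }
  structure(list(fraction = min(max(frac, 0), 1),
                 per_slice = pmin(pmax(per_slice, 0), 1),
                 n_slices = n, method = average,
                 cell_mask = cell_mask, pm_mask = pm_mask),
            class = "internalization_result")
}

# mode of (near-integer) pixel values; ties resolve to the smaller value
.pixel_mode <- function(v) {
  if (!length(v)) return(0)
  tab <- table(round(v))
  as.numeric(names(tab)[which.max(tab)])
}

#' @export
print.internalization_result <- function(x, ...) {
  cat(sprintf(
    "internalization: fraction = %.3f (%d slice(s), %s averaging)\n",
    x$fraction, x$n_slices, x$method))
  invisible(x)
}

#' Write mask overlays for audit
#'
#' Renders the cell outline (white) and PM ring (red) over the max
#' projection as a PNG.
#'
#' @param result an `internalization_result`.
#' @param stack the analyzed `z_stack`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_overlay <- function(result, stack, path) {
  proj <- apply(stack$slices, c(1L, 2L), max)
  g <- proj / max(proj)
  rgb <- array(g, dim = c(dim(g), 3L))
  ring <- result$pm_mask
  edge <- result$cell_mask & !EBImage::imageData(
    EBImage::erode(EBImage::Image(result$cell_mask * 1),
                   EBImage::makeBrush(3L, "disc"))) > 0.5
  rgb[, , 1L][ring] <- 1; rgb[, , 2L][ring] <- rgb[, , 2L][ring] * 0.3
  rgb[, , 3L][ring] <- rgb[, , 3L][ring] * 0.3
  rgb[, , 1L][edge] <- 1; rgb[, , 2L][edge] <- 1; rgb[, , 3L][edge] <- 1
  png::writePNG(rgb, path)
  invisible(path)
}
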