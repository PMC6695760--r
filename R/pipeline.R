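#' Compare a statistic across experimental conditions
#'
#' Per-condition mean, SD and n plus pairwise Welch two-sample t-tests
#' with Holm correction across all condition pairs. Welch is used rather
#' than the pooled-variance test because group variances routinely differ
#' between treatment arms; multi-group inference is pairwise + Holm (no
#' multiple-range procedure).
#'
#' @param values_by_condition named list of numeric vectors, one per
#'   condition (each a set of per-replicate values).
#' @param statistic label for printing.
#' @return a `condition_comparison`: `summary` data.frame (condition,
#'   mean, sd, n) and `tests` data.frame (a, b, diff, p, p_holm); `tests`
#'   is NULL when any condition has < 2 replicates.
#' @export
compare_conditions <- function(values_by_condition, statistic = "statistic") {
  stopifnot(is.list(values_by_condition), length(values_by_condition) >= 1L,
            !is.null(names(values_by_condition)))
  cond <- names(values_by_condition)
  summ <- do.call(rbind, lapply(cond, function(cn) {
    v <- values_by_condition[[cn]]
    data.frame(condition = cn, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  tests <- NULL
  if (length(cond) >= 2L && all(summ$n >= 2L)) {
    pairs <- utils::combn(cond, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- values_by_condition[[pairs[1L, k]]]
      b <- values_by_condition[[pairs[2L, k]]]
      p <- .welch_p(a, b)
      data.frame(a = pairs[1L, k], b = pairs[2L, k],
                 diff = mean(a) - mean(b), p = p)
    }))
    tests$p_holm <- stats::p.adjust(tests$p, method = "holm")
  }
  structure(list(statistic = statistic, summary = summ, tests = tests),
            class = "condition_comparison")
}

# Welch p-value that tolerates zero-variance groups (t.test refuses them):
# identical constant groups compare equal (p = 1), different ones p ~ 0
.welch_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("condition_comparison (%s):\n", x$statistic))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("pairwise Welch t-tests (Holm-adjusted):\n")
    print(x$tests, row.names = FALSE)
  } else cat("(fewer than 2 replicates somewhere: tests not run)\n")
  invisible(x)
}

#' Read a pipeline run configuration from YAML
#' @param path YAML file.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the simulate-track-analyze pipeline end to end
#'
#' Executes, per named condition: TIRF simulation (ground truth written
#' alongside), spot detection + linking, per-trajectory dynamics (D and
#' motion range with Gaussian population peaks), and trajectory-based dwell
#' times; then compares the per-trajectory diffusion coefficients across
#' conditions. All outputs (movie TIFF, trajectory CSV, dynamics CSV,
#' summary JSON) land under `config$out_dir`, and a manifest records the
#' package version, seed, full configuration and MD5 checksum of every
#' file, so a run can be re-executed from its manifest alone and verified
#' bit-for-bit.
#'
#' Configuration fields: `out_dir`; `seed`; `conditions`, a named list
#' whose entries are [tirf_sim_params()] argument lists (each condition
#' gets seed `seed + index`); optional `track` (psf_sigma_px,
#' snr_threshold, max_disp_px, max_gap_frames, min_length), `dynamics`
#' (n_lags, max_lag, min_values), `write_movies` (default TRUE).
#'
#' @param config configuration list (see above) or a YAML path.
#' @return a `pipeline_result`: per-condition results (`trajectories`,
#'   `dynamics`, `population` fits where enough trajectories exist,
#'   `dwell`), `comparison`, `manifest_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config), !is.null(config$out_dir),
            !is.null(config$conditions), length(config$conditions) >= 1L,
            !is.null(names(config$conditions)))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  trk <- utils::modifyList(
    list(psf_sigma_px = 1.2, snr_threshold = 5, max_disp_px = 4,
         max_gap_frames = 1L, min_length = 5L),
    if (is.null(config$track)) list() else config$track)
  dyn <- utils::modifyList(
    list(n_lags = 2L, max_lag = 10L, min_values = 50L,
         min_track_frames = 15L),
    if (is.null(config$dynamics)) list() else config$dynamics)
  write_movies <- !isFALSE(config$write_movies)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  files <- character(0)
  for (i in seq_along(config$conditions)) {
    cn <- names(config$conditions)[i]
    args <- config$conditions[[i]]
    args$seed <- seed + i
    params <- do.call(tirf_sim_params, args)
    sim <- simulate_tirf_movie(params)
    cdir <- file.path(config$out_dir, cn)
    dir.create(cdir, showWarnings = FALSE)
    if (write_movies) {
      files <- c(files, write_stack_tiff(sim$stack,
                                         file.path(cdir, "movie.tif")),
                 file.path(cdir, "movie.tif.json"))
      files <- c(files, write_ground_truth(sim$truth,
                                           file.path(cdir, "truth.csv")),
                 file.path(cdir, "truth.csv.json"))
    }
    traj <- track_movie(sim$stack, psf_sigma_px = trk$psf_sigma_px,
                        snr_threshold = trk$snr_threshold,
                        max_disp_px = trk$max_disp_px,
                        max_gap_frames = trk$max_gap_frames,
                        min_length = trk$min_length)
    files <- c(files, write_trajectories_csv(traj,
                                             file.path(cdir, "traj.csv")),
               file.path(cdir, "traj.csv.json"))
    dtab <- trajectory_dynamics(traj, n_lags = dyn$n_lags,
                                max_lag = dyn$max_lag)
    utils::write.csv(dtab, file.path(cdir, "dynamics.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(cdir, "dynamics.csv"))
    pop <- list()
    # population summaries use long tracks only: short-track D estimates are
    # right-skewed and drag the fitted histogram peak below the true D
    dpop <- dtab[dtab$n_frames >= dyn$min_track_frames, , drop = FALSE]
    if (nrow(dpop) >= dyn$min_values) {
      pop$diffusion <- fit_population_peak(dpop$D_um2_s,
                                           "diffusion_coefficient",
                                           min_values = dyn$min_values)
      pop$motion_range <- fit_population_peak(dpop$motion_range_um,
                                              "motion_range",
                                              min_values = dyn$min_values)
    }
    dw <- dwell_from_trajectories(traj, n_frames(sim$stack))
    utils::write.csv(dw, file.path(cdir, "dwell.csv"), row.names = FALSE)
    files <- c(files, file.path(cdir, "dwell.csv"))
    summ <- list(
      condition = cn, n_trajectories = length(unique(traj$id)),
      diffusion_peak = if (!is.null(pop$diffusion)) pop$diffusion$peak,
      motion_range_peak = if (!is.null(pop$motion_range))
        pop$motion_range$peak,
      dwell = unclass(summarize_dwell(dw, cn))[c("mean_s", "sd_s", "n",
                                                 "n_censored")])
    jsonlite::write_json(summ, file.path(cdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, file.path(cdir, "summary.json"))
    results[[cn]] <- list(params = params, trajectories = traj,
                          dynamics = dtab, population = pop, dwell = dw,
                          summary = summ)
  }

  comparison <- NULL
  if (length(results) >= 2L) {
    dvals <- lapply(results, function(r) r$dynamics$D_um2_s)
    if (all(vapply(dvals, length, integer(1)) >= 2L))
      comparison <- compare_conditions(dvals, "diffusion_coefficient")
  }

  files <- sort(unique(files))
  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                              config$out_dir), "/?"), "", files)
  checks <- as.list(unname(tools::md5sum(files)))
  names(checks) <- rel
  manifest <- list(
    package = "pmspt",
    version = as.character(utils::packageVersion("pmspt")),
    seed = seed, config = config,
    files = checks)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")

  structure(list(conditions = results, comparison = comparison,
                 manifest_path = manifest_path),
            class = "pipeline_result")
}

#' Read a pipeline manifest
#' @param path `manifest.json` written by [run_pipeline()].
#' @return the manifest list; `$config` re-runs the pipeline.
#' @export
read_manifest <- function(path) jsonlite::read_json(path,
                                                    simplifyVector = TRUE)

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d condition(s)\n", length(x$conditions)))
  for (cn in names(x$conditions)) {
    s <- x$conditions[[cn]]$summary
    cat(sprintf(
      "  %s: %d trajectories, D peak %s um^2/s, dwell %.3g s (n=%d)\n",
      cn, s$n_trajectories,
      if (is.null(s$diffusion_peak)) "NA" else sprintf("%.3g",
                                                       s$diffusion_peak),
      s$dwell$mean_s, s$dwell$n))
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
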