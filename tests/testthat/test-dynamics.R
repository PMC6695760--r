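traj_df <- function(x, y, frame = seq_along(x), dt = 0.15) {
  d <- data.frame(frame = frame, x_um = x, y_um = y)
  attr(d, "frame_interval_s") <- dt
  d
}

test_that("MSD of collinear unit steps matches hand arithmetic", {
  tr <- traj_df(c(0, 1, 2), c(0, 0, 0))
  m <- compute_msd(tr, max_lag = 2)
  expect_equal(m$msd_um2[m$lag_frames == 1], 1.0)
  expect_equal(m$msd_um2[m$lag_frames == 2], 4.0)
  expect_equal(m$lag_s, c(0.15, 0.30))
  expect_equal(m$n_pairs, c(2L, 1L))
})

test_that("a stationary trajectory has zero MSD at all lags", {
  tr <- traj_df(rep(2, 10), rep(3, 10))
  m <- compute_msd(tr, max_lag = 5)
  expect_true(all(m$msd_um2 == 0))
})

test_that("MSD equals the brute-force double-loop oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(4:20, 1)
    tr <- random_trajectory(n, with_gaps = rep %% 2 == 0)
    m <- suppressWarnings(compute_msd(tr, max_lag = n - 1))
    o <- msd_oracle(tr$frame, tr$x_um, tr$y_um, max_lag = n - 1, dt = 0.15)
    expect_equal(m$lag_frames, o$lag_frames)
    expect_equal(m$msd_um2, o$msd_um2, tolerance = 1e-12)
    expect_equal(m$n_pairs, o$n_pairs)
  }
})

test_that("gap-spanning pairs are honoured via true frame numbers", {
  tr <- traj_df(c(0, 1, 3), c(0, 0, 0), frame = c(1, 2, 4))
  m <- suppressWarnings(compute_msd(tr, max_lag = 3))
  # lag 1: only (f1, f2); lag 2: only (f2, f4); lag 3: (f1, f4)
  expect_equal(m$msd_um2[m$lag_frames == 1], 1)
  expect_equal(m$msd_um2[m$lag_frames == 2], 4)
  expect_equal(m$msd_um2[m$lag_frames == 3], 9)
})

test_that("diffusion fit recovers exact lines to machine precision", {
  lag_s <- (1:6) * 0.15
  m <- data.frame(lag_frames = 1:6, lag_s = lag_s,
                  msd_um2 = 4 * 2e-3 * lag_s, n_pairs = 6:1)
  class(m) <- c("msd_curve", "data.frame")
  est <- fit_diffusion(m, n_lags = 4)
  expect_equal(est$D_um2_s, 2e-3, tolerance = 1e-12)
  expect_equal(est$intercept_um2, 0, tolerance = 1e-15)
  expect_equal(est$r2, 1)
  expect_false(est$clamped)

  m$msd_um2 <- 4 * 2e-3 * lag_s + 0.01
  est2 <- fit_diffusion(m, n_lags = 4)
  expect_equal(est2$D_um2_s, 2e-3, tolerance = 1e-12)
  expect_equal(est2$intercept_um2, 0.01, tolerance = 1e-12)
})

test_that("negative MSD slopes clamp to zero with a flag", {
  m <- data.frame(lag_frames = 1:4, lag_s = (1:4) * 0.15,
                  msd_um2 = c(4, 3, 2, 1) * 1e-3, n_pairs = 4:1)
  class(m) <- c("msd_curve", "data.frame")
  est <- fit_diffusion(m)
  expect_equal(est$D_um2_s, 0)
  expect_true(est$clamped)
})

test_that("motion range matches geometry and the all-pairs oracle", {
  expect_equal(motion_range(traj_df(c(0, 1, 1), c(0, 0, 1))), sqrt(2))
  expect_equal(motion_range(traj_df(rep(1, 5), rep(1, 5))), 0)
  expect_error(motion_range(traj_df(1, 1)), "single-point")
  set.seed(7)
  for (rep in 1:20) {
    tr <- random_trajectory(20)
    expect_equal(motion_range(tr),
                 motion_range_oracle(tr$x_um, tr$y_um),
                 tolerance = 1e-12)
  }
})

test_that("scale covariance: positions scaled by c scale range by c, D by c^2", {
  set.seed(8)
  tr <- random_trajectory(30)
  c_ <- 3.7
  tr2 <- tr; tr2$x_um <- c_ * tr$x_um; tr2$y_um <- c_ * tr$y_um
  expect_equal(motion_range(tr2), c_ * motion_range(tr), tolerance = 1e-12)
  d1 <- fit_diffusion(compute_msd(tr, 5))$D_um2_s
  d2 <- fit_diffusion(compute_msd(tr2, 5))$D_um2_s
  expect_equal(d2, c_^2 * d1, tolerance = 1e-10)
})

test_that("population peak recovers known Gaussian centres", {
  set.seed(9)
  v <- rnorm(1e4, 0.40, 0.05)         # motion-range-like population
  fit <- fit_population_peak(v, "motion_range")
  expect_lt(abs(fit$peak - 0.40), 0.01)
  expect_equal(fit$n, 1e4)
  expect_equal(sum(fit$counts), 1e4)

  v2 <- rnorm(1e4, 1.97e-3, 0.3e-3)   # diffusion-coefficient-like
  fit2 <- fit_population_peak(v2, "diffusion_coefficient")
  expect_lt(abs(fit2$peak / 1.97e-3 - 1), 0.05)
})

test_that("degenerate or scant populations are refused", {
  expect_error(fit_population_peak(rep(1, 100)), "zero-width")
  expect_error(fit_population_peak(rnorm(10)), "floor")
})

test_that("larger diffusion gives larger population peaks for D and range", {
  sims <- lapply(c(1e-3, 3e-3), function(D) {
    p <- tirf_sim_params(field_size_px = c(160, 160), n_frames = 250,
                         diffusion_um2_s = D, dwell_mean_s = 2,
                         birth_rate_per_frame = 3, photons_per_spot = 0,
                         seed = 51)
    sim <- simulate_tirf_movie(p)
    d <- trajectory_dynamics(truth_trajectories(sim$truth))
    d[d$n_frames >= 15, ]
  })
  pk <- lapply(sims, function(d) list(
    D = fit_population_peak(d$D_um2_s, "D")$peak,
    mr = fit_population_peak(d$motion_range_um, "mr")$peak))
  expect_lt(pk[[1]]$D, pk[[2]]$D)
  expect_lt(pk[[1]]$mr, pk[[2]]$mr)
})
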