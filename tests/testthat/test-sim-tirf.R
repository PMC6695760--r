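test_that("zero-diffusion immortal particle stays put", {
  p <- tirf_sim_params(field_size_px = c(32, 32), n_frames = 20,
                       diffusion_um2_s = 0, dwell_mean_s = Inf,
                       birth_rate_per_frame = 0, n_initial = 1, seed = 3)
  sim <- simulate_tirf_movie(p)
  pos <- sim$truth$positions
  expect_equal(nrow(pos), 20L)
  expect_equal(length(unique(pos$x_um)), 1L)
  expect_equal(length(unique(pos$y_um)), 1L)
})

test_that("with no spot photons no pixel rises far above background", {
  p <- tirf_sim_params(field_size_px = c(64, 64), n_frames = 100,
                       photons_per_spot = 0, background_photons = 10,
                       read_noise_sd = 2, birth_rate_per_frame = 2,
                       seed = 5)
  sim <- simulate_tirf_movie(p)
  # Poisson(10) tail + Gaussian read noise: ceiling checked by simulation
  bound <- 10 + 6 * sqrt(10 + 2^2)
  expect_lt(max(sim$stack$frames), bound + 10)
  expect_true(all(sim$stack$frames >= 0))
})

test_that("Brownian steps have per-axis variance 2*D*dt", {
  p <- tirf_sim_params(field_size_px = c(128, 128), n_frames = 80,
                       diffusion_um2_s = 2e-3, dwell_mean_s = 2,
                       birth_rate_per_frame = 3, seed = 11)
  sim <- simulate_tirf_movie(p)
  pos <- sim$truth$positions
  steps <- do.call(rbind, lapply(split(pos, pos$id), function(d) {
    if (nrow(d) < 2) return(NULL)
    data.frame(dx = diff(d$x_um), dy = diff(d$y_um),
               dfr = diff(d$frame))
  }))
  steps <- steps[steps$dfr == 1, ]
  expect_gt(nrow(steps), 500)
  expected <- 2 * 2e-3 * 0.15          # 6e-4 um^2
  expect_lt(abs(var(steps$dx) / expected - 1), 0.2)
  expect_lt(abs(var(steps$dy) / expected - 1), 0.2)
})

test_that("simulated dwell lifetimes match the exponential mean", {
  p <- tirf_sim_params(field_size_px = c(256, 256), n_frames = 60,
                       dwell_mean_s = 2, birth_rate_per_frame = 40,
                       photons_per_spot = 0, seed = 13)
  sim <- simulate_tirf_movie(p)
  life <- sim$truth$particles$lifetime_s
  expect_gt(length(life), 1000)
  expect_lt(abs(mean(life) / 2 - 1), 0.05)
})

test_that("ensemble MSD of true positions is linear with slope 4D", {
  p <- tirf_sim_params(field_size_px = c(256, 256), n_frames = 40,
                       diffusion_um2_s = 2e-3, dwell_mean_s = 4,
                       birth_rate_per_frame = 25, photons_per_spot = 0,
                       seed = 17)
  sim <- simulate_tirf_movie(p)
  tt <- truth_trajectories(sim$truth, min_length = 5)
  expect_gt(length(unique(tt$id)), 500)
  # ensemble average of squared displacement per lag over all trajectories
  tracks <- split_trajectories(tt)
  lags <- 1:4
  ens <- sapply(lags, function(k) {
    d2 <- unlist(lapply(tracks, function(tr) {
      o <- order(tr$frame)
      fr <- tr$frame[o]; x <- tr$x_um[o]; y <- tr$y_um[o]
      idx <- match(fr + k, fr)
      ok <- !is.na(idx)
      (x[idx[ok]] - x[ok])^2 + (y[idx[ok]] - y[ok])^2
    }))
    mean(d2)
  })
  slope <- coef(lm(ens ~ I(lags * 0.15)))[2]
  expect_lt(abs(slope / 4 / 2e-3 - 1), 0.10)
})

test_that("expected noiseless intensity conserves photons", {
  p <- tirf_sim_params(field_size_px = c(64, 64), n_frames = 10,
                       diffusion_um2_s = 1e-3, dwell_mean_s = Inf,
                       birth_rate_per_frame = 0, n_initial = 6,
                       photons_per_spot = 300, background_photons = 4,
                       seed = 19)
  sim <- simulate_tirf_movie(p, return_noiseless = TRUE)
  pos <- sim$truth$positions
  for (f in c(1, 5, 10)) {
    n_live <- sum(pos$frame == f)
    expected <- n_live * 300 + 64 * 64 * 4
    # PSF tails may fall off the field for edge particles: allow 2%
    expect_lt(abs(sum(sim$noiseless[, , f]) / expected - 1), 0.02)
  }
})

test_that("identical seed and params give bit-identical output", {
  p <- tirf_sim_params(field_size_px = c(48, 48), n_frames = 15, seed = 23)
  a <- simulate_tirf_movie(p)
  b <- simulate_tirf_movie(p)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$positions, b$truth$positions)
})

test_that("invalid parameters are rejected naming the field", {
  expect_error(tirf_sim_params(frame_interval_s = 0), "frame_interval_s")
  expect_error(tirf_sim_params(n_frames = 1), "n_frames")
  expect_error(tirf_sim_params(psf_sigma_px = -1), "psf_sigma_px")
  expect_error(tirf_sim_params(photons_per_spot = -5), "photons_per_spot")
})

test_that("particle traces carry the dwell structure", {
  tr <- simulate_particle_traces(50, dwell_mean_s = 2, n_frames = 400,
                                 seed = 2)
  expect_equal(dim(tr$traces), c(50L, 400L))
  expect_equal(nrow(tr$truth), 50L)
  expect_true(all(tr$truth$death_frame >= tr$truth$birth_frame))
  expect_true(all(tr$truth$death_frame <= 400L))
})
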