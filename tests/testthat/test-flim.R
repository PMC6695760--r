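test_that("the ML lifetime fit recovers tau to 1% at high photon counts", {
  p <- flim_sim_params(2.5, map_size_px = c(2, 2), photons_per_pixel = 1e5,
                       window_ns = 25, seed = 11)
  fd <- simulate_flim(p)
  tau <- fit_pixel_lifetime(fd$counts[1, 1, ], fd$bin_width_ns)
  expect_lt(abs(tau / 2.5 - 1), 0.01)
  # least-squares fallback agrees at high counts
  tau_ls <- fit_pixel_lifetime(fd$counts[1, 1, ], fd$bin_width_ns,
                               method = "ls")
  expect_lt(abs(tau_ls / 2.5 - 1), 0.05)
})

test_that("the ML fit corrects the truncation bias of the naive mean", {
  # short window makes the truncation bite: naive mean must undershoot
  p <- flim_sim_params(2.5, map_size_px = c(2, 2), photons_per_pixel = 1e5,
                       window_ns = 8, n_bins = 160, seed = 12)
  fd <- simulate_flim(p)
  h <- fd$counts[1, 1, ]
  naive <- naive_lifetime(h, fd$bin_width_ns)
  ml <- fit_pixel_lifetime(h, fd$bin_width_ns)
  expect_lt(naive, 2.5 * 0.92)          # bias ~0.34 ns at W = 8 ns
  expect_lt(abs(ml / 2.5 - 1), 0.02)
  expect_lt(abs(naive - truncated_exp_mean(2.5, 8)), 0.03)
})

test_that("lifetime estimation is unbiased across the 2.1-2.7 ns range", {
  for (tau in c(2.1, 2.36, 2.53, 2.7)) {
    p <- flim_sim_params(tau, map_size_px = c(4, 4),
                         photons_per_pixel = 1e4, seed = round(tau * 100))
    map <- fit_lifetime_map(simulate_flim(p))
    est <- roi_lifetime(map)$mean_ns
    expect_lt(abs(est / tau - 1), 0.02)
  }
})

test_that("degenerate single-bin histograms fit to the bin scale", {
  h <- rep(0L, 100); h[1] <- 500L
  tau <- fit_pixel_lifetime(h, bin_width_ns = 0.1)
  expect_lt(tau, 0.1)
})

test_that("ROI averaging is photon-weighted", {
  tau_map <- matrix(c(2.1, 2.7), 2, 2)
  map <- structure(list(tau_ns = tau_map,
                        photons = matrix(c(100, 300, 100, 300), 2, 2),
                        fitted = matrix(TRUE, 2, 2),
                        bin_width_ns = 0.1, window_ns = 25),
                   class = "lifetime_map")
  r <- roi_lifetime(map)
  expect_equal(r$mean_ns, (2.1 * 200 + 2.7 * 600) / 800)
  # equal photons -> plain arithmetic mean
  map$photons[] <- 100
  expect_equal(roi_lifetime(map)$mean_ns, 2.4)
  expect_error(roi_lifetime(map, matrix(FALSE, 2, 2)), "no successfully")
})

test_that("the rainbow lifetime scale is absolute, navy to red", {
  mk <- function(tau) structure(
    list(tau_ns = matrix(tau, 2, 2), photons = matrix(1000, 2, 2),
         fitted = matrix(TRUE, 2, 2), bin_width_ns = 0.1, window_ns = 25),
    class = "lifetime_map")
  navy <- render_lifetime_map(mk(2.1))
  expect_true(all(navy[, , 3] == 1) && all(navy[, , 1] == 0))
  red <- render_lifetime_map(mk(2.7))
  expect_true(all(red[, , 1] == 1) && all(red[, , 3] == 0))
  # same tau -> same color regardless of the rest of the map; clamping
  mid_a <- render_lifetime_map(mk(2.4))[1, 1, ]
  m2 <- mk(2.4); m2$tau_ns[2, 2] <- 5
  rend2 <- render_lifetime_map(m2)
  expect_equal(rend2[1, 1, ], mid_a)
  expect_equal(rend2[2, 2, ], red[1, 1, ])
  # unfit pixels are black
  m3 <- mk(2.4); m3$fitted[1, 1] <- FALSE; m3$tau_ns[1, 1] <- NA
  expect_equal(render_lifetime_map(m3)[1, 1, ], c(0, 0, 0))
})

test_that("FRET efficiency follows 1 - tauDA/tauD", {
  expect_equal(fret_efficiency(2.53, 2.53), 0)
  expect_equal(fret_efficiency(2.53, 2.36), (1 - 2.36 / 2.53) * 100)
  expect_equal(fret_efficiency(2.0, 1.0), 50)
  expect_error(fret_efficiency(0, 1), "positive")
  # monotone: E falls as tauDA rises toward tauD
  taus <- seq(2.0, 2.53, by = 0.1)
  e <- fret_efficiency(2.53, taus)
  expect_true(all(diff(e) < 0))
  # negative efficiency is reported, not an error
  expect_lt(fret_efficiency(2.36, 2.50), 0)
})
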