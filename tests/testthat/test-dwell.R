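test_that("kymograph of a static uniform movie is constant", {
  st <- image_stack(array(7, dim = c(32, 32, 10)), 0.1, 0.15)
  k <- build_kymograph(st, c(5, 16, 28, 16), width_px = 3)
  expect_true(all(k$intensity == 7))
  expect_equal(ncol(k$intensity), 10L)
})

test_that("a particle parked on the line leaves a band of the right length", {
  frames <- array(0, dim = c(32, 32, 40))
  for (f in 10:29)
    frames[, , f] <- synthetic_spot_frame(32, 32, 16, 16, 100, 1.2,
                                          background = 0)
  st <- image_stack(frames, 0.1, 0.15)
  k <- build_kymograph(st, c(4, 16, 28, 16))
  band <- apply(k$intensity, 2, max) > 50
  expect_equal(which(band), 10:29)
  expect_equal(sum(band), 20L)
})

test_that("a line missing all particles stays at background", {
  frames <- array(5, dim = c(32, 32, 8))
  for (f in 1:8)
    frames[, , f] <- frames[, , f] +
      synthetic_spot_frame(32, 32, 8, 8, 100, 1.2, background = 0)
  st <- image_stack(frames, 0.1, 0.15)
  k <- build_kymograph(st, c(20, 25, 30, 25))
  expect_lt(max(k$intensity), 6)
  expect_error(build_kymograph(st, c(5, 5, 5, 5)), "zero-length")
})

test_that("kymograph columns equal independent per-frame line sums", {
  p <- tirf_sim_params(field_size_px = c(48, 48), n_frames = 6,
                       birth_rate_per_frame = 2, seed = 6)
  sim <- simulate_tirf_movie(p)
  line <- c(5, 24, 44, 24)
  k <- build_kymograph(sim$stack, line)
  for (f in c(1, 4, 6)) {
    one <- image_stack(sim$stack$frames[, , f, drop = FALSE], 0.1, 0.15)
    expect_equal(sum(k$intensity[, f]),
                 sum(build_kymograph(one, line)$intensity[, 1]))
  }
})

test_that("dwell time reads the longest above-half-max run", {
  trace <- rep(0, 40); trace[10:29] <- 100
  r <- dwell_time(trace, frame_interval_s = 0.15)
  expect_equal(r$dwell_s, 3.0)
  expect_equal(r$n_frames, 20L)
  expect_false(r$censored)
})

test_that("whole-movie presence is censored; empty traces refuse", {
  r <- dwell_time(rep(50, 100), 0.15)
  expect_equal(r$dwell_s, 15)
  expect_true(r$censored)
  expect_error(dwell_time(rep(0, 50), 0.15), "no positive signal")
})

test_that("dwell is invariant to positive scaling of the trace", {
  set.seed(10)
  trace <- pmax(rnorm(60, 0, 3), 0); trace[20:35] <- trace[20:35] + 80
  a <- dwell_time(trace, 0.15)
  b <- dwell_time(trace * 17.3, 0.15)
  expect_equal(a$dwell_s, b$dwell_s)
  expect_equal(a$n_frames, b$n_frames)
})

test_that("dwell summaries average uncensored records only", {
  rec <- data.frame(dwell_s = c(1.5, 2.5), censored = c(FALSE, FALSE))
  s <- summarize_dwell(rec, "CK")
  expect_equal(s$mean_s, 2.0)
  rec2 <- data.frame(dwell_s = c(4.0, 1.5), censored = c(TRUE, FALSE))
  s2 <- summarize_dwell(rec2)
  expect_equal(s2$mean_s, 1.5)
  expect_equal(s2$n_censored, 1L)
})

test_that("recovered dwell means preserve the condition ordering", {
  means <- c(CK = 2.0, JA = 1.5)
  rec <- lapply(means, function(m) {
    tr <- simulate_particle_traces(400, dwell_mean_s = m, n_frames = 400,
                                   seed = round(m * 100))
    dwell_records(tr$traces, 0.15)
  })
  s <- lapply(names(means), function(cn)
    summarize_dwell(rec[[cn]][!rec[[cn]]$censored, ], cn))
  expect_gt(s[[1]]$mean_s, s[[2]]$mean_s)
  expect_lt(abs(s[[1]]$mean_s / 2.0 - 1), 0.15)
  expect_lt(abs(s[[2]]$mean_s / 1.5 - 1), 0.15)
})
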