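make_dets <- function(...) {
  d <- rbind(...)
  data.frame(frame = d[, 1], x = d[, 2], y = d[, 3], intensity = 100)
}

test_that("one clean particle links into one full-length trajectory", {
  det <- make_dets(cbind(1:20, 10 + 0.1 * (1:20), 15))
  traj <- link_spots(det, max_disp_px = 4, min_length = 5)
  expect_equal(length(unique(traj$id)), 1L)
  expect_equal(nrow(traj), 20L)
  expect_equal(traj$frame, 1:20)
})

test_that("two well-separated particles never swap identities", {
  det <- make_dets(cbind(1:20, 10, 10), cbind(1:20, 40, 40))
  traj <- link_spots(det, max_disp_px = 4, min_length = 5)
  expect_equal(length(unique(traj$id)), 2L)
  for (tr in split_trajectories(traj)) {
    expect_equal(nrow(tr), 20L)
    expect_equal(length(unique(round(tr$x_um, 6))), 1L)
  }
})

test_that("a one-frame dropout is bridged when max_gap allows it", {
  frames <- setdiff(1:21, 11)
  det <- make_dets(cbind(frames, 10 + 0.05 * frames, 12))
  traj1 <- link_spots(det, max_disp_px = 4, max_gap_frames = 1,
                      min_length = 5)
  expect_equal(length(unique(traj1$id)), 1L)
  expect_equal(nrow(traj1), 20L)
  traj0 <- link_spots(det, max_disp_px = 4, max_gap_frames = 0,
                      min_length = 5)
  expect_equal(length(unique(traj0$id)), 2L)
})

test_that("linking is invariant to detection order within frames", {
  set.seed(4)
  det <- make_dets(cbind(rep(1:15, 3),
                         rep(c(10, 20, 30), each = 15) +
                           rnorm(45, 0, 0.3),
                         rep(c(10, 25, 8), each = 15) + rnorm(45, 0, 0.3)))
  traj_a <- link_spots(det, max_disp_px = 3, min_length = 5)
  perm <- det[sample(nrow(det)), ]
  traj_b <- link_spots(perm, max_disp_px = 3, min_length = 5)
  key <- function(tr) {
    tracks <- split_trajectories(tr)
    sort(vapply(tracks, function(d)
      paste(d$frame, round(d$x_um, 9), round(d$y_um, 9), collapse = ";"),
      character(1)))
  }
  expect_equal(unname(key(traj_a)), unname(key(traj_b)))
})

test_that("trajectories below the length floor are discarded", {
  det <- make_dets(cbind(1:4, 10, 10), cbind(1:20, 30, 30))
  traj <- link_spots(det, max_disp_px = 4, min_length = 5)
  expect_equal(length(unique(traj$id)), 1L)
})

test_that("tracking on a simulated movie keeps trajectories pure", {
  p <- tirf_sim_params(field_size_px = c(96, 96), n_frames = 40,
                       diffusion_um2_s = 2e-3, dwell_mean_s = 2,
                       birth_rate_per_frame = 1, seed = 37)
  sim <- simulate_tirf_movie(p)
  traj <- track_movie(sim$stack)
  expect_gt(length(unique(traj$id)), 10)
  pur <- trajectory_purity(traj, sim$truth)
  expect_gte(pur$purity, 0.9)
})

test_that("trajectory CSV round-trips", {
  det <- make_dets(cbind(1:10, 10 + 0.1 * (1:10), 15))
  traj <- link_spots(det, max_disp_px = 4, min_length = 5,
                     pixel_size_um = 0.1, frame_interval_s = 0.15)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectories_csv(traj, path)
  back <- read_trajectories_csv(path)
  expect_equal(back$x_um, traj$x_um)
  expect_equal(attr(back, "frame_interval_s"), 0.15)
  unlink(c(path, paste0(path, ".json")))
})
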