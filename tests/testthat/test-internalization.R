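test_that("slice selection does the depth arithmetic on 0.5-um steps", {
  # apical surface at slice 2 of the simulated geometry (slice 1 is medium)
  p <- confocal_sim_params(n_slices = 10, seed = 2)
  sim <- simulate_confocal_stack(p)
  sub <- select_analysis_slices(sim$stack, c(2, 3))
  # depths 2, 2.5, 3 um below apical slice 2 -> slices 6, 7, 8
  expect_equal(attr(sub, "slice_indices"), 6:8)
  expect_equal(attr(sub, "apical_slice"), 2L)

  sub0 <- select_analysis_slices(sim$stack, c(0, 0))
  expect_equal(attr(sub0, "slice_indices"), 2L)
})

test_that("stacks too shallow for the depth range are refused", {
  p <- confocal_sim_params(n_slices = 4, seed = 3)
  sim <- simulate_confocal_stack(p)
  expect_error(select_analysis_slices(sim$stack, c(2, 3)), "depth range")
})

test_that("pure-membrane and pure-cytoplasm stacks hit the limits", {
  p0 <- confocal_sim_params(internal_fraction = 0, seed = 4)
  s0 <- simulate_confocal_stack(p0)
  sub0 <- select_analysis_slices(s0$stack, c(2, 3))
  f0 <- internalized_fraction(sub0, s0$truth$cell_mask, s0$truth$pm_mask)
  expect_lte(f0$fraction, 0.02)

  p1 <- confocal_sim_params(internal_fraction = 1, seed = 4)
  s1 <- simulate_confocal_stack(p1)
  sub1 <- select_analysis_slices(s1$stack, c(2, 3))
  f1 <- internalized_fraction(sub1, s1$truth$cell_mask, s1$truth$pm_mask)
  expect_gte(f1$fraction, 0.98)
})

test_that("a partial internal fraction is recovered", {
  p <- confocal_sim_params(internal_fraction = 0.23, seed = 5)
  sim <- simulate_confocal_stack(p)
  sub <- select_analysis_slices(sim$stack, c(2, 3))
  f <- internalized_fraction(sub, sim$truth$cell_mask, sim$truth$pm_mask)
  expect_lt(abs(f$fraction - 0.23), 0.02)
})

test_that("automatic Otsu segmentation recovers membrane-visible fractions", {
  for (frac in c(0.1, 0.25, 0.5)) {
    p <- confocal_sim_params(internal_fraction = frac, seed = 6)
    sim <- simulate_confocal_stack(p)
    sub <- select_analysis_slices(sim$stack, c(2, 3))
    f <- internalized_fraction(sub)   # masks from segment_cell()
    expect_lt(abs(f$fraction - frac), 0.02)
  }
})

test_that("the measured fraction is invariant to gain and uniform offset", {
  p <- confocal_sim_params(internal_fraction = 0.25, read_noise_sd = 0,
                           background_photons = 0, seed = 7)
  sim <- simulate_confocal_stack(p)
  sub <- select_analysis_slices(sim$stack, c(2, 3))
  base <- internalized_fraction(sub, sim$truth$cell_mask,
                                sim$truth$pm_mask)$fraction
  scaled <- sub; scaled$slices <- sub$slices * 3 + 20
  f2 <- internalized_fraction(scaled, sim$truth$cell_mask,
                              sim$truth$pm_mask)$fraction
  expect_lt(abs(f2 - base), 0.01)
})

test_that("mask containment is enforced", {
  p <- confocal_sim_params(seed = 8)
  sim <- simulate_confocal_stack(p)
  sub <- select_analysis_slices(sim$stack, c(2, 3))
  bad_pm <- !sim$truth$cell_mask
  expect_error(internalized_fraction(sub, sim$truth$cell_mask, bad_pm),
               "contained")
})
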