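# Chromatic co-registration: centres of mass, reference ellipsoid, ratios.

meta_2ch <- acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
                             pixel_size_xy = 0.05, z_step = 0.15,
                             channels = list(channel_meta("blue", 405, 460),
                                             channel_meta("green", 488, 525)))

test_that("the centre of mass recovers an off-grid bead position", {
  out <- make_bead_stack(positions = c(1.512, 2.034, 3.07),
                         quantize = FALSE)
  ctr <- bead_center_of_mass(out$stack, meta_2ch)
  expect_equal(unname(ctr["x"]), 1.512, tolerance = 0.005)
  expect_equal(unname(ctr["y"]), 2.034, tolerance = 0.005)
  expect_equal(unname(ctr["z"]), 3.07, tolerance = 0.01)
})

test_that("an empty ROI after background subtraction is an error", {
  flat <- array(100, dim = c(9, 9, 9))
  expect_error(bead_center_of_mass(flat, meta_2ch), "empty")
})

test_that("the reference distance is the resolution ellipsoid radius", {
  spec <- list(lateral = 0.2, axial = 0.6)
  expect_equal(reference_distance(c(1, 0, 0), spec), 0.2)
  expect_equal(reference_distance(c(0, 1, 0), spec), 0.2)
  expect_equal(reference_distance(c(0, 0, 1), spec), 0.6)
  # hand-evaluated oblique direction (1, 0, 1)/sqrt(2)
  expect_equal(reference_distance(c(1, 0, 1), spec),
               1 / sqrt(0.5 / 0.2^2 + 0.5 / 0.6^2), tolerance = 1e-12)
  expect_equal(reference_distance(c(1, 0, 1), spec), 0.26833,
               tolerance = 1e-4)
  # scale of the direction vector is irrelevant
  expect_equal(reference_distance(c(5, 0, 5), spec),
               reference_distance(c(1, 0, 1), spec))
  expect_error(reference_distance(c(0, 0, 0), spec), "non-zero")
})

test_that("a purely lateral shift of one resolution gives ratio one", {
  spec_b <- theoretical_resolution(meta_2ch, meta_2ch$channels[[1]])
  pos <- rbind(c(1.6, 1.6, 3.0), c(4.8, 4.8, 3.0))
  sc <- make_shifted_channels(dim_yx = c(128, 128), positions = pos,
                              shifts = rbind(c(0, 0, 0),
                                             c(spec_b$lateral, 0, 0)),
                              quantize = FALSE)
  res <- suppressWarnings(coreg_analysis(sc$stack, meta_2ch,
                                         prominence = 1000))
  expect_equal(res$pairs$mean_ratio, 1, tolerance = 0.02)
  expect_equal(res$per_bead$dx_um, rep(spec_b$lateral, 2),
               tolerance = 0.005)
})

test_that("the ratio is symmetric under channel order", {
  pos <- rbind(c(1.6, 1.6, 3.0), c(4.8, 4.8, 3.0))
  shift <- c(0.08, 0.05, 0.2)
  sc <- make_shifted_channels(dim_yx = c(128, 128), positions = pos,
                              shifts = rbind(c(0, 0, 0), shift),
                              quantize = FALSE)
  fwd <- suppressWarnings(coreg_analysis(sc$stack, meta_2ch,
                                         prominence = 1000))
  rev_stack <- sc$stack[, , , c(2, 1)]
  meta_rev <- acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
                               pixel_size_xy = 0.05, z_step = 0.15,
                               channels = rev(meta_2ch$channels))
  rev_ <- suppressWarnings(coreg_analysis(rev_stack, meta_rev,
                                          prominence = 1000))
  expect_equal(rev_$pairs$mean_ratio, fwd$pairs$mean_ratio,
               tolerance = 1e-6)
  expect_equal(rev_$per_bead$dx_um, -fwd$per_bead$dx_um, tolerance = 1e-6)
})

test_that("the stringent resolution comes from the shorter-wavelength channel", {
  expect_equal(microqc:::shorter_wavelength_channel(meta_2ch, 1, 2), 1)
  expect_equal(microqc:::shorter_wavelength_channel(meta_2ch, 2, 1), 1)
})

test_that("zero shift gives a near-zero ratio that passes", {
  pos <- rbind(c(1.6, 1.6, 3.0), c(4.8, 4.8, 3.0))
  sc <- make_shifted_channels(dim_yx = c(128, 128), positions = pos,
                              shifts = rbind(c(0, 0, 0), c(0, 0, 0)),
                              quantize = FALSE)
  res <- suppressWarnings(coreg_analysis(sc$stack, meta_2ch,
                                         prominence = 1000))
  expect_lt(res$pairs$mean_ratio, 0.05)
  expect_true(res$pairs$pass)
})

test_that("three channels yield all three pairwise ratios", {
  meta_3ch <- acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
                               pixel_size_xy = 0.05, z_step = 0.15,
                               channels = list(channel_meta("b", 405, 460),
                                               channel_meta("g", 488, 525),
                                               channel_meta("r", 561, 600)))
  pos <- rbind(c(1.6, 1.6, 3.0), c(4.8, 4.8, 3.0))
  sc <- make_shifted_channels(dim_yx = c(128, 128), positions = pos,
                              shifts = rbind(c(0, 0, 0),
                                             c(0.05, 0, 0),
                                             c(0, 0.05, 0)),
                              quantize = FALSE)
  res <- suppressWarnings(coreg_analysis(sc$stack, meta_3ch,
                                         prominence = 1000))
  expect_equal(nrow(res$pairs), 3L)
  expect_equal(nrow(res$per_bead), 6L)  # 2 beads x 3 pairs
})

test_that("a channel saturated at a bead is skipped and counted", {
  pos <- rbind(c(1.6, 1.6, 3.0), c(4.8, 4.8, 3.0))
  sc <- make_shifted_channels(dim_yx = c(128, 128), positions = pos,
                              shifts = rbind(c(0, 0, 0), c(0, 0, 0)),
                              quantize = FALSE)
  stack <- sc$stack
  stack[33, 33, 21, 2] <- 65535  # saturate channel 2 inside bead 1's ROI
  res <- suppressWarnings(coreg_analysis(stack, meta_2ch,
                                         prominence = 1000))
  expect_equal(res$n_skipped, 1L)
  expect_equal(nrow(res$per_bead), 1L)
})
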