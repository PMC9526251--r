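# Stage drift metrics and positioning repeatability.

spec_stage <- theoretical_resolution(
  acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
                   pixel_size_xy = 0.05, z_step = 0.15,
                   channels = list(channel_meta("GFP", 488, 525))))

test_that("the classification bands follow the drift bounds table", {
  b <- drift_class_bounds()
  expect_equal(microqc:::classify_band(30, b$tau_standard_max,
                                       b$tau_acceptable_max), "standard")
  expect_equal(microqc:::classify_band(45, b$tau_standard_max,
                                       b$tau_acceptable_max), "acceptable")
  expect_equal(microqc:::classify_band(120, b$tau_standard_max,
                                       b$tau_acceptable_max), "acceptable")
  expect_equal(microqc:::classify_band(121, b$tau_standard_max,
                                       b$tau_acceptable_max), "critical")
  expect_equal(microqc:::worst_class(c("standard", "acceptable")),
               "acceptable")
  expect_equal(microqc:::worst_class(c("critical", "standard")), "critical")
})

test_that("an immobile track stabilizes immediately with zero velocities", {
  tr <- track_series(seq(0, 100, 10), rep(1, 11), rep(2, 11), rep(3, 11))
  m <- drift_metrics(tr, spec_stage)
  expect_true(m$stabilized)
  expect_equal(m$tau_stab, 0)
  expect_equal(m$v_before, 0)
  expect_equal(m$v_after, 0)
  expect_equal(m$class_overall, "standard")
})

test_that("stabilization time follows the relaxation model analytically", {
  gen <- make_drift_track(noise_sd = 0, amplitude = c(1.5, 1.0, 3.0),
                          tau_min = 30, interval_min = 10,
                          duration_min = 900)
  tr <- track_series(gen$track$t_min, gen$track$x_um, gen$track$y_um,
                     gen$track$z_um)
  m <- drift_metrics(tr, spec_stage)
  # first frame whose remaining displacement per axis is inside resolution
  t_star <- max(30 * log(1.5 / spec_stage$lateral),
                30 * log(1.0 / spec_stage$lateral),
                30 * log(3.0 / spec_stage$axial))
  truth <- 10 * ceiling(t_star / 10)
  expect_true(m$stabilized)
  expect_lte(abs(m$tau_stab - truth), 10)
  expect_gt(m$v_before, m$v_after)
})

test_that("a tighter resolution can only lengthen the stabilization time", {
  gen <- make_drift_track(seed = 5, amplitude = c(1.5, 1.0, 3.0))
  tr <- track_series(gen$track$t_min, gen$track$x_um, gen$track$y_um,
                     gen$track$z_um)
  loose <- drift_metrics(tr, spec_stage)
  tight <- drift_metrics(tr, list(lateral = spec_stage$lateral / 3,
                                  axial = spec_stage$axial / 3))
  expect_gte(tight$tau_stab, loose$tau_stab)
})

test_that("a runaway drift is reported as never stabilized", {
  t <- seq(0, 300, 10)
  tr <- track_series(t, 0.05 * t, rep(0, length(t)), rep(0, length(t)))
  m <- drift_metrics(tr, spec_stage)
  expect_false(m$stabilized)
  expect_true(is.na(m$tau_stab))
  expect_equal(m$class_tau, "critical")
  expect_equal(m$class_overall, "critical")
  # 0.05 um/min everywhere -> 50 nm/min before stabilization
  expect_equal(m$v_before, 50, tolerance = 1e-9)
})

test_that("the printed worked example classifies as expected", {
  cls <- classify_drift(105, 56, 8)
  expect_equal(cls$tau, "acceptable")
  expect_equal(cls$v_before, "acceptable")
  expect_equal(cls$v_after, "standard")
  expect_equal(cls$overall, "acceptable")
})

test_that("flagged frames are excluded and never interpolated", {
  t <- seq(0, 100, 10)
  x <- rep(1, 11); x[5] <- 50  # wild outlier on a lost frame
  flg <- rep(FALSE, 11); flg[5] <- TRUE
  tr <- track_series(t, x, rep(2, 11), rep(3, 11), flagged = flg)
  m <- drift_metrics(tr, spec_stage)
  expect_equal(m$tau_stab, 0)
  expect_equal(m$v_before, 0)
})

test_that("tracking a synthetic time-lapse recovers the drift path", {
  meta_tl <- acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
                              pixel_size_xy = 0.05, z_step = 0.15,
                              time_interval = 60,
                              channels = list(channel_meta("GFP", 488, 525)))
  n_t <- 6
  tl <- array(0, dim = c(64, 64, 21, n_t))
  xs <- 1.4 + 0.04 * (seq_len(n_t) - 1)
  for (k in seq_len(n_t)) {
    tl[, , , k] <- make_bead_stack(positions = c(xs[k], 1.6, 1.5),
                                   n_z = 21, quantize = FALSE)$stack
  }
  tr <- track_single_bead(tl, meta_tl)
  expect_equal(tr$t_min, 0:(n_t - 1))
  expect_equal(diff(tr$x_um), rep(0.04, n_t - 1), tolerance = 0.005)
  expect_true(all(abs(tr$y_um - 1.6) < 0.01))
})

test_that("repeatability is the sample SD of the revisit coordinates", {
  gen <- make_repeat_visits(seed = 6, n_visits = 500,
                            sigma = c(0.05, 0.08))
  r <- repeatability(gen$visits)
  expect_equal(r$sigma_x, sd(gen$visits$x_um), tolerance = 1e-12)
  expect_equal(r$sigma_x, 0.05, tolerance = 0.15)
  expect_equal(r$sigma_y, 0.08, tolerance = 0.15)
  expect_true(r$pass_x)
  expect_true(r$pass_y)
  bad <- make_repeat_visits(seed = 6, n_visits = 100, sigma = c(0.5, 0.5))
  rb <- repeatability(bad$visits)
  expect_false(rb$pass_x)
})

test_that("reference visits follow the nine-position schedule", {
  n <- 18
  tr <- track_series(seq_len(n), seq_len(n), rep(0, n))
  v <- reference_visits(tr, cycle = 9, ref_index = c(0, 2, 4, 6, 8))
  expect_equal(nrow(v), 10)
  expect_equal(v$x_um, c(1, 3, 5, 7, 9, 10, 12, 14, 16, 18))
})

test_that("track CSV round-trips through the reader", {
  gen <- make_drift_track(seed = 2, duration_min = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(gen$track, f, row.names = FALSE)
  tr <- read_track_csv(f)
  expect_s3_class(tr, "track_series")
  expect_equal(tr$z_um, gen$track$z_um)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1:3, b = 1:3), bad, row.names = FALSE)
  expect_error(read_track_csv(bad), "t_min")
})
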