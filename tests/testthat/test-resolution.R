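# Theoretical resolution formulas, Nyquist criterion, sampling checks.

meta_wf <- acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
                            pixel_size_xy = 0.05, z_step = 0.15,
                            channels = list(channel_meta("GFP", 488, 525)))

test_that("wide-field FWHM matches the hand-evaluated formulas", {
  spec <- theoretical_resolution(meta_wf)
  expect_equal(spec$lateral, 0.51 * 0.525 / 1.4, tolerance = 1e-12)
  expect_equal(spec$lateral, 0.19125, tolerance = 1e-5)
  expect_equal(spec$axial, 1.77 * 1.515 * 0.525 / 1.4^2, tolerance = 1e-12)
  expect_equal(spec$axial, 0.71827, tolerance = 1e-4)
})

test_that("confocal formulas use the excitation wavelength and pinhole term", {
  meta <- acquisition_meta("LSCM", na = 1.4, refractive_index = 1.515,
                           pixel_size_xy = 0.05,
                           channels = list(channel_meta("GFP", 488, 525)))
  spec <- theoretical_resolution(meta)
  expect_equal(spec$lateral, 0.51 * 0.488 / 1.4, tolerance = 1e-12)
  expect_equal(spec$lateral, 0.17777, tolerance = 1e-4)
  expect_equal(spec$axial,
               0.88 * 0.488 / (1.515 - sqrt(1.515^2 - 1.4^2)),
               tolerance = 1e-12)
  expect_equal(spec$axial, 0.45879, tolerance = 1e-4)
})

test_that("spinning-disk axial formula drops the 0.88 pinhole factor", {
  meta <- acquisition_meta("SDCM", na = 1.4, refractive_index = 1.515,
                           pixel_size_xy = 0.05,
                           channels = list(channel_meta("GFP", 488, 525)))
  spec <- theoretical_resolution(meta)
  expect_equal(spec$lateral, 0.51 * 0.525 / 1.4, tolerance = 1e-12)
  expect_equal(spec$axial, 0.525 / (1.515 - sqrt(1.515^2 - 1.4^2)),
               tolerance = 1e-12)
  expect_equal(spec$axial, 0.56089, tolerance = 1e-4)
})

test_that("axial FWHM exceeds lateral FWHM for every modality", {
  for (mod in c("WF", "LSCM", "SDCM")) {
    for (na in c(0.8, 1.0, 1.2, 1.4)) {
      meta <- acquisition_meta(mod, na = na, refractive_index = 1.515,
                               pixel_size_xy = 0.05,
                               channels = list(channel_meta("GFP", 488, 525)))
      spec <- theoretical_resolution(meta)
      expect_gt(spec$axial, spec$lateral)
    }
  }
})

test_that("resolution shrinks with NA and grows with wavelength", {
  res_at <- function(mod, na, em) {
    meta <- acquisition_meta(mod, na = na, refractive_index = 1.515,
                             pixel_size_xy = 0.05,
                             channels = list(channel_meta("c", em - 30, em)))
    theoretical_resolution(meta)
  }
  for (mod in c("WF", "LSCM", "SDCM")) {
    nas <- c(0.6, 0.9, 1.2, 1.4)
    lat <- vapply(nas, function(a) res_at(mod, a, 525)$lateral, numeric(1))
    ax <- vapply(nas, function(a) res_at(mod, a, 525)$axial, numeric(1))
    expect_true(all(diff(lat) < 0))
    expect_true(all(diff(ax) < 0))
    ems <- c(460, 525, 600, 680)
    lat_w <- vapply(ems, function(e) res_at(mod, 1.4, e)$lateral, numeric(1))
    ax_w <- vapply(ems, function(e) res_at(mod, 1.4, e)$axial, numeric(1))
    expect_true(all(diff(lat_w) > 0))
    expect_true(all(diff(ax_w) > 0))
  }
})

test_that("confocal axial formulas stay finite and positive as NA -> n", {
  meta <- acquisition_meta("LSCM", na = 1.515 - 1e-9,
                           refractive_index = 1.515, pixel_size_xy = 0.05,
                           channels = list(channel_meta("GFP", 488, 525)))
  spec <- theoretical_resolution(meta)
  expect_true(is.finite(spec$axial) && spec$axial > 0)
})

test_that("Nyquist criterion follows lambda/(8 NA) with the pinhole factor", {
  expect_equal(nyquist_pixel(488, 1.4), 488 / (8 * 1.4), tolerance = 1e-12)
  expect_equal(nyquist_pixel(488, 1.4), 43.5714, tolerance = 1e-4)
  expect_equal(nyquist_pixel(488, 1.4, 1.6), 1.6 * 488 / (8 * 1.4),
               tolerance = 1e-12)
  expect_equal(nyquist_pixel(488, 1.4, 1.6), 69.7143, tolerance = 1e-4)
  expect_equal(nyquist_pixel(800, 1.0), 100)
  expect_error(nyquist_pixel(488, 1.4, 0.9), "pinhole_factor")
  expect_error(nyquist_pixel(488, -1), "na")
})

test_that("the integer criterion truncates so it never exceeds the bound", {
  for (lam in c(405, 488, 561, 640)) {
    for (na in c(0.8, 1.0, 1.4)) {
      expect_lte(nyquist_pixel_nm(lam, na), nyquist_pixel(lam, na))
      expect_lt(nyquist_pixel(lam, na) - nyquist_pixel_nm(lam, na), 1)
    }
  }
})

test_that("sensor pixel pitch projects to the sample plane by magnification", {
  expect_equal(effective_pixel_size(6.5, 20), 0.325)
  expect_equal(effective_pixel_size(6.5, 100), 0.065)
  expect_error(effective_pixel_size(-6.5, 20))
  expect_error(effective_pixel_size(6.5, 0))
})

test_that("sampling check passes at exactly half the resolution", {
  spec <- theoretical_resolution(meta_wf)
  at <- function(px, dz) {
    m <- acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
                          pixel_size_xy = px, z_step = dz,
                          channels = list(channel_meta("GFP", 488, 525)))
    sampling_check(m)
  }
  ok <- at(spec$lateral / 2, spec$axial / 2)
  expect_true(ok$lateral_pass)
  expect_true(ok$axial_pass)
  expect_true(ok$complete)
  bad <- at(0.325, 0.15)  # 6.5 um sensor pixel behind a 20x objective
  expect_false(bad$lateral_pass)
  incomplete <- at(0.05, NA)
  expect_false(incomplete$complete)
  expect_true(is.na(incomplete$axial_pass))
})

test_that("an objective NA above the immersion index is a domain error", {
  expect_error(
    acquisition_meta("LSCM", na = 1.4, refractive_index = 1.33,
                     pixel_size_xy = 0.05,
                     channels = list(channel_meta("GFP", 488, 525))))
})
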