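# Bead detection, exclusion rules and Gaussian PSF fitting.

meta_psf <- acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
                             pixel_size_xy = 0.05, z_step = 0.15,
                             channels = list(channel_meta("GFP", 488, 525)))
spec_psf <- theoretical_resolution(meta_psf)

test_that("detection finds an isolated bead at its projected position", {
  out <- make_bead_stack(positions = c(1.5, 2.0, 3.0))
  beads <- detect_beads(out$stack, meta_psf, prominence = 1000)
  kept <- beads[beads$status == "kept", ]
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$x_px, 30)
  expect_equal(kept$y_px, 40)
  expect_equal(kept$z_max, 20)
})

test_that("border beads are excluded, not silently dropped", {
  out <- make_bead_stack(dim_yx = c(96, 96),
                         positions = rbind(c(0.3, 2.4, 3.0),
                                           c(2.7, 2.4, 3.0)))
  beads <- detect_beads(out$stack, meta_psf, prominence = 1000)
  expect_equal(nrow(beads), 2L)
  expect_identical(as.character(beads$status[beads$x_px < 10]), "edge")
  expect_identical(as.character(beads$status[beads$x_px > 10]), "kept")
})

test_that("both members of a too-close pair are excluded", {
  out <- suppressWarnings(
    make_bead_stack(dim_yx = c(96, 96),
                    positions = rbind(c(1.7, 1.7, 3.0),
                                      c(3.0, 1.7, 3.0))))
  expect_warning(
    beads <- detect_beads(out$stack, meta_psf, prominence = 1000,
                          min_spacing = 2),
    "no beads kept")
  expect_true(all(as.character(beads$status) == "too_close"))
})

test_that("a saturated bead is flagged when its ROI touches the ceiling", {
  out <- make_bead_stack(dim_yx = c(96, 96),
                         positions = c(2.4, 2.4, 3.0),
                         amplitude = 70000, bit_depth = 16L)
  expect_warning(
    beads <- detect_beads(out$stack, meta_psf, prominence = 1000),
    "no beads kept")
  expect_identical(as.character(beads$status), "saturated")
  kept_ok <- detect_beads(out$stack, meta_psf, prominence = 1000,
                          discard_saturated = FALSE)
  expect_identical(as.character(kept_ok$status), "kept")
})

test_that("the central-zone filter re-flags off-centre beads", {
  beads <- data.frame(x_px = c(47, 5), y_px = c(47, 5), z_max = c(20, 20),
                      value = c(8000, 8000),
                      status = factor(c("kept", "kept"),
                                      levels = microqc:::bead_status_levels()))
  out <- central_zone_filter(beads, c(96, 96), fraction = 0.30)
  expect_identical(as.character(out$status), c("kept", "central_zone_out"))
})

test_that("noiseless fits recover the injected FWHM to within 0.5%", {
  out <- make_bead_stack(positions = c(1.5, 2.0, 3.0), quantize = FALSE)
  beads <- detect_beads(out$stack, meta_psf, prominence = 1000)
  fit <- fit_psf(out$stack, beads[1, ], meta_psf, spec = spec_psf)
  expect_true(fit$valid)
  expect_equal(fit$fwhm_x, out$truth$fwhm_x, tolerance = 0.005)
  expect_equal(fit$fwhm_y, out$truth$fwhm_y, tolerance = 0.005)
  expect_equal(fit$fwhm_z, out$truth$fwhm_z, tolerance = 0.005)
  expect_gt(fit$r2_x, 0.999)
  expect_gt(fit$r2_z, 0.999)
  expect_equal(fit$lar, 1, tolerance = 1e-6)
  expect_equal(fit$ratio_xy, 1, tolerance = 0.005)
  expect_equal(fit$ratio_z, 1, tolerance = 0.005)
})

test_that("an anisotropic lateral PSF drives the LAR below one", {
  out <- make_bead_stack(positions = c(1.5, 1.5, 3.0),
                         fwhm = c(0.30, 0.20, 0.70), quantize = FALSE)
  bead <- data.frame(x_px = 30, y_px = 30, z_max = 20)
  fit <- fit_psf(out$stack, bead, meta_psf, spec = spec_psf)
  expect_equal(fit$lar, 0.20 / 0.30, tolerance = 0.02)
  expect_equal(fit$lar, min(fit$fwhm_x, fit$fwhm_y) /
                        max(fit$fwhm_x, fit$fwhm_y), tolerance = 1e-12)
})

test_that("SNR follows the square root of the 12-bit-rescaled maximum", {
  out <- make_bead_stack(positions = c(1.5, 1.5, 3.0),
                         amplitude = 40000 - 100, quantize = FALSE)
  bead <- data.frame(x_px = 30, y_px = 30, z_max = 20)
  fit <- fit_psf(out$stack, bead, meta_psf, spec = spec_psf)
  # max 40000 ADU on a 16-bit scale -> sqrt(40000 / 16) = 50
  expect_equal(fit$snr, 50, tolerance = 1e-9)
})

test_that("SBR of a bright bead on a dim background is high", {
  out <- make_bead_stack(positions = c(1.5, 1.5, 3.0), amplitude = 8000,
                         background = 100, quantize = FALSE)
  bead <- data.frame(x_px = 30, y_px = 30, z_max = 20)
  fit <- fit_psf(out$stack, bead, meta_psf, spec = spec_psf)
  expect_gt(fit$sbr, 3)
})

test_that("a flat profile yields an invalid fit with a reason", {
  r <- microqc:::fit_gaussian_profile(rep(100, 31))
  expect_false(r$valid)
  expect_match(r$reason, "flat")
})

test_that("summaries filter beads per axis by goodness of fit", {
  out <- make_bead_stack(dim_yx = c(128, 128),
                         positions = rbind(c(1.4, 1.4, 3.0),
                                           c(5.0, 1.4, 3.0),
                                           c(1.4, 5.0, 3.0),
                                           c(5.0, 5.0, 3.0),
                                           c(3.2, 3.2, 3.0)),
                         quantize = FALSE)
  beads <- detect_beads(out$stack, meta_psf, prominence = 1000)
  kept <- beads[beads$status == "kept", ]
  fits <- lapply(seq_len(nrow(kept)), function(i)
    fit_psf(out$stack, kept[i, ], meta_psf, spec = spec_psf))
  s <- summarize_psf(fits, spec_psf)
  expect_equal(s$n_beads, 5L)
  expect_equal(s$axes$n, c(5L, 5L, 5L))
  expect_equal(s$ratio_xy, 1, tolerance = 0.005)
  expect_equal(s$ratio_z, 1, tolerance = 0.005)
  expect_true(s$pass_xy)
  expect_true(s$pass_z)
  # an impossible R^2 floor removes every bead and is reported as an error
  expect_error(suppressWarnings(summarize_psf(fits, spec_psf, r2_min = 1.1)),
               "R\\^2")
})

test_that("the full pipeline emits a report with ratio flags", {
  out <- make_bead_stack(dim_yx = c(128, 128),
                         positions = rbind(c(1.4, 1.4, 3.0),
                                           c(5.0, 1.4, 3.0),
                                           c(1.4, 5.0, 3.0),
                                           c(5.0, 5.0, 3.0),
                                           c(3.2, 3.2, 3.0)))
  res <- analyze_psf(out$stack, meta_psf, prominence = 1000,
                     central_fraction = 1)
  expect_s3_class(res$report, "qc_report")
  m <- res$report$metrics
  expect_true(all(c("fwhm_ratio_xy", "fwhm_ratio_z") %in% m$metric))
  expect_true(all(m$pass[m$metric %in% c("fwhm_ratio_xy", "fwhm_ratio_z")]))
  expect_equal(m$value[m$metric == "n_beads"], 5)
})
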