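#' @name psf
#' @title PSF measurement from sub-resolution bead stacks
#'
#' @description
#' Detects beads on the maximum-intensity z-projection of a single-channel
#' 3D stack, fits one-dimensional Gaussians to intensity profiles drawn
#' through the brightest voxel of each bead along x, y and z, and reports
#' FWHM values, their ratios to the theoretical resolution, the lateral
#' asymmetry ratio (LAR), the signal-to-background ratio (SBR) and a
#' square-root signal-to-noise proxy (SNR).
NULL

# Default cubic ROI half-sizes (um): the box side is 6x the expected FWHM
# on each axis, which contains essentially all of a Gaussian spot.
default_roi <- function(spec) {
  list(half_xy = 3 * spec$lateral, half_z = 3 * spec$axial)
}

#' Detect beads on a maximum-intensity projection
#'
#' Local maxima of the z-projection whose intensity exceeds the image
#' median by at least \code{prominence} become candidates. Candidates too
#' close to the border, too close to one another, or (optionally)
#' containing a saturated voxel in their ROI are marked excluded rather
#' than silently dropped.
#'
#' @param stack Array \code{[y, x, z]}, single channel, >= 3 z planes.
#' @param meta An \code{\link{acquisition_meta}}.
#' @param prominence Minimum height above the projection median (ADU).
#' @param min_spacing Minimum centre-to-centre bead distance (um);
#'   default 2x the ROI side.
#' @param edge_margin Minimum distance from the image border (um);
#'   default the ROI half-side.
#' @param discard_saturated Mark beads whose ROI contains a voxel at the
#'   saturation level?
#' @param spec Optional \code{resolution_spec} used for the default ROI;
#'   computed from \code{meta} when absent.
#'
#' @return A data frame of class \code{bead_records}: 0-based pixel
#'   coordinates \code{x_px}, \code{y_px}, the brightest plane
#'   \code{z_max}, the projection \code{value}, and a \code{status} factor
#'   (\code{kept}, \code{edge}, \code{too_close}, \code{saturated},
#'   \code{central_zone_out}).
#' @export
detect_beads <- function(stack, meta, prominence,
                         min_spacing = NULL, edge_margin = NULL,
                         discard_saturated = TRUE, spec = NULL) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("'stack' must be a [y, x, z] array", call. = FALSE)
  if (dim(stack)[3] < 3L)
    stop("'stack' must have at least 3 z planes", call. = FALSE)
  if (!is.finite(prominence) || prominence <= 0)
    stop("'prominence' must be > 0", call. = FALSE)
  if (is.null(spec)) spec <- theoretical_resolution(meta)
  roi <- default_roi(spec)
  if (is.null(min_spacing)) min_spacing <- 2 * 2 * roi$half_xy
  if (is.null(edge_margin)) edge_margin <- roi$half_xy

  px <- meta$pixel_size_xy
  mip <- apply(stack, c(1, 2), max)
  ny <- nrow(mip); nx <- ncol(mip)
  floor_level <- stats::median(mip)

  # 8-neighbourhood local maxima above the prominence floor
  cand <- which(mip >= floor_level + prominence, arr.ind = TRUE)
  is_max <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    nb <- mip[max(1, i - 1):min(ny, i + 1), max(1, j - 1):min(nx, j + 1)]
    is_max[k] <- mip[i, j] >= max(nb)
  }
  cand <- cand[is_max, , drop = FALSE]
  # collapse plateau ties closer than one FWHM to a single record
  if (nrow(cand) > 1) {
    keep <- rep(TRUE, nrow(cand))
    d <- as.matrix(stats::dist(cand)) * px
    for (k in seq_len(nrow(cand))) {
      if (!keep[k]) next
      dup <- which(d[k, ] < spec$lateral & seq_len(nrow(cand)) > k)
      keep[dup] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  n <- nrow(cand)
  if (n == 0L) {
    warning("no beads detected above the prominence threshold")
    return(empty_beads())
  }

  x_px <- cand[, 2] - 1  # 0-based
  y_px <- cand[, 1] - 1
  value <- mip[cand]
  z_max <- vapply(seq_len(n), function(k)
    which.max(stack[cand[k, 1], cand[k, 2], ]) - 1L, integer(1))

  status <- rep("kept", n)
  # border proximity (physical units)
  dist_edge <- pmin(x_px, nx - 1 - x_px, y_px, ny - 1 - y_px) * px
  status[dist_edge < edge_margin] <- "edge"
  # mutual proximity: both members of a close pair are excluded
  if (n > 1) {
    d <- as.matrix(stats::dist(cbind(x_px, y_px))) * px
    diag(d) <- Inf
    status[apply(d, 1, min) < min_spacing & status == "kept"] <- "too_close"
    # also flag pairs where one member was already edge-excluded
    close_any <- apply(d, 1, min) < min_spacing
    status[close_any & status == "kept"] <- "too_close"
  }
  if (discard_saturated) {
    sat <- saturation_level(meta)
    hx <- max(1L, round(roi$half_xy / px))
    hz <- max(1L, round(roi$half_z / ifelse(is.na(meta$z_step), px,
                                            meta$z_step)))
    for (k in which(status == "kept")) {
      ii <- max(1, y_px[k] + 1 - hx):min(ny, y_px[k] + 1 + hx)
      jj <- max(1, x_px[k] + 1 - hx):min(nx, x_px[k] + 1 + hx)
      kk <- max(1, z_max[k] + 1 - hz):min(dim(stack)[3], z_max[k] + 1 + hz)
      if (any(stack[ii, jj, kk] >= sat)) status[k] <- "saturated"
    }
  }
  beads <- data.frame(x_px = x_px, y_px = y_px, z_max = z_max,
                      value = value,
                      status = factor(status, levels = bead_status_levels()))
  class(beads) <- c("bead_records", class(beads))
  if (!any(beads$status == "kept"))
    warning("no beads kept after exclusion rules")
  beads
}

bead_status_levels <- function() {
  c("kept", "edge", "too_close", "saturated", "central_zone_out")
}

empty_beads <- function() {
  b <- data.frame(x_px = integer(0), y_px = integer(0), z_max = integer(0),
                  value = numeric(0),
                  status = factor(character(0),
                                  levels = bead_status_levels()))
  class(b) <- c("bead_records", class(b))
  b
}

#' Restrict beads to the central zone of the field of view
#'
#' Beads outside a centred square window whose side is
#' \code{fraction * min(width, height)} pixels are flagged
#' \code{central_zone_out}; the off-axis aberrations that grow toward the
#' corners of the field would otherwise bias the FWHM statistics.
#'
#' @param beads A \code{bead_records} data frame.
#' @param image_shape \code{c(ny, nx)} of the projection.
#' @param fraction Window side as a fraction of the smaller image side,
#'   in (0, 1]; default 0.30.
#'
#' @return The bead table with updated \code{status}.
#' @export
central_zone_filter <- function(beads, image_shape, fraction = 0.30) {
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(beads) == 0L) return(beads)
  ny <- image_shape[1]; nx <- image_shape[2]
  half <- fraction * min(nx, ny) / 2
  cx <- (nx - 1) / 2
  cy <- (ny - 1) / 2
  out <- abs(beads$x_px - cx) > half | abs(beads$y_px - cy) > half
  beads$status[out & beads$status == "kept"] <- "central_zone_out"
  beads
}

# Gaussian + constant fit of a 1D profile. Returns sigma (pixels), centre,
# R^2 and a validity flag.
fit_gaussian_profile <- function(profile) {
  n <- length(profile)
  t <- seq_len(n) - 1
  c0 <- min(profile)
  a0 <- max(profile) - c0
  if (a0 <= 0)
    return(list(valid = FALSE, reason = "flat profile"))
  w <- pmax(profile - c0, 0)
  mu0 <- sum(t * w) / sum(w)
  s0 <- sqrt(sum((t - mu0)^2 * w) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- n / 6
  fit <- tryCatch(
    minpack.lm::nlsLM(
      profile ~ C + A * exp(-(t - mu)^2 / (2 * s^2)),
      start = list(C = c0, A = a0, mu = mu0, s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(valid = FALSE, reason = "fit did not converge"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["s"]]) || cf[["s"]] <= 0)
    return(list(valid = FALSE, reason = "non-positive fitted sigma"))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((profile - mean(profile))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(valid = TRUE, sigma = abs(cf[["s"]]), mu = cf[["mu"]],
       amplitude = cf[["A"]], offset = cf[["C"]], r2 = r2)
}

#' Fit per-axis Gaussians through a bead's brightest voxel
#'
#' Locates the maximum-intensity voxel inside the bead's ROI (ties broken
#' toward the lowest z, then y, then x index), extracts single-voxel-wide
#' intensity profiles along x, y and z through it, and fits each with a
#' Gaussian-plus-constant model. FWHM is \eqn{2\sqrt{2\ln 2}\,\sigma}
#' converted to micrometres with the lateral pixel size or z step.
#' SBR is the mean intensity of the Otsu-segmented bead on its brightest
#' plane divided by the mean of a 1-um-thick annulus around the
#' segmentation; SNR is the square root of the maximum voxel intensity
#' rescaled to a 12-bit range.
#'
#' @param stack Array \code{[y, x, z]}.
#' @param bead One row of a \code{bead_records} table.
#' @param meta An \code{\link{acquisition_meta}} (needs \code{z_step}).
#' @param spec Optional \code{resolution_spec}; computed from \code{meta}
#'   when absent. Supplies ratios to theory and the default ROI.
#'
#' @return An object of class \code{psf_result}: per-axis \code{fwhm_*}
#'   (um) and \code{r2_*}, \code{sbr}, \code{snr}, \code{lar},
#'   \code{ratio_xy}, \code{ratio_z}, \code{valid} and \code{reason}.
#' @export
fit_psf <- function(stack, bead, meta, spec = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (is.na(meta$z_step))
    stop("'meta$z_step' is required for 3D PSF fitting", call. = FALSE)
  if (is.null(spec)) spec <- theoretical_resolution(meta)
  roi <- default_roi(spec)
  px <- meta$pixel_size_xy
  zs <- meta$z_step
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nz <- dim(stack)[3]

  hx <- max(2L, round(roi$half_xy / px))
  hz <- max(2L, round(roi$half_z / zs))
  ii <- max(1, bead$y_px + 1 - hx):min(ny, bead$y_px + 1 + hx)
  jj <- max(1, bead$x_px + 1 - hx):min(nx, bead$x_px + 1 + hx)
  kk <- max(1, bead$z_max + 1 - hz):min(nz, bead$z_max + 1 + hz)
  sub <- stack[ii, jj, kk, drop = FALSE]

  # brightest voxel; ties resolved toward the lowest (z, y, x)
  mx <- max(sub)
  idx <- which(sub == mx, arr.ind = TRUE)
  idx <- idx[order(idx[, 3], idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  y0 <- ii[idx[1]]; x0 <- jj[idx[2]]; z0 <- kk[idx[3]]

  fx <- fit_gaussian_profile(stack[y0, jj, z0])
  fy <- fit_gaussian_profile(stack[ii, x0, z0])
  fz <- fit_gaussian_profile(stack[y0, x0, kk])
  invalid <- !fx$valid || !fy$valid || !fz$valid
  reason <- if (invalid) {
    paste(stats::na.omit(c(if (!fx$valid) paste("x:", fx$reason),
                           if (!fy$valid) paste("y:", fy$reason),
                           if (!fz$valid) paste("z:", fz$reason))),
          collapse = "; ")
  } else NA_character_

  fac <- fwhm_factor()
  fwhm_x <- if (fx$valid) fac * fx$sigma * px else NA_real_
  fwhm_y <- if (fy$valid) fac * fy$sigma * px else NA_real_
  fwhm_z <- if (fz$valid) fac * fz$sigma * zs else NA_real_

  # SBR on the brightest plane: Otsu segmentation inside the ROI and a
  # 1-um annulus around the segmented bead
  plane <- stack[, , z0]
  rng <- range(plane)
  sbr <- NA_real_
  if (diff(rng) > 0) {
    roi_plane <- plane[ii, jj]
    thr <- EBImage::otsu((roi_plane - rng[1]) / diff(rng), range = c(0, 1)) *
      diff(rng) + rng[1]
    mask <- matrix(0, ny, nx)
    mask[ii, jj] <- roi_plane > thr
    if (any(mask > 0) && !all(mask > 0)) {
      dist_px <- EBImage::distmap(1 - mask)
      ann <- dist_px > 0 & dist_px * px <= 1
      if (any(ann) && mean(plane[ann]) > 0)
        sbr <- mean(plane[mask > 0]) / mean(plane[ann])
    }
  }
  snr <- sqrt(mx * 2^12 / 2^meta$bit_depth)
  lar <- if (!invalid) min(fwhm_x, fwhm_y) / max(fwhm_x, fwhm_y) else NA_real_

  structure(
    list(fwhm_x = fwhm_x, fwhm_y = fwhm_y, fwhm_z = fwhm_z,
         r2_x = if (fx$valid) fx$r2 else NA_real_,
         r2_y = if (fy$valid) fy$r2 else NA_real_,
         r2_z = if (fz$valid) fz$r2 else NA_real_,
         sbr = sbr, snr = snr, lar = lar,
         ratio_xy = mean(c(fwhm_x, fwhm_y)) / spec$lateral,
         ratio_z = fwhm_z / spec$axial,
         valid = !invalid, reason = reason),
    class = "psf_result")
}

#' Summarize PSF fits across beads
#'
#' Per-axis mean and SD of the FWHM over beads whose fit quality passes
#' \code{r2_min} on that axis, mean measured/theoretical ratios, mean SBR
#' and LAR, and tolerance flags for the lateral and axial ratios.
#'
#' @param results List of \code{psf_result} objects.
#' @param spec A \code{resolution_spec} providing the theoretical FWHM.
#' @param r2_min Minimum per-axis goodness of fit; default 0.95.
#' @param registry A \code{\link{tolerance_registry}}.
#'
#' @return A list with the per-axis summary table (\code{axes}), mean
#'   ratios and flags, \code{n_beads} (valid fits) and \code{mean_sbr},
#'   \code{mean_lar}.
#' @export
summarize_psf <- function(results, spec, r2_min = 0.95,
                          registry = tolerance_registry()) {
  results <- Filter(function(r) isTRUE(r$valid), results)
  if (length(results) == 0L)
    stop("no valid PSF fits to summarize", call. = FALSE)
  if (length(results) < 5L)
    warning("fewer than 5 beads analyzed; protocol recommends at least 5")
  g <- function(field) vapply(results, `[[`, numeric(1), field)
  axes <- data.frame(axis = c("x", "y", "z"),
                     theoretical = c(spec$lateral, spec$lateral, spec$axial))
  fwhm <- cbind(g("fwhm_x"), g("fwhm_y"), g("fwhm_z"))
  r2 <- cbind(g("r2_x"), g("r2_y"), g("r2_z"))
  axes$n <- colSums(r2 >= r2_min, na.rm = TRUE)
  if (any(axes$n == 0L))
    stop(sprintf("all beads filtered out by the R^2 >= %g criterion on axis %s",
                 r2_min, paste(axes$axis[axes$n == 0], collapse = ",")),
         call. = FALSE)
  sel <- r2 >= r2_min
  axes$mean_fwhm <- vapply(1:3, function(a) mean(fwhm[sel[, a], a]),
                           numeric(1))
  axes$sd_fwhm <- vapply(1:3, function(a) {
    v <- fwhm[sel[, a], a]
    if (length(v) > 1) stats::sd(v) else 0
  }, numeric(1))
  axes$ratio <- axes$mean_fwhm / axes$theoretical
  ratio_xy <- mean(axes$ratio[1:2])
  ratio_z <- axes$ratio[3]
  list(axes = axes,
       ratio_xy = ratio_xy,
       ratio_z = ratio_z,
       pass_xy = flag_metric(ratio_xy, "fwhm_ratio", registry),
       pass_z = flag_metric(ratio_z, "fwhm_ratio", registry),
       n_beads = length(results),
       mean_sbr = mean(g("sbr"), na.rm = TRUE),
       mean_lar = mean(g("lar"), na.rm = TRUE))
}

#' Full PSF analysis of a bead stack
#'
#' Convenience pipeline: detect beads, restrict them to the central zone,
#' fit every kept bead and summarize, returning a \code{\link{qc_report}}
#' alongside the per-bead tables.
#'
#' @inheritParams detect_beads
#' @param central_fraction Central-zone side fraction (see
#'   \code{\link{central_zone_filter}}); \code{1} disables the filter.
#' @param r2_min Per-axis goodness-of-fit filter.
#' @param registry A \code{\link{tolerance_registry}}.
#' @param input Input label recorded in the report.
#'
#' @return A list with \code{report} (\code{qc_report}), \code{beads}
#'   (detection table), \code{fits} (list of \code{psf_result}) and
#'   \code{summary}.
#' @export
analyze_psf <- function(stack, meta, prominence,
                        min_spacing = NULL, edge_margin = NULL,
                        discard_saturated = TRUE,
                        central_fraction = 0.30, r2_min = 0.95,
                        registry = tolerance_registry(),
                        input = NA_character_) {
  spec <- theoretical_resolution(meta)
  beads <- detect_beads(stack, meta, prominence, min_spacing, edge_margin,
                        discard_saturated, spec = spec)
  beads <- central_zone_filter(beads, dim(stack)[1:2], central_fraction)
  kept <- beads[beads$status == "kept", , drop = FALSE]
  fits <- lapply(seq_len(nrow(kept)), function(i)
    fit_psf(stack, kept[i, ], meta, spec = spec))
  summary <- summarize_psf(fits, spec, r2_min, registry)
  metrics <- rbind(
    metric_row("fwhm_ratio_xy", summary$ratio_xy,
               registry$thresholds[["fwhm_ratio"]], summary$pass_xy),
    metric_row("fwhm_ratio_z", summary$ratio_z,
               registry$thresholds[["fwhm_ratio"]], summary$pass_z),
    metric_row("mean_lar", summary$mean_lar),
    metric_row("mean_sbr", summary$mean_sbr),
    metric_row("n_beads", summary$n_beads))
  list(report = qc_report("psf", metrics, input = input, meta = meta),
       beads = beads, fits = fits, summary = summary)
}
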