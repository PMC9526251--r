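#' @name coreg
#' @title Chromatic co-registration analysis
#'
#' @description
#' Measures the chromatic shift between channels from multicolor beads:
#' per-channel intensity centres of mass give the experimental
#' inter-centre distance r_exp, which is compared with a reference
#' distance r_ref, the radius of the resolution ellipsoid along the
#' displacement direction. A ratio r_exp/r_ref above 1 means the two
#' channel images of the same bead would not be scored as colocalized.
NULL

#' Intensity-weighted bead centre of mass
#'
#' Subtracts the median of the ROI border voxels as background, clamps
#' negatives to zero, and returns the intensity-weighted centroid in
#' physical units (um).
#'
#' @param stack Array \code{[y, x, z]}, single channel (one bead's ROI).
#' @param meta An \code{\link{acquisition_meta}} (pixel size and z step).
#'
#' @return Named vector \code{c(x, y, z)} in um.
#' @export
bead_center_of_mass <- function(stack, meta) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nz <- dim(stack)[3]
  border <- c(stack[c(1, ny), , ], stack[, c(1, nx), ], stack[, , c(1, nz)])
  w <- pmax(stack - stats::median(border), 0)
  tot <- sum(w)
  if (tot <= 0)
    stop("ROI is empty after background subtraction", call. = FALSE)
  xs <- (seq_len(nx) - 1) * meta$pixel_size_xy
  ys <- (seq_len(ny) - 1) * meta$pixel_size_xy
  zstep <- if (is.na(meta$z_step)) meta$pixel_size_xy else meta$z_step
  zs <- (seq_len(nz) - 1) * zstep
  c(x = sum(apply(w, 2, sum) * xs) / tot,
    y = sum(apply(w, 1, sum) * ys) / tot,
    z = sum(apply(w, 3, sum) * zs) / tot)
}

#' Direction-dependent co-registration reference distance
#'
#' Radius of the resolution ellipsoid with semi-axes
#' \code{(R_lat, R_lat, R_ax)} along a unit direction \code{u}:
#' \deqn{r_{ref} = 1/\sqrt{(u_x^2+u_y^2)/R_{lat}^2 + u_z^2/R_{ax}^2}.}
#' The semi-axes are the full theoretical FWHM resolution values of the
#' pair's shorter-wavelength channel, so a purely lateral displacement
#' equal to the lateral resolution gives a ratio of exactly 1.
#'
#' @param direction Numeric length-3 vector; normalized internally, must
#'   be non-zero.
#' @param spec A \code{resolution_spec} (from the shorter-wavelength
#'   channel of the pair).
#'
#' @return r_ref in um.
#' @examples
#' spec <- list(lateral = 0.2, axial = 0.6)
#' reference_distance(c(1, 0, 0), spec)  # 0.2 (lateral semi-axis)
#' reference_distance(c(0, 0, 1), spec)  # 0.6 (axial semi-axis)
#' @export
reference_distance <- function(direction, spec) {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("'direction' must be a non-zero vector", call. = FALSE)
  u <- direction / nrm
  1 / sqrt((u[1]^2 + u[2]^2) / spec$lateral^2 + u[3]^2 / spec$axial^2)
}

# Index of the pair's resolution channel: the shortest excitation
# wavelength is the most stringent resolution value.
shorter_wavelength_channel <- function(meta, a, b) {
  la <- meta$channels[[a]]$lambda_ex
  lb <- meta$channels[[b]]$lambda_ex
  if (la <= lb) a else b
}

#' Co-registration analysis of a multichannel bead stack
#'
#' For each bead and each of the C(C-1)/2 channel pairs, computes the
#' inter-centre distance r_exp from per-channel centres of mass within the
#' bead ROI, the reference distance r_ref along the displacement
#' direction (lateral direction when the displacement is zero), and the
#' ratio r_exp/r_ref. Beads below detection in a channel are skipped for
#' the pairs involving that channel and counted.
#'
#' @param stack Array \code{[y, x, z, channel]}.
#' @param meta An \code{\link{acquisition_meta}} whose \code{channels}
#'   match the stack's channel dimension.
#' @param beads Data frame with 0-based \code{x_px}, \code{y_px},
#'   \code{z_max} bead coordinates (e.g. from \code{\link{detect_beads}}
#'   on one channel), or \code{NULL} to detect beads on the first channel.
#' @param roi_half_um Half-size of the cubic ROI around each bead (um);
#'   default 3x the first channel's lateral FWHM laterally and 3x the
#'   axial FWHM in z.
#' @param prominence Detection prominence when \code{beads} is
#'   \code{NULL}.
#' @param registry A \code{\link{tolerance_registry}}.
#'
#' @return A list with \code{per_bead} (one row per bead x pair:
#'   displacements in um and pixels, r_exp, r_ref, ratio), \code{pairs}
#'   (mean +/- SD ratio and pass flag per channel pair), \code{n_skipped},
#'   and a \code{qc_report}.
#' @export
coreg_analysis <- function(stack, meta, beads = NULL, roi_half_um = NULL,
                           prominence = NULL,
                           registry = tolerance_registry()) {
  stopifnot(is.array(stack), length(dim(stack)) == 4L)
  n_ch <- dim(stack)[4]
  if (n_ch < 2L) stop("at least two channels required", call. = FALSE)
  if (length(meta$channels) != n_ch)
    stop("meta$channels must match the stack's channel count", call. = FALSE)

  spec1 <- theoretical_resolution(meta, meta$channels[[1]])
  if (is.null(roi_half_um))
    roi_half_um <- c(xy = 3 * spec1$lateral, z = 3 * spec1$axial)
  if (is.null(beads)) {
    if (is.null(prominence))
      prominence <- diff(range(stack[, , , 1])) / 10
    beads <- detect_beads(stack[, , , 1], meta, prominence)
    beads <- beads[beads$status == "kept", , drop = FALSE]
  }
  if (nrow(beads) < 5L)
    warning("fewer than 5 beads; protocol recommends at least 5")

  px <- meta$pixel_size_xy
  zs <- if (is.na(meta$z_step)) px else meta$z_step
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nz <- dim(stack)[3]
  hx <- max(2L, round(roi_half_um[["xy"]] / px))
  hz <- max(2L, round(roi_half_um[["z"]] / zs))
  sat <- saturation_level(meta)

  pair_idx <- utils::combn(n_ch, 2)
  rows <- list()
  n_skipped <- 0L
  for (b in seq_len(nrow(beads))) {
    ii <- max(1, beads$y_px[b] + 1 - hx):min(ny, beads$y_px[b] + 1 + hx)
    jj <- max(1, beads$x_px[b] + 1 - hx):min(nx, beads$x_px[b] + 1 + hx)
    kk <- max(1, beads$z_max[b] + 1 - hz):min(nz, beads$z_max[b] + 1 + hz)
    centers <- vector("list", n_ch)
    for (ch in seq_len(n_ch)) {
      roi <- stack[ii, jj, kk, ch, drop = TRUE]
      if (any(roi >= sat)) next  # saturated in this channel: skip
      ctr <- tryCatch(bead_center_of_mass(roi, meta), error = function(e) NULL)
      centers[[ch]] <- ctr
    }
    for (p in seq_len(ncol(pair_idx))) {
      a <- pair_idx[1, p]; cb <- pair_idx[2, p]
      if (is.null(centers[[a]]) || is.null(centers[[cb]])) {
        n_skipped <- n_skipped + 1L
        next
      }
      delta <- centers[[cb]] - centers[[a]]
      r_exp <- sqrt(sum(delta^2))
      res_ch <- shorter_wavelength_channel(meta, a, cb)
      spec <- theoretical_resolution(meta, meta$channels[[res_ch]])
      dir <- if (r_exp > 0) delta else c(1, 0, 0)
      r_ref <- reference_distance(dir, spec)
      rows[[length(rows) + 1L]] <- data.frame(
        bead = b, channel_a = a, channel_b = cb,
        dx_um = unname(delta["x"]), dy_um = unname(delta["y"]),
        dz_um = unname(delta["z"]),
        dx_px = unname(delta["x"]) / px, dy_px = unname(delta["y"]) / px,
        dz_px = unname(delta["z"]) / zs,
        r_exp = r_exp, r_ref = r_ref, ratio = r_exp / r_ref,
        resolution_channel = res_ch)
    }
  }
  if (length(rows) == 0L)
    stop("no bead/channel pair could be measured", call. = FALSE)
  per_bead <- do.call(rbind, rows)

  key <- paste(per_bead$channel_a, per_bead$channel_b, sep = "-")
  pairs <- do.call(rbind, lapply(split(per_bead, key), function(d) {
    data.frame(channel_a = d$channel_a[1], channel_b = d$channel_b[1],
               n = nrow(d), mean_ratio = mean(d$ratio),
               sd_ratio = if (nrow(d) > 1) stats::sd(d$ratio) else 0)
  }))
  pairs$pass <- vapply(pairs$mean_ratio, flag_metric, logical(1),
                       metric_id = "coreg_ratio_max", registry = registry)
  rownames(pairs) <- NULL

  metrics <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    metric_row(sprintf("ratio_%d_%d", pairs$channel_a[i], pairs$channel_b[i]),
               pairs$mean_ratio[i],
               registry$thresholds[["coreg_ratio_max"]], pairs$pass[i])))
  list(per_bead = per_bead, pairs = pairs, n_skipped = n_skipped,
       report = qc_report("coreg", metrics, meta = meta))
}
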