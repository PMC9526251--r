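#' @name synth
#' @title Synthetic ground-truth fixtures
#'
#' @description
#' Deterministic generators producing data in exactly the format each
#' analysis consumes, together with a truth sidecar listing the injected
#' parameters. Identical seed and parameters give bit-identical output.
#' Array conventions: 2D images are matrices indexed \code{[y, x]}; 3D
#' stacks are arrays \code{[y, x, z]}; multichannel stacks
#' \code{[y, x, z, channel]}. Pixel (0-based) index i has its centre at
#' \code{i * pixel_size} micrometres.
NULL

# Run expr under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' FWHM-to-sigma conversion factor for a Gaussian
#'
#' The full width at half maximum of a Gaussian profile spans
#' \eqn{2\sqrt{2\ln 2} \approx 2.3548} standard deviations (about 2.4 to
#' one decimal).
#'
#' @return The constant \code{2*sqrt(2*log(2))}.
#' @examples
#' round(fwhm_factor(), 1)  # 2.4
#' @export
fwhm_factor <- function() 2 * sqrt(2 * log(2))

# Poisson shot noise + Gaussian read noise, then quantization to bit depth.
apply_noise <- function(x, read_sd = 0, poisson = FALSE, bit_depth = 16L,
                        quantize = TRUE) {
  if (poisson) x[] <- stats::rpois(length(x), lambda = pmax(x, 0))
  if (read_sd > 0) x <- x + stats::rnorm(length(x), sd = read_sd)
  if (quantize) x <- round(x)
  pmin(pmax(x, 0), 2^bit_depth - 1)
}

#' Generate a 3D bead stack with known PSF widths
#'
#' Sums anisotropic 3D Gaussian spots on a constant background, optionally
#' broadens them to emulate a finite bead diameter, applies Poisson shot
#' noise plus Gaussian read noise, and quantizes to the detector bit
#' depth. Finite bead size is modelled by moment matching: the solid
#' sphere of diameter d contributes a marginal variance of (d/2)^2/5 per
#' axis, which is added to the PSF variance, so the apparent FWHM exceeds
#' the injected PSF FWHM.
#'
#' @param seed Integer seed; the generator is deterministic given it.
#' @param dim_yx Image size in pixels, \code{c(ny, nx)}.
#' @param n_z Number of z planes.
#' @param pixel_size Lateral pixel size (um).
#' @param z_step Axial step (um).
#' @param positions Matrix with columns x, y, z (um), one row per bead.
#' @param fwhm PSF FWHM per axis (um), \code{c(x, y, z)}; recycled across
#'   beads if a single triple.
#' @param amplitude Peak signal above background (ADU), recycled.
#' @param background Constant background level (ADU).
#' @param bead_diameter Physical bead diameter (um); 0 for point emitters.
#' @param read_sd Gaussian read-noise SD (ADU); 0 for noiseless.
#' @param poisson Apply Poisson shot noise?
#' @param bit_depth Detector bit depth for quantization/clipping.
#' @param quantize Round to integer ADU? Disable for analytic checks.
#'
#' @return A list with \code{stack} (array \code{[y, x, z]}) and
#'   \code{truth} (data frame of injected positions, PSF FWHMs and the
#'   effective, size-broadened FWHMs; a \code{too_close} flag marks beads
#'   nearer than 6x the lateral FWHM to another bead).
#' @export
make_bead_stack <- function(seed = 1L,
                            dim_yx = c(64L, 64L),
                            n_z = 41L,
                            pixel_size = 0.05,
                            z_step = 0.15,
                            positions,
                            fwhm = c(0.19125, 0.19125, 0.71827),
                            amplitude = 8000,
                            background = 100,
                            bead_diameter = 0,
                            read_sd = 0,
                            poisson = FALSE,
                            bit_depth = 16L,
                            quantize = TRUE) {
  positions <- matrix(as.numeric(positions), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  n <- nrow(positions)
  fwhm <- matrix(as.numeric(fwhm), nrow = n, ncol = 3, byrow = TRUE)
  amplitude <- rep_len(amplitude, n)
  min_fwhm_px <- min(fwhm[, 1:2] / pixel_size, fwhm[, 3] / z_step)
  if (min_fwhm_px < 2)
    warning("bead FWHM below 2 pixels on some axis; fits will be unreliable")

  # effective widths after finite-size broadening (moment matching)
  sigma <- fwhm / fwhm_factor()
  if (bead_diameter > 0)
    sigma <- sqrt(sigma^2 + (bead_diameter / 2)^2 / 5)
  fwhm_eff <- sigma * fwhm_factor()

  ny <- dim_yx[1]; nx <- dim_yx[2]
  xs <- (seq_len(nx) - 1) * pixel_size
  ys <- (seq_len(ny) - 1) * pixel_size
  zs <- (seq_len(n_z) - 1) * z_step
  stack <- array(background, dim = c(ny, nx, n_z))
  for (i in seq_len(n)) {
    gx <- exp(-(xs - positions[i, "x"])^2 / (2 * sigma[i, 1]^2))
    gy <- exp(-(ys - positions[i, "y"])^2 / (2 * sigma[i, 2]^2))
    gz <- exp(-(zs - positions[i, "z"])^2 / (2 * sigma[i, 3]^2))
    spot <- outer(outer(gy, gx), gz) * amplitude[i]
    stack <- stack + spot
  }
  stack <- with_seed(seed, apply_noise(stack, read_sd = read_sd,
                                       poisson = poisson,
                                       bit_depth = bit_depth,
                                       quantize = quantize))
  too_close <- rep(FALSE, n)
  if (n > 1) {
    d <- as.matrix(stats::dist(positions[, c("x", "y")]))
    diag(d) <- Inf
    too_close <- apply(d, 1, min) < 6 * fwhm[, 1]
  }
  if (any(too_close))
    warning("some generated beads are closer than 6x the lateral FWHM")
  truth <- data.frame(
    x = positions[, "x"], y = positions[, "y"], z = positions[, "z"],
    fwhm_x = fwhm[, 1], fwhm_y = fwhm[, 2], fwhm_z = fwhm[, 3],
    fwhm_eff_x = fwhm_eff[, 1], fwhm_eff_y = fwhm_eff[, 2],
    fwhm_eff_z = fwhm_eff[, 3],
    amplitude = amplitude, too_close = too_close)
  list(stack = stack, truth = truth,
       meta = list(pixel_size = pixel_size, z_step = z_step,
                   background = background, bit_depth = bit_depth,
                   bead_diameter = bead_diameter, seed = seed))
}

#' Generate a vignetted (or flat) field-illumination image
#'
#' A Gaussian vignette centred at \code{peak_at} whose intensity falls to
#' \code{edge_ratio} times the peak at the most distant image corner, so
#' the expected uniformity is \code{100 * edge_ratio} before smoothing.
#'
#' @param seed Integer seed (used only when \code{noise_sd > 0}).
#' @param dim_yx Image size \code{c(ny, nx)} in pixels.
#' @param peak Peak intensity (ADU).
#' @param peak_at Peak position \code{c(x, y)} in 0-based pixel
#'   coordinates; defaults to the image centre.
#' @param edge_ratio Corner/peak intensity ratio in (0, 1]; 1 gives a
#'   perfectly flat field.
#' @param noise_sd Additive Gaussian noise SD (ADU).
#' @param bit_depth Bit depth for clipping.
#' @param quantize Round to integer ADU?
#'
#' @return A list with \code{image} (matrix \code{[y, x]}) and
#'   \code{truth} (peak position, edge ratio, expected uniformity).
#' @export
make_flat_field <- function(seed = 1L,
                            dim_yx = c(256L, 256L),
                            peak = 40000,
                            peak_at = NULL,
                            edge_ratio = 1,
                            noise_sd = 0,
                            bit_depth = 16L,
                            quantize = FALSE) {
  stopifnot(edge_ratio > 0, edge_ratio <= 1)
  ny <- dim_yx[1]; nx <- dim_yx[2]
  if (is.null(peak_at)) peak_at <- c((nx - 1) / 2, (ny - 1) / 2)
  xs <- seq_len(nx) - 1
  ys <- seq_len(ny) - 1
  d2 <- outer((ys - peak_at[2])^2, (xs - peak_at[1])^2, `+`)
  if (edge_ratio < 1) {
    corners <- rbind(c(0, 0), c(nx - 1, 0), c(0, ny - 1), c(nx - 1, ny - 1))
    dmax2 <- max((corners[, 1] - peak_at[1])^2 + (corners[, 2] - peak_at[2])^2)
    s2 <- dmax2 / (2 * log(1 / edge_ratio))
    img <- peak * exp(-d2 / (2 * s2))
  } else {
    img <- matrix(peak, ny, nx)
  }
  img <- with_seed(seed, apply_noise(img, read_sd = noise_sd,
                                     bit_depth = bit_depth,
                                     quantize = quantize))
  list(image = img,
       truth = list(peak_at = peak_at, edge_ratio = edge_ratio,
                    expected_uniformity = 100 * edge_ratio, seed = seed))
}

#' Generate a multichannel bead stack with known channel shifts
#'
#' Replicates a bead field across channels, displacing each channel by its
#' own 3D shift; used to validate co-registration recovery.
#'
#' @param seed Integer seed.
#' @param shifts Matrix with one row per channel and columns dx, dy, dz
#'   (um); the first row is typically zero (reference channel).
#' @param positions Bead positions (um) in the reference channel; matrix
#'   with columns x, y, z.
#' @param fwhm PSF FWHM per axis (um).
#' @inheritParams make_bead_stack
#'
#' @return A list with \code{stack} (array \code{[y, x, z, channel]}) and
#'   \code{truth} (positions and per-channel shifts).
#' @export
make_shifted_channels <- function(seed = 1L,
                                  dim_yx = c(64L, 64L),
                                  n_z = 41L,
                                  pixel_size = 0.05,
                                  z_step = 0.15,
                                  positions,
                                  shifts,
                                  fwhm = c(0.19125, 0.19125, 0.71827),
                                  amplitude = 8000,
                                  background = 100,
                                  bead_diameter = 0,
                                  read_sd = 0,
                                  poisson = FALSE,
                                  bit_depth = 16L,
                                  quantize = TRUE) {
  shifts <- matrix(as.numeric(shifts), ncol = 3,
                   dimnames = list(NULL, c("dx", "dy", "dz")))
  positions <- matrix(as.numeric(positions), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  n_ch <- nrow(shifts)
  stack <- array(0, dim = c(dim_yx[1], dim_yx[2], n_z, n_ch))
  for (ch in seq_len(n_ch)) {
    pos <- sweep(positions, 2, shifts[ch, ], `+`)
    one <- make_bead_stack(seed = seed + ch, dim_yx = dim_yx, n_z = n_z,
                           pixel_size = pixel_size, z_step = z_step,
                           positions = pos, fwhm = fwhm,
                           amplitude = amplitude, background = background,
                           bead_diameter = bead_diameter, read_sd = read_sd,
                           poisson = poisson, bit_depth = bit_depth,
                           quantize = quantize)
    stack[, , , ch] <- one$stack
  }
  list(stack = stack,
       truth = list(positions = positions, shifts = shifts, seed = seed),
       meta = list(pixel_size = pixel_size, z_step = z_step,
                   background = background, bit_depth = bit_depth))
}

#' Generate an illumination power trace
#'
#' Emits a two-column time series (time in seconds, power in watts) for
#' one of four scenarios: a constant source, a stable source with
#' proportional Gaussian jitter, a warm-up step that settles at
#' \code{step_at_s}, or a monotone ramp that never settles.
#'
#' @param seed Integer seed.
#' @param type One of \code{"constant"}, \code{"stable"}, \code{"step"},
#'   \code{"ramp"}.
#' @param duration_s Trace duration in seconds.
#' @param interval_s Sampling interval in seconds.
#' @param mean_power Settled power level (W).
#' @param noise_frac SD of the multiplicative jitter (fraction of mean).
#' @param step_at_s For \code{"step"}: time at which power settles.
#' @param step_depth For \code{"step"}: initial power as a fraction of the
#'   settled level.
#'
#' @return A list with \code{trace} (data frame \code{time_s},
#'   \code{power_w}) and \code{truth}.
#' @export
make_power_trace <- function(seed = 1L,
                             type = c("constant", "stable", "step", "ramp"),
                             duration_s = 7200,
                             interval_s = 30,
                             mean_power = 1e-3,
                             noise_frac = 0.002,
                             step_at_s = 1800,
                             step_depth = 0.8) {
  type <- match.arg(type)
  t <- seq(0, duration_s, by = interval_s)
  base <- switch(type,
    constant = rep(mean_power, length(t)),
    stable = rep(mean_power, length(t)),
    step = mean_power * ifelse(t < step_at_s,
      step_depth + (1 - step_depth) * t / step_at_s, 1),
    ramp = mean_power * (0.5 + 0.5 * t / duration_s))
  p <- if (type %in% c("stable", "step") && noise_frac > 0) {
    with_seed(seed, base * (1 + stats::rnorm(length(t), sd = noise_frac)))
  } else base
  list(trace = data.frame(time_s = t, power_w = pmax(p, 0)),
       truth = list(type = type, mean_power = mean_power,
                    noise_frac = noise_frac, step_at_s = step_at_s,
                    seed = seed))
}

#' Generate a stage-drift track
#'
#' Positions relax exponentially toward a plateau:
#' \eqn{p(t) = p_\infty + A\,e^{-t/\tau}} per axis, plus Gaussian
#' centroid noise. Times are minutes and positions micrometres, matching
#' the track-table format the drift analysis reads.
#'
#' @param seed Integer seed.
#' @param duration_min Track duration (min).
#' @param interval_min Frame interval (min).
#' @param amplitude Initial displacement from the plateau per axis (um),
#'   \code{c(x, y, z)}.
#' @param tau_min Relaxation time constant (min).
#' @param noise_sd Centroid noise SD per axis (um).
#'
#' @return A list with \code{track} (data frame \code{t_min}, \code{x_um},
#'   \code{y_um}, \code{z_um}) and \code{truth}.
#' @export
make_drift_track <- function(seed = 1L,
                             duration_min = 900,
                             interval_min = 10,
                             amplitude = c(1.5, 1.0, 3.0),
                             tau_min = 30,
                             noise_sd = 0.005) {
  t <- seq(0, duration_min, by = interval_min)
  decay <- exp(-t / tau_min)
  pos <- cbind(x_um = amplitude[1] * decay,
               y_um = amplitude[2] * decay,
               z_um = amplitude[3] * decay)
  if (noise_sd > 0)
    pos <- with_seed(seed, pos + matrix(stats::rnorm(length(pos),
                                                     sd = noise_sd),
                                        nrow = nrow(pos)))
  list(track = data.frame(t_min = t, pos),
       truth = list(amplitude = amplitude, tau_min = tau_min,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate stage repositioning visits
#'
#' Reference-position coordinates observed on successive returns of the
#' stage, drawn around a true position with independent per-axis Gaussian
#' jitter whose SD is the true repeatability.
#'
#' @param seed Integer seed.
#' @param n_visits Number of returns to the reference position.
#' @param centre True position \code{c(x, y)} (um).
#' @param sigma True repeatability per axis (um), \code{c(x, y)}.
#'
#' @return A list with \code{visits} (data frame \code{x_um}, \code{y_um})
#'   and \code{truth}.
#' @export
make_repeat_visits <- function(seed = 1L,
                               n_visits = 20L,
                               centre = c(100, 100),
                               sigma = c(0.05, 0.05)) {
  visits <- with_seed(seed, data.frame(
    x_um = stats::rnorm(n_visits, centre[1], sigma[1]),
    y_um = stats::rnorm(n_visits, centre[2], sigma[2])))
  list(visits = visits,
       truth = list(centre = centre, sigma = sigma, seed = seed))
}

#' Generate a dark-frame series
#'
#' Per-pixel offsets (optionally with a column pattern, as in sCMOS fixed
#' pattern noise) plus independent per-frame Gaussian temporal noise.
#' Values are left unquantized by default so that the analytic relations
#' between injected and recovered noise hold exactly.
#'
#' @param seed Integer seed.
#' @param dim_yx Sensor size \code{c(ny, nx)} in pixels.
#' @param n_frames Number of dark frames (protocol default 100).
#' @param offset Mean dark offset (ADU).
#' @param offset_sd SD of the static per-pixel offset map (ADU); this is
#'   the spatial non-uniformity the DSNU estimates.
#' @param column_amp Amplitude of a sinusoidal column offset pattern (ADU).
#' @param temporal_sd Per-pixel temporal read-noise SD (ADU); scalar or a
#'   \code{[y, x]} matrix.
#' @param bit_depth Bit depth for clipping.
#' @param quantize Round to integer ADU?
#'
#' @return A list with \code{frames} (array \code{[y, x, t]}),
#'   \code{offset_map} (the noiseless truth map) and \code{truth}.
#' @export
make_dark_stack <- function(seed = 1L,
                            dim_yx = c(64L, 64L),
                            n_frames = 100L,
                            offset = 100,
                            offset_sd = 1,
                            column_amp = 0,
                            temporal_sd = 2,
                            bit_depth = 16L,
                            quantize = FALSE) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  with_seed(seed, {
    offset_map <- matrix(offset + stats::rnorm(ny * nx, sd = offset_sd),
                         ny, nx)
    if (column_amp > 0) {
      colpat <- column_amp * sin(2 * pi * (seq_len(nx) - 1) / 8)
      offset_map <- sweep(offset_map, 2, colpat, `+`)
    }
    sd_map <- if (is.matrix(temporal_sd)) temporal_sd
              else matrix(temporal_sd, ny, nx)
    frames <- array(0, dim = c(ny, nx, n_frames))
    for (k in seq_len(n_frames)) {
      f <- offset_map + stats::rnorm(ny * nx, sd = c(sd_map))
      if (quantize) f <- round(f)
      frames[, , k] <- pmin(pmax(f, 0), 2^bit_depth - 1)
    }
    list(frames = frames, offset_map = offset_map,
         truth = list(offset = offset, offset_sd = offset_sd,
                      column_amp = column_amp,
                      temporal_sd = temporal_sd, seed = seed))
  })
}
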