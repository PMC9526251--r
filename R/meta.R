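#' Channel metadata
#'
#' Describes one fluorescence channel by its excitation and emission
#' wavelengths. Emission is always red-shifted relative to excitation
#' (Stokes shift), which is enforced.
#'
#' @param name Channel label (e.g. \code{"DAPI"}, \code{"GFP"}).
#' @param lambda_ex Excitation wavelength in nanometres (> 0).
#' @param lambda_em Emission wavelength in nanometres (>= \code{lambda_ex}).
#'
#' @return An object of class \code{channel_meta}.
#' @examples
#' channel_meta("GFP", lambda_ex = 488, lambda_em = 525)
#' @export
channel_meta <- function(name, lambda_ex, lambda_em) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lambda_ex) || lambda_ex <= 0)
    stop("'lambda_ex' must be a positive wavelength in nm", call. = FALSE)
  if (!is.finite(lambda_em) || lambda_em < lambda_ex)
    stop("'lambda_em' must be >= 'lambda_ex' (Stokes shift)", call. = FALSE)
  structure(
    list(name = name, lambda_ex = lambda_ex, lambda_em = lambda_em),
    class = "channel_meta"
  )
}

#' @export
print.channel_meta <- function(x, ...) {
  cat(sprintf("<channel %s: ex %g nm / em %g nm>\n",
              x$name, x$lambda_ex, x$lambda_em))
  invisible(x)
}

#' Acquisition metadata
#'
#' Optical and sensor context shared by every analysis: modality, numerical
#' aperture, immersion refractive index, voxel calibration, channel
#' wavelengths, detector bit depth, and (for camera analyses) the
#' electron-per-ADU conversion gain.
#'
#' @param modality One of \code{"WF"} (wide-field), \code{"LSCM"}
#'   (laser-scanning confocal) or \code{"SDCM"} (spinning-disk confocal).
#' @param na Numerical aperture of the objective (> 0). Must not exceed the
#'   refractive index, otherwise the confocal axial resolution formulas
#'   involve the square root of a negative number.
#' @param refractive_index Refractive index of the immersion medium (>= 1).
#' @param pixel_size_xy Lateral pixel size in micrometres per pixel (> 0).
#' @param z_step Axial step in micrometres (> 0), or \code{NA} for 2D data.
#' @param time_interval Frame interval in seconds (> 0), or \code{NA}.
#' @param channels A list of \code{\link{channel_meta}} objects.
#' @param bit_depth Detector bit depth; one of 8, 10, 12, 14, 16.
#' @param conversion_gain Conversion gain in electrons per ADU (> 0), used
#'   by camera analyses only; \code{NA} otherwise.
#'
#' @return An object of class \code{acquisition_meta}.
#' @examples
#' acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
#'                  pixel_size_xy = 0.065, z_step = 0.2,
#'                  channels = list(channel_meta("GFP", 488, 525)))
#' @export
acquisition_meta <- function(modality = c("WF", "LSCM", "SDCM"),
                             na,
                             refractive_index = 1.515,
                             pixel_size_xy,
                             z_step = NA_real_,
                             time_interval = NA_real_,
                             channels = list(),
                             bit_depth = 16L,
                             conversion_gain = NA_real_) {
  modality <- match.arg(modality)
  if (!is.finite(na) || na <= 0)
    stop("'na' must be a positive numerical aperture", call. = FALSE)
  if (!is.finite(refractive_index) || refractive_index < 1)
    stop("'refractive_index' must be >= 1", call. = FALSE)
  if (na > refractive_index)
    stop("'na' must not exceed 'refractive_index' ",
         "(the axial confocal formulas require NA <= n)", call. = FALSE)
  if (!is.finite(pixel_size_xy) || pixel_size_xy <= 0)
    stop("'pixel_size_xy' must be > 0 (um/pixel)", call. = FALSE)
  if (!is.na(z_step) && (!is.finite(z_step) || z_step <= 0))
    stop("'z_step' must be > 0 (um) or NA", call. = FALSE)
  if (!is.na(time_interval) && (!is.finite(time_interval) || time_interval <= 0))
    stop("'time_interval' must be > 0 (s) or NA", call. = FALSE)
  if (!bit_depth %in% c(8L, 10L, 12L, 14L, 16L))
    stop("'bit_depth' must be one of 8, 10, 12, 14, 16", call. = FALSE)
  if (!is.na(conversion_gain) &&
      (!is.finite(conversion_gain) || conversion_gain <= 0))
    stop("'conversion_gain' must be > 0 (e-/ADU) or NA", call. = FALSE)
  if (!all(vapply(channels, inherits, logical(1), "channel_meta")))
    stop("'channels' must be a list of channel_meta objects", call. = FALSE)
  structure(
    list(modality = modality,
         na = na,
         refractive_index = refractive_index,
         pixel_size_xy = pixel_size_xy,
         z_step = z_step,
         time_interval = time_interval,
         channels = channels,
         bit_depth = as.integer(bit_depth),
         conversion_gain = conversion_gain),
    class = "acquisition_meta"
  )
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("<acquisition: %s, NA %g / n %g, pixel %g um, z %s um, %d-bit>\n",
              x$modality, x$na, x$refractive_index, x$pixel_size_xy,
              ifelse(is.na(x$z_step), "-", format(x$z_step)), x$bit_depth))
  for (ch in x$channels) print(ch)
  invisible(x)
}

# Max ADU value representable at the declared bit depth.
saturation_level <- function(meta) 2^meta$bit_depth - 1
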