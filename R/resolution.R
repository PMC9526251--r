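#' Theoretical resolution (PSF FWHM) for a channel
#'
#' Computes the diffraction-limited lateral and axial resolution, expressed
#' as the FWHM of the point spread function, for the three supported
#' modalities:
#' \describe{
#'   \item{WF}{lateral \eqn{0.51\,\lambda_{em}/NA}; axial
#'     \eqn{1.77\,n\,\lambda_{em}/NA^2}.}
#'   \item{LSCM}{lateral \eqn{0.51\,\lambda_{ex}/NA}; axial
#'     \eqn{0.88\,\lambda_{ex}/(n-\sqrt{n^2-NA^2})} (pinhole >= 1 A.U.,
#'     NA > 0.5).}
#'   \item{SDCM}{lateral \eqn{0.51\,\lambda_{em}/NA}; axial
#'     \eqn{\lambda_{em}/(n-\sqrt{n^2-NA^2})} (pinhole below 1 A.U.).}
#' }
#' Wavelengths are supplied in nanometres and results returned in
#' micrometres.
#'
#' @param meta An \code{\link{acquisition_meta}} (modality, NA, n).
#' @param channel A \code{\link{channel_meta}}; defaults to the first
#'   channel of \code{meta}.
#'
#' @return An object of class \code{resolution_spec} with fields
#'   \code{lateral} and \code{axial} (um), \code{modality} and
#'   \code{channel}.
#' @examples
#' meta <- acquisition_meta("WF", na = 1.4, refractive_index = 1.515,
#'                          pixel_size_xy = 0.065,
#'                          channels = list(channel_meta("GFP", 488, 525)))
#' theoretical_resolution(meta)  # lateral 0.19125 um, axial 0.71827 um
#' @export
theoretical_resolution <- function(meta, channel = meta$channels[[1]]) {
  stopifnot(inherits(meta, "acquisition_meta"),
            inherits(channel, "channel_meta"))
  na <- meta$na
  n <- meta$refractive_index
  lam_em <- channel$lambda_em / 1000  # nm -> um
  lam_ex <- channel$lambda_ex / 1000
  if (na > n)
    stop("NA exceeds the refractive index: axial formula undefined",
         call. = FALSE)
  res <- switch(meta$modality,
    WF = list(lateral = 0.51 * lam_em / na,
              axial   = 1.77 * n * lam_em / na^2),
    LSCM = list(lateral = 0.51 * lam_ex / na,
                axial   = 0.88 * lam_ex / (n - sqrt(n^2 - na^2))),
    SDCM = list(lateral = 0.51 * lam_em / na,
                axial   = lam_em / (n - sqrt(n^2 - na^2)))
  )
  structure(
    list(lateral = res$lateral, axial = res$axial,
         modality = meta$modality, channel = channel),
    class = "resolution_spec"
  )
}

#' @export
print.resolution_spec <- function(x, ...) {
  cat(sprintf("<resolution %s/%s: lateral %.4f um, axial %.4f um>\n",
              x$modality, x$channel$name, x$lateral, x$axial))
  invisible(x)
}

#' Shannon-Nyquist pixel-size criterion
#'
#' Maximum pixel size satisfying the sampling criterion for confocal PSF
#' imaging, \eqn{\lambda_{ex}/(8\,NA)}, optionally relaxed by a pinhole
#' factor (1.6 for a 1 A.U. pinhole; 1 for a nearly closed pinhole).
#' Returned in nanometres. The printed integer criterion is conservative:
#' it truncates rather than rounds, so the reported pixel size never
#' exceeds the exact bound (e.g. 43 nm for NA 1.4 at 488 nm).
#'
#' @param lambda_ex Excitation wavelength in nm.
#' @param na Numerical aperture (> 0).
#' @param pinhole_factor Sampling relaxation factor (>= 1); default 1.
#'
#' @return The criterion pixel size in nm (exact value, not rounded).
#' @seealso \code{\link{nyquist_pixel_nm}} for the conservative integer.
#' @examples
#' nyquist_pixel(488, 1.4)          # 43.57 nm
#' nyquist_pixel(488, 1.4, 1.6)     # 69.71 nm for a 1 A.U. pinhole
#' @export
nyquist_pixel <- function(lambda_ex, na, pinhole_factor = 1.0) {
  if (!is.finite(na) || na <= 0) stop("'na' must be > 0", call. = FALSE)
  if (!is.finite(lambda_ex) || lambda_ex <= 0)
    stop("'lambda_ex' must be > 0 (nm)", call. = FALSE)
  if (!is.finite(pinhole_factor) || pinhole_factor < 1)
    stop("'pinhole_factor' must be >= 1", call. = FALSE)
  pinhole_factor * lambda_ex / (8 * na)
}

#' Conservative integer Nyquist criterion in nm
#'
#' Truncates \code{\link{nyquist_pixel}} to whole nanometres so that the
#' reported criterion never exceeds the exact bound.
#'
#' @inheritParams nyquist_pixel
#' @return Integer nanometres.
#' @export
nyquist_pixel_nm <- function(lambda_ex, na, pinhole_factor = 1.0) {
  as.integer(floor(nyquist_pixel(lambda_ex, na, pinhole_factor)))
}

#' Effective sample-plane pixel size
#'
#' Converts a camera (sensor) pixel pitch to the pixel size projected
#' into the sample plane by dividing by the total magnification, e.g. a
#' 6.5 um sensor pixel behind a 20x objective samples the specimen at
#' 0.325 um (325 nm).
#'
#' @param camera_pixel_um Physical sensor pixel pitch in micrometres
#'   (> 0).
#' @param magnification Total magnification between sample and sensor
#'   (> 0).
#'
#' @return Sample-plane pixel size in micrometres.
#' @examples
#' effective_pixel_size(6.5, 20)  # 0.325 um
#' @export
effective_pixel_size <- function(camera_pixel_um, magnification) {
  if (!is.finite(camera_pixel_um) || camera_pixel_um <= 0)
    stop("'camera_pixel_um' must be > 0", call. = FALSE)
  if (!is.finite(magnification) || magnification <= 0)
    stop("'magnification' must be > 0", call. = FALSE)
  camera_pixel_um / magnification
}

#' Check spatial sampling against the Nyquist criterion
#'
#' Lateral sampling passes when the pixel size is at most half the lateral
#' resolution; axial sampling when the z step is at most half the axial
#' resolution. When no z step is recorded only the lateral check is
#' performed and the result is flagged incomplete.
#'
#' @param meta An \code{\link{acquisition_meta}}.
#' @param channel A \code{\link{channel_meta}}; defaults to the first.
#'
#' @return A list with logical \code{lateral_pass}, \code{axial_pass}
#'   (\code{NA} when no z step), the \code{resolution_spec} used, and
#'   \code{complete} (\code{FALSE} when the axial check could not be run).
#' @export
sampling_check <- function(meta, channel = meta$channels[[1]]) {
  spec <- theoretical_resolution(meta, channel)
  lateral_pass <- meta$pixel_size_xy <= spec$lateral / 2
  if (is.na(meta$z_step)) {
    axial_pass <- NA
    complete <- FALSE
  } else {
    axial_pass <- meta$z_step <= spec$axial / 2
    complete <- TRUE
  }
  list(lateral_pass = lateral_pass, axial_pass = axial_pass,
       resolution = spec, complete = complete)
}
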