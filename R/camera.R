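#' @name camera
#' @title Dark-frame camera noise characterization
#'
#' @description
#' Characterizes a camera sensor from a time series of dark frames
#' (typically 100 frames at a short exposure, so dark current is
#' negligible). The temporal mean image gives the offset (its global
#' mean, ADU) and the DSNU (its global SD times the conversion gain,
#' electrons); the per-pixel temporal SD times the gain is the read-noise
#' map, summarized by its RMS and median. The VAR metric compares the
#' measured noise with the manufacturer's specification and STAB_noise
#' tracks the noise across sessions.
NULL

#' Analyze a dark-frame series
#'
#' @param frames Array \code{[y, x, t]} of dark frames, t >= 2 (the
#'   protocol recommends 100; a warning is issued below that).
#' @param gain Conversion gain in electrons per ADU (> 0).
#' @param hot_threshold Read-noise level (electrons) above which a pixel
#'   is counted as hot; default 5.
#' @param registry A \code{\link{tolerance_registry}} (not used for
#'   flags here: offset/DSNU have no universal tolerance, VAR and STAB
#'   are computed separately).
#'
#' @return An object of class \code{camera_noise_result}: \code{offset}
#'   (ADU), \code{offset_e} (electrons), \code{dsnu} (e-),
#'   \code{noise_map} (per-pixel read noise, e-), \code{rms_noise},
#'   \code{median_noise} (e-), \code{hot_pixel_count}, \code{n_frames},
#'   \code{gain}.
#' @examples
#' d <- make_dark_stack(seed = 1, n_frames = 50)
#' dark_series_analysis(d$frames, gain = 0.5)$offset
#' @export
dark_series_analysis <- function(frames, gain, hot_threshold = 5,
                                 registry = tolerance_registry()) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a [y, x, t] array", call. = FALSE)
  n_frames <- dim(frames)[3]
  if (n_frames < 2L)
    stop("at least two dark frames required", call. = FALSE)
  if (n_frames < 100L)
    warning("fewer than 100 dark frames; DSNU estimate will be noisier")
  if (any(!is.finite(frames)))
    stop("non-finite pixel values in dark frames", call. = FALSE)
  if (!is.finite(gain) || gain <= 0)
    stop("'gain' must be > 0 (e-/ADU)", call. = FALSE)

  mean_img <- apply(frames, c(1, 2), mean)
  offset <- mean(mean_img)
  dsnu <- stats::sd(mean_img) * gain
  sd_img <- apply(frames, c(1, 2), stats::sd)
  noise_map <- sd_img * gain
  structure(
    list(offset = offset,
         offset_e = offset * gain,
         dsnu = dsnu,
         noise_map = noise_map,
         rms_noise = sqrt(mean(noise_map^2)),
         median_noise = stats::median(noise_map),
         hot_pixel_count = sum(noise_map > hot_threshold),
         n_frames = n_frames,
         gain = gain),
    class = "camera_noise_result")
}

#' @export
print.camera_noise_result <- function(x, ...) {
  cat(sprintf(paste0("<camera noise: offset %.2f ADU, DSNU %.3f e-, ",
                     "read noise RMS %.3f / median %.3f e- ",
                     "(%d frames, gain %g e-/ADU)>\n"),
              x$offset, x$dsnu, x$rms_noise, x$median_noise,
              x$n_frames, x$gain))
  invisible(x)
}

#' Read-noise VAR metric
#'
#' Percentage of the manufacturer's specified read noise relative to the
#' measured value, \eqn{VAR = 100\,N_{theor}/N_{exp}}. Values above 100%
#' mean the sensor measures better than its datasheet; values below 90%
#' are flagged.
#'
#' @param n_theor Specified read noise (e-), RMS or median to match the
#'   datasheet.
#' @param n_exp Measured read noise (e-) of the same kind.
#' @param registry A \code{\link{tolerance_registry}}.
#'
#' @return A list with \code{var} (%) and \code{pass}.
#' @export
var_metric <- function(n_theor, n_exp, registry = tolerance_registry()) {
  if (!is.finite(n_theor) || n_theor <= 0 ||
      !is.finite(n_exp) || n_exp <= 0)
    stop("read-noise values must be positive", call. = FALSE)
  v <- 100 * n_theor / n_exp
  list(var = v, pass = flag_metric(v, "var_noise_min", registry))
}

#' Read-noise stability across sessions
#'
#' Min-max stability factor of the read noise (RMS or median) recorded
#' over long-term monitoring sessions,
#' \eqn{STAB = 100\,[1 - (N_{max}-N_{min})/(N_{max}+N_{min})]}, flagged
#' against the 97% tolerance.
#'
#' @param history Numeric vector of per-session read-noise values (e-),
#'   all positive, length >= 2.
#' @param registry A \code{\link{tolerance_registry}}.
#'
#' @return A list with \code{stab} (%) and \code{pass}.
#' @export
stab_noise <- function(history, registry = tolerance_registry()) {
  if (length(history) < 2L)
    stop("at least two sessions required", call. = FALSE)
  if (any(!is.finite(history)) || any(history <= 0))
    stop("all read-noise values must be positive", call. = FALSE)
  n_max <- max(history)
  n_min <- min(history)
  s <- 100 * (1 - (n_max - n_min) / (n_max + n_min))
  list(stab = s, pass = flag_metric(s, "stab_noise_min", registry))
}

#' Full camera analysis with report
#'
#' @inheritParams dark_series_analysis
#' @param spec_noise Manufacturer's specified read noise (e-), or
#'   \code{NA} to skip the VAR metric.
#' @param spec_kind Which summary the specification refers to,
#'   \code{"rms"} or \code{"median"}.
#' @param input Input label for the report.
#'
#' @return A list with \code{result} (\code{camera_noise_result}),
#'   \code{var} (or \code{NULL}) and \code{report}.
#' @export
analyze_camera <- function(frames, gain, spec_noise = NA_real_,
                           spec_kind = c("rms", "median"),
                           hot_threshold = 5,
                           registry = tolerance_registry(),
                           input = NA_character_) {
  spec_kind <- match.arg(spec_kind)
  res <- dark_series_analysis(frames, gain, hot_threshold, registry)
  metrics <- rbind(
    metric_row("offset_adu", res$offset),
    metric_row("offset_e", res$offset_e),
    metric_row("dsnu_e", res$dsnu),
    metric_row("rms_noise_e", res$rms_noise),
    metric_row("median_noise_e", res$median_noise),
    metric_row("hot_pixels", res$hot_pixel_count))
  v <- NULL
  if (!is.na(spec_noise)) {
    measured <- if (spec_kind == "rms") res$rms_noise else res$median_noise
    v <- var_metric(spec_noise, measured, registry)
    metrics <- rbind(metrics,
                     metric_row("var_pct", v$var,
                                registry$thresholds[["var_noise_min"]],
                                v$pass))
  }
  list(result = res, var = v,
       report = qc_report("camera", metrics, input = input))
}
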