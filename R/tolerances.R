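#' Drift classification bounds
#'
#' Bounds separating the three stage-drift classes (standard, acceptable,
#' critical) for the stabilization time and the mean 3D drift velocities
#' before and after stabilization.
#'
#' @param tau_standard_max Stabilization time below which drift is standard
#'   (minutes, default 45).
#' @param tau_acceptable_max Stabilization time above which drift is
#'   critical (minutes, default 120).
#' @param v_standard_max Velocity (before or after stabilization) below
#'   which the quantity is standard (nm/min, default 15).
#' @param vb_acceptable_max Upper acceptable bound for the velocity before
#'   stabilization (nm/min, default 100).
#' @param va_acceptable_max Upper acceptable bound for the velocity after
#'   stabilization (nm/min, default 50).
#'
#' @return An object of class \code{drift_class_bounds}.
#' @export
drift_class_bounds <- function(tau_standard_max = 45,
                               tau_acceptable_max = 120,
                               v_standard_max = 15,
                               vb_acceptable_max = 100,
                               va_acceptable_max = 50) {
  b <- list(tau_standard_max = tau_standard_max,
            tau_acceptable_max = tau_acceptable_max,
            v_standard_max = v_standard_max,
            vb_acceptable_max = vb_acceptable_max,
            va_acceptable_max = va_acceptable_max)
  if (any(!vapply(b, function(v) is.finite(v) && v > 0, logical(1))))
    stop("all drift bounds must be strictly positive", call. = FALSE)
  if (tau_standard_max >= tau_acceptable_max)
    stop("'tau_standard_max' must be below 'tau_acceptable_max'", call. = FALSE)
  if (v_standard_max >= vb_acceptable_max || v_standard_max >= va_acceptable_max)
    stop("'v_standard_max' must be below the acceptable velocity bounds",
         call. = FALSE)
  structure(b, class = "drift_class_bounds")
}

# Direction of comparison for each registered metric:
#   "min" -> value must be >= threshold to pass
#   "max" -> value must be <= threshold to pass
.metric_directions <- c(
  fwhm_ratio        = "max",
  uniformity_min    = "min",
  centering_min     = "min",
  coreg_ratio_max   = "max",
  stab_power_min    = "min",
  sd_norm_power_max = "max",
  repeatability_max = "max",
  var_noise_min     = "min",
  stab_noise_min    = "min"
)

#' Tolerance registry
#'
#' Default pass/fail thresholds for every quality-control metric. The
#' defaults are the recommended limit values for routine monitoring:
#' measured/theoretical FWHM ratio below 1.5, field uniformity above 50%,
#' centering above 20%, co-registration ratio at most 1, power stability
#' above 97% with a normalized-power SD at most 0.02, positioning
#' repeatability at most 0.2 um, camera noise VAR above 90% and noise
#' stability above 97%. Thresholds are inclusive on the passing side
#' (a uniformity of exactly 50% passes).
#'
#' @param fwhm_ratio_max Maximum measured/theoretical FWHM ratio.
#' @param uniformity_min Minimum field-illumination uniformity (%).
#' @param centering_min Minimum field-illumination centering (%).
#' @param coreg_ratio_max Maximum co-registration ratio r_exp/r_ref.
#' @param stab_power_min Minimum illumination power stability factor (%).
#' @param sd_norm_power_max Maximum SD of max-normalized power.
#' @param repeatability_max Maximum positioning repeatability SD (um).
#' @param var_noise_min Minimum read-noise VAR metric (%).
#' @param stab_noise_min Minimum read-noise stability factor (%).
#' @param drift_bounds A \code{\link{drift_class_bounds}} object.
#'
#' @return An object of class \code{tolerance_registry}.
#' @seealso \code{\link{flag_metric}}, \code{\link{registry_from_config}}
#' @examples
#' reg <- tolerance_registry()
#' flag_metric(1.4, "fwhm_ratio", reg)   # TRUE: within the 1.5 limit
#' flag_metric(36.7, "uniformity_min", reg) # FALSE: below the 50% limit
#' @export
tolerance_registry <- function(fwhm_ratio_max = 1.5,
                               uniformity_min = 50,
                               centering_min = 20,
                               coreg_ratio_max = 1.0,
                               stab_power_min = 97,
                               sd_norm_power_max = 0.02,
                               repeatability_max = 0.2,
                               var_noise_min = 90,
                               stab_noise_min = 97,
                               drift_bounds = drift_class_bounds()) {
  thresholds <- c(
    fwhm_ratio        = fwhm_ratio_max,
    uniformity_min    = uniformity_min,
    centering_min     = centering_min,
    coreg_ratio_max   = coreg_ratio_max,
    stab_power_min    = stab_power_min,
    sd_norm_power_max = sd_norm_power_max,
    repeatability_max = repeatability_max,
    var_noise_min     = var_noise_min,
    stab_noise_min    = stab_noise_min
  )
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("all thresholds must be strictly positive", call. = FALSE)
  stopifnot(inherits(drift_bounds, "drift_class_bounds"))
  structure(
    list(thresholds = thresholds,
         directions = .metric_directions[names(thresholds)],
         drift_bounds = drift_bounds),
    class = "tolerance_registry"
  )
}

#' @export
print.tolerance_registry <- function(x, ...) {
  cat("<tolerance registry>\n")
  for (id in names(x$thresholds)) {
    cat(sprintf("  %-18s %s %g\n", id,
                if (x$directions[[id]] == "min") ">=" else "<=",
                x$thresholds[[id]]))
  }
  invisible(x)
}

#' Flag a metric value against its registered tolerance
#'
#' Compares a measured value with its threshold in the registry, honouring
#' the metric's direction: minimum-type metrics pass when the value is at
#' or above the threshold, maximum-type metrics when at or below it.
#' Boundary values pass.
#'
#' @param value Finite numeric value of the metric.
#' @param metric_id Identifier of a registered metric (see
#'   \code{\link{tolerance_registry}}).
#' @param registry A \code{\link{tolerance_registry}}.
#'
#' @return \code{TRUE} if the value is within tolerance, \code{FALSE}
#'   otherwise.
#' @export
flag_metric <- function(value, metric_id, registry = tolerance_registry()) {
  stopifnot(inherits(registry, "tolerance_registry"))
  if (!metric_id %in% names(registry$thresholds))
    stop(sprintf("unknown metric id '%s'", metric_id), call. = FALSE)
  if (!is.finite(value))
    stop("'value' must be finite", call. = FALSE)
  thr <- registry$thresholds[[metric_id]]
  if (registry$directions[[metric_id]] == "min") value >= thr else value <= thr
}

#' Build a tolerance registry from a YAML config file
#'
#' Reads a YAML file whose top-level keys override individual registry
#' defaults (e.g. \code{sd_norm_power_max: 0.2}). Keys under
#' \code{drift_bounds} override the drift classification bounds. Unknown
#' keys are an error so that typos do not silently keep a default.
#'
#' @param path Path to a YAML file.
#' @return A \code{\link{tolerance_registry}}.
#' @export
registry_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(tolerance_registry())
  drift_args <- cfg$drift_bounds
  cfg$drift_bounds <- NULL
  known <- names(formals(tolerance_registry))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown tolerance keys in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(drift_args)) {
    bad <- setdiff(names(drift_args), names(formals(drift_class_bounds)))
    if (length(bad))
      stop("unknown drift bound keys in config: ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg$drift_bounds <- do.call(drift_class_bounds, drift_args)
  }
  do.call(tolerance_registry, cfg)
}

#' Serialize the tolerance registry to a plain list
#'
#' Used by the report writers; the returned list round-trips through JSON
#' or YAML without loss.
#'
#' @param registry A \code{\link{tolerance_registry}}.
#' @return A named list of thresholds plus a \code{drift_bounds} sublist.
#' @export
registry_to_list <- function(registry = tolerance_registry()) {
  stopifnot(inherits(registry, "tolerance_registry"))
  out <- as.list(registry$thresholds)
  out$drift_bounds <- unclass(registry$drift_bounds)
  out
}
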