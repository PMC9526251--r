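#' @name stage
#' @title Stage drift and positioning repeatability
#'
#' @description
#' Stage drift is characterized from a tracked bead's 3D positions over a
#' long time-lapse: the stabilization time tau_stab (first frame from
#' which every later position stays within the system's spatial
#' resolution of the anchor position on each axis), and the mean 3D drift
#' velocities before (V_b) and after (V_a) stabilization, classified as
#' standard / acceptable / critical. Positioning repeatability is the SD
#' of the reference-position coordinates across successive stage returns.
NULL

#' Construct a track series
#'
#' @param t_min Frame times in minutes, strictly increasing.
#' @param x_um,y_um Lateral positions (um).
#' @param z_um Axial positions (um); optional.
#' @param flagged Logical per frame; \code{TRUE} marks frames where the
#'   bead was lost (excluded from metrics, never interpolated).
#'
#' @return An object of class \code{track_series}.
#' @export
track_series <- function(t_min, x_um, y_um, z_um = NULL, flagged = NULL) {
  n <- length(t_min)
  if (any(diff(t_min) <= 0))
    stop("'t_min' must be strictly increasing", call. = FALSE)
  if (length(x_um) != n || length(y_um) != n)
    stop("one position per frame required", call. = FALSE)
  if (!is.null(z_um) && length(z_um) != n)
    stop("'z_um' must match the frame count", call. = FALSE)
  if (is.null(flagged)) flagged <- rep(FALSE, n)
  structure(list(t_min = as.numeric(t_min), x_um = as.numeric(x_um),
                 y_um = as.numeric(y_um),
                 z_um = if (is.null(z_um)) NULL else as.numeric(z_um),
                 flagged = flagged),
            class = "track_series")
}

#' Read a track table from CSV
#'
#' Expects columns \code{t_min}, \code{x_um}, \code{y_um} and optionally
#' \code{z_um}.
#'
#' @param path CSV file path.
#' @return A \code{\link{track_series}}.
#' @export
read_track_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_min", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop("track CSV must have columns t_min, x_um, y_um[, z_um]",
         call. = FALSE)
  track_series(d$t_min, d$x_um, d$y_um,
               z_um = if ("z_um" %in% names(d)) d$z_um else NULL)
}

#' Track a single bead through a time-lapse stack
#'
#' Computes the background-subtracted intensity centroid of the dominant
#' bead in every frame. Frames with no voxel above half the frame maximum
#' over background are flagged as lost and excluded from metrics;
#' positions are never interpolated.
#'
#' @param timelapse 4D array \code{[y, x, z, t]}.
#' @param meta An \code{\link{acquisition_meta}} (pixel size, z step,
#'   time interval in seconds).
#'
#' @return A \code{\link{track_series}} with times in minutes.
#' @export
track_single_bead <- function(timelapse, meta) {
  stopifnot(is.array(timelapse), length(dim(timelapse)) == 4L)
  n_t <- dim(timelapse)[4]
  dt_min <- if (is.na(meta$time_interval)) 1 else meta$time_interval / 60
  xs <- ys <- zs <- numeric(n_t)
  flagged <- logical(n_t)
  for (k in seq_len(n_t)) {
    frame <- timelapse[, , , k, drop = TRUE]
    bg <- stats::median(frame)
    peak <- max(frame) - bg
    if (peak <= 0) {
      flagged[k] <- TRUE
      next
    }
    ctr <- tryCatch(bead_center_of_mass(frame, meta), error = function(e) NULL)
    if (is.null(ctr)) {
      flagged[k] <- TRUE
      next
    }
    xs[k] <- ctr["x"]; ys[k] <- ctr["y"]; zs[k] <- ctr["z"]
  }
  xs[flagged] <- NA_real_; ys[flagged] <- NA_real_; zs[flagged] <- NA_real_
  track_series((seq_len(n_t) - 1) * dt_min, xs, ys, zs, flagged = flagged)
}

# classify one quantity against (standard_max, acceptable_max)
classify_band <- function(value, standard_max, acceptable_max) {
  if (is.na(value)) return("critical")
  if (value < standard_max) "standard"
  else if (value <= acceptable_max) "acceptable"
  else "critical"
}

worst_class <- function(classes) {
  order <- c("standard", "acceptable", "critical")
  order[max(match(classes, order))]
}

#' Stage drift metrics
#'
#' tau_stab is the earliest frame time t_k such that every later frame
#' stays, simultaneously on each axis, within the lateral resolution (x,
#' y) and the axial resolution (z) of the position at t_k. V_b is the
#' mean over the pre-stabilization steps of the 3D step length divided by
#' the step interval, V_a the same after stabilization, both in nm/min.
#' Each quantity is classified independently against the drift bounds and
#' the overall class is the worst of the three.
#'
#' @param track A \code{\link{track_series}} (>= 3 unflagged frames,
#'   times in minutes).
#' @param spec A \code{resolution_spec} supplying the lateral and axial
#'   resolutions (um).
#' @param bounds A \code{\link{drift_class_bounds}}.
#'
#' @return An object of class \code{drift_metrics}: \code{tau_stab} (min,
#'   \code{NA} when never stabilized), \code{stabilized}, \code{v_before}
#'   and \code{v_after} (nm/min), per-quantity and overall
#'   classifications, and a \code{qc_report}.
#' @export
drift_metrics <- function(track, spec, bounds = drift_class_bounds()) {
  stopifnot(inherits(track, "track_series"))
  ok <- !track$flagged
  t <- track$t_min[ok]
  x <- track$x_um[ok]
  y <- track$y_um[ok]
  z <- if (is.null(track$z_um)) rep(0, sum(ok)) else track$z_um[ok]
  n <- length(t)
  if (n < 3L) stop("at least 3 frames required", call. = FALSE)

  r_lat <- spec$lateral
  r_ax <- spec$axial
  # the last frame is never a valid anchor: stabilization cannot be
  # claimed without at least one later frame confirming it
  tau_idx <- NA_integer_
  for (k in seq_len(n - 1L)) {
    later <- k:n
    if (all(abs(x[later] - x[k]) < r_lat) &&
        all(abs(y[later] - y[k]) < r_lat) &&
        all(abs(z[later] - z[k]) < r_ax)) {
      tau_idx <- k
      break
    }
  }
  stabilized <- !is.na(tau_idx)
  tau <- if (stabilized) t[tau_idx] - t[1] else NA_real_

  step_len <- sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2)  # um
  step_v <- 1000 * step_len / diff(t)                  # nm/min
  if (stabilized) {
    before <- seq_len(n - 1) < tau_idx   # steps ending at or before tau
    v_before <- if (any(before)) mean(step_v[before]) else 0
    v_after <- if (any(!before)) mean(step_v[!before]) else 0
  } else {
    v_before <- mean(step_v)
    v_after <- NA_real_
  }

  class_tau <- if (!stabilized) "critical"
    else classify_band(tau, bounds$tau_standard_max, bounds$tau_acceptable_max)
  class_vb <- classify_band(v_before, bounds$v_standard_max,
                            bounds$vb_acceptable_max)
  class_va <- classify_band(v_after, bounds$v_standard_max,
                            bounds$va_acceptable_max)
  overall <- worst_class(c(class_tau, class_vb, class_va))

  metrics <- rbind(
    metric_row("tau_stab_min", if (stabilized) tau else NA_real_,
               bounds$tau_acceptable_max,
               stabilized && tau <= bounds$tau_acceptable_max),
    metric_row("v_before_nm_min", v_before, bounds$vb_acceptable_max,
               is.finite(v_before) && v_before <= bounds$vb_acceptable_max),
    metric_row("v_after_nm_min", v_after, bounds$va_acceptable_max,
               is.finite(v_after) && v_after <= bounds$va_acceptable_max))
  structure(
    list(tau_stab = tau, stabilized = stabilized,
         v_before = v_before, v_after = v_after,
         class_tau = class_tau, class_vb = class_vb, class_va = class_va,
         class_overall = overall,
         report = qc_report("drift", metrics)),
    class = "drift_metrics")
}

#' @export
print.drift_metrics <- function(x, ...) {
  cat(sprintf(
    "<drift: tau %s min [%s], Vb %.1f nm/min [%s], Va %s nm/min [%s] -> %s>\n",
    ifelse(x$stabilized, format(round(x$tau_stab, 1)), "not stabilized"),
    x$class_tau, x$v_before, x$class_vb,
    ifelse(is.na(x$v_after), "-", format(round(x$v_after, 1))), x$class_va,
    x$class_overall))
  invisible(x)
}

#' Classify a printed drift triple
#'
#' Convenience wrapper classifying already-measured drift values against
#' the drift bounds (e.g. values read from an external tracking tool).
#'
#' @param tau_stab Stabilization time (min), or \code{NA} if never
#'   stabilized.
#' @param v_before,v_after Mean velocities (nm/min).
#' @param bounds A \code{\link{drift_class_bounds}}.
#' @return A list with the three per-quantity classes and the overall
#'   (worst) class.
#' @export
classify_drift <- function(tau_stab, v_before, v_after,
                           bounds = drift_class_bounds()) {
  class_tau <- if (is.na(tau_stab)) "critical"
    else classify_band(tau_stab, bounds$tau_standard_max,
                       bounds$tau_acceptable_max)
  class_vb <- classify_band(v_before, bounds$v_standard_max,
                            bounds$vb_acceptable_max)
  class_va <- classify_band(v_after, bounds$v_standard_max,
                            bounds$va_acceptable_max)
  list(tau = class_tau, v_before = class_vb, v_after = class_va,
       overall = worst_class(c(class_tau, class_vb, class_va)))
}

#' Stage positioning repeatability
#'
#' Sample SD of the x and y coordinates measured on successive returns of
#' the stage to a reference position, flagged against the repeatability
#' tolerance (default 0.2 um).
#'
#' @param visits Data frame with columns \code{x_um} and \code{y_um}, one
#'   row per reference visit (>= 2), or a \code{\link{track_series}}
#'   restricted to reference-position frames.
#' @param registry A \code{\link{tolerance_registry}}.
#'
#' @return A list with \code{sigma_x}, \code{sigma_y} (um), their pass
#'   flags, \code{n_visits} and a \code{qc_report}.
#' @export
repeatability <- function(visits, registry = tolerance_registry()) {
  if (inherits(visits, "track_series"))
    visits <- data.frame(x_um = visits$x_um[!visits$flagged],
                         y_um = visits$y_um[!visits$flagged])
  stopifnot(is.data.frame(visits),
            all(c("x_um", "y_um") %in% names(visits)))
  if (nrow(visits) < 2L)
    stop("at least 2 reference visits required", call. = FALSE)
  sigma_x <- stats::sd(visits$x_um)
  sigma_y <- stats::sd(visits$y_um)
  pass_x <- flag_metric(sigma_x, "repeatability_max", registry)
  pass_y <- flag_metric(sigma_y, "repeatability_max", registry)
  thr <- registry$thresholds[["repeatability_max"]]
  metrics <- rbind(
    metric_row("sigma_x_um", sigma_x, thr, pass_x),
    metric_row("sigma_y_um", sigma_y, thr, pass_y))
  list(sigma_x = sigma_x, sigma_y = sigma_y,
       pass_x = pass_x, pass_y = pass_y, n_visits = nrow(visits),
       report = qc_report("repeat", metrics))
}

#' Extract reference-position visits from a nine-position cycle
#'
#' In the nine-position repeatability protocol
#' (Pref-P1-Pref-P2-Pref-P3-Pref-P4-Pref per cycle) the reference
#' position occupies every other frame; this helper selects those frames
#' by schedule.
#'
#' @param track A \code{\link{track_series}} covering the full protocol.
#' @param cycle Cycle length in frames (default 9).
#' @param ref_index 0-based indices of the reference frames within each
#'   cycle (default \code{c(0, 2, 4, 6, 8)}).
#' @return A data frame of reference visits (\code{x_um}, \code{y_um}).
#' @export
reference_visits <- function(track, cycle = 9L,
                             ref_index = c(0L, 2L, 4L, 6L, 8L)) {
  stopifnot(inherits(track, "track_series"))
  n <- length(track$t_min)
  pos_in_cycle <- (seq_len(n) - 1L) %% cycle
  sel <- pos_in_cycle %in% ref_index & !track$flagged
  data.frame(x_um = track$x_um[sel], y_um = track$y_um[sel])
}
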