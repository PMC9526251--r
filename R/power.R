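#' @name power
#' @title Illumination power stability
#'
#' @description
#' Metrics for illumination power time series recorded with a power meter
#' at the sample plane. The stability factor
#' \eqn{STAB = 100\,[1 - (P_{max}-P_{min})/(P_{max}+P_{min})]} and the SD
#' of the max-normalized power summarize short-term (5 min at 1 Hz) and
#' mid-term (2 h at 1/30 Hz) recordings; a windowed-settling rule
#' estimates the warm-up time of a source.
NULL

#' Construct a power trace
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param power_w Non-negative power readings (W or any fixed unit).
#' @param label Source label (e.g. \code{"488 nm"}).
#' @param regime Acquisition regime: \code{"short"} (5 min at 1 s),
#'   \code{"mid"} (2 h at 30 s) or \code{"long"} (monthly sessions).
#'
#' @return An object of class \code{power_trace}.
#' @export
power_trace <- function(time_s, power_w, label = NA_character_,
                        regime = c("mid", "short", "long")) {
  regime <- match.arg(regime)
  if (length(time_s) != length(power_w))
    stop("'time_s' and 'power_w' must have equal length", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("'time_s' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(power_w)) || any(power_w < 0))
    stop("'power_w' must be finite and non-negative", call. = FALSE)
  structure(list(time_s = as.numeric(time_s), power_w = as.numeric(power_w),
                 label = label, regime = regime),
            class = "power_trace")
}

#' Read a power trace from CSV
#'
#' Expects two columns, time in seconds and power in watts; a header row
#' is optional.
#'
#' @param path CSV file path.
#' @inheritParams power_trace
#' @return A \code{power_trace}.
#' @export
read_power_trace <- function(path, label = NA_character_,
                             regime = c("mid", "short", "long")) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE]+\\s*[,;\\t]", first)
  d <- utils::read.csv(path, header = has_header)
  if (ncol(d) < 2L) stop("expected two columns: time_s, power_w",
                         call. = FALSE)
  power_trace(d[[1]], d[[2]], label = label, regime = regime)
}

#' Power stability metrics
#'
#' Computes the min-max stability factor and the SD of the power
#' normalized by its maximum, flagged against the 97% / 0.02 tolerances.
#'
#' @param trace A \code{\link{power_trace}} (>= 2 samples, not all zero).
#' @param registry A \code{\link{tolerance_registry}}.
#'
#' @return A list with \code{stab} (%), \code{sd_norm}, their pass flags,
#'   \code{p_max}, \code{p_min} and a \code{qc_report}.
#' @examples
#' tr <- power_trace(0:9, c(rep(1, 5), rep(0.9, 5)))
#' stability_metrics(tr)$stab  # 94.74
#' @export
stability_metrics <- function(trace, registry = tolerance_registry()) {
  stopifnot(inherits(trace, "power_trace"))
  if (length(trace$power_w) < 2L)
    stop("at least two samples required", call. = FALSE)
  p_max <- max(trace$power_w)
  p_min <- min(trace$power_w)
  if (p_max <= 0) stop("all-zero power trace", call. = FALSE)
  stab <- 100 * (1 - (p_max - p_min) / (p_max + p_min))
  sd_norm <- stats::sd(trace$power_w / p_max)
  pass_stab <- flag_metric(stab, "stab_power_min", registry)
  pass_sd <- flag_metric(sd_norm, "sd_norm_power_max", registry)
  metrics <- rbind(
    metric_row("stab_power", stab,
               registry$thresholds[["stab_power_min"]], pass_stab),
    metric_row("sd_norm_power", sd_norm,
               registry$thresholds[["sd_norm_power_max"]], pass_sd))
  list(stab = stab, sd_norm = sd_norm,
       pass_stab = pass_stab, pass_sd = pass_sd,
       p_max = p_max, p_min = p_min,
       report = qc_report("power", metrics, input = trace$label))
}

#' Warm-up time of a light source
#'
#' Declares the source warmed up at the earliest time t such that every
#' later sample stays within a relative band of the settled level, taken
#' as the mean of the final window of the trace.
#'
#' @param trace A \code{\link{power_trace}} spanning at least twice
#'   \code{window_s}.
#' @param window_s Width of the final reference window in seconds.
#' @param band Relative half-width of the settling band (default 0.01,
#'   i.e. +/- 1% of the settled level).
#'
#' @return A list with \code{warmup_s} (seconds; 0 when settled from the
#'   start) and \code{stabilized} (\code{FALSE} when the criterion is
#'   never met, in which case \code{warmup_s} is \code{NA}).
#' @export
warmup_summary <- function(trace, window_s = 600, band = 0.01) {
  stopifnot(inherits(trace, "power_trace"))
  t <- trace$time_s
  p <- trace$power_w
  span <- t[length(t)] - t[1]
  if (span < 2 * window_s)
    stop("trace must span at least twice the reference window",
         call. = FALSE)
  settled <- mean(p[t >= t[length(t)] - window_s])
  if (settled <= 0) stop("settled level is zero", call. = FALSE)
  within <- abs(p - settled) <= band * settled
  # last index violating the band; warm-up is the next sample time
  bad <- which(!within)
  if (length(bad) == 0L) return(list(warmup_s = 0, stabilized = TRUE))
  last_bad <- max(bad)
  if (last_bad == length(p))
    return(list(warmup_s = NA_real_, stabilized = FALSE))
  list(warmup_s = t[last_bad + 1L], stabilized = TRUE)
}

#' Long-term power trend summary
#'
#' Descriptive per-session table for monthly monitoring: each session's
#' mean power, STAB and normalized SD, plus the overall min-max stability
#' across session means.
#'
#' @param sessions Named list of \code{\link{power_trace}} objects.
#' @param registry A \code{\link{tolerance_registry}}.
#' @return A list with \code{table} (one row per session) and
#'   \code{stab_across_sessions}.
#' @export
longterm_summary <- function(sessions, registry = tolerance_registry()) {
  stopifnot(length(sessions) >= 1L)
  rows <- lapply(seq_along(sessions), function(i) {
    tr <- sessions[[i]]
    m <- stability_metrics(tr, registry)
    data.frame(session = if (!is.null(names(sessions)))
                 names(sessions)[i] else as.character(i),
               mean_power = mean(tr$power_w),
               stab = m$stab, sd_norm = m$sd_norm)
  })
  tab <- do.call(rbind, rows)
  means <- tab$mean_power
  stab_lt <- if (length(means) > 1)
    100 * (1 - (max(means) - min(means)) / (max(means) + min(means)))
  else 100
  list(table = tab, stab_across_sessions = stab_lt)
}
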