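#' Read a TIFF stack into the package's array convention
#'
#' Reads a (multi-page) TIFF into an array \code{[y, x, z]} of raw ADU
#' values, or \code{[y, x, z, channel]} when \code{n_channels > 1}. Plane
#' order is assumed channel-fastest within z (the common hyperstack
#' interleaving); RGB pages are reduced to their first sample.
#'
#' @param path TIFF file path.
#' @param n_channels Number of interleaved channels (default 1).
#'
#' @return A numeric array in ADU.
#' @export
read_stack_tiff <- function(path, n_channels = 1L) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p
  })
  n <- length(planes)
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  if (n_channels == 1L) {
    out <- array(0, dim = c(ny, nx, n))
    for (k in seq_len(n)) out[, , k] <- planes[[k]]
    return(out)
  }
  if (n %% n_channels != 0L)
    stop("plane count is not a multiple of 'n_channels'", call. = FALSE)
  nz <- n %/% n_channels
  out <- array(0, dim = c(ny, nx, nz, n_channels))
  k <- 1L
  for (z in seq_len(nz)) for (ch in seq_len(n_channels)) {
    out[, , z, ch] <- planes[[k]]
    k <- k + 1L
  }
  out
}

#' Write an image or stack as TIFF
#'
#' Scales ADU values by the bit-depth range and writes 16-bit pages.
#'
#' @param x Matrix \code{[y, x]} or array \code{[y, x, z]} in ADU.
#' @param path Output path.
#' @param bit_depth Bit depth of the ADU scale (default 16).
#' @return \code{path}, invisibly.
#' @export
write_image_tiff <- function(x, path, bit_depth = 16L) {
  scale <- 2^bit_depth - 1
  norm <- function(m) pmin(pmax(m / scale, 0), 1)
  if (is.matrix(x)) {
    tiff::writeTIFF(norm(x), path, bits.per.sample = 16L)
  } else {
    planes <- lapply(seq_len(dim(x)[3]), function(k) norm(x[, , k]))
    tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Run an analysis over a batch of inputs
#'
#' Applies \code{fun} to every input; one failing input is recorded as a
#' named failure and never aborts the batch. \code{fun} must return
#' either a \code{\link{qc_report}} or a list containing one under
#' \code{$report}.
#'
#' @param inputs Character vector of file paths (or any objects
#'   \code{fun} accepts); must be non-empty.
#' @param fun Function of one input returning a report.
#' @param ... Further arguments passed to \code{fun}.
#'
#' @return A list with \code{reports} (per successful input),
#'   \code{failures} (named error messages), and \code{aggregate}: per
#'   metric the mean, SD over files and the pass rate.
#' @export
run_batch <- function(inputs, fun, ...) {
  if (length(inputs) == 0L)
    stop("no inputs matched", call. = FALSE)
  reports <- list()
  failures <- character(0)
  labels <- if (is.character(inputs)) make.unique(inputs)
            else as.character(seq_along(inputs))
  for (i in seq_along(inputs)) {
    label <- labels[[i]]
    out <- tryCatch(fun(inputs[[i]], ...), error = function(e) e)
    if (inherits(out, "error")) {
      failures[[label]] <- conditionMessage(out)
      next
    }
    rep_ <- if (inherits(out, "qc_report")) out else out$report
    if (is.na(rep_$input)) rep_$input <- label
    reports[[label]] <- rep_
  }
  aggregate <- NULL
  if (length(reports) > 0L) {
    all_m <- do.call(rbind, lapply(reports, function(r) r$metrics))
    aggregate <- do.call(rbind, lapply(split(all_m, all_m$metric),
      function(d) data.frame(
        metric = d$metric[1], n = nrow(d),
        mean = mean(d$value, na.rm = TRUE),
        sd = if (sum(!is.na(d$value)) > 1) stats::sd(d$value, na.rm = TRUE)
             else 0,
        pass_rate = if (all(is.na(d$pass))) NA_real_
                    else mean(d$pass, na.rm = TRUE))))
    rownames(aggregate) <- NULL
  }
  list(reports = reports, failures = failures, aggregate = aggregate)
}
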