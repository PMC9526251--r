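#' @name fieldillum
#' @title Field-illumination flatness analysis
#'
#' @description
#' Quantifies how evenly a microscope illuminates its field of view from a
#' single image of a uniformly fluorescent sample. The image is smoothed
#' with a Gaussian blur (sigma = 2 pixels) to de-weight hot pixels and
#' dust, normalized to its maximum, binned into isointensity steps, and
#' two metrics are computed: uniformity \eqn{U = 100\,I_{min}/I_{max}}
#' and centering
#' \eqn{C = 100 - 100 \cdot 2 d / D}, where \eqn{d} is the distance of the
#' brightest-zone centre from the image centre and \eqn{D} the image
#' diagonal, both measured in the pixel-centre coordinate frame (so a
#' reference zone centred on a corner pixel gives exactly C = 0).
NULL

#' Centering metric from a reference-zone centre
#'
#' \eqn{C = 100 - 100 \cdot 2 d / D}: \eqn{d} is the Euclidean distance
#' between \code{center_xy} and the geometric image centre
#' \code{((nx-1)/2, (ny-1)/2)}, and \eqn{D} the pixel-centre diagonal
#' \code{sqrt((nx-1)^2 + (ny-1)^2)}, so a centre on the geometric centre
#' gives exactly 100 and a centre on any corner pixel exactly 0.
#'
#' @param center_xy Reference-zone centre \code{c(x, y)} in 0-based pixel
#'   coordinates.
#' @param dim_yx Image size \code{c(ny, nx)} in pixels.
#'
#' @return The centering metric (%), 100 at the centre, 0 at a corner.
#' @examples
#' centering_value(c(0, 0), c(256, 256))        # 0 (corner)
#' centering_value(c(127.5, 127.5), c(256, 256)) # 100 (centre)
#' @export
centering_value <- function(center_xy, dim_yx) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  geo <- c((nx - 1) / 2, (ny - 1) / 2)
  d <- sqrt(sum((center_xy - geo)^2))
  diag_len <- sqrt((nx - 1)^2 + (ny - 1)^2)
  100 - 100 * 2 * d / diag_len
}

#' Analyze a single-channel field-illumination image
#'
#' @param image Numeric matrix \code{[y, x]}, at least 16 x 16 pixels.
#' @param bins Number of isointensity bins (>= 2); 10 gives 10% steps.
#' @param ref_band Lower edge of the reference band on the normalized
#'   scale; the default 0.9 uses the 90-100% zone as the brightest-zone
#'   reference, which is more robust than the single maximum pixel.
#' @param bit_depth Detector bit depth; saturation is evaluated on the
#'   blurred image (any blurred pixel at the saturation level).
#' @param discard_saturated If \code{TRUE} and the blurred image is
#'   saturated, the analysis is skipped (an error of class
#'   \code{saturated_image} is signalled).
#' @param sigma Gaussian blur SD in pixels (default 2).
#' @param registry A \code{\link{tolerance_registry}} used for flags.
#'
#' @return An object of class \code{fieldillum_result}: \code{uniformity}
#'   and \code{centering} (%), their pass flags, \code{centers} (geometric
#'   centre, intensity centroid, maximum pixel, reference-zone centre, in
#'   0-based pixels), \code{centering_max_pixel} (the raw max-pixel
#'   variant), \code{normalized_map}, \code{iso_map} and \code{saturated}.
#' @examples
#' img <- make_flat_field(dim_yx = c(64, 64))$image
#' analyze_field(img)$uniformity  # 100 for a flat field
#' @export
analyze_field <- function(image, bins = 10L, ref_band = 0.9,
                          bit_depth = 16L, discard_saturated = FALSE,
                          sigma = 2, registry = tolerance_registry()) {
  if (!is.matrix(image) || nrow(image) < 16L || ncol(image) < 16L)
    stop("'image' must be a matrix of at least 16 x 16 pixels",
         call. = FALSE)
  if (bins < 2L) stop("'bins' must be >= 2", call. = FALSE)
  if (max(image) <= 0)
    stop("image has no positive intensity; normalization undefined",
         call. = FALSE)

  blurred <- EBImage::gblur(image, sigma = sigma, boundary = "replicate")
  blurred <- pmax(blurred, 0)

  sat_level <- 2^bit_depth - 1
  saturated <- any(blurred >= sat_level * (1 - 1e-9))
  if (saturated && discard_saturated) {
    cond <- simpleError("image saturated after blurring; skipped")
    class(cond) <- c("saturated_image", class(cond))
    stop(cond)
  }

  i_max <- max(blurred)
  i_min <- min(blurred)
  uniformity <- 100 * i_min / i_max

  norm <- blurred / i_max
  iso <- matrix(pmin(floor(norm * bins) + 1L, bins),
                nrow(norm), ncol(norm))

  ny <- nrow(image); nx <- ncol(image)
  geo_center <- c(x = (nx - 1) / 2, y = (ny - 1) / 2)

  # intensity centroid and single max pixel of the blurred image
  xs <- seq_len(nx) - 1
  ys <- seq_len(ny) - 1
  tot <- sum(blurred)
  centroid <- c(x = sum(colSums(blurred) * xs) / tot,
                y = sum(rowSums(blurred) * ys) / tot)
  mi <- which(blurred == i_max, arr.ind = TRUE)[1, ]
  max_pixel <- c(x = unname(mi[2]) - 1, y = unname(mi[1]) - 1)

  # reference zone: geometric centre of pixels in the top band
  in_band <- norm >= ref_band
  idx <- which(in_band, arr.ind = TRUE)
  ref_center <- c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)

  centering_of <- function(pt) centering_value(pt, c(ny, nx))
  centering <- centering_of(ref_center)
  structure(
    list(uniformity = uniformity,
         centering = centering,
         centering_max_pixel = centering_of(max_pixel),
         pass_uniformity = flag_metric(uniformity, "uniformity_min", registry),
         pass_centering = flag_metric(centering, "centering_min", registry),
         centers = list(geometric = geo_center, centroid = centroid,
                        max_pixel = max_pixel, reference_zone = ref_center),
         normalized_map = norm,
         iso_map = iso,
         saturated = saturated,
         bins = bins, ref_band = ref_band),
    class = "fieldillum_result")
}

#' @export
print.fieldillum_result <- function(x, ...) {
  cat(sprintf("<field illumination: U %.1f%% [%s], C %.1f%% [%s]%s>\n",
              x$uniformity, ifelse(x$pass_uniformity, "pass", "fail"),
              x$centering, ifelse(x$pass_centering, "pass", "fail"),
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}

#' Analyze each channel of a multichannel field-illumination image
#'
#' Channels are independent: a failure in one (e.g. saturation with
#' \code{discard_saturated}) is recorded and the remaining channels are
#' still processed.
#'
#' @param stack 3D array \code{[y, x, channel]} or a list of matrices.
#' @param meta Optional \code{\link{acquisition_meta}} supplying the bit
#'   depth and channel names.
#' @inheritParams analyze_field
#'
#' @return A list of \code{fieldillum_result} objects (or error
#'   conditions for skipped channels), one per channel, plus a
#'   \code{qc_report} with per-channel U and C flags under
#'   \code{attr(, "report")}.
#' @export
analyze_field_multichannel <- function(stack, meta = NULL, bins = 10L,
                                       ref_band = 0.9,
                                       discard_saturated = FALSE,
                                       sigma = 2,
                                       registry = tolerance_registry()) {
  channels <- if (is.list(stack)) stack
              else lapply(seq_len(dim(stack)[3]), function(ch) stack[, , ch])
  if (length(channels) < 1L) stop("at least one channel required",
                                  call. = FALSE)
  bit_depth <- if (is.null(meta)) 16L else meta$bit_depth
  names_ch <- if (!is.null(meta) && length(meta$channels) == length(channels))
    vapply(meta$channels, `[[`, character(1), "name")
  else paste0("ch", seq_along(channels))

  results <- lapply(channels, function(img) {
    tryCatch(
      analyze_field(img, bins = bins, ref_band = ref_band,
                    bit_depth = bit_depth,
                    discard_saturated = discard_saturated, sigma = sigma,
                    registry = registry),
      error = function(e) e)
  })
  names(results) <- names_ch

  rows <- list()
  for (ch in seq_along(results)) {
    r <- results[[ch]]
    if (inherits(r, "error")) {
      rows[[length(rows) + 1L]] <-
        metric_row(paste0(names_ch[ch], "_skipped"), NA_real_)
      next
    }
    rows[[length(rows) + 1L]] <- metric_row(
      paste0(names_ch[ch], "_uniformity"), r$uniformity,
      registry$thresholds[["uniformity_min"]], r$pass_uniformity)
    rows[[length(rows) + 1L]] <- metric_row(
      paste0(names_ch[ch], "_centering"), r$centering,
      registry$thresholds[["centering_min"]], r$pass_centering)
  }
  attr(results, "report") <- qc_report("field", do.call(rbind, rows),
                                       meta = meta)
  results
}
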