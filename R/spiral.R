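#' Square-spiral pixel ordering
#'
#' Linear indices (column-major, into a `side` x `side` matrix) of the
#' deterministic inward square spiral that starts at the top-left corner
#' and proceeds clockwise (right along the top row, down the last column,
#' left along the bottom row, up, and inward). `spiral_order(side)[k]` is
#' the matrix position of the k-th element along the spiral.
#'
#' @param side Image side in pixels.
#' @return Integer vector of length `side^2`.
#' @export
spiral_order <- function(side) {
  side <- as.integer(side)
  stopifnot(side >= 1L)
  top <- 1L; bottom <- side; left <- 1L; right <- side
  out <- integer(side^2); k <- 0L
  idx <- function(r, c) r + (c - 1L) * side
  while (top <= bottom && left <= right) {
    for (c in left:right) { k <- k + 1L; out[k] <- idx(top, c) }
    top <- top + 1L
    if (top > bottom) break
    for (r in top:bottom) { k <- k + 1L; out[k] <- idx(r, right) }
    right <- right - 1L
    if (left > right) break
    for (c in right:left) { k <- k + 1L; out[k] <- idx(bottom, c) }
    bottom <- bottom - 1L
    if (top > bottom) break
    for (r in bottom:top) { k <- k + 1L; out[k] <- idx(r, left) }
    left <- left + 1L
  }
  out
}

#' Encode a decay curve as a square-spiral grayscale image
#'
#' Maps bin k of the histogram to the k-th pixel along the inward
#' clockwise spiral ([spiral_order()]), dividing counts by a
#' normalization factor `scale` stored in the image metadata. Unused
#' trailing pixels are zero. The encoding is lossless: decoding recovers
#' the original counts exactly (up to quantization if the image has been
#' written to a 16-bit file).
#'
#' @param curve A [decay_curve()].
#' @param side Image side in pixels; `side^2` must be at least the number
#'   of bins (default: smallest sufficient side).
#' @param scale Counts per intensity unit; default `max(counts)` so pixel
#'   intensities lie in `[0, 1]`.
#' @return An object of class `spiral_image` with fields `pixels`
#'   (`side` x `side` matrix), `side`, `bin_width` (ns), `scale`,
#'   `n_bins`, `path_spec` and the curve's acquisition metadata.
#' @export
spiral_encode <- function(curve, side = NULL, scale = NULL) {
  stopifnot(inherits(curve, "decay_curve"))
  n <- length(curve$counts)
  if (is.null(side)) side <- ceiling(sqrt(n))
  side <- as.integer(side)
  if (side^2 < n) {
    stop(sprintf("side %d too small for %d bins", side, n), call. = FALSE)
  }
  if (is.null(scale)) scale <- max(curve$counts, 1e-12)
  px <- numeric(side^2)
  px[spiral_order(side)[seq_len(n)]] <- curve$counts / scale
  structure(list(pixels = matrix(px, side, side), side = side,
                 bin_width = diff(curve$bin_edges)[1], scale = scale,
                 n_bins = n, path_spec = "top-left-clockwise-inward",
                 wavelength_em = curve$wavelength_em,
                 wavelength_exc = curve$wavelength_exc,
                 temperature = curve$temperature,
                 integration_time = curve$integration_time),
            class = "spiral_image")
}

#' @export
print.spiral_image <- function(x, ...) {
  cat(sprintf(
    "<spiral_image: %dx%d px, %d bins of %.4g ns, scale %.4g, %s>\n",
    x$side, x$side, x$n_bins, x$bin_width, x$scale, x$path_spec))
  invisible(x)
}

#' Decode a spiral image back to a decay curve
#'
#' Inverse of [spiral_encode()]: reads the first `n_bins` pixels along the
#' spiral path and multiplies by the stored scale.
#'
#' @param img A `spiral_image`.
#' @return A [decay_curve()].
#' @export
spiral_decode <- function(img) {
  stopifnot(inherits(img, "spiral_image"))
  counts <- as.vector(img$pixels)[spiral_order(img$side)[seq_len(img$n_bins)]] *
    img$scale
  counts[counts < 0] <- 0
  decay_curve(seq(0, by = img$bin_width, length.out = img$n_bins + 1L),
              counts, wavelength_em = img$wavelength_em,
              wavelength_exc = img$wavelength_exc,
              temperature = img$temperature,
              integration_time = img$integration_time)
}

#' Average lifetime from a spiral image
#'
#' Reconstructs the temporal signal along the spiral path (pixel intensity
#' times scale per temporal bin) and applies the intensity-weighted
#' average-lifetime estimator. On an un-denoised image this equals
#' [average_lifetime()] of the source curve up to quantization.
#'
#' @param img A `spiral_image`.
#' @param ... Passed to [average_lifetime()] (e.g. `window`).
#' @return Average lifetime in ns.
#' @export
lifetime_from_image <- function(img, ...) {
  average_lifetime(spiral_decode(img), ...)
}

#' Write / read a spiral image as 16-bit grayscale TIFF with a YAML sidecar
#'
#' Pixels are quantized to 16 bits relative to the image maximum; the
#' quantization ceiling and all spiral metadata go to `<path>.yml`.
#'
#' @param img A `spiral_image`.
#' @param path TIFF file path.
#' @return `write_spiral_image` returns `path` invisibly;
#'   `read_spiral_image` returns a `spiral_image`.
#' @export
write_spiral_image <- function(img, path) {
  stopifnot(inherits(img, "spiral_image"))
  ceiling_val <- max(img$pixels, 1e-12)
  tiff::writeTIFF(pmin(pmax(img$pixels / ceiling_val, 0), 1), path,
                  bits.per.sample = 16L)
  yaml::write_yaml(list(side = img$side, bin_width = img$bin_width,
                        scale = img$scale, n_bins = img$n_bins,
                        path_spec = img$path_spec,
                        pixel_ceiling = ceiling_val,
                        wavelength_em = img$wavelength_em,
                        wavelength_exc = img$wavelength_exc,
                        temperature = img$temperature,
                        integration_time = img$integration_time),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_spiral_image
#' @export
read_spiral_image <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  px <- tiff::readTIFF(path) * meta$pixel_ceiling
  structure(list(pixels = px, side = meta$side, bin_width = meta$bin_width,
                 scale = meta$scale, n_bins = meta$n_bins,
                 path_spec = meta$path_spec,
                 wavelength_em = meta$wavelength_em %||% NA_real_,
                 wavelength_exc = meta$wavelength_exc %||% NA_real_,
                 temperature = meta$temperature %||% NA_real_,
                 integration_time = meta$integration_time %||% NA_real_),
            class = "spiral_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
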