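#' Emission line shape of one emitting state
#'
#' A normalized emission spectrum g(lambda) of either the monomeric or the
#' aggregated (excimer) state of the dye, tabulated on an ascending
#' wavelength grid and normalized so that the trapezoidal integral over the
#' grid equals one.
#'
#' @param state `"monomer"` or `"aggregate"`.
#' @param wavelength_grid Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param density Non-negative numeric vector, same length as
#'   `wavelength_grid`; rescaled internally to unit integral.
#'
#' @return An object of class `emission_line_shape` with elements `state`,
#'   `wavelength_grid` and `density`.
#' @seealso [make_line_shapes()] to build the canonical Gaussian-mixture
#'   shapes, [line_shape_at()] to evaluate by interpolation.
#' @export
emission_line_shape <- function(state = c("monomer", "aggregate"),
                                wavelength_grid, density) {
  state <- match.arg(state)
  wavelength_grid <- as.numeric(wavelength_grid)
  density <- as.numeric(density)
  if (length(wavelength_grid) < 2L || any(diff(wavelength_grid) <= 0)) {
    stop("`wavelength_grid` must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  if (length(density) != length(wavelength_grid)) {
    stop("`density` and `wavelength_grid` lengths differ", call. = FALSE)
  }
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("`density` must be finite and non-negative", call. = FALSE)
  }
  z <- trapz_integral(wavelength_grid, density)
  if (z <= 0) stop("line shape integrates to zero", call. = FALSE)
  structure(
    list(state = state, wavelength_grid = wavelength_grid,
         density = density / z),
    class = "emission_line_shape"
  )
}

trapz_integral <- function(x, y) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' @export
print.emission_line_shape <- function(x, ...) {
  cat(sprintf("<emission_line_shape: %s, %g-%g nm (%d points), peak at %g nm>\n",
              x$state, min(x$wavelength_grid), max(x$wavelength_grid),
              length(x$wavelength_grid),
              x$wavelength_grid[which.max(x$density)]))
  invisible(x)
}

#' Evaluate a line shape at arbitrary wavelengths
#'
#' Linear interpolation on the stored grid; zero outside the grid.
#'
#' @param shape An [emission_line_shape()].
#' @param wavelength Wavelengths in nm.
#' @return Numeric vector of densities (per nm).
#' @export
line_shape_at <- function(shape, wavelength) {
  stopifnot(inherits(shape, "emission_line_shape"))
  stats::approx(shape$wavelength_grid, shape$density, xout = wavelength,
                yleft = 0, yright = 0, ties = "ordered")$y
}

#' Build monomer and aggregate emission line shapes
#'
#' Constructs the two normalized emission line shapes from Gaussian-peak
#' parameters. The monomer spectrum is a mixture of vibronic Gaussian peaks
#' in the green; the aggregate (excimer) spectrum is a single broad red
#' Gaussian. The canonical fixture (see [cns_fixture()]) places the
#' monomer peaks near 520 and 560 nm and the aggregate peak near 650 nm,
#' with widths chosen so the two densities cross at 614 nm -- the wavelength
#' where the two-state model predicts maximum thermal sensitivity.
#'
#' @param monomer_peaks Data frame or list with numeric fields `center`
#'   (nm), `width` (Gaussian sd, nm) and `weight` (mixture weights, any
#'   positive scale) for the monomer peaks.
#' @param aggregate_peaks Same structure for the aggregate state.
#' @param wavelength_grid Wavelength grid in nm (default 480-750 nm in
#'   0.5 nm steps).
#' @return List with elements `monomer` and `aggregate`, both
#'   [emission_line_shape()] objects.
#' @export
make_line_shapes <- function(monomer_peaks, aggregate_peaks,
                             wavelength_grid = seq(480, 750, by = 0.5)) {
  mk <- function(p, state) {
    p <- as.data.frame(p)
    if (!all(c("center", "width", "weight") %in% names(p))) {
      stop("peak tables need columns center, width, weight", call. = FALSE)
    }
    if (any(p$width <= 0) || any(p$weight < 0)) {
      stop("peak widths must be positive and weights non-negative",
           call. = FALSE)
    }
    if (any(p$center < min(wavelength_grid)) ||
        any(p$center > max(wavelength_grid))) {
      stop("peak centers must lie within the wavelength grid", call. = FALSE)
    }
    d <- rep(0, length(wavelength_grid))
    for (i in seq_len(nrow(p))) {
      d <- d + p$weight[i] *
        exp(-0.5 * ((wavelength_grid - p$center[i]) / p$width[i])^2)
    }
    emission_line_shape(state, wavelength_grid, d)
  }
  list(monomer = mk(monomer_peaks, "monomer"),
       aggregate = mk(aggregate_peaks, "aggregate"))
}

#' Locate the crossing of the two line shapes
#'
#' Finds the wavelength(s) where g_A(lambda) = g_M(lambda) within a search
#' band, by sign change of the difference on the grid refined with linear
#' interpolation. At this wavelength the two-state model's lifetime
#' contrast between the solid and liquid phases is maximal.
#'
#' @param shapes List with `monomer` and `aggregate` line shapes (as from
#'   [make_line_shapes()]).
#' @param band Numeric length-2 search window in nm (default the 590-640 nm
#'   overlap band).
#' @return Numeric vector of crossing wavelengths in nm (possibly empty).
#' @export
line_shape_crossing <- function(shapes, band = c(590, 640)) {
  g <- shapes$monomer$wavelength_grid
  stopifnot(identical(g, shapes$aggregate$wavelength_grid))
  d <- shapes$aggregate$density - shapes$monomer$density
  in_band <- which(g >= band[1] & g <= band[2])
  if (length(in_band) < 2L) return(numeric(0))
  i <- in_band[which(diff(sign(d[in_band])) != 0)]
  if (!length(i)) return(numeric(0))
  g[i] - d[i] * (g[i + 1] - g[i]) / (d[i + 1] - d[i])
}
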