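#' Define a single absorption band
#'
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), positive.
#' @param height Peak absorbance, non-negative.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A one-row data frame describing the band.
#' @export
band <- function(center, fwhm, height, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("band fwhm must be positive", call. = FALSE)
  if (height < 0) stop("band height must be non-negative", call. = FALSE)
  data.frame(center = center, fwhm = fwhm, height = height, shape = shape,
             stringsAsFactors = FALSE)
}

#' Evaluate a parametric band list on a wavenumber grid
#'
#' Gaussian profile: `h * exp(-4 ln 2 ((v - c) / fwhm)^2)`; Lorentzian:
#' `h / (1 + (2 (v - c) / fwhm)^2)`. The spectrum is the sum of all bands.
#'
#' @param bands Data frame of bands (rows as returned by [band()], possibly
#'   `rbind`-ed) or an empty data frame for a zero spectrum.
#' @param grid Wavenumber grid (cm^-1).
#' @param label Label for the resulting spectrum.
#' @return An `ir_spectrum`.
#' @export
build_pure_spectrum <- function(bands, grid, label = "") {
  grid <- wn_grid(grid)
  a <- numeric(length(grid))
  if (NROW(bands)) {
    for (i in seq_len(nrow(bands))) {
      u <- (grid - bands$center[i]) / bands$fwhm[i]
      a <- a + switch(bands$shape[i],
                      gaussian = bands$height[i] * exp(-4 * log(2) * u^2),
                      lorentzian = bands$height[i] / (1 + (2 * u)^2),
                      stop("unknown band shape: ", bands$shape[i]))
    }
  }
  ir_spectrum(grid, a, label)
}

# Band lists for the synthetic pure components. Positions anchored to the
# named bands of the system (cellulose C-O backbone 1100-950, C-O-C ether
# 1160, CH bend 1370; amide I/II 1650/1550; acetate C=O/C-O 1742/1219;
# oxidized-cellulose carbonyl inside 1700-1600); widths and heights are
# emulation parameters and travel with the library object so tests read
# them from there, never from copies.
default_band_lists <- function() {
  g <- function(center, fwhm, height) band(center, fwhm, height, "gaussian")
  cellulose <- rbind(
    g(980, 40, 0.50), g(1035, 55, 1.00), g(1160, 28, 0.42),
    g(1315, 35, 0.18), g(1370, 26, 0.35), g(1430, 30, 0.12))
  acetate <- rbind(g(1742, 32, 0.65), g(1219, 30, 0.48))
  protein <- rbind(
    g(1650, 55, 1.00), g(1550, 48, 0.72), g(1450, 35, 0.12),
    g(1240, 50, 0.06))
  carbo <- cellulose$center >= 950 & cellulose$center <= 1100
  oxidized <- cellulose
  oxidized$height[carbo] <- oxidized$height[carbo] * 0.55
  oxidized <- rbind(oxidized, g(1620, 60, 0.50))
  wv_centers <- c(1340, 1362, 1387, 1419, 1456, 1473, 1508, 1540, 1559,
                  1576, 1617, 1636, 1653, 1684, 1700, 1717, 1740, 1772, 1790)
  wv_heights <- c(0.45, 0.60, 0.50, 0.65, 1.00, 0.55, 0.70, 0.50, 0.85,
                  0.60, 0.90, 0.50, 0.70, 0.40, 0.55, 0.65, 0.35, 0.50, 0.30)
  water_vapor <- do.call(rbind, Map(g, wv_centers, 3, wv_heights))
  list(cellulose = cellulose,
       cellulose_acetate = rbind(cellulose, acetate),
       oxidized_cellulose = oxidized,
       protein = protein,
       water_vapor = water_vapor)
}

#' Default pure-component spectral library
#'
#' Builds the five named components the scene generator mixes: `cellulose`
#' (strongest absorption in the 1100-950 cm^-1 carbohydrate region, ether
#' band at 1160 cm^-1, CH-bend anchor at 1370 cm^-1), `cellulose_acetate`
#' (cellulose plus acetate bands at 1742 and 1219 cm^-1),
#' `oxidized_cellulose` (carbohydrate bands attenuated, carbonyl band added
#' inside 1700-1600 cm^-1), `protein` (amide I/II at 1650/1550 cm^-1) and
#' `water_vapor` (narrow atmospheric lines confined to 1300-1800 cm^-1).
#' The generating band lists are attached to the returned object.
#'
#' @param grid Wavenumber grid spanning at least 900-1800 cm^-1.
#' @return A `component_library`: list with `components` (named
#'   `ir_spectrum` list), `bands` (the generating band lists) and `grid`.
#' @export
default_component_library <- function(grid = default_grid()) {
  grid <- wn_grid(grid)
  if (min(grid) > 900 || max(grid) < 1800)
    stop(sprintf("library grid must span at least 900-1800 cm-1 (got %g-%g)",
                 min(grid), max(grid)), call. = FALSE)
  bl <- default_band_lists()
  comps <- lapply(names(bl), function(nm)
    build_pure_spectrum(bl[[nm]], grid, label = nm))
  names(comps) <- names(bl)
  structure(list(components = comps, bands = bl, grid = grid),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %s on %d-point grid %.0f-%.0f cm-1\n",
              paste(names(x$components), collapse = ", "),
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Spectrum of a partially deacetylated cellulose film
#'
#' Linear interpolation between regenerated cellulose (`residual_fraction`
#' 0, the completed deacetylation end point whose acetate bands at 1742 and
#' 1219 cm^-1 have vanished) and intact cellulose acetate
#' (`residual_fraction` 1).
#'
#' @param library A `component_library`.
#' @param residual_fraction Remaining acetate fraction in `[0, 1]`.
#' @return An `ir_spectrum`.
#' @export
simulate_deacetylation <- function(library, residual_fraction) {
  stopifnot(inherits(library, "component_library"))
  if (!is.numeric(residual_fraction) || length(residual_fraction) != 1 ||
      residual_fraction < 0 || residual_fraction > 1)
    stop("residual_fraction must be a single value in [0, 1]", call. = FALSE)
  cel <- library$components$cellulose
  ca <- library$components$cellulose_acetate
  ir_spectrum(cel$wavenumber,
              cel$absorbance +
                residual_fraction * (ca$absorbance - cel$absorbance),
              label = sprintf("deacetylated (residual %.3g)", residual_fraction))
}
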