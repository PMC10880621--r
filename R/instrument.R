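#' Instrument modality configuration
#'
#' @param name `"conventional"` (diffraction-limited FTIR; the probed spot
#'   scales with the IR wavelength) or `"optir"` (photothermal readout; the
#'   probed spot is set by the fixed visible probe laser).
#' @param numerical_aperture Objective NA, in (0, 1).
#' @param pixel_size Detector pixel size (um).
#' @param n_coadded_scans Number of co-averaged scans per pixel.
#' @param probe_wavelength_nm Probe laser wavelength (nm); O-PTIR only.
#' @param noise_sd_single_scan Absorbance noise SD of a single scan.
#' @param baseline_drift_amplitude Maximum absolute baseline drift
#'   (absorbance units).
#' @param atmosphere_strength Scale of the water-vapor line contamination.
#' @param rng_seed Default seed for [simulate_measurement()].
#' @return A `modality_config`.
#' @export
modality_config <- function(name = c("conventional", "optir"),
                            numerical_aperture, pixel_size, n_coadded_scans,
                            probe_wavelength_nm = NA_real_,
                            noise_sd_single_scan = 0.02,
                            baseline_drift_amplitude = 0.04,
                            atmosphere_strength = 0.02,
                            rng_seed = 0L) {
  name <- match.arg(name)
  if (numerical_aperture <= 0 || numerical_aperture >= 1)
    stop("numerical_aperture must lie in (0, 1)", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (n_coadded_scans < 1) stop("n_coadded_scans must be >= 1", call. = FALSE)
  if (name == "optir" && !is.finite(probe_wavelength_nm))
    stop("optir modality requires probe_wavelength_nm", call. = FALSE)
  structure(list(name = name, numerical_aperture = numerical_aperture,
                 pixel_size = pixel_size,
                 n_coadded_scans = as.integer(n_coadded_scans),
                 probe_wavelength_nm = probe_wavelength_nm,
                 noise_sd_single_scan = noise_sd_single_scan,
                 baseline_drift_amplitude = baseline_drift_amplitude,
                 atmosphere_strength = atmosphere_strength,
                 rng_seed = as.integer(rng_seed)),
            class = "modality_config")
}

#' Built-in instrument presets
#'
#' `conventional`: NA 0.4 Cassegrain, 2.3 um pixels, 1024 co-added scans.
#' `optir`: NA 0.78, 532 nm probe laser, 0.5 um pixels, 3 co-added scans.
#' Noise, drift and atmosphere magnitudes are emulation parameters.
#'
#' @param name Preset name.
#' @return A `modality_config`.
#' @export
modality_preset <- function(name = c("conventional", "optir")) {
  name <- match.arg(name)
  if (name == "conventional")
    modality_config("conventional", numerical_aperture = 0.4,
                    pixel_size = 2.3, n_coadded_scans = 1024,
                    noise_sd_single_scan = 0.15)
  else
    modality_config("optir", numerical_aperture = 0.78, pixel_size = 0.5,
                    n_coadded_scans = 3, probe_wavelength_nm = 532,
                    noise_sd_single_scan = 0.015)
}

#' Rayleigh diffraction-limited resolution
#'
#' `0.61 * wavelength / NA`, returned in the unit of `wavelength`. With
#' NA 0.4 this gives 16.9 um at 900 cm^-1 (wavelength 10^4 / 900 um) and
#' 8.5 um at 1800 cm^-1; with NA 0.78 and a 532 nm probe it gives 416 nm.
#'
#' @param wavelength Wavelength (any length unit), positive.
#' @param numerical_aperture Objective NA, in (0, 1].
#' @return Resolution in the unit of `wavelength`.
#' @export
rayleigh_resolution <- function(wavelength, numerical_aperture) {
  if (any(wavelength <= 0)) stop("wavelength must be positive", call. = FALSE)
  if (numerical_aperture <= 0 || numerical_aperture > 1)
    stop("numerical_aperture must lie in (0, 1]", call. = FALSE)
  0.61 * wavelength / numerical_aperture
}

#' Point-spread-function width at a given wavenumber
#'
#' Conventional FTIR probes with the IR beam itself, so the spot follows
#' the Rayleigh limit at the IR wavelength and shrinks from 900 to
#' 1800 cm^-1; O-PTIR probes with the fixed green laser, so the width is
#' wavenumber independent.
#'
#' @param modality A `modality_config`.
#' @param wavenumber Wavenumber(s), cm^-1.
#' @return PSF width(s) in um (FWHM of the Gaussian emulation kernel).
#' @export
psf_width <- function(modality, wavenumber) {
  stopifnot(inherits(modality, "modality_config"))
  if (any(wavenumber <= 0)) stop("wavenumber must be positive", call. = FALSE)
  if (modality$name == "conventional") {
    rayleigh_resolution(1e4 / wavenumber, modality$numerical_aperture)
  } else {
    rep(rayleigh_resolution(modality$probe_wavelength_nm / 1000,
                            modality$numerical_aperture),
        length(wavenumber))
  }
}

# Gaussian blur of a matrix with reflecting boundaries, exact separable
# convolution via dense per-axis operators. sigma in um, step = grid
# spacing in um.
gaussian_blur_reflect <- function(mat, sigma_um, step_um) {
  if (sigma_um / step_um < 1e-6) return(mat)
  conv_op <- function(n) {
    s <- sigma_um / step_um
    half <- max(1L, ceiling(4 * s))
    offs <- -half:half
    k <- exp(-offs^2 / (2 * s^2))
    k <- k / sum(k)
    op <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + offs
      # reflect about the half-sample boundary: ... 2 1 | 1 2 ... n | n n-1
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > n, 2L * n + 1L - j, j)
      # a tail may fold more than once on very small images
      while (any(j < 1L | j > n)) {
        j <- ifelse(j < 1L, 1L - j, j)
        j <- ifelse(j > n, 2L * n + 1L - j, j)
      }
      for (m in seq_along(offs)) op[i, j[m]] <- op[i, j[m]] + k[m]
    }
    op
  }
  op_r <- conv_op(nrow(mat))
  op_c <- if (ncol(mat) == nrow(mat)) op_r else conv_op(ncol(mat))
  op_r %*% mat %*% t(op_c)
}

# Area-average a fine-grid matrix onto a coarse pixel grid: pixel (r, c)
# averages the fine samples whose centers fall inside it.
pixel_average <- function(mat, fine_step, pixel_size, n_r, n_c) {
  centers_r <- (seq_len(nrow(mat)) - 0.5) * fine_step
  centers_c <- (seq_len(ncol(mat)) - 0.5) * fine_step
  idx_r <- pmin(floor(centers_r / pixel_size) + 1L, n_r)
  idx_c <- pmin(floor(centers_c / pixel_size) + 1L, n_c)
  keep_r <- idx_r <= n_r & centers_r <= n_r * pixel_size
  keep_c <- idx_c <= n_c & centers_c <= n_c * pixel_size
  agg_op <- function(idx, n) {
    op <- matrix(0, n, length(idx))
    op[cbind(idx, seq_along(idx))] <- 1
    op / rowSums(op)
  }
  agg_op(idx_r[keep_r], n_r) %*% mat[keep_r, keep_c, drop = FALSE] %*%
    t(agg_op(idx_c[keep_c], n_c))
}

#' Simulate a hyperspectral measurement of a scene
#'
#' Per wavenumber, the ideal absorbance map (concentration maps mixed with
#' the library spectra) is convolved with an isotropic Gaussian PSF of FWHM
#' [psf_width()] (reflecting boundaries), area-integrated over the detector
#' pixels, and then corrupted per pixel with (a) a random smooth convex
#' polynomial baseline drift of amplitude up to
#' `baseline_drift_amplitude`, (b) the water-vapor line spectrum at
#' `atmosphere_strength` times a per-cube random scale, and (c) zero-mean
#' Gaussian noise with SD `noise_sd_single_scan / sqrt(n_coadded_scans)`.
#' Deterministic given `seed`. For the conventional modality the
#' wavenumber-dependent PSF width is quantized to `psf_levels` values
#' across the band and blurred maps are computed once per level.
#'
#' @param scene A `scene_definition`.
#' @param library A `component_library` covering `grid`.
#' @param modality A `modality_config`.
#' @param grid Acquisition wavenumber grid.
#' @param seed Integer seed; defaults to the modality's `rng_seed`.
#' @param psf_levels Number of quantized PSF widths for the
#'   wavenumber-dependent case.
#' @return A `hyper_cube` in the modality's pixel raster.
#' @export
simulate_measurement <- function(scene, library, modality,
                                 grid = default_grid(),
                                 seed = modality$rng_seed, psf_levels = 64L) {
  stopifnot(inherits(scene, "scene_definition"),
            inherits(library, "component_library"),
            inherits(modality, "modality_config"))
  grid <- wn_grid(grid)
  if (scene$fine_step > modality$pixel_size / 4)
    stop("configuration error: scene fine_step must be <= pixel_size / 4",
         call. = FALSE)
  set.seed(seed)

  n_r <- max(1L, floor(scene$extent[2] / modality$pixel_size + 1e-9))
  n_c <- max(1L, floor(scene$extent[1] / modality$pixel_size + 1e-9))
  comp_names <- names(scene$maps)
  L <- vapply(comp_names, function(nm)
    resample_to_grid(library$components[[nm]], grid)$absorbance,
    numeric(length(grid)))

  fwhm <- psf_width(modality, grid)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  n_wn <- length(grid)
  arr <- array(0, c(n_r, n_c, n_wn))
  if (max(sig) - min(sig) < 1e-12) {
    # constant PSF (O-PTIR or degenerate): one blur per component
    for (ci in seq_along(comp_names)) {
      b <- pixel_average(
        gaussian_blur_reflect(scene$maps[[ci]], sig[1], scene$fine_step),
        scene$fine_step, modality$pixel_size, n_r, n_c)
      arr <- arr + outer(b, L[, ci])
    }
  } else {
    sig_lev <- seq(min(sig), max(sig), length.out = psf_levels)
    assign_lev <- round(stats::approx(range(sig), c(1, psf_levels),
                                      xout = sig)$y)
    for (ci in seq_along(comp_names)) {
      for (lv in sort(unique(assign_lev))) {
        idx <- which(assign_lev == lv)
        b <- pixel_average(
          gaussian_blur_reflect(scene$maps[[ci]], sig_lev[lv],
                                scene$fine_step),
          scene$fine_step, modality$pixel_size, n_r, n_c)
        arr[, , idx] <- arr[, , idx] +
          outer(b, L[idx, ci], FUN = "*")
      }
    }
  }

  n_pix <- n_r * n_c
  u <- (grid - min(grid)) / diff(range(grid))
  # convex quadratic drift per pixel, scaled to a random amplitude
  a2 <- runif(n_pix, 0, 1); a1 <- runif(n_pix, -1, 1); a0 <- runif(n_pix, -0.3, 0.3)
  drift <- outer(a0, rep(1, n_wn)) + outer(a1, u) + outer(a2, u^2)
  amp <- runif(n_pix, 0, modality$baseline_drift_amplitude)
  drift <- drift * (amp / pmax(apply(abs(drift), 1, max), 1e-12))
  atm_scale <- runif(1, 0.5, 1.5) * modality$atmosphere_strength
  wv <- resample_to_grid(library$components$water_vapor, grid)$absorbance
  noise_sd <- modality$noise_sd_single_scan / sqrt(modality$n_coadded_scans)
  noise <- matrix(rnorm(n_pix * n_wn, 0, noise_sd), n_pix, n_wn)
  extra <- drift + outer(rep(atm_scale, n_pix), wv) + noise
  arr <- arr + array(extra, c(n_r, n_c, n_wn))

  hyper_cube(arr, grid, modality$pixel_size,
             if (modality$name == "conventional") "conventional" else "optir",
             provenance = sprintf(
               paste0("step=simulate_measurement;modality=%s;seed=%d;",
                      "na=%g;pixel=%g;scans=%d;noise_sd=%g;drift=%g;",
                      "atmosphere=%g;substrate=%s"),
               modality$name, as.integer(seed), modality$numerical_aperture,
               modality$pixel_size, modality$n_coadded_scans,
               modality$noise_sd_single_scan,
               modality$baseline_drift_amplitude,
               modality$atmosphere_strength, scene$substrate))
}

#' Noise-free atmospheric reference spectrum
#'
#' The unit-scale water-vapor line spectrum on the given grid — the
#' "blank" measurement consumed by [correct_atmosphere()]. Identical
#' across seeds by construction.
#'
#' @param modality A `modality_config` (present for interface symmetry; the
#'   reference does not depend on it).
#' @param grid Wavenumber grid.
#' @param library Component library supplying the water-vapor lines.
#' @return An `ir_spectrum`.
#' @export
simulate_atmospheric_reference <- function(modality, grid = default_grid(),
                                           library =
                                             default_component_library(grid)) {
  grid <- wn_grid(grid)
  resample_to_grid(library$components$water_vapor, grid)
}
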