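test_that("psf width tracks the IR wavelength only for conventional optics", {
  conv <- modality_preset("conventional")
  opt <- modality_preset("optir")
  # conventional: width ratio across one octave is exactly the wavelength ratio
  expect_equal(psf_width(conv, 900) / psf_width(conv, 1800), 2)
  # optir: constant, set by the probe laser
  expect_equal(psf_width(opt, 900), psf_width(opt, 1800))
  expect_equal(psf_width(opt, 1200), 0.61 * 0.532 / 0.78)
  expect_error(rayleigh_resolution(-1, 0.4), "positive")
  expect_error(rayleigh_resolution(10, 1.4), "numerical_aperture")
  expect_error(psf_width(conv, -5), "positive")
})

test_that("simulation reduces to the ideal pixel-averaged map in the degenerate limit", {
  sc <- build_scene(extent = c(8, 8), fine_step = 0.1,
                    hypha_midline = rbind(c(4, 2.5), c(4, 5.5)),
                    hypha_width = 2, halo_extent = 1)
  lib <- default_component_library()
  md <- modality_config("optir", 0.78, pixel_size = 0.4, n_coadded_scans = 1,
                        probe_wavelength_nm = 1e-6, noise_sd_single_scan = 0,
                        baseline_drift_amplitude = 0, atmosphere_strength = 0)
  cube <- simulate_measurement(sc, lib, md, default_grid(), seed = 3)
  # oracle: average each 4x4 fine block, mix with the library spectra
  ideal <- array(0, dim(cube$data))
  for (nm in names(sc$maps)) {
    m <- sc$maps[[nm]]
    coarse <- matrix(0, 20, 20)
    for (r in 1:20) for (c in 1:20)
      coarse[r, c] <- mean(m[(4 * r - 3):(4 * r), (4 * c - 3):(4 * c)])
    spec <- resample_to_grid(lib$components[[nm]], cube$wavenumber)$absorbance
    ideal <- ideal + outer(coarse, spec)
  }
  expect_equal(cube$data, ideal, tolerance = 1e-12)
})

test_that("simulation is deterministic given the seed", {
  sc <- build_scene(extent = c(8, 8), fine_step = 0.2,
                    hypha_midline = rbind(c(4, 2.5), c(4, 5.5)),
                    hypha_width = 2, halo_extent = 1)
  lib <- default_component_library()
  md <- modality_preset("optir")
  md$pixel_size <- 1
  c1 <- simulate_measurement(sc, lib, md, default_grid(), seed = 42)
  c2 <- simulate_measurement(sc, lib, md, default_grid(), seed = 42)
  expect_identical(c1$data, c2$data)
  c3 <- simulate_measurement(sc, lib, md, default_grid(), seed = 43)
  expect_false(identical(c1$data, c3$data))
  expect_error(simulate_measurement(
    build_scene(extent = c(8, 8), fine_step = 0.25,
                hypha_midline = rbind(c(4, 2.5), c(4, 5.5)),
                hypha_width = 2, halo_extent = 1),
    lib, modality_preset("optir"), default_grid()),
    "configuration error")
})

test_that("noise averages down as one over the square root of scan count", {
  sc <- build_scene(extent = c(8, 8), fine_step = 0.2,
                    hypha_midline = rbind(c(4, 2.5), c(4, 5.5)),
                    hypha_width = 2, halo_extent = 1)
  lib <- default_component_library()
  clean_md <- modality_config("optir", 0.78, 0.8, 1, 532,
                              noise_sd_single_scan = 0,
                              baseline_drift_amplitude = 0,
                              atmosphere_strength = 0)
  clean <- simulate_measurement(sc, lib, clean_md, default_grid(), seed = 1)
  for (n in c(1, 4, 16, 64)) {
    md <- modality_config("optir", 0.78, 0.8, n, 532,
                          noise_sd_single_scan = 0.05,
                          baseline_drift_amplitude = 0,
                          atmosphere_strength = 0)
    cb <- simulate_measurement(sc, lib, md, default_grid(), seed = n + 100)
    ratio <- stats::sd(cb$data - clean$data) * sqrt(n) / 0.05
    expect_lt(abs(ratio - 1), 0.2)
  }
})

test_that("psf blur conserves the spatial mean and inflates stripe widths", {
  p <- preset_scene("fig3_optir")
  m <- p$scene$maps$cellulose
  b <- hyphir:::gaussian_blur_reflect(m, 1.0, p$scene$fine_step)
  expect_equal(mean(b), mean(m), tolerance = 1e-9)
  expect_equal(dim(b), dim(m))

  # apparent above-half-max width of the amide stripe, per modality
  stripe_width <- function(cube) {
    w <- which.min(abs(cube$wavenumber - 1650))
    prof <- cube$data[, round(dim(cube$data)[2] / 2), w]
    prof <- prof - min(prof)
    sum(prof >= max(prof) / 2) * cube$pixel_size
  }
  lib <- default_component_library(wn_grid(seq(800, 1900, 2)))
  truth <- stripe_width(scene_to_cube(p$scene, lib, seq(800, 1900, 2)))
  optir <- stripe_width(pipeline_run("fig3_optir", 1)$gen$cube)
  conv <- stripe_width(pipeline_run("fig2_conventional", 1)$gen$cube)
  expect_equal(truth, 4.6, tolerance = 0.15)
  expect_gte(optir, truth)
  expect_gt(conv, optir)
})

test_that("the atmospheric reference is noise-free, narrow and confined", {
  grid <- default_grid()
  ref1 <- simulate_atmospheric_reference(modality_preset("optir"), grid)
  ref2 <- simulate_atmospheric_reference(modality_preset("conventional"), grid)
  expect_identical(ref1$absorbance, ref2$absorbance)  # independent of seed/modality
  expect_lt(max(ref1$absorbance[grid <= 1300]), 1e-12)
  pk <- detect_peaks(ref1, min_height = 0.2, window = 4)
  expect_gt(nrow(pk), 5)
  expect_true(all(pk$center >= 1300 & pk$center <= 1800))
})
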