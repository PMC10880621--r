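test_that("atmosphere correction recovers known gas coefficients", {
  grid <- default_grid()
  lib <- default_component_library(grid)
  wv <- lib$components$water_vapor
  smooth <- build_pure_spectrum(band(1200, 120, 0.8), grid)
  mixed <- ir_spectrum(grid, smooth$absorbance + 0.37 * wv$absorbance)
  corr <- correct_atmosphere(mixed, list(wv))
  expect_equal(attr(corr, "coefficients"), 0.37, tolerance = 0.02)
  expect_lt(max(abs(corr$absorbance - smooth$absorbance)),
            0.02 * max(smooth$absorbance))

  # nothing to remove: near-identity
  corr2 <- correct_atmosphere(smooth, list(wv))
  expect_lt(max(abs(corr2$absorbance - smooth$absorbance)),
            0.01 * max(smooth$absorbance))
  # no references: exact identity
  expect_equal(correct_atmosphere(mixed, list())$absorbance, mixed$absorbance)
  zero_ref <- ir_spectrum(grid, ifelse(grid < 1200, 1, 0))
  expect_error(correct_atmosphere(mixed, list(zero_ref), c(1300, 1800)),
               "degenerate reference")
})

test_that("atmosphere coefficient recovery holds across magnitudes", {
  grid <- default_grid()
  lib <- default_component_library(grid)
  wv <- lib$components$water_vapor
  sample_bands <- rbind(band(1100, 150, 0.7), band(1650, 80, 0.3))
  smooth <- build_pure_spectrum(sample_bands, grid)
  set.seed(21)
  for (i in 1:100) {
    cc <- runif(1, 0.05, 2)
    y <- ir_spectrum(grid, smooth$absorbance + cc * wv$absorbance)
    chat <- attr(correct_atmosphere(y, list(wv)), "coefficients")
    expect_lt(abs(chat - cc) / cc, 0.05)
  }
})

test_that("cropping keeps the closed interval", {
  grid <- seq(850, 1850, by = 2)
  s <- ir_spectrum(grid, seq_along(grid))
  cs <- crop(s, 900, 1800)
  expect_equal(min(cs$wavenumber), 900)
  expect_equal(max(cs$wavenumber), 1800)
  expect_equal(crop(s, 850, 1850)$absorbance, s$absorbance)
  expect_error(crop(s, 1900, 2000), "range error")

  cube <- hyper_cube(array(1, c(2, 2, length(grid))), grid, 1, "optir")
  cc <- crop(cube, 900, 1800)
  expect_equal(range(cc$wavenumber), c(900, 1800))
  expect_match(tail(cc$provenance, 1), "step=crop")
})

test_that("rubberband equals the brute-force hull oracle and is idempotent", {
  grid <- wn_grid(seq(900, 1800, length.out = 64))
  # affine spectra are their own baseline
  aff <- ir_spectrum(grid, 0.3 + 0.001 * grid)
  rb <- rubberband_baseline(aff)
  expect_equal(rb$corrected$absorbance, numeric(64))

  # gaussian peak + convex drift: corrected matches the pure peak away
  # from the endpoints
  peak <- build_pure_spectrum(band(1350, 60, 1), grid)
  drift <- 0.5 * ((grid - 900) / 900)^2 + 0.1
  rb <- rubberband_baseline(ir_spectrum(grid, peak$absorbance + drift))
  inner <- grid > 1000 & grid < 1700
  expect_lt(max(abs(rb$corrected$absorbance[inner] -
                      peak$absorbance[inner])), 0.02)

  set.seed(31)
  for (i in 1:200) {
    n <- sample(8:64, 1)
    x <- sort(runif(n, 900, 1800))
    x <- x + seq_len(n) * 1e-6           # ensure strict monotonicity
    y <- runif(n) + cumsum(rnorm(n, 0, 0.2))
    s <- ir_spectrum(x, y)
    rb <- rubberband_baseline(s)
    expect_equal(rb$baseline$absorbance, oracle_lower_hull(x, y),
                 tolerance = 1e-9)
    expect_gte(min(rb$corrected$absorbance), 0)
    again <- rubberband_baseline(rb$corrected)
    expect_equal(again$corrected$absorbance, rb$corrected$absorbance,
                 tolerance = 1e-9)
  }
})

test_that("normalization divides by the anchor-window maximum", {
  grid <- default_grid()
  s <- build_pure_spectrum(rbind(band(1370, 26, 2), band(1035, 55, 5)), grid)
  n1 <- normalize_to_peak(s)
  idx <- grid >= 1355 & grid <= 1385
  expect_equal(max(n1$absorbance[idx]), 1)
  expect_equal(n1$absorbance, s$absorbance / max(s$absorbance[idx]))
  expect_equal(normalize_to_peak(n1)$absorbance, n1$absorbance)  # idempotent
  expect_error(normalize_to_peak(ir_spectrum(grid, numeric(length(grid)))),
               "normalization error")
})

test_that("the cube pipeline applies steps in order with masking", {
  run <- pipeline_run("fig3_optir", 1)
  pre <- run$res$preprocessed
  grid <- pre$wavenumber
  expect_equal(range(grid), c(900, 1800))
  idx <- grid >= 1355 & grid <= 1385
  anchor_max <- apply(pre$data, c(1, 2), function(v) max(v[idx]))
  expect_equal(max(abs(anchor_max[!pre$mask] - 1)), 0)

  # empty step list is the identity
  cube <- run$gen$cube
  same <- preprocess_cube(cube, preprocess_config(steps = character()))
  expect_equal(same$data, cube$data)

  # scale invariance of rubberband + normalize
  cfg <- preprocess_config(steps = c("rubberband", "normalize"))
  small <- hyper_cube(cube$data[1:3, 1:3, , drop = FALSE], cube$wavenumber,
                      cube$pixel_size, cube$modality)
  scaled <- small
  scaled$data <- small$data * 7.3
  expect_equal(preprocess_cube(scaled, cfg)$data,
               preprocess_cube(small, cfg)$data, tolerance = 1e-12)

  # rubberband on a cube is idempotent
  cfg_rb <- preprocess_config(steps = "rubberband")
  once <- preprocess_cube(small, cfg_rb)
  twice <- preprocess_cube(once, cfg_rb)
  expect_equal(twice$data, once$data, tolerance = 1e-9)
})

test_that("peak detection finds the named bands and clears removed ones", {
  lib <- default_component_library()
  pk <- detect_peaks(lib$components$protein)
  expect_equal(sort(pk$center[1:2]), c(1550, 1650), tolerance = 2e-3)

  regen <- simulate_deacetylation(lib, 0)
  pk <- detect_peaks(regen, min_height = 0.02)
  expect_false(any(abs(pk$center - 1742) <= 10 &
                     pk$height > 0.02 * max(regen$absorbance)))
  flat <- ir_spectrum(default_grid(), numeric(451))
  expect_equal(nrow(detect_peaks(flat)), 0)
})
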