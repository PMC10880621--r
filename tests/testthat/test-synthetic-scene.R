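test_that("band profiles follow their definitions", {
  grid <- wn_grid(seq(1000, 1200, by = 0.5))
  b <- band(1100, 20, 0.8)
  s <- build_pure_spectrum(b, grid)
  expect_equal(s$absorbance[grid == 1100], 0.8)
  expect_equal(s$absorbance[grid == 1090], 0.4, tolerance = 1e-6)
  expect_equal(s$absorbance[grid == 1110], 0.4, tolerance = 1e-6)
  lor <- build_pure_spectrum(band(1100, 20, 0.8, "lorentzian"), grid)
  expect_equal(lor$absorbance[grid == 1110], 0.4, tolerance = 1e-6)

  expect_equal(build_pure_spectrum(data.frame(), grid)$absorbance,
               numeric(length(grid)))
  b2 <- band(1180, 6, 0.3)
  sum12 <- build_pure_spectrum(rbind(b, b2), grid)
  expect_equal(sum12$absorbance,
               s$absorbance + build_pure_spectrum(b2, grid)$absorbance)
  expect_error(band(1100, -1, 1), "fwhm")
})

test_that("the default library satisfies the spectral invariants", {
  lib <- default_component_library(default_grid())
  for (comp in lib$components) expect_gte(min(comp$absorbance), 0)

  grid <- lib$grid
  cel <- lib$components$cellulose
  pk <- detect_peaks(cel, min_height = 0.02)
  expect_true(any(abs(pk$center - 1370) <= 2))
  expect_true(any(abs(pk$center - 1160) <= 2))
  strongest <- grid[which.max(cel$absorbance)]
  expect_true(strongest >= 950 && strongest <= 1100)

  prot <- lib$components$protein
  pk <- detect_peaks(prot)
  expect_equal(sort(pk$center[1:2]), c(1550, 1650), tolerance = 2e-3)
  low <- prot$absorbance[grid >= 950 & grid <= 1200]
  expect_lt(max(low), 0.05 * max(prot$absorbance))

  excess <- ir_spectrum(grid, lib$components$cellulose_acetate$absorbance -
                          cel$absorbance)
  pk <- detect_peaks(excess)
  expect_equal(sort(pk$center[1:2]), c(1219, 1742), tolerance = 2e-3)

  ox <- lib$components$oxidized_cellulose
  carb <- grid >= 950 & grid <= 1100
  expect_true(all(ox$absorbance[carb] <= cel$absorbance[carb] + 1e-12))
  added <- ox$absorbance - 0.55 * cel$absorbance  # carbonyl region excess
  co_peak <- grid[which.max(ifelse(grid >= 1600 & grid <= 1700, added, -Inf))]
  expect_true(co_peak >= 1600 && co_peak <= 1700)

  wv <- lib$components$water_vapor
  expect_lt(max(wv$absorbance[grid <= 1300]), 1e-12)
  expect_true(all(lib$bands$water_vapor$fwhm <= 4))
  expect_true(all(lib$bands$water_vapor$center >= 1300 &
                    lib$bands$water_vapor$center <= 1800))
  expect_error(default_component_library(seq(1000, 1700, by = 2)), "span")
})

test_that("deacetylation interpolates between cellulose and acetate", {
  lib <- default_component_library()
  expect_equal(simulate_deacetylation(lib, 0)$absorbance,
               lib$components$cellulose$absorbance)
  expect_equal(simulate_deacetylation(lib, 1)$absorbance,
               lib$components$cellulose_acetate$absorbance)
  half <- simulate_deacetylation(lib, 0.5)
  excess_at <- function(s, wn) {
    i <- which.min(abs(lib$grid - wn))
    s$absorbance[i] - lib$components$cellulose$absorbance[i]
  }
  expect_equal(excess_at(half, 1742),
               excess_at(lib$components$cellulose_acetate, 1742) / 2)
  expect_error(simulate_deacetylation(lib, 1.2), "\\[0, 1\\]")
})

test_that("scene maps follow the geometry and the linear oxidation law", {
  sc <- build_scene(extent = c(30, 20), fine_step = 0.1,
                    hypha_midline = rbind(c(10, 10), c(20, 10)),
                    hypha_width = 4, halo_extent = 5, oxidation_max = 0.6)
  ox_frac <- sc$maps$oxidized_cellulose /
    (sc$maps$cellulose + sc$maps$oxidized_cellulose)
  at <- function(x, y) {
    c_idx <- round(x / 0.1 + 0.5); r_idx <- round(y / 0.1 + 0.5)
    list(ox = ox_frac[r_idx, c_idx], hypha = sc$maps$protein[r_idx, c_idx] > 0)
  }
  # oxidation degree: max at the hyphal edge (and under the hypha),
  # linear decline, 0 at and beyond the halo end
  expect_equal(at(15, 10)$ox, 0.6)
  expect_equal(at(15, 10 + 2.05)$ox, 0.6 * (1 - 0.05 / 5), tolerance = 1e-9)
  expect_equal(at(15, 10 + 2 + 5)$ox, 0, tolerance = 0.01)
  expect_equal(at(15, 10 + 2 + 7)$ox, 0)
  # partway through the halo the degree follows the linear law exactly
  expect_equal(at(15, 10 + 2 + 2.55)$ox, 0.6 * (1 - 2.55 / 5),
               tolerance = 1e-9)
  expect_true(at(15, 10)$hypha)
  expect_false(at(15, 10 + 2 + 0.15)$hypha)
  # closure outside the hypha
  closure <- sc$maps$cellulose + sc$maps$oxidized_cellulose
  expect_equal(max(abs(closure[sc$maps$protein == 0] - 1)), 0)
  # linearity in protein density; determinism
  sc2 <- build_scene(extent = c(30, 20), fine_step = 0.1,
                     hypha_midline = rbind(c(10, 10), c(20, 10)),
                     hypha_width = 4, halo_extent = 5, oxidation_max = 0.6,
                     protein_density = 2)
  expect_equal(sc2$maps$protein, 2 * sc$maps$protein)
  expect_identical(sc$maps, build_scene(extent = c(30, 20), fine_step = 0.1,
                                        hypha_midline = rbind(c(10, 10),
                                                              c(20, 10)),
                                        hypha_width = 4, halo_extent = 5,
                                        oxidation_max = 0.6)$maps)
  expect_error(build_scene(extent = c(12, 12),
                           hypha_midline = rbind(c(4, 6), c(8, 6)),
                           hypha_width = 4.6, halo_extent = 6.3),
               "geometry error")
})

test_that("presets pin the study geometry", {
  p3 <- preset_scene("fig3_optir")
  expect_equal(p3$scene$hypha_width, 4.6)
  expect_equal(p3$scene$halo_extent, 6.3)
  expect_equal(p3$modality$pixel_size, 0.5)
  p2 <- preset_scene("fig2_conventional")
  expect_identical(p2$scene$maps, p3$scene$maps)  # one shared ground truth
  expect_equal(p2$modality$pixel_size, 2.3)
  p5 <- preset_scene("fig5_gold")
  expect_equal(max(p5$scene$maps$cellulose), 0)
  expect_equal(max(p5$scene$maps$oxidized_cellulose), 0)
  expect_error(preset_scene("fig9"), "unknown preset")
})
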