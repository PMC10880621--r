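test_that("radial cuts fan out from the hyphal tip", {
  cmap <- painted_cluster_map()
  one <- make_radial_cuts(cmap, n_cuts = 1, fan = 0)
  # single ray along the outward principal-axis direction (stripe is
  # horizontal, so the axis is the x direction)
  expect_equal(abs(one$rays[[1]]$dir[1]), 1, tolerance = 1e-9)

  five <- make_radial_cuts(cmap, n_cuts = 5, fan = 90)
  spacing <- diff(sort(five$angles)) * 180 / pi
  expect_equal(spacing, rep(22.5, 4))

  far <- make_radial_cuts(cmap, n_cuts = 1, fan = 0, max_length = 500)
  expect_true(far$rays[[1]]$clipped)
  expect_lt(far$rays[[1]]$length, 500)
  expect_error(make_radial_cuts(cmap, origin = c(0.2, 0.2)),
               "geometry error")
})

test_that("pixel selection near cuts is exact and monotone in halfwidth", {
  cmap <- painted_cluster_map(pixel_size = 1)
  grid <- default_grid()
  cube <- hyper_cube(array(1, c(41, 30, length(grid))), grid, 1, "optir")
  cuts <- make_radial_cuts(cmap, n_cuts = 1, fan = 0, max_length = 6)
  # force a vertical ray from a known origin for a painted-geometry check
  cuts$origin <- c(10.5, 21.5)
  cuts$rays <- list(list(dir = c(0, 1), length = 6, clipped = FALSE))
  sel <- select_pixels_near_cuts(cuts, cube, cmap, halfwidth = 0.5)
  # exactly the pixel column under the ray, rows spanned by the segment
  expect_true(all(sel$selected_pixels$col == 11))
  expect_equal(sort(sel$selected_pixels$row), 22:28)

  wider <- select_pixels_near_cuts(cuts, cube, cmap, halfwidth = 1)
  key <- function(d) paste(d$row, d$col)
  expect_true(all(key(sel$selected_pixels) %in% key(wider$selected_pixels)))

  run <- pipeline_run("fig3_optir", 1)
  n_sel <- nrow(run$res$cuts$selected_pixels)
  expect_gte(n_sel, 200)
  expect_lte(n_sel, 500)
})

test_that("two-component profiles recover exact linear gradients", {
  grid <- default_grid()
  A <- build_pure_spectrum(band(1035, 55, 1), grid)$absorbance
  B <- build_pure_spectrum(band(1620, 60, 1), grid)$absorbance
  n <- 60
  t <- seq(0, 1, length.out = n)
  arr <- array(0, c(n, 1, length(grid)))
  for (i in 1:n) arr[i, 1, ] <- (1 - t[i]) * A + t[i] * B
  cube <- hyper_cube(arr, grid, 0.5, "optir")
  cuts <- structure(list(origin = c(0.25, 0.25),
                         rays = list(list(dir = c(0, 1), length = 30,
                                          clipped = FALSE)),
                         midline = rbind(c(0.25, 0), c(0.25, 0.1)),
                         pixel_size = 0.5, selection_halfwidth = 0.5,
                         selected_pixels = data.frame(
                           row = 1:n, col = 1,
                           distance_um = (1:n - 0.5) * 0.5)),
                    class = "radial_cuts")
  prof <- two_component_profile(cube, cuts)
  # the carbonyl-rich component is tagged as the decomposition signature
  dec <- prof$contributions[, prof$decomposition_component]
  fit <- suppressWarnings(summary(stats::lm(dec ~ prof$distances)))
  expect_gte(fit$r.squared, 0.999)
  # the decomposition signature grows along this constructed gradient
  expect_gt(stats::coef(fit)[2, 1], 0)
})

test_that("lowess reproduces lines and resists noise", {
  grid_prof <- function(x, y) {
    structure(list(distances = x, contributions = cbind(y, y),
                   components = NULL, decomposition_component = 1,
                   result = NULL, trend = NULL), class = "gradient_profile")
  }
  x <- seq(0, 10, length.out = 50)
  p <- lowess_trend(grid_prof(x, 2 + 3 * x), frac = 0.5)
  expect_equal(p$trend$values[, 1], 2 + 3 * p$trend$distance,
               tolerance = 1e-6)
  expect_error(lowess_trend(grid_prof(x, x), frac = 1.5), "frac")

  set.seed(51)
  xs <- runif(200, 0, 10)
  ys <- 5 + rnorm(200, 0, 0.3)
  p2 <- lowess_trend(grid_prof(xs, ys), frac = 0.5)
  se <- 0.3 / sqrt(200 * 0.5)
  expect_lt(max(abs(p2$trend$values[, 1] - 5)), 3 * se * 3)
})

test_that("zone linearity separates the ramp from the plateau", {
  # exact piecewise-linear construction
  x <- seq(0, 12, by = 0.25)
  ramp <- ifelse(x <= 2.3, 1, ifelse(x <= 8.6, 1 - (x - 2.3) / 6.3, 0))
  prof <- structure(list(distances = x, contributions = cbind(ramp, 1 - ramp),
                         components = NULL, decomposition_component = 1,
                         result = NULL, trend = NULL),
                    class = "gradient_profile")
  fit <- zone_linearity(prof, hypha_width = 4.6, halo_extent = 6.3)
  expect_equal(fit$r2_in, 1)
  expect_equal(fit$slope_out, 0)
  expect_equal(fit$slope_in, -1 / 6.3)

  # permutation control destroys the in-zone fit
  set.seed(52)
  shuffled <- prof
  shuffled$distances <- sample(prof$distances)
  fit_s <- zone_linearity(shuffled, 4.6, 6.3)
  expect_lt(fit_s$r2_in, 0.3)

  # preset run, with the generator's zone boundaries isolating the
  # gradient chemistry from segmentation bias
  run <- pipeline_run("fig3_optir", 1)
  fit3 <- zone_linearity(run$res$profile, 4.6, 6.3)
  expect_gte(fit3$r2_in, 0.8)
  expect_lte(abs(fit3$slope_out), 0.2 * abs(fit3$slope_in))
})
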