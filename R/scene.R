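#' Build a ground-truth scene of a hypha on a substrate
#'
#' Lays out per-component concentration maps on a fine spatial grid. The
#' hypha is the set of points within `hypha_width / 2` of the midline
#' segment; it contains protein at `protein_density` and transmits only a
#' fraction `1 - hypha_opacity` of the underlying film signal. Around the
#' hypha, the film's degree of oxidation is `oxidation_max` at the hyphal
#' edge, declines linearly to zero at `halo_extent` from the edge, and is
#' zero beyond — the piecewise-linear law the downstream gradient analysis
#' assumes. Outside the hypha the cellulose and oxidized-cellulose
#' fractions sum to one (closure); on bare gold there is no film at all.
#'
#' @param extent Scene size `c(width_um, height_um)`.
#' @param fine_step Ground-truth grid spacing (um), at most 0.25.
#' @param hypha_midline 2 x 2 matrix, rows are the segment endpoints
#'   `(x_um, y_um)`.
#' @param hypha_width Hyphal width (um).
#' @param halo_extent Decomposition-zone extent from the hyphal edge (um).
#' @param oxidation_max Degree of oxidation at the hyphal edge, in `[0, 1]`.
#' @param protein_density Relative protein concentration inside the hypha.
#' @param substrate `"cellulose_film"` or `"bare_gold"`.
#' @param hypha_opacity Fraction of film signal suppressed beneath the
#'   hypha, in `[0, 1]`.
#' @return A `scene_definition` with fields as above plus `maps`, a named
#'   list of fine-grid concentration matrices (`cellulose`,
#'   `oxidized_cellulose`, `protein`).
#' @export
build_scene <- function(extent = c(40, 25), fine_step = 0.1,
                        hypha_midline = rbind(c(10, 12.5), c(28, 12.5)),
                        hypha_width = 4.6, halo_extent = 6.3,
                        oxidation_max = 0.6, protein_density = 1,
                        substrate = c("cellulose_film", "bare_gold"),
                        hypha_opacity = 0.7) {
  substrate <- match.arg(substrate)
  if (fine_step > 0.25)
    stop("fine_step must be <= 0.25 um to resolve the instrument PSFs",
         call. = FALSE)
  if (oxidation_max < 0 || oxidation_max > 1)
    stop("oxidation_max must lie in [0, 1]", call. = FALSE)
  hypha_midline <- rbind(hypha_midline)
  stopifnot(nrow(hypha_midline) == 2, ncol(hypha_midline) == 2)
  margin <- hypha_width / 2 + halo_extent
  if (any(hypha_midline[, 1] - margin < 0) ||
      any(hypha_midline[, 1] + margin > extent[1]) ||
      any(hypha_midline[, 2] - margin < 0) ||
      any(hypha_midline[, 2] + margin > extent[2]))
    stop("geometry error: hypha plus halo extends beyond the scene extent",
         call. = FALSE)

  nr <- round(extent[2] / fine_step)
  nc <- round(extent[1] / fine_step)
  x <- (seq_len(nc) - 0.5) * fine_step
  y <- (seq_len(nr) - 0.5) * fine_step
  dist <- dist_to_segment(matrix(x[col(matrix(0, nr, nc))], nr, nc),
                          matrix(y[row(matrix(0, nr, nc))], nr, nc),
                          hypha_midline)

  hypha <- dist <= hypha_width / 2
  edge_dist <- pmax(dist - hypha_width / 2, 0)
  if (halo_extent > 0) {
    degree <- oxidation_max * pmax(0, 1 - edge_dist / halo_extent)
  } else {
    degree <- ifelse(hypha, oxidation_max, 0)
  }
  film <- if (substrate == "cellulose_film")
    ifelse(hypha, 1 - hypha_opacity, 1) else matrix(0, nr, nc)

  maps <- list(cellulose = film * (1 - degree),
               oxidized_cellulose = film * degree,
               protein = protein_density * hypha)
  structure(list(extent = extent, fine_step = fine_step,
                 hypha_midline = hypha_midline, hypha_width = hypha_width,
                 halo_extent = halo_extent, oxidation_max = oxidation_max,
                 protein_density = protein_density, substrate = substrate,
                 hypha_opacity = hypha_opacity, maps = maps),
            class = "scene_definition")
}

# Euclidean distance from points (xm, ym) (matrices) to a segment given as
# a 2 x 2 matrix of endpoints.
dist_to_segment <- function(xm, ym, seg) {
  p1 <- seg[1, ]; p2 <- seg[2, ]
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 == 0) return(sqrt((xm - p1[1])^2 + (ym - p1[2])^2))
  t <- ((xm - p1[1]) * v[1] + (ym - p1[2]) * v[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((xm - (p1[1] + t * v[1]))^2 + (ym - (p1[2] + t * v[2]))^2)
}

#' @export
print.scene_definition <- function(x, ...) {
  cat(sprintf(paste0("<scene_definition> %s, %.0f x %.0f um at %.3g um, ",
                     "hypha %.2g um wide, halo %.2g um, oxidation max %.2g\n"),
              x$substrate, x$extent[1], x$extent[2], x$fine_step,
              x$hypha_width, x$halo_extent, x$oxidation_max))
  invisible(x)
}

#' Named scene presets paired with an instrument modality
#'
#' `fig2_conventional` and `fig3_optir` share a single scene — a 4.6 um
#' hypha with a 6.3 um decomposition halo on a regenerated cellulose film
#' in a 40 x 25 um field — measured through the conventional FTIR and the
#' O-PTIR modality respectively, so the two modalities can be contrasted on
#' identical ground truth. `fig5_gold` is a hypha on bare gold (no film)
#' under O-PTIR.
#'
#' @param name Preset name.
#' @return List with elements `scene` (a `scene_definition`) and `modality`
#'   (a `modality_config`).
#' @export
preset_scene <- function(name = c("fig2_conventional", "fig3_optir",
                                  "fig5_gold")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown preset: ", name[1],
                                            call. = FALSE))
  if (name %in% c("fig2_conventional", "fig3_optir")) {
    scene <- build_scene()
    modality <- modality_preset(
      if (name == "fig2_conventional") "conventional" else "optir")
  } else {
    scene <- build_scene(extent = c(20, 12), fine_step = 0.1,
                         hypha_midline = rbind(c(4, 6), c(16, 6)),
                         hypha_width = 4.6, halo_extent = 0,
                         oxidation_max = 0, substrate = "bare_gold")
    modality <- modality_preset("optir")
  }
  list(scene = scene, modality = modality)
}

#' Serialize a scene's ground truth as a hyperspectral cube
#'
#' Mixes the fine-grid concentration maps with the library spectra with no
#' instrument effects; the result carries the `ground_truth` modality and
#' the fine grid spacing as its pixel size.
#'
#' @param scene A `scene_definition`.
#' @param library A `component_library`.
#' @param grid Wavenumber grid for the cube.
#' @return A `hyper_cube`.
#' @export
scene_to_cube <- function(scene, library, grid = default_grid()) {
  stopifnot(inherits(scene, "scene_definition"),
            inherits(library, "component_library"))
  grid <- wn_grid(grid)
  d <- dim(scene$maps[[1]])
  arr <- array(0, c(d[1], d[2], length(grid)))
  for (nm in names(scene$maps)) {
    spec <- resample_to_grid(library$components[[nm]], grid)$absorbance
    arr <- arr + outer(scene$maps[[nm]], spec)
  }
  hyper_cube(arr, grid, scene$fine_step, "ground_truth",
             provenance = sprintf("step=scene_to_cube;substrate=%s",
                                  scene$substrate))
}
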