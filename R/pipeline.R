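#' Generate a simulated measurement from a named preset
#'
#' Builds the preset scene and component library, simulates the
#' measurement through the preset's instrument modality and returns all
#' intermediate objects. Deterministic given `seed`.
#'
#' @param preset Scene preset name (see [preset_scene()]).
#' @param seed Integer seed for the instrument noise model.
#' @param grid Acquisition wavenumber grid; the default extends past the
#'   900-1800 cm^-1 fingerprint window so the crop step has work to do.
#' @return List with `cube`, `scene`, `modality`, `library` and
#'   `reference` (the atmospheric blank).
#' @export
generate_cube <- function(preset = "fig3_optir", seed = 0,
                          grid = seq(800, 1900, by = 2)) {
  ps <- preset_scene(preset)
  library <- default_component_library(wn_grid(grid))
  cube <- simulate_measurement(ps$scene, library, ps$modality, grid,
                               seed = seed)
  reference <- simulate_atmospheric_reference(ps$modality, grid, library)
  list(cube = cube, scene = ps$scene, modality = ps$modality,
       library = library, reference = reference)
}

#' Run the full analysis pipeline on a cube
#'
#' Preprocessing (atmosphere, crop, rubberband, 1370 cm^-1 normalization),
#' SIMPLISMA-seeded MCR-ALS unmixing, k-means zone segmentation with
#' semantic labels and geometry measurement, and — when a decomposition
#' zone is present — the radial gradient analysis (cuts, pixel selection,
#' two-component unmixing, lowess trend, zone linearity). If `out_dir` is
#' given, all artifacts are written there.
#'
#' @param cube A `hyper_cube` (raw measurement).
#' @param reference Atmospheric reference spectrum (or `NULL` to skip the
#'   atmosphere step's references).
#' @param config A `preprocess_config`.
#' @param k Number of MCR-ALS components for the image-wide run.
#' @param alpha SIMPLISMA noise offset.
#' @param cluster_seed Seed for the k-means restarts.
#' @param n_cuts,fan,frac Radial-cut count, fan angle (degrees) and lowess
#'   span.
#' @param gradient Run the radial gradient stage (skipped automatically
#'   when no decomposition cluster exists).
#' @param zone_boundaries Optional `c(hypha_width, halo_extent)` (um) used
#'   for the zone-linearity fit instead of the measured geometry.
#' @param out_dir Optional output directory.
#' @return List with `preprocessed`, `mixture`, `unmixing`, `cluster_map`,
#'   `geometry`, and (when run) `cuts`, `profile`, `zone_fit`.
#' @export
analyze_cube <- function(cube, reference = NULL,
                         config = preprocess_config(), k = 3, alpha = 0.05,
                         cluster_seed = 0, n_cuts = 6, fan = 150,
                         frac = 0.3, gradient = TRUE,
                         zone_boundaries = NULL, out_dir = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  refs <- if (is.null(reference)) list() else list(reference)
  pre <- preprocess_cube(cube, config, references = refs)
  mm <- mixture_matrix(pre)
  init <- simplisma(mm, k = k, alpha = alpha)
  um <- mcr_als(mm, init$S0, pure_variables = init$pure_variables)
  labels <- cluster_contributions(um, k = k, seed = cluster_seed)
  cmap <- assign_zone_labels(labels, mm, pre)
  geometry <- measure_zone_geometry(cmap)

  out <- list(preprocessed = pre, mixture = mm, unmixing = um,
              cluster_map = cmap, geometry = geometry)

  has_decomp <- any(cmap$labels == zone_codes[["decomposition"]])
  if (gradient && has_decomp) {
    cuts <- make_radial_cuts(cmap, n_cuts = n_cuts, fan = fan)
    cuts <- select_pixels_near_cuts(cuts, pre, cmap)
    profile <- two_component_profile(pre, cuts)
    profile <- lowess_trend(profile, frac = frac)
    zb <- if (is.null(zone_boundaries))
      c(geometry$hypha_width, geometry$halo_extent) else zone_boundaries
    fit <- tryCatch(zone_linearity(profile, zb[1], zb[2]),
                    error = function(e) NULL)
    out$cuts <- cuts
    out$profile <- profile
    out$zone_fit <- fit
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cube(pre, file.path(out_dir, "preprocessed.h5"))
    for (j in seq_len(um$k))
      write_spectrum_csv(ir_spectrum(mm$grid, um$S[, j],
                                     sprintf("component %d", j)),
                         file.path(out_dir, sprintf("mcr_component_%d.csv", j)))
    contrib <- data.frame(row = mm$pixel_index[, 1],
                          col = mm$pixel_index[, 2])
    for (j in seq_len(um$k)) contrib[[paste0("c", j)]] <- um$C[, j]
    utils::write.csv(contrib, file.path(out_dir, "mcr_contributions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(k = um$k, lof_percent = um$lof_percent,
                              n_iterations = um$n_iterations,
                              converged = um$converged,
                              pure_variables = um$pure_variables),
                         file.path(out_dir, "mcr_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    export_cluster_map(cmap, geometry, out_dir)
    if (!is.null(out$profile))
      export_gradient_profile(out$profile, out$cuts, out_dir, out$zone_fit)
    writeLines(c(pre$provenance,
                 sprintf("step=unmixing;params=k=%d,alpha=%g", k, alpha),
                 sprintf("step=kmeans;params=k=%d,seed=%d,n_init=10", k,
                         as.integer(cluster_seed)),
                 sprintf("step=geometry;hypha_width=%.4g;halo_extent=%.4g",
                         geometry$hypha_width, geometry$halo_extent)),
               file.path(out_dir, "run.log"))
  }
  out
}

#' Read / write a full run configuration as YAML
#'
#' A run configuration bundles the preset name, the preprocessing
#' parameters and the unmixing / clustering / gradient options behind one
#' document; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param config For writing: a list as returned by [default_run_config()].
#' @return `read_run_config` returns the validated configuration list.
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  default <- default_run_config()
  unknown <- setdiff(names(v), names(default))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(default, v)
  if (!is.null(cfg$preprocess)) {
    unknown <- setdiff(names(cfg$preprocess),
                       names(formals(preprocess_config)))
    if (length(unknown))
      stop("unknown preprocess keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(preset = "fig3_optir", seed = 0L,
       preprocess = unclass(preprocess_config()),
       unmixing = list(k = 3L, alpha = 0.05, tol = 1e-6, max_iter = 500L),
       cluster_seed = 0L,
       gradient = list(n_cuts = 6L, fan = 150, frac = 0.3),
       out_dir = NULL)
}
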