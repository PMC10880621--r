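# Memoised full-pipeline runs shared across test files (the generator and
# analysis are deterministic given preset + seed, so caching is safe).
.run_cache <- new.env(parent = emptyenv())

pipeline_run <- function(preset, seed) {
  key <- paste(preset, seed, sep = "#")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  g <- generate_cube(preset, seed = seed)
  r <- analyze_cube(g$cube, reference = g$reference,
                    gradient = (preset == "fig3_optir"))
  .run_cache[[key]] <- list(gen = g, res = r)
  .run_cache[[key]]
}

# Ground-truth zone labels of a scene on the cube's pixel raster.
truth_zone_labels <- function(scene, cmap) {
  d <- dim(cmap$labels)
  ps <- cmap$pixel_size
  cx <- (rep(seq_len(d[2]), each = d[1]) - 0.5) * ps
  cy <- (rep(seq_len(d[1]), d[2]) - 0.5) * ps
  dist <- as.vector(hyphir:::dist_to_segment(matrix(cx, 1), matrix(cy, 1),
                                             scene$hypha_midline))
  edge <- dist - scene$hypha_width / 2
  matrix(ifelse(edge <= 0, 2L, ifelse(edge <= scene$halo_extent, 1L, 0L)),
         d[1], d[2])
}
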