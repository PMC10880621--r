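#' Cluster pixels by their unmixing contributions
#'
#' k-means (squared Euclidean, best of `n_init` restarts) on the rows of
#' the contribution matrix, standardized per column to unit variance so no
#' single dominant component swamps the distance. Deterministic given
#' `seed`.
#'
#' @param result An `unmixing_result` (or a plain contribution matrix).
#' @param k Number of clusters.
#' @param seed RNG seed for the restarts.
#' @param n_init Number of random restarts.
#' @return Integer vector of cluster indices (1..k), one per contribution
#'   row, with the total within-cluster sum of squares as attribute
#'   `"wcss"`.
#' @export
cluster_contributions <- function(result, k = 3, seed = 0, n_init = 10) {
  C <- if (inherits(result, "unmixing_result")) result$C else as.matrix(result)
  if (nrow(C) < k) stop("fewer rows than clusters", call. = FALSE)
  if (nrow(unique(C)) < k)
    stop("degeneracy error: fewer distinct rows than clusters", call. = FALSE)
  sds <- apply(C, 2, stats::sd)
  sds[sds == 0] <- 1
  X <- sweep(C, 2, sds, "/")
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100)
  structure(km$cluster, wcss = km$tot.withinss)
}

zone_codes <- c(background = 0L, decomposition = 1L, hypha = 2L, masked = -1L)

#' Attach semantic zone labels to a clustering
#'
#' Ranks the clusters by their mean normalized absorbance over
#' 1700-1500 cm^-1 (the amide/carbonyl region): highest becomes the hypha,
#' intermediate the decomposition zone, lowest the background. With only
#' two populated clusters (a hypha on bare gold has no film, hence no
#' decomposition zone) the labels reduce to hypha/background and the
#' absence is flagged. Per-zone mean and SD spectra are attached.
#'
#' @param labels Cluster indices from [cluster_contributions()].
#' @param mm The `mixture_matrix` the contributions came from (provides the
#'   pixel index and spectra).
#' @param cube The preprocessed `hyper_cube`.
#' @param amide_region Ranking interval (cm^-1).
#' @return A `cluster_map`: integer label matrix (`0` background, `1`
#'   decomposition, `2` hypha, `-1` masked), per-zone `mean_spectra` and
#'   `sd_spectra`, `pixel_size`, ranking diagnostics and provenance.
#' @export
assign_zone_labels <- function(labels, mm, cube,
                               amide_region = c(1500, 1700)) {
  stopifnot(inherits(mm, "mixture_matrix"), inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  idx_amide <- which(mm$grid >= amide_region[1] & mm$grid <= amide_region[2])
  if (!length(idx_amide)) stop("amide region misses the grid", call. = FALSE)
  present <- sort(unique(labels))
  amide_mean <- vapply(present, function(cl)
    mean(mm$D[labels == cl, idx_amide]), numeric(1))
  ord <- order(amide_mean)
  if (any(diff(sort(amide_mean)) <= 1e-9))
    stop("ambiguous-labeling error: amide-region cluster means tie",
         call. = FALSE)
  semantic <- rep(NA_integer_, length(present))
  prov <- character()
  if (length(present) >= 3) {
    semantic[ord] <- c(zone_codes[["background"]],
                       rep(zone_codes[["decomposition"]],
                           length(present) - 2),
                       zone_codes[["hypha"]])[seq_along(present)]
    semantic[ord[length(ord)]] <- zone_codes[["hypha"]]
  } else if (length(present) == 2) {
    semantic[ord] <- c(zone_codes[["background"]], zone_codes[["hypha"]])
    prov <- "note=decomposition label absent (two-cluster scene)"
  } else {
    semantic <- zone_codes[["background"]]
    prov <- "note=single cluster"
  }

  lab_mat <- matrix(zone_codes[["masked"]], d[1], d[2])
  for (i in seq_along(present)) {
    px <- mm$pixel_index[labels == present[i], , drop = FALSE]
    lab_mat[px] <- semantic[i]
  }

  zones <- names(zone_codes)[match(sort(unique(semantic)), zone_codes)]
  mean_spectra <- sd_spectra <- stats::setNames(vector("list", length(zones)),
                                                zones)
  for (z in zones) {
    rows <- which(labels %in% present[semantic == zone_codes[[z]]])
    M <- mm$D[rows, , drop = FALSE]
    mean_spectra[[z]] <- ir_spectrum(mm$grid, colMeans(M), paste0(z, " mean"))
    sdv <- if (nrow(M) > 1) apply(M, 2, stats::sd) else numeric(ncol(M))
    sd_spectra[[z]] <- ir_spectrum(mm$grid, sdv, paste0(z, " sd"))
  }

  structure(list(labels = lab_mat, mean_spectra = mean_spectra,
                 sd_spectra = sd_spectra, pixel_size = cube$pixel_size,
                 amide_means = stats::setNames(amide_mean, present),
                 provenance = prov),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = zone_codes,
                      labels = names(zone_codes)))
  cat("<cluster_map>", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "),
      sprintf("(pixel %.3g um)\n", x$pixel_size))
  invisible(x)
}

# Pixel centers (um) of the pixels carrying a given label.
label_centers <- function(cmap, code) {
  idx <- which(cmap$labels == code, arr.ind = TRUE)
  cbind(x = (idx[, 2] - 0.5) * cmap$pixel_size,
        y = (idx[, 1] - 0.5) * cmap$pixel_size)
}

# Principal axis of the hypha cluster: list(center, dir (unit), t_range).
hypha_axis <- function(cmap) {
  pts <- label_centers(cmap, zone_codes[["hypha"]])
  if (nrow(pts) < 4)
    stop("insufficient-support error: hypha cluster has < 4 pixels",
         call. = FALSE)
  ctr <- colMeans(pts)
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1]
  t <- (pts[, 1] - ctr[1]) * dir[1] + (pts[, 2] - ctr[2]) * dir[2]
  list(center = ctr, dir = dir, t_range = range(t), points = pts, t = t)
}

#' Measure zone geometry in micrometres
#'
#' Estimates the hyphal midline as the principal axis of the hypha-labeled
#' pixel centers, then scans cross-sections perpendicular to it at
#' stations spaced one pixel apart. Per station, the hyphal width is the
#' length of the contiguous hypha run and the halo extent the distance
#' from the run's outer edge to the last decomposition-labeled pixel,
#' averaged over the two sides; medians over stations are reported
#' (robust to the ragged tip).
#'
#' @param cmap A `cluster_map`.
#' @return A `zone_geometry`: `hypha_width` (um), `halo_extent` (um),
#'   `midline_estimate` (2 x 2 matrix of endpoints, um), per-station
#'   `widths` and `halo_sides`.
#' @export
measure_zone_geometry <- function(cmap) {
  stopifnot(inherits(cmap, "cluster_map"))
  ax <- hypha_axis(cmap)
  ps <- cmap$pixel_size
  d <- dim(cmap$labels)
  perp <- c(-ax$dir[2], ax$dir[1])
  half_span <- sqrt(sum((d * ps)^2)) / 2
  offsets <- seq(-half_span, half_span, by = ps)
  stations <- seq(ax$t_range[1], ax$t_range[2], by = ps)

  label_at <- function(x, y) {
    c_idx <- floor(x / ps) + 1
    r_idx <- floor(y / ps) + 1
    ok <- r_idx >= 1 & r_idx <= d[1] & c_idx >= 1 & c_idx <= d[2]
    out <- rep(NA_integer_, length(x))
    out[ok] <- cmap$labels[cbind(r_idx[ok], c_idx[ok])]
    out
  }

  widths <- numeric(0)
  halos <- numeric(0)
  for (t in stations) {
    p0 <- ax$center + t * ax$dir
    lab <- label_at(p0[1] + offsets * perp[1], p0[2] + offsets * perp[2])
    hy <- which(lab == zone_codes[["hypha"]])
    if (!length(hy)) next
    mid <- which.min(abs(offsets))
    # contiguous hypha run containing (or nearest to) the midline sample
    runs <- split(hy, cumsum(c(1, diff(hy) != 1)))
    run <- runs[[which.min(vapply(runs, function(r)
      min(abs(r - mid)), numeric(1)))]]
    widths <- c(widths, length(run) * ps)
    side <- numeric(2)
    for (s in 1:2) {
      outward <- if (s == 1) seq(min(run) - 1, 1) else
        seq(max(run) + 1, length(offsets))
      if (min(run) == 1 && s == 1) outward <- integer(0)
      if (max(run) == length(offsets) && s == 2) outward <- integer(0)
      dec <- outward[which(lab[outward] == zone_codes[["decomposition"]])]
      side[s] <- if (length(dec))
        max(abs(dec - if (s == 1) min(run) else max(run))) * ps else 0
    }
    halos <- c(halos, mean(side))
  }
  if (!length(widths))
    stop("insufficient-support error: no usable cross-sections", call. = FALSE)
  midline <- rbind(ax$center + ax$t_range[1] * ax$dir,
                   ax$center + ax$t_range[2] * ax$dir)
  structure(list(hypha_width = stats::median(widths),
                 halo_extent = stats::median(halos),
                 midline_estimate = midline,
                 widths = widths, halo_sides = halos),
            class = "zone_geometry")
}

#' @export
print.zone_geometry <- function(x, ...) {
  cat(sprintf("<zone_geometry> hypha width %.2f um, halo extent %.2f um (%d stations)\n",
              x$hypha_width, x$halo_extent, length(x$widths)))
  invisible(x)
}

#' Export a cluster map as CSV / spectra / geometry files
#'
#' Writes `labels.csv` (`row,col,label`), per-zone mean and SD spectrum
#' CSVs, and `geometry.json`.
#'
#' @param cmap A `cluster_map`.
#' @param geometry A `zone_geometry` (optional).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
export_cluster_map <- function(cmap, geometry = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  d <- dim(cmap$labels)
  lab <- data.frame(row = rep(seq_len(d[1]), d[2]),
                    col = rep(seq_len(d[2]), each = d[1]),
                    label = as.vector(cmap$labels))
  f <- file.path(dir, "labels.csv")
  utils::write.csv(lab, f, row.names = FALSE)
  files <- c(files, f)
  for (z in names(cmap$mean_spectra)) {
    f1 <- file.path(dir, sprintf("zone_%s_mean.csv", z))
    f2 <- file.path(dir, sprintf("zone_%s_sd.csv", z))
    write_spectrum_csv(cmap$mean_spectra[[z]], f1)
    write_spectrum_csv(cmap$sd_spectra[[z]], f2)
    files <- c(files, f1, f2)
  }
  if (!is.null(geometry)) {
    f <- file.path(dir, "geometry.json")
    jsonlite::write_json(list(hypha_width_um = geometry$hypha_width,
                              halo_extent_um = geometry$halo_extent),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
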