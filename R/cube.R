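#' Construct a hyperspectral cube
#'
#' The container every stage of the pipeline consumes and produces: a
#' rows x cols grid of square pixels, each holding one absorbance spectrum
#' on a shared wavenumber grid. Geometry is metric: pixel (r, c) has its
#' center at ((c - 0.5) * pixel_size, (r - 0.5) * pixel_size) micrometres,
#' row-major with origin at the top-left corner.
#'
#' @param data 3-D numeric array, rows x cols x n_wavenumbers.
#' @param wavenumber Shared wavenumber grid (cm^-1). If supplied descending,
#'   both the grid and the spectral axis of `data` are flipped to ascending.
#' @param pixel_size Pixel edge length in micrometres (square pixels).
#' @param modality One of `"conventional"`, `"optir"`, `"ground_truth"`.
#' @param provenance Character vector of processing-history entries;
#'   append-only (see [cube_add_provenance()]).
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavenumber, pixel_size,
                       modality = c("ground_truth", "conventional", "optir"),
                       provenance = character()) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array (rows x cols x n_wavenumbers)", call. = FALSE)
  desc <- length(wavenumber) > 1 && all(diff(wavenumber) < 0)
  wavenumber <- wn_grid(wavenumber)
  if (desc) data <- data[, , rev(seq_len(dim(data)[3])), drop = FALSE]
  if (dim(data)[3] != length(wavenumber))
    stop("spectral dimension of data does not match wavenumber grid",
         call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um)", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("cube absorbance must be finite everywhere", call. = FALSE)
  structure(list(data = data, wavenumber = wavenumber,
                 pixel_size = as.numeric(pixel_size), modality = modality,
                 provenance = as.character(provenance)),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<hyper_cube> %s: %d x %d pixels (%.3g um), ",
                     "%d wavenumbers %.0f-%.0f cm-1, %d provenance entries\n"),
              x$modality, d[1], d[2], x$pixel_size, d[3],
              min(x$wavenumber), max(x$wavenumber), length(x$provenance)))
  invisible(x)
}

#' Append a processing-history entry to a cube
#'
#' @param cube A `hyper_cube`.
#' @param entry Character entry, conventionally `"step=<name>;params=<...>"`.
#' @return The cube with the entry appended.
#' @export
cube_add_provenance <- function(cube, entry) {
  stopifnot(inherits(cube, "hyper_cube"))
  cube$provenance <- c(cube$provenance, as.character(entry))
  cube
}

#' Extract one pixel spectrum from a cube
#'
#' @param cube A `hyper_cube`.
#' @param r,c Row and column index (1-based).
#' @return An `ir_spectrum`.
#' @export
cube_spectrum <- function(cube, r, c) {
  stopifnot(inherits(cube, "hyper_cube"))
  ir_spectrum(cube$wavenumber, cube$data[r, c, ],
              label = sprintf("pixel (%d, %d)", r, c))
}

#' Write a hyperspectral cube to an HDF5 file
#'
#' Layout: root attributes `format_version` (1), `pixel_size_um`, `modality`;
#' datasets `/wavenumbers_cm1` (1-D float64) and `/absorbance` (3-D float64,
#' rows x cols x n_wavenumbers); group `/provenance` holding one string
#' attribute per history entry. 64-bit floats throughout.
#'
#' @param cube A `hyper_cube`.
#' @param path Destination file; its directory must exist.
#' @return Invisibly, `path`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (!dir.exists(dirname(path)))
    stop("I/O error: directory does not exist: ", dirname(path), call. = FALSE)
  d <- dim(cube$data)
  # column-major R array -> C-order buffer with the wavenumber axis fastest
  data_c <- as.numeric(aperm(cube$data, c(3L, 2L, 1L)))
  cpp_h5_write_cube(path, cube$wavenumber, data_c,
                    as.integer(d), cube$pixel_size, cube$modality,
                    cube$provenance)
  invisible(path)
}

#' Read a hyperspectral cube from an HDF5 file
#'
#' Inverse of [write_cube()]. Wavenumber order is normalized to ascending
#' regardless of on-disk order; all layout elements are validated and a
#' format error names any missing dataset or attribute.
#'
#' @param path HDF5 file written by [write_cube()] (or conforming to its
#'   layout).
#' @return A `hyper_cube`.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- cpp_h5_read_cube(path)
  d <- raw$dims
  arr <- aperm(array(raw$data_c, dim = c(d[3], d[2], d[1])), c(3L, 2L, 1L))
  modality <- raw$modality
  if (!modality %in% c("conventional", "optir", "ground_truth"))
    stop("format error: unknown modality '", modality, "'", call. = FALSE)
  hyper_cube(arr, raw$wavenumbers, raw$pixel_size_um, modality,
             provenance = raw$provenance)
}

#' Pixel-center coordinates of a cube
#'
#' @param cube A `hyper_cube` (or anything with `$data` dims and
#'   `$pixel_size`).
#' @return A list with vectors `x` (per column, um) and `y` (per row, um).
#' @export
pixel_centers <- function(cube) {
  d <- dim(cube$data)
  list(x = (seq_len(d[2]) - 0.5) * cube$pixel_size,
       y = (seq_len(d[1]) - 0.5) * cube$pixel_size)
}
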