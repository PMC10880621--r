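#' Validate a wavenumber grid
#'
#' A wavenumber grid is a plain numeric vector of band positions in cm^-1.
#' It must be strictly increasing, positive everywhere and hold at least 8
#' points, so that hull baselines and peak windows are well defined. Input
#' supplied in descending order is accepted and flipped; the canonical
#' in-memory order is always ascending.
#'
#' @param values Numeric vector of wavenumbers (cm^-1).
#' @return The validated (ascending) numeric vector.
#' @export
wn_grid <- function(values) {
  if (!is.numeric(values) || length(values) < 8L)
    stop("wavenumber grid needs at least 8 numeric values", call. = FALSE)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("wavenumber grid must be finite", call. = FALSE)
  if (any(values <= 0))
    stop("wavenumbers must be positive", call. = FALSE)
  d <- diff(values)
  if (all(d < 0)) {
    values <- rev(values)
    d <- -rev(d)
  }
  if (any(d <= 0))
    stop("wavenumber grid must be strictly monotone (duplicates found)",
         call. = FALSE)
  values
}

#' Default fingerprint-region wavenumber grid
#'
#' @param lo,hi Interval bounds in cm^-1.
#' @param step Grid spacing in cm^-1.
#' @return Ascending numeric grid.
#' @export
default_grid <- function(lo = 900, hi = 1800, step = 2) {
  wn_grid(seq(lo, hi, by = step))
}

#' Construct an infrared spectrum
#'
#' @param wavenumber Wavenumber grid (cm^-1); may be descending on input.
#' @param absorbance Absorbance values, same length as `wavenumber`.
#' @param label Free-text label.
#' @return An object of class `ir_spectrum`: a list with elements
#'   `wavenumber`, `absorbance`, `label`.
#' @export
ir_spectrum <- function(wavenumber, absorbance, label = "") {
  if (length(wavenumber) != length(absorbance))
    stop("wavenumber and absorbance lengths differ", call. = FALSE)
  ord_desc <- length(wavenumber) > 1 && all(diff(wavenumber) < 0)
  wavenumber <- wn_grid(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (ord_desc) absorbance <- rev(absorbance)
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance must be finite everywhere", call. = FALSE)
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 label = as.character(label)[1]),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %s: %d points, %.1f-%.1f cm-1, A in [%.4g, %.4g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' Resample a spectrum onto a target wavenumber grid
#'
#' Linear interpolation; exact at wavenumbers shared with the source grid.
#' Extrapolation beyond the source span is refused.
#'
#' @param spectrum An `ir_spectrum`.
#' @param grid Target wavenumber grid (cm^-1).
#' @return An `ir_spectrum` on `grid`.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  grid <- wn_grid(grid)
  src <- spectrum$wavenumber
  if (min(grid) < min(src) || max(grid) > max(src))
    stop(sprintf("target grid [%g, %g] outside source span [%g, %g]",
                 min(grid), max(grid), min(src), max(src)), call. = FALSE)
  a <- stats::approx(src, spectrum$absorbance, xout = grid, method = "linear")$y
  ir_spectrum(grid, a, spectrum$label)
}

#' Read a spectrum from a two-column CSV file
#'
#' Expected columns: wavenumber (cm^-1), absorbance; a header line is
#' optional. Descending wavenumber order is normalized to ascending.
#'
#' @param path File path.
#' @return An `ir_spectrum` labelled with the file name.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path, call. = FALSE)
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  has_header <- suppressWarnings(anyNA(as.numeric(first)))
  start <- if (has_header) 2L else 1L
  if (start > length(lines)) stop("no data rows in ", path, call. = FALSE)
  wn <- ab <- numeric(length(lines) - start + 1L)
  for (i in seq_along(wn)) {
    row <- strsplit(lines[[start + i - 1L]], ",", fixed = TRUE)[[1]]
    if (length(row) != 2L)
      stop(sprintf("parse error at line %d of %s: expected 2 columns, got %d",
                   start + i - 1L, path, length(row)), call. = FALSE)
    v <- suppressWarnings(as.numeric(row))
    if (anyNA(v))
      stop(sprintf("parse error at line %d of %s: non-numeric cell",
                   start + i - 1L, path), call. = FALSE)
    wn[i] <- v[1]; ab[i] <- v[2]
  }
  ir_spectrum(wn, ab, label = basename(path))
}

#' Write a spectrum to CSV
#'
#' Writes `wavenumber_cm1,absorbance` with 9 significant digits, UTF-8, LF
#' line endings.
#'
#' @param spectrum An `ir_spectrum`.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("wavenumber_cm1,absorbance",
               sprintf("%.9g,%.9g", spectrum$wavenumber, spectrum$absorbance)),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
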