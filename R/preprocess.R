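#' Preprocessing configuration
#'
#' Defaults follow the analysis chain for cellulose-film hyperspectral
#' images: atmospheric gas correction, crop to the 900-1800 cm^-1
#' fingerprint region, rubberband baseline correction, then normalization
#' to the cellulose band at 1370 cm^-1. Steps run in the order listed in
#' `steps`.
#'
#' @param crop_lo,crop_hi Crop interval (cm^-1), closed.
#' @param anchor Normalization band position (cm^-1).
#' @param anchor_window Half-width of the normalization search window
#'   (cm^-1).
#' @param atmosphere_fit_region Interval (cm^-1) over which gas-line
#'   coefficients are fitted.
#' @param steps Ordered subset of
#'   `c("atmosphere", "crop", "rubberband", "normalize")`.
#' @return A `preprocess_config`.
#' @export
preprocess_config <- function(crop_lo = 900, crop_hi = 1800, anchor = 1370,
                              anchor_window = 15,
                              atmosphere_fit_region = c(1300, 1800),
                              steps = c("atmosphere", "crop", "rubberband",
                                        "normalize")) {
  if (crop_lo >= crop_hi) stop("crop_lo must be < crop_hi", call. = FALSE)
  if (anchor < crop_lo || anchor > crop_hi)
    stop("anchor must lie inside [crop_lo, crop_hi]", call. = FALSE)
  bad <- setdiff(steps, c("atmosphere", "crop", "rubberband", "normalize"))
  if (length(bad)) stop("unknown steps: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(crop_lo = crop_lo, crop_hi = crop_hi, anchor = anchor,
                 anchor_window = anchor_window,
                 atmosphere_fit_region = atmosphere_fit_region,
                 steps = steps),
            class = "preprocess_config")
}

#' Write / read a preprocessing configuration as YAML
#'
#' @param config A `preprocess_config`.
#' @param path File path.
#' @return `write_preprocess_config` returns `path` invisibly;
#'   `read_preprocess_config` returns a `preprocess_config`.
#' @export
write_preprocess_config <- function(config, path) {
  stopifnot(inherits(config, "preprocess_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_preprocess_config
#' @export
read_preprocess_config <- function(path) {
  v <- yaml::read_yaml(path)
  known <- names(formals(preprocess_config))
  unknown <- setdiff(names(v), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(preprocess_config, v)
}

# Internal: fit-and-subtract gas references from the rows of a spectra
# matrix. Coefficients minimize the squared second differences (roughness)
# of the corrected spectrum inside the fit region: sharp rotational lines
# add curvature that broad sample bands do not, so the smoothest residual
# is the gas-free one. Returns list(corrected, coefficients).
atmosphere_fit <- function(Y, grid, refs, fit_region) {
  if (!length(refs)) return(list(corrected = Y,
                                 coefficients = matrix(0, nrow(Y), 0)))
  R <- vapply(refs, function(s) resample_to_grid(s, grid)$absorbance,
              numeric(length(grid)))
  idx <- which(grid >= fit_region[1] & grid <= fit_region[2])
  if (length(idx) < 3) stop("atmosphere fit region too narrow", call. = FALSE)
  if (any(colSums(abs(R[idx, , drop = FALSE])) == 0))
    stop("degenerate reference: all-zero inside the fit region",
         call. = FALSE)
  m <- length(idx)
  # second-difference (roughness) operator on the fit region
  D2 <- matrix(0, m - 2, m)
  D2[cbind(seq_len(m - 2), seq_len(m - 2))] <- 1
  D2[cbind(seq_len(m - 2), seq_len(m - 2) + 1)] <- -2
  D2[cbind(seq_len(m - 2), seq_len(m - 2) + 2)] <- 1
  A <- D2 %*% R[idx, , drop = FALSE]
  proj <- solve(crossprod(A), t(A) %*% D2)           # k x m
  coefs <- Y[, idx, drop = FALSE] %*% t(proj)        # n x k
  list(corrected = Y - coefs %*% t(R), coefficients = coefs)
}

#' Remove atmospheric gas lines from a spectrum
#'
#' Subtracts a least-roughness combination of the reference spectra: the
#' coefficients minimize the sum of squared second differences of the
#' corrected spectrum inside `fit_region`. The result is unchanged where
#' every reference is zero. Fitted coefficients are attached as attribute
#' `"coefficients"`.
#'
#' @param spectrum An `ir_spectrum`.
#' @param references List of reference `ir_spectrum` objects (e.g. from
#'   [simulate_atmospheric_reference()]); an empty list is the identity.
#' @param fit_region Interval (cm^-1).
#' @return The corrected `ir_spectrum`.
#' @export
correct_atmosphere <- function(spectrum, references,
                               fit_region = c(1300, 1800)) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  fit <- atmosphere_fit(matrix(spectrum$absorbance, 1), spectrum$wavenumber,
                        references, fit_region)
  out <- ir_spectrum(spectrum$wavenumber, fit$corrected[1, ], spectrum$label)
  attr(out, "coefficients") <- drop(fit$coefficients)
  out
}

#' Crop to a wavenumber interval
#'
#' Retains wavenumbers in the closed interval `[lo, hi]`.
#'
#' @param x An `ir_spectrum` or `hyper_cube`.
#' @param lo,hi Interval bounds (cm^-1).
#' @return Object of the same class, truncated.
#' @export
crop <- function(x, lo = 900, hi = 1800) UseMethod("crop")

#' @export
crop.ir_spectrum <- function(x, lo = 900, hi = 1800) {
  keep <- x$wavenumber >= lo & x$wavenumber <= hi
  if (sum(keep) < 8)
    stop(sprintf("range error: crop [%g, %g] leaves %d points", lo, hi,
                 sum(keep)), call. = FALSE)
  ir_spectrum(x$wavenumber[keep], x$absorbance[keep], x$label)
}

#' @export
crop.hyper_cube <- function(x, lo = 900, hi = 1800) {
  keep <- x$wavenumber >= lo & x$wavenumber <= hi
  if (sum(keep) < 8)
    stop(sprintf("range error: crop [%g, %g] leaves %d points", lo, hi,
                 sum(keep)), call. = FALSE)
  out <- x
  out$wavenumber <- x$wavenumber[keep]
  out$data <- x$data[, , keep, drop = FALSE]
  cube_add_provenance(out, sprintf("step=crop;params=lo=%g,hi=%g", lo, hi))
}

# Internal: lower convex hull baseline of (x, y); returns the baseline
# evaluated at every x. Andrew monotone chain restricted to the lower
# chain; x must be strictly increasing.
lower_hull_baseline <- function(x, y) {
  n <- length(x)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      a <- stack[top - 1L]; b <- stack[top]
      # pop b if it lies on or above segment a-i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0)
        top <- top - 1L
      else break
    }
    top <- top + 1L
    stack[top] <- i
  }
  v <- stack[seq_len(top)]
  stats::approx(x[v], y[v], xout = x, method = "linear")$y
}

#' Rubberband baseline correction
#'
#' The baseline is the lower convex hull of the spectrum's points,
#' linearly interpolated between hull vertices; subtracting it yields a
#' non-negative spectrum that is zero at every hull vertex (including both
#' endpoints). Applying the correction twice changes nothing.
#'
#' @param spectrum An `ir_spectrum` with at least 3 points.
#' @return List with `baseline` and `corrected`, both `ir_spectrum`.
#' @export
rubberband_baseline <- function(spectrum) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (length(spectrum$wavenumber) < 3)
    stop("rubberband needs at least 3 points", call. = FALSE)
  base <- lower_hull_baseline(spectrum$wavenumber, spectrum$absorbance)
  list(baseline = ir_spectrum(spectrum$wavenumber, base, "baseline"),
       corrected = ir_spectrum(spectrum$wavenumber,
                               pmax(spectrum$absorbance - base, 0),
                               spectrum$label))
}

#' Normalize a spectrum to a band maximum
#'
#' Divides the whole spectrum by its maximum inside
#' `[anchor - window, anchor + window]` (clipped to the grid), so the value
#' at that maximum becomes exactly 1.
#'
#' @param spectrum A baseline-corrected `ir_spectrum`.
#' @param anchor Band position (cm^-1).
#' @param window Half-width of the search window (cm^-1).
#' @param floor Smallest usable anchor maximum; at or below it the pixel
#'   has no usable anchor band (e.g. a hypha on bare gold) and a
#'   normalization error is raised.
#' @return The normalized `ir_spectrum`.
#' @export
normalize_to_peak <- function(spectrum, anchor = 1370, window = 15,
                              floor = 1e-6) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  idx <- which(spectrum$wavenumber >= anchor - window &
                 spectrum$wavenumber <= anchor + window)
  if (!length(idx)) stop("anchor window misses the grid", call. = FALSE)
  m <- max(spectrum$absorbance[idx])
  if (m <= floor)
    stop(sprintf("normalization error: anchor-window max %.3g <= floor %.3g",
                 m, floor), call. = FALSE)
  ir_spectrum(spectrum$wavenumber, spectrum$absorbance / m, spectrum$label)
}

#' Apply the preprocessing chain to every pixel of a cube
#'
#' Runs the steps enabled in `config$steps`, in order, on every pixel
#' spectrum. Pixels whose normalization anchor is at or below the floor
#' (no cellulose band, e.g. bare gold under the hypha) are masked, left
#' unnormalized and excluded from downstream statistics; the mask is
#' stored in `$mask` and the count recorded in provenance.
#'
#' @param cube A `hyper_cube`.
#' @param config A `preprocess_config`.
#' @param references List of gas reference spectra for the atmosphere step.
#' @param norm_floor Normalization floor (see [normalize_to_peak()]).
#' @return The processed `hyper_cube` with logical `$mask` (TRUE =
#'   excluded).
#' @export
preprocess_cube <- function(cube, config = preprocess_config(),
                            references = list(), norm_floor = 1e-6) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(config, "preprocess_config"))
  d <- dim(cube$data)
  grid <- cube$wavenumber
  Y <- matrix(aperm(cube$data, c(3, 1, 2)), nrow = d[1] * d[2],
              ncol = d[3], byrow = TRUE)
  mask <- if (is.null(cube$mask)) matrix(FALSE, d[1], d[2]) else cube$mask
  prov <- character()

  for (step in config$steps) {
    if (step == "atmosphere") {
      fit <- atmosphere_fit(Y, grid, references, config$atmosphere_fit_region)
      Y <- fit$corrected
      prov <- c(prov, sprintf(
        "step=atmosphere;params=fit_region=%g-%g,n_refs=%d,mean_coef=%.6g",
        config$atmosphere_fit_region[1], config$atmosphere_fit_region[2],
        length(references),
        if (length(references)) mean(fit$coefficients) else 0))
    } else if (step == "crop") {
      keep <- grid >= config$crop_lo & grid <= config$crop_hi
      if (sum(keep) < 8)
        stop("range error: crop leaves too few points", call. = FALSE)
      grid <- grid[keep]
      Y <- Y[, keep, drop = FALSE]
      prov <- c(prov, sprintf("step=crop;params=lo=%g,hi=%g",
                              config$crop_lo, config$crop_hi))
    } else if (step == "rubberband") {
      for (i in seq_len(nrow(Y)))
        Y[i, ] <- pmax(Y[i, ] - lower_hull_baseline(grid, Y[i, ]), 0)
      prov <- c(prov, "step=rubberband;params=lower_convex_hull")
    } else if (step == "normalize") {
      idx <- which(grid >= config$anchor - config$anchor_window &
                     grid <= config$anchor + config$anchor_window)
      if (!length(idx)) stop("anchor window misses the grid", call. = FALSE)
      m <- apply(Y[, idx, drop = FALSE], 1, max)
      bad <- m <= norm_floor
      mask <- mask | matrix(bad, d[1], d[2])
      scale <- ifelse(bad, 1, m)
      Y <- Y / scale
      prov <- c(prov, sprintf(
        "step=normalize;params=anchor=%g,window=%g;masked=%d",
        config$anchor, config$anchor_window, sum(bad)))
    }
  }

  out <- hyper_cube(aperm(array(t(Y), c(length(grid), d[1], d[2])),
                          c(2, 3, 1)),
                    grid, cube$pixel_size, cube$modality,
                    provenance = c(cube$provenance, prov))
  out$mask <- mask
  out
}

#' Detect peaks in a baseline-corrected spectrum
#'
#' Local maxima above `min_height` times the global maximum, separated by
#' at least `window` cm^-1 (greedy, strongest first); centers refined by
#' 3-point parabolic interpolation.
#'
#' @param spectrum An `ir_spectrum`.
#' @param min_height Height threshold as a fraction of the global maximum.
#' @param window Minimum separation between reported peaks (cm^-1).
#' @return Data frame with columns `center` (cm^-1) and `height`, sorted by
#'   descending height; zero rows if the spectrum is flat.
#' @export
detect_peaks <- function(spectrum, min_height = 0.05, window = 8) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  wn <- spectrum$wavenumber
  a <- spectrum$absorbance
  n <- length(a)
  gmax <- max(a)
  if (gmax <= 0 || n < 3)
    return(data.frame(center = numeric(0), height = numeric(0)))
  i <- 2:(n - 1)
  is_max <- a[i] > a[i - 1] & a[i] >= a[i + 1] & a[i] >= min_height * gmax
  cand <- i[is_max]
  if (!length(cand))
    return(data.frame(center = numeric(0), height = numeric(0)))
  centers <- heights <- numeric(length(cand))
  for (j in seq_along(cand)) {
    k <- cand[j]
    denom <- a[k - 1] - 2 * a[k] + a[k + 1]
    delta <- if (abs(denom) > 1e-15) 0.5 * (a[k - 1] - a[k + 1]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    step <- if (delta >= 0) wn[k + 1] - wn[k] else wn[k] - wn[k - 1]
    centers[j] <- wn[k] + delta * step
    heights[j] <- a[k] - 0.25 * (a[k - 1] - a[k + 1]) * delta
  }
  ord <- order(heights, decreasing = TRUE)
  keep <- logical(length(ord))
  for (j in ord) {
    if (!any(keep & abs(centers - centers[j]) < window)) keep[j] <- TRUE
  }
  out <- data.frame(center = centers[keep], height = heights[keep])
  out[order(out$height, decreasing = TRUE), , drop = FALSE]
}
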