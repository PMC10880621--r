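#' Assemble the pixel-by-wavenumber mixture matrix of a cube
#'
#' Rows are the (unmasked) pixel spectra, columns the wavenumber channels.
#' Masked and all-zero pixels are excluded before assembly.
#'
#' @param cube A (preprocessed) `hyper_cube`.
#' @param pixels Optional 2-column matrix (row, col) restricting the rows,
#'   e.g. a radial-cut selection.
#' @return A `mixture_matrix`: list with `D` (n_pixels x n_wavenumbers),
#'   `pixel_index` (n_pixels x 2), `grid`.
#' @export
mixture_matrix <- function(cube, pixels = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  if (is.null(pixels)) {
    pixels <- cbind(rep(seq_len(d[1]), d[2]),
                    rep(seq_len(d[2]), each = d[1]))
  } else {
    pixels <- rbind(pixels)
  }
  if (!is.null(cube$mask)) {
    keep <- !cube$mask[pixels]
    pixels <- pixels[keep, , drop = FALSE]
  }
  D <- t(apply(pixels, 1, function(p) cube$data[p[1], p[2], ]))
  nz <- rowSums(abs(D)) > 0
  D <- D[nz, , drop = FALSE]
  pixels <- pixels[nz, , drop = FALSE]
  if (!nrow(D)) stop("no usable pixels for the mixture matrix", call. = FALSE)
  structure(list(D = D, pixel_index = pixels, grid = cube$wavenumber),
            class = "mixture_matrix")
}

# Exact multiple-right-hand-side non-negative least squares:
# min ||A x_i - b_i||, x_i >= 0 for every column b_i of B, solved by
# enumerating active sets (exact for the small k used here). Returns a
# k x ncol(B) matrix.
nnls_cols <- function(A, B) {
  k <- ncol(A)
  if (k > 12L) stop("support-enumeration NNLS limited to k <= 12",
                    call. = FALSE)
  N <- ncol(B)
  best_res <- colSums(B^2)          # empty support
  X <- matrix(0, k, N)
  for (size in seq_len(k)) {
    for (sup in utils::combn(k, size, simplify = FALSE)) {
      As <- A[, sup, drop = FALSE]
      G <- crossprod(As)
      ok <- TRUE
      cf <- tryCatch(chol(G), error = function(e) { ok <<- FALSE; NULL })
      if (!ok) next
      AtB <- crossprod(As, B)
      Xs <- backsolve(cf, backsolve(cf, AtB, transpose = TRUE))
      feas <- colSums(Xs < -1e-10) == 0
      res <- colSums(B^2) - colSums(Xs * AtB)
      upd <- feas & res < best_res - 1e-12
      if (any(upd)) {
        best_res[upd] <- res[upd]
        X[, upd] <- 0
        X[sup, upd] <- pmax(Xs[, upd, drop = FALSE], 0)
      }
    }
  }
  X
}

#' SIMPLISMA pure-variable selection
#'
#' Purity of channel j is `sd_j / (mean_j + alpha * max(mean))`. The first
#' pure variable maximizes purity; each subsequent one maximizes purity
#' times the determinant of the correlation-around-the-origin matrix of
#' the candidate channel joined with the channels already selected, which
#' suppresses channels correlated with earlier picks. Ties break to the
#' lowest index; the procedure is deterministic.
#'
#' @param D A `mixture_matrix` or a plain non-negative matrix
#'   (pixels x wavenumbers).
#' @param k Number of components to seed.
#' @param alpha Noise offset as a fraction of the largest channel mean.
#' @return List with `pure_variables` (channel indices), `S0` (initial
#'   spectra, n_wavenumbers x k, unit maximum per column) and `C0` (the
#'   pure-variable concentration profiles, unit maximum per column).
#' @export
simplisma <- function(D, k, alpha = 0.05) {
  if (inherits(D, "mixture_matrix")) D <- D$D
  n <- nrow(D); m <- ncol(D)
  if (k < 1 || k > min(n, m))
    stop("k must lie in [1, min(n_pixels, n_wavenumbers)]", call. = FALSE)
  mu <- colMeans(D)
  sg <- sqrt(pmax(colMeans(D^2) - mu^2, 0))
  if (max(sg) <= 1e-14 * max(abs(mu), 1))
    stop("degeneracy error: all channels constant", call. = FALSE)
  purity <- sg / (mu + alpha * max(mu))
  lambda <- sqrt(mu^2 + sg^2)
  lambda[lambda == 0] <- Inf                    # dead channels never win
  Z <- sweep(D, 2, lambda * sqrt(n), "/")
  sel <- integer(0)
  for (j in seq_len(k)) {
    if (!length(sel)) {
      score <- purity
    } else {
      Zs <- Z[, sel, drop = FALSE]
      G <- crossprod(Zs)
      zz <- crossprod(Zs, Z)                    # |sel| x m
      diagz <- colSums(Z^2)
      detG <- det(G)
      score <- vapply(seq_len(m), function(cand) {
        M <- rbind(cbind(diagz[cand], t(zz[, cand])),
                   cbind(zz[, cand, drop = FALSE], G))
        purity[cand] * det(M)
      }, numeric(1))
      score[sel] <- -Inf
    }
    sel <- c(sel, which.max(score))             # which.max -> lowest index
  }
  C0 <- D[, sel, drop = FALSE]
  C0 <- sweep(C0, 2, pmax(apply(C0, 2, max), 1e-300), "/")
  S0 <- nnls_cols(C0, D)                        # k x m spectra estimate
  S0 <- t(S0)
  S0 <- sweep(S0, 2, pmax(apply(S0, 2, max), 1e-300), "/")
  list(pure_variables = sel, S0 = S0, C0 = C0)
}

#' Non-negative MCR-ALS factorization
#'
#' Alternating exact non-negative least squares for `D ~ C S^T`: the
#' contribution step solves every pixel row, the spectra step every
#' wavenumber column, and after each iteration the spectra columns are
#' rescaled to unit maximum (scale moved into `C`). Each half-step is the
#' true constrained minimizer, so the recorded lack-of-fit sequence is
#' non-increasing. Stops when the relative lack-of-fit change drops below
#' `tol` or after `max_iter` iterations (then `converged = FALSE`).
#'
#' @param D A `mixture_matrix` or plain matrix (pixels x wavenumbers).
#' @param S0 Initial spectra (n_wavenumbers x k), e.g. from [simplisma()].
#' @param max_iter Maximum number of full iterations.
#' @param tol Relative lack-of-fit convergence tolerance.
#' @param pure_variables Optional channel indices recorded in the result.
#' @return An `unmixing_result`: `S` (n_wavenumbers x k, unit-maximum
#'   columns), `C` (n_pixels x k), `k`, `lof_percent`, `lof_history`,
#'   `n_iterations`, `converged`, `pure_variables`, plus `grid` and
#'   `pixel_index` when `D` is a `mixture_matrix`.
#' @export
mcr_als <- function(D, S0, max_iter = 500L, tol = 1e-6,
                    pure_variables = integer(0)) {
  grid <- NULL; pixel_index <- NULL
  if (inherits(D, "mixture_matrix")) {
    grid <- D$grid; pixel_index <- D$pixel_index; D <- D$D
  }
  S0 <- as.matrix(S0)
  k <- ncol(S0)
  if (any(S0 < 0) || any(colSums(abs(S0)) == 0))
    stop("S0 columns must be non-negative and non-zero", call. = FALSE)
  if (qr(S0)$rank < k)
    stop("degeneracy error: S0 is rank deficient", call. = FALSE)
  denom <- sum(D^2)
  if (denom == 0) stop("domain error: D is identically zero", call. = FALSE)

  S <- S0
  lof_history <- numeric(0)
  lof <- Inf
  converged <- FALSE
  iter <- 0L
  C <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    C <- t(nnls_cols(S, t(D)))                  # n x k
    S <- t(nnls_cols(C, D))                     # m x k
    scale <- apply(S, 2, max)
    scale[scale == 0] <- 1
    S <- sweep(S, 2, scale, "/")
    C <- sweep(C, 2, scale, "*")
    new_lof <- 100 * sqrt(sum((D - C %*% t(S))^2) / denom)
    lof_history <- c(lof_history, new_lof)
    if (is.finite(lof) && abs(lof - new_lof) < tol * max(lof, 1e-12)) {
      lof <- new_lof
      converged <- TRUE
      break
    }
    lof <- new_lof
  }
  structure(list(S = S, C = C, k = k, lof_percent = lof,
                 lof_history = lof_history, n_iterations = iter,
                 converged = converged, pure_variables = pure_variables,
                 grid = grid, pixel_index = pixel_index),
            class = "unmixing_result")
}

#' @export
print.unmixing_result <- function(x, ...) {
  cat(sprintf(paste0("<unmixing_result> k=%d, LOF %.4g%%, %d iterations",
                     " (%sconverged), pure variables: %s\n"),
              x$k, x$lof_percent, x$n_iterations,
              if (x$converged) "" else "not ",
              if (length(x$pure_variables))
                paste(x$pure_variables, collapse = ", ") else "-"))
  invisible(x)
}

#' Lack of fit of a bilinear factorization
#'
#' `100 * sqrt(sum((D - C S^T)^2) / sum(D^2))`.
#'
#' @param D Data matrix (pixels x wavenumbers).
#' @param C Contributions (pixels x k).
#' @param S Spectra (wavenumbers x k).
#' @return Lack of fit in percent.
#' @export
lack_of_fit <- function(D, C, S) {
  if (inherits(D, "mixture_matrix")) D <- D$D
  stopifnot(nrow(C) == nrow(D), nrow(S) == ncol(D), ncol(C) == ncol(S))
  denom <- sum(D^2)
  if (denom == 0) stop("domain error: D is identically zero", call. = FALSE)
  100 * sqrt(sum((D - C %*% t(S))^2) / denom)
}

#' Match recovered components to reference spectra
#'
#' Exhaustive search (k <= 6) for the column permutation maximizing the
#' total cosine similarity between recovered and reference spectra.
#'
#' @param result An `unmixing_result`, or a spectra matrix
#'   (n_wavenumbers x k).
#' @param truth List of reference `ir_spectrum` objects (resampled to the
#'   result grid if needed) or a matrix of reference spectra columns.
#' @return List with `permutation` (truth column assigned to each recovered
#'   column) and `similarities` (cosine per recovered column, in recovered
#'   order).
#' @export
match_components <- function(result, truth) {
  S <- if (inherits(result, "unmixing_result")) result$S else as.matrix(result)
  if (is.list(truth) && !is.matrix(truth)) {
    grid <- if (inherits(result, "unmixing_result") && !is.null(result$grid))
      result$grid else NULL
    truth <- vapply(truth, function(s) {
      if (!is.null(grid)) s <- resample_to_grid(s, grid)
      s$absorbance
    }, numeric(nrow(S)))
  }
  truth <- as.matrix(truth)
  k <- ncol(S)
  if (ncol(truth) != k) stop("component counts differ", call. = FALSE)
  if (k > 6) stop("exhaustive matching limited to k <= 6", call. = FALSE)
  cosm <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ni <- sqrt(sum(S[, i]^2)); nj <- sqrt(sum(truth[, j]^2))
    cosm[i, j] <- if (ni > 0 && nj > 0) sum(S[, i] * truth[, j]) / (ni * nj)
    else 0
  }
  perms <- all_permutations(k)
  totals <- vapply(perms, function(p) sum(cosm[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(totals)]]
  list(permutation = best,
       similarities = cosm[cbind(seq_len(k), best)])
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in all_permutations(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
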