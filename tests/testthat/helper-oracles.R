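# Independent oracles used by the tests; deliberately slow and simple.

# O(n^2)-ish lower convex hull: the hull is the pointwise maximum of all
# lines through point pairs that lie on or below every point.
oracle_lower_hull <- function(x, y) {
  n <- length(x)
  base <- rep(-Inf, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      slope <- (y[j] - y[i]) / (x[j] - x[i])
      line <- y[i] + slope * (x - x[i])
      if (all(y - line >= -1e-9 * max(1, max(abs(y))))) {
        base <- pmax(base, line)
      }
    }
  }
  base
}

# Rank-1 non-negative factorization by multiplicative updates (Lee-Seung),
# used as the optimum oracle for k = 1 MCR-ALS.
oracle_nmf_rank1 <- function(D, iters = 3000, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(nrow(D)), ncol = 1)
  H <- matrix(runif(ncol(D)), nrow = 1)
  for (i in seq_len(iters)) {
    H <- H * (t(W) %*% D) / pmax(t(W) %*% W %*% H, 1e-12)
    W <- W * (D %*% t(H)) / pmax(W %*% H %*% t(H), 1e-12)
  }
  list(W = W, H = H)
}

# Paint a zone-label matrix directly (for geometry tests): horizontal
# hypha stripe of `hypha_px` rows flanked by `halo_px` decomposition rows,
# centered vertically.
painted_cluster_map <- function(nr = 41, nc = 30, hypha_px = 9, halo_px = 12,
                                pixel_size = 0.5) {
  labels <- matrix(0L, nr, nc)
  mid <- (nr + 1) / 2
  half_h <- (hypha_px - 1) / 2
  hypha_rows <- which(abs(seq_len(nr) - mid) <= half_h)
  halo_rows <- setdiff(which(abs(seq_len(nr) - mid) <= half_h + halo_px),
                       hypha_rows)
  labels[halo_rows, ] <- 1L
  labels[hypha_rows, ] <- 2L
  grid <- default_grid()
  zero <- ir_spectrum(grid, numeric(length(grid)))
  structure(list(labels = labels,
                 mean_spectra = list(background = zero, decomposition = zero,
                                     hypha = zero),
                 sd_spectra = list(background = zero, decomposition = zero,
                                   hypha = zero),
                 pixel_size = pixel_size, amide_means = NULL,
                 provenance = character()),
            class = "cluster_map")
}
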