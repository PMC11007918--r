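# Independent oracles and small fixture builders shared across tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1L]]

rand_seq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                collapse = "")

make_records <- function(seqs, ids = sprintf("t:g%03d", seq_along(seqs)),
                         annotations = vector("list", length(seqs))) {
  mapply(function(id, s, a) seq_record(id, s, a %||% character()),
         ids, seqs, annotations, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive per-residue mock-embedding oracle: plain loops over k-mer windows,
# independent of the package's prefix-sum implementation.
naive_mock_embed <- function(sequence, spec) {
  L <- nchar(sequence)
  k <- spec$kmer_size
  M <- matrix(0, L, spec$dim)
  for (i in seq_len(L)) {
    for (s in seq_len(max(L - k + 1L, 0L))) {
      if (s <= i && i <= s + k - 1L) {
        M[i, ] <- M[i, ] + kmer_direction(substr(sequence, s, s + k - 1L),
                                          spec)
      }
    }
  }
  switch(spec$pooling,
         mean = colMeans(M),
         max = apply(M, 2, max),
         first = M[1, ])
}

# Brute-force nearest-neighbour loop: per-coordinate accumulation, no
# vectorized matrix ops.
brute_force_nn <- function(query, embeddings, tie_tol = 0) {
  d <- numeric(nrow(embeddings))
  for (i in seq_len(nrow(embeddings))) {
    acc <- 0
    for (j in seq_along(query)) acc <- acc + (embeddings[i, j] - query[j])^2
    d[i] <- sqrt(acc)
  }
  list(dmin = min(d), best = which(d <= min(d) + tie_tol), d = d)
}

# Best rigid superposition by numerical optimization over Euler angles
# (multi-start), independent of the SVD route.
optim_superpose_rmsd <- function(moving, fixed, n_starts = 8L) {
  rot_from_angles <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  A <- sweep(moving, 2, colMeans(moving))
  B <- sweep(fixed, 2, colMeans(fixed))
  obj <- function(a) sqrt(mean(rowSums((A %*% rot_from_angles(a) - B)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    a0 <- runif(3, -pi, pi)
    fit <- stats::optim(a0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Two-Gaussian embedding fixture: two clusters in R^d whose centroids are
# `separation` standard deviations apart along a random direction.
two_gaussian_fixture <- function(n = 400L, d = 64L, separation = 10,
                                 seed = 101L) {
  set.seed(seed)
  dir <- rnorm(d); dir <- dir / sqrt(sum(dir^2))
  half <- n %/% 2L
  X <- rbind(
    matrix(rnorm(half * d), half, d),
    matrix(rnorm((n - half) * d), n - half, d) +
      matrix(dir * separation, n - half, d, byrow = TRUE)
  )
  list(x = X, y = rep(c(0, 1), c(half, n - half)))
}

# Confusion counts recomputed naively from label/prediction pairs.
naive_confusion <- function(truth, predicted) {
  list(TP = sum(truth & predicted), FP = sum(!truth & predicted),
       FN = sum(truth & !predicted), TN = sum(!truth & !predicted))
}
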