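#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1) and translation minimizing
#' the root-mean-square deviation between paired point sets, via the SVD of
#' the cross-covariance matrix.
#'
#' @param moving,fixed Numeric `n x 3` matrices of paired coordinates,
#'   `n >= 3`, all finite. `moving` is superposed onto `fixed`.
#' @return List with `rotation` (3x3, acts on coordinate rows as
#'   `x %*% rotation`), `translation` (length 3) and `rmsd` (angstroms):
#'   the transformed points are `moving %*% rotation + translation`.
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (ncol(moving) != 3L || ncol(fixed) != 3L ||
      nrow(moving) != nrow(fixed)) {
    stop("moving and fixed must be n x 3 matrices of equal length",
         call. = FALSE)
  }
  if (nrow(moving) < 3L) {
    stop("superposition needs at least 3 point pairs", call. = FALSE)
  }
  if (!all(is.finite(moving)) || !all(is.finite(fixed))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2L, cm); B <- sweep(fixed, 2L, cf)
  sv <- svd(crossprod(A, B))
  if (sv$d[2L] <= 1e-8 * max(sv$d[1L], 1e-300)) {
    warning("degenerate (near-collinear) point set; superposition is best-effort")
  }
  d <- det(sv$u %*% t(sv$v))
  R <- sv$u %*% diag(c(1, 1, if (d < 0) -1 else 1)) %*% t(sv$v)
  moved <- A %*% R
  list(rotation = R,
       translation = drop(cf - cm %*% R),
       rmsd = sqrt(mean(rowSums((moved - B)^2))))
}

#' Length-dependent TM-score distance scale d0
#'
#' `d0(L) = 1.24 * (L - 15)^(1/3) - 1.8` angstroms, floored at 0.5
#' whenever the formula yields less (the cube root is undefined or the
#' value negative for short targets, roughly L below 27).
#'
#' @param L_target Target length in residues, at least 1.
#' @return d0 in angstroms (at least 0.5).
#' @export
d0_scale <- function(L_target) {
  assert_scalar_number(L_target, "L_target", lower = 1)
  v <- if (L_target > 15) 1.24 * (L_target - 15)^(1 / 3) - 1.8 else -Inf
  max(0.5, v)
}

#' TM-score between two C-alpha traces over a residue correspondence
#'
#' Template-modeling score
#' \deqn{TM = (1/L_{target}) \sum_{i=1}^{L_{common}} 1/(1 + (d_i/d_0)^2)}
#' where the `d_i` are the paired-residue distances after rigid
#' superposition of the template onto the target and `d0 = d0_scale(L_target)`.
#' The maximization over superpositions is approximated by a least-squares
#' (Kabsch) fit followed by iterative re-weighting: pairs with
#' `d_i > 2 * d0` are discarded and the fit repeated (up to `max_iter`
#' rounds or convergence), always scoring over the full correspondence.
#' The returned value is therefore a lower bound on the true maximum.
#' With fewer than 3 correspondence pairs (or `superpose = FALSE`) the raw
#' coordinate distances are used.
#'
#' @param target,template [ca_trace()] objects; `target` supplies
#'   `L_target`.
#' @param correspondence Two-column matrix of (target index, template
#'   index) pairs, strictly increasing in target order. Default: the
#'   identity correspondence over the shorter trace.
#' @param superpose Superpose before measuring distances (default `TRUE`).
#' @param max_iter Maximum re-weighting rounds (default 5).
#' @return Object of class `tm_score_result`: list with `tm_score`,
#'   `rmsd`, `d0`, `L_target`, `L_common` and `interpretation`
#'   (`"highly similar structures"` for scores of at least 0.8,
#'   `"similar structural domains"` for at least 0.5, otherwise
#'   `"dissimilar structural domains"`).
#' @export
tm_score <- function(target, template, correspondence = NULL,
                     superpose = TRUE, max_iter = 5L) {
  stopifnot(inherits(target, "ca_trace"), inherits(template, "ca_trace"))
  Lt <- nrow(target$coords)
  Lm <- nrow(template$coords)
  if (is.null(correspondence)) {
    n <- min(Lt, Lm)
    correspondence <- cbind(seq_len(n), seq_len(n))
  }
  corr <- as.matrix(correspondence)
  if (ncol(corr) != 2L || nrow(corr) < 1L) {
    stop("correspondence must be a non-empty 2-column matrix", call. = FALSE)
  }
  if (any(corr[, 1L] < 1L | corr[, 1L] > Lt) ||
      any(corr[, 2L] < 1L | corr[, 2L] > Lm)) {
    stop("correspondence indices out of range", call. = FALSE)
  }
  if (nrow(corr) > 1L && any(diff(corr[, 1L]) <= 0)) {
    stop("correspondence must be strictly increasing in target order",
         call. = FALSE)
  }
  P_t <- target$coords[corr[, 1L], , drop = FALSE]
  P_m <- template$coords[corr[, 2L], , drop = FALSE]
  n <- nrow(corr)
  d0 <- d0_scale(Lt)

  pair_dist <- function(M) sqrt(rowSums((M - P_t)^2))

  if (superpose && n >= 3L) {
    fit <- kabsch_superpose(P_m, P_t)
    moved <- P_m %*% fit$rotation + rep(fit$translation, each = n)
    di <- pair_dist(moved)
    keep_prev <- rep(TRUE, n)
    for (it in seq_len(max_iter)) {
      keep <- di <= 2 * d0
      if (sum(keep) < 3L || identical(keep, keep_prev)) break
      fit <- kabsch_superpose(P_m[keep, , drop = FALSE],
                              P_t[keep, , drop = FALSE])
      moved <- P_m %*% fit$rotation + rep(fit$translation, each = n)
      di <- pair_dist(moved)
      keep_prev <- keep
    }
    rmsd <- sqrt(mean(di^2))
  } else {
    if (superpose && n < 3L) {
      warning("fewer than 3 correspondence pairs: scoring raw distances without superposition")
    }
    di <- pair_dist(P_m)
    rmsd <- sqrt(mean(di^2))
  }

  score <- sum(1 / (1 + (di / d0)^2)) / Lt
  structure(list(
    tm_score = score, rmsd = rmsd, d0 = d0, L_target = Lt, L_common = n,
    interpretation = if (score >= 0.8) "highly similar structures"
                     else if (score >= 0.5) "similar structural domains"
                     else "dissimilar structural domains"
  ), class = "tm_score_result")
}

#' @export
print.tm_score_result <- function(x, ...) {
  cat(sprintf("TM-score %.4f (L_target %d, L_common %d, d0 %.3f A, RMSD %.3f A): %s\n",
              x$tm_score, x$L_target, x$L_common, x$d0, x$rmsd,
              x$interpretation))
  invisible(x)
}

get_substitution_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  e <- new.env()
  utils::data(list = x, package = "Biostrings", envir = e)
  e[[x]]
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment by Gotoh dynamic programming. A gap of length L
#' costs `gap_open + L * gap_extend`. Traceback tie-breaking is
#' deterministic: diagonal is preferred over a gap in the reference
#' ("up"), which is preferred over a gap in the query ("left"); among
#' equal-scoring end cells the first in row-major order is used. Percent
#' identity is 100 times the number of identical columns over the number
#' of alignment columns (gaps counted in the denominator by default).
#'
#' @param query,ref Non-empty sequences over the 20 standard letters.
#' @param substitution_matrix Matrix or the name of a Biostrings scoring
#'   matrix (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 0.5).
#' @param identity_denominator Denominator convention for percent
#'   identity: `"alignment"` (all alignment columns, default),
#'   `"min_length"` (shorter input sequence) or `"aligned_columns"`
#'   (gapless columns only).
#' @return Object of class `sw_alignment`: list with `aligned_query`,
#'   `aligned_ref` (gapped strings of equal length), `score`,
#'   `identity_percent`, `n_columns`, `n_identical`. A best score of 0
#'   yields an empty alignment with identity 0.
#' @export
smith_waterman <- function(query, ref, substitution_matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5,
                           identity_denominator = c("alignment", "min_length",
                                                    "aligned_columns")) {
  identity_denominator <- match.arg(identity_denominator)
  for (s in c(query, ref)) {
    if (!is.character(s) || length(s) != 1L || !nzchar(s) ||
        grepl("[^ACDEFGHIKLMNPQRSTVWY]", toupper(s))) {
      stop("sequences must be non-empty strings over the 20 standard letters",
           call. = FALSE)
    }
  }
  query <- toupper(query); ref <- toupper(ref)
  S <- get_substitution_matrix(substitution_matrix)
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  r <- strsplit(ref, "", fixed = TRUE)[[1L]]
  n <- length(q); m <- length(r)
  go <- gap_open + gap_extend  # cost of opening a length-1 gap
  ge <- gap_extend
  NEG <- -Inf

  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in query (left move)
  F_ <- matrix(NEG, n + 1L, m + 1L) # gap in ref (up move)
  sub <- S[q, r, drop = FALSE]
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - go, E[i + 1L, j] - ge)
      F_[i + 1L, j + 1L] <- max(H[i, j + 1L] - go, F_[i, j + 1L] - ge)
      h <- max(0, H[i, j] + sub[i, j], E[i + 1L, j + 1L], F_[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }

  aq <- character(); ar <- character()
  if (best > 0) {
    i <- bi; j <- bj; state <- "H"
    repeat {
      if (state == "H") {
        h <- H[i + 1L, j + 1L]
        if (h == 0) break
        if (i >= 1L && j >= 1L && h == H[i, j] + sub[i, j]) {
          aq <- c(q[i], aq); ar <- c(r[j], ar)
          i <- i - 1L; j <- j - 1L
        } else if (h == F_[i + 1L, j + 1L]) {
          state <- "F"
        } else if (h == E[i + 1L, j + 1L]) {
          state <- "E"
        } else break
      } else if (state == "F") {
        aq <- c(q[i], aq); ar <- c("-", ar)
        from_h <- H[i, j + 1L] - go
        i <- i - 1L
        state <- if (F_[i + 2L, j + 1L] == from_h) "H" else "F"
      } else { # E
        aq <- c("-", aq); ar <- c(r[j], ar)
        from_h <- H[i + 1L, j] - go
        j <- j - 1L
        state <- if (E[i + 1L, j + 2L] == from_h) "H" else "E"
      }
    }
  }

  ncol_aln <- length(aq)
  nid <- sum(aq == ar & aq != "-")
  denom <- switch(identity_denominator,
    alignment = ncol_aln,
    min_length = min(n, m),
    aligned_columns = sum(aq != "-" & ar != "-")
  )
  structure(list(
    aligned_query = paste(aq, collapse = ""),
    aligned_ref = paste(ar, collapse = ""),
    score = best,
    identity_percent = if (denom > 0) 100 * nid / denom else 0,
    n_columns = ncol_aln,
    n_identical = nid
  ), class = "sw_alignment")
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %.1f, identity %.1f%% over %d columns\n",
              x$score, x$identity_percent, x$n_columns))
  if (nzchar(x$aligned_query)) {
    cat(" ", x$aligned_query, "\n ", x$aligned_ref, "\n", sep = "")
  }
  invisible(x)
}

#' Binned identity distribution per outcome category
#'
#' Summarizes percent identities into ten-point bins over `[0, 100]` —
#' half-open `[lo, hi)` except the final bin `[90, 100]` — optionally
#' grouped by the per-id outcome category from [evaluate_run()].
#'
#' @param identities Named numeric vector: percent identity per id.
#' @param outcomes Optional data frame with columns `id` and `outcome`
#'   (e.g. `evaluate_run()$outcomes`); every outcome id must have an
#'   identity.
#' @return Data frame with columns `category`, `bin_lo`, `bin_hi`,
#'   `count`, suitable for serialization as TSV.
#' @export
identity_distribution <- function(identities, outcomes = NULL) {
  stopifnot(is.numeric(identities))
  if (is.null(names(identities))) {
    stop("identities must be named by id", call. = FALSE)
  }
  if (any(identities < 0 | identities > 100)) {
    stop("identities must lie in [0, 100]", call. = FALSE)
  }
  if (is.null(outcomes)) {
    groups <- list(all = names(identities))
  } else {
    stopifnot(is.data.frame(outcomes), all(c("id", "outcome") %in% names(outcomes)))
    missing_ids <- setdiff(outcomes$id, names(identities))
    if (length(missing_ids)) {
      stop(sprintf("no identity for id(s): %s",
                   paste(missing_ids, collapse = ", ")), call. = FALSE)
    }
    groups <- split(outcomes$id, outcomes$outcome)
  }
  lo <- seq(0, 90, by = 10)
  do.call(rbind, lapply(names(groups), function(g) {
    v <- identities[groups[[g]]]
    idx <- pmin(findInterval(v, lo), 10L)  # last bin closed above at 100
    data.frame(category = g, bin_lo = lo, bin_hi = lo + 10,
               count = tabulate(idx, nbins = 10L), row.names = NULL)
  }))
}
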