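#' Synthetic fixture configuration
#'
#' Controls the generators that emulate the statistical structure the
#' pipeline assumes: KO families of point-mutated relatives, non-KO
#' random sequences, labelled embedding clusters (functionally similar
#' proteins close in embedding space), and toy CA traces.
#'
#' @param n_ko_families Number of KO families (default 20), annotated
#'   K00001, K00002, ...
#' @param members_per_family Sequences (and reference embeddings) per
#'   family (default 20).
#' @param n_nonko Number of non-KO records / far-away queries
#'   (default 200).
#' @param seq_len_range Length range in residues, uniform (default
#'   100-600).
#' @param embed_dim Embedding-space dimension (default 64).
#' @param cluster_sigma Isotropic within-cluster standard deviation
#'   (default 0.5).
#' @param centroid_separation Minimum inter-centroid distance (default 10;
#'   label-recovery fixtures need `centroid_separation / cluster_sigma`
#'   of at least 4).
#' @param mutation_rate Per-site substitution rate within a family
#'   (default 0.05).
#' @param undefined_aa_rate Fraction of records receiving one undefined
#'   letter (default 0).
#' @param duplicate_rate Expected fraction of exact duplicates injected
#'   (default 0).
#' @param seed Integer seed; every generator derives a named stream.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n_ko_families = 20L, members_per_family = 20L,
                           n_nonko = 200L, seq_len_range = c(100L, 600L),
                           embed_dim = 64L, cluster_sigma = 0.5,
                           centroid_separation = 10, mutation_rate = 0.05,
                           undefined_aa_rate = 0, duplicate_rate = 0,
                           seed = 1L) {
  assert_scalar_number(n_ko_families, "n_ko_families", lower = 1)
  assert_scalar_number(members_per_family, "members_per_family", lower = 1)
  assert_scalar_number(n_nonko, "n_nonko", lower = 0)
  stopifnot(length(seq_len_range) == 2L, seq_len_range[1L] >= 1,
            seq_len_range[2L] >= seq_len_range[1L])
  assert_scalar_number(cluster_sigma, "cluster_sigma",
                       lower = .Machine$double.xmin)
  assert_scalar_number(centroid_separation, "centroid_separation", lower = 0)
  for (r in c(mutation_rate, undefined_aa_rate, duplicate_rate)) {
    stopifnot(r >= 0, r <= 1)
  }
  structure(list(
    n_ko_families = as.integer(n_ko_families),
    members_per_family = as.integer(members_per_family),
    n_nonko = as.integer(n_nonko),
    seq_len_range = as.integer(seq_len_range),
    embed_dim = as.integer(embed_dim), cluster_sigma = cluster_sigma,
    centroid_separation = centroid_separation,
    mutation_rate = mutation_rate,
    undefined_aa_rate = undefined_aa_rate,
    duplicate_rate = duplicate_rate, seed = as.integer(seed)
  ), class = "fixture_config")
}

random_aa_seq <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

# uniform integer draw that is safe when lo == hi (avoids sample()'s
# scalar-first-argument behaviour)
draw_len <- function(range) {
  if (range[1L] == range[2L]) range[1L]
  else sample(range[1L]:range[2L], 1L)
}

mutate_seq <- function(sequence, rate) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Generate synthetic sequence records with truth annotations
#'
#' Per family, a seeded ancestor sequence is sampled and members derive
#' from it by uniform point substitutions (no indels), all annotated with
#' the family's K number. Non-KO records are independent uniform random
#' sequences with empty annotation sets. Optionally, undefined letters and
#' exact duplicates are injected at the configured rates. Bit-reproducible
#' given the seed.
#'
#' @param cfg A [fixture_config()].
#' @return List with `records` (list of [seq_record()]) and `truth`
#'   (named list id to K-number set, the [read_annotation_table()] shape).
#' @export
make_sequences <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(op_seed(cfg$seed, "sequences"))
  records <- list()
  for (f in seq_len(cfg$n_ko_families)) {
    ko <- sprintf("K%05d", f)
    len <- draw_len(cfg$seq_len_range)
    ancestor <- random_aa_seq(len)
    for (m in seq_len(cfg$members_per_family)) {
      s <- if (m == 1L) ancestor else mutate_seq(ancestor, cfg$mutation_rate)
      records[[length(records) + 1L]] <-
        seq_record(sprintf("syn:F%03d_%03d", f, m), s, ko)
    }
  }
  for (i in seq_len(cfg$n_nonko)) {
    len <- draw_len(cfg$seq_len_range)
    records[[length(records) + 1L]] <-
      seq_record(sprintf("syn:N%04d", i), random_aa_seq(len))
  }
  if (cfg$undefined_aa_rate > 0) {
    hit <- which(stats::runif(length(records)) < cfg$undefined_aa_rate)
    for (i in hit) {
      r <- records[[i]]
      pos <- sample.int(nchar(r$sequence), 1L)
      substr(r$sequence, pos, pos) <- sample(c("X", "B", "Z", "U", "O", "J"), 1L)
      records[[i]] <- r
    }
  }
  if (cfg$duplicate_rate > 0) {
    n_dup <- stats::rbinom(1L, length(records), cfg$duplicate_rate)
    src <- sample(seq_along(records), n_dup, replace = TRUE)
    for (k in seq_along(src)) {
      r <- records[[src[k]]]
      records[[length(records) + 1L]] <-
        seq_record(sprintf("syn:D%04d", k), r$sequence, r$annotations)
    }
  }
  truth <- stats::setNames(lapply(records, function(r) r$annotations),
                           record_ids(records))
  list(records = records, truth = truth)
}

#' Generate labelled embedding clusters
#'
#' Emulates the premise that functionally related proteins lie close in
#' embedding space: one well-separated centroid per KO family, reference
#' and query vectors drawn as centroid plus isotropic Gaussian noise, and
#' non-KO queries placed at least three separations away from every
#' centroid.
#'
#' @param cfg A [fixture_config()].
#' @param queries_per_family Query vectors drawn per family (default:
#'   `members_per_family`).
#' @return List with `reference` (list `ids`, `embeddings`, `annotations`
#'   ready for [build_index()]) and `queries` (list `ids`, `embeddings`,
#'   `truth`; non-KO queries have empty truth sets).
#' @export
make_embedding_clusters <- function(cfg = fixture_config(),
                                    queries_per_family = cfg$members_per_family) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(op_seed(cfg$seed, "clusters"))
  k <- cfg$n_ko_families
  d <- cfg$embed_dim
  sep <- cfg$centroid_separation

  centroids <- NULL
  for (try in seq_len(200L)) {
    cand <- matrix(stats::rnorm(k * d, sd = sep), k, d)
    if (k == 1L || min(stats::dist(cand)) >= sep) { centroids <- cand; break }
  }
  if (is.null(centroids)) {
    stop("could not place mutually separated centroids; increase embed_dim or lower centroid_separation",
         call. = FALSE)
  }

  draw <- function(center, n) {
    matrix(stats::rnorm(n * d, sd = cfg$cluster_sigma), n, d) +
      matrix(center, n, d, byrow = TRUE)
  }

  ref_ids <- character(); ref_rows <- list(); ref_ann <- list()
  q_ids <- character(); q_rows <- list(); q_truth <- list()
  for (f in seq_len(k)) {
    ko <- sprintf("K%05d", f)
    R <- draw(centroids[f, ], cfg$members_per_family)
    ids <- sprintf("ref:F%03d_%03d", f, seq_len(cfg$members_per_family))
    ref_ids <- c(ref_ids, ids)
    ref_rows[[f]] <- R
    for (id in ids) ref_ann[[id]] <- ko
    Q <- draw(centroids[f, ], queries_per_family)
    qids <- sprintf("qry:F%03d_%03d", f, seq_len(queries_per_family))
    q_ids <- c(q_ids, qids)
    q_rows[[length(q_rows) + 1L]] <- Q
    for (id in qids) q_truth[[id]] <- ko
  }
  # non-KO queries: at least 3 separations from every centroid
  if (cfg$n_nonko > 0L) {
    far <- matrix(NA_real_, cfg$n_nonko, d)
    for (i in seq_len(cfg$n_nonko)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        dir <- stats::rnorm(d)
        dir <- dir / sqrt(sum(dir^2))
        pt <- colMeans(centroids) + dir * (4 * sep * sqrt(d))
        if (min(sqrt(colSums((t(centroids) - pt)^2))) >= 3 * sep) {
          far[i, ] <- pt; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place a far non-KO query", call. = FALSE)
    }
    qids <- sprintf("qry:N%04d", seq_len(cfg$n_nonko))
    q_ids <- c(q_ids, qids)
    q_rows[[length(q_rows) + 1L]] <- far
    for (id in qids) q_truth[[id]] <- character()
  }

  ref_m <- do.call(rbind, ref_rows); rownames(ref_m) <- ref_ids
  q_m <- do.call(rbind, q_rows); rownames(q_m) <- q_ids
  list(
    reference = list(ids = ref_ids, embeddings = ref_m,
                     annotations = ref_ann),
    queries = list(ids = q_ids, embeddings = q_m, truth = q_truth)
  )
}

#' Generate a toy CA-trace pair with known correspondence
#'
#' The target is a random extended 3-D walk with exact 3.8-angstrom bonds
#' (consecutive step directions are correlated so the chain stays
#' extended); the template is a rigid motion of the target plus optional
#' per-atom Gaussian jitter; the correspondence is the identity.
#'
#' @param cfg A [fixture_config()] (supplies the seed).
#' @param n_residues Chain length (default 100).
#' @param jitter_sigma Per-atom Gaussian jitter in angstroms (default 0).
#' @return List with `target`, `template` ([ca_trace()] objects) and
#'   `correspondence` (two-column index matrix).
#' @export
make_toy_structures <- function(cfg = fixture_config(), n_residues = 100L,
                                jitter_sigma = 0) {
  stopifnot(inherits(cfg, "fixture_config"))
  assert_scalar_number(n_residues, "n_residues", lower = 2)
  assert_scalar_number(jitter_sigma, "jitter_sigma", lower = 0)
  set.seed(op_seed(cfg$seed, "structures"))
  n <- as.integer(n_residues)
  coords <- matrix(0, n, 3L)
  dir <- stats::rnorm(3L); dir <- dir / sqrt(sum(dir^2))
  for (i in 2:n) {
    dir <- dir + 0.4 * stats::rnorm(3L)
    dir <- dir / sqrt(sum(dir^2))
    coords[i, ] <- coords[i - 1L, ] + 3.8 * dir
  }
  target <- ca_trace("toy_target", coords)

  # random proper rotation from the QR decomposition of a Gaussian matrix
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  shift <- stats::rnorm(3L, sd = 20)
  tmpl <- coords %*% R + matrix(shift, n, 3L, byrow = TRUE)
  if (jitter_sigma > 0) {
    tmpl <- tmpl + matrix(stats::rnorm(3L * n, sd = jitter_sigma), n, 3L)
  }
  list(
    target = target,
    template = ca_trace("toy_template", tmpl),
    correspondence = cbind(seq_len(n), seq_len(n))
  )
}
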