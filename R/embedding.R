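#' Sequence-embedder specification
#'
#' The pipeline consumes per-sequence embeddings through a pluggable
#' contract. Two implementations ship: `"mock"`, a deterministic seeded
#' k-mer-hash embedder suitable for desk-scale testing, and `"plm"`, an
#' adapter slot for a pre-trained protein language model supplied by the
#' user as a function returning per-residue hidden states. Pooling over
#' per-residue vectors applies identically to both.
#'
#' @param name `"mock"` or `"plm"`.
#' @param dim Embedding dimension (mock default 64; for `"plm"` the
#'   dimension is discovered from the model output and `dim` may be `NA`).
#' @param pooling Pooling operator over per-residue vectors: `"mean"`
#'   (default), `"max"` or `"first"`.
#' @param kmer_size k-mer length for the mock embedder (default 3).
#' @param seed Seed for the mock embedder's hash directions.
#' @param plm_fun For `"plm"`: a function `function(sequence)` returning an
#'   `L x dim` numeric matrix of per-residue states (deterministic in eval
#'   mode). Ignored for `"mock"`.
#' @return An object of class `embedder_spec`.
#' @export
embedder_spec <- function(name = c("mock", "plm"), dim = 64L,
                          pooling = c("mean", "max", "first"),
                          kmer_size = 3L, seed = 1L, plm_fun = NULL) {
  name <- match.arg(name)
  pooling <- match.arg(pooling)
  if (name == "mock") {
    assert_scalar_number(dim, "dim", lower = 2)
    assert_scalar_number(kmer_size, "kmer_size", lower = 1)
  }
  structure(list(
    name = name, dim = if (name == "mock") as.integer(dim) else dim,
    pooling = pooling, kmer_size = as.integer(kmer_size),
    seed = as.integer(seed), plm_fun = plm_fun,
    cache = new.env(parent = emptyenv())
  ), class = "embedder_spec")
}

#' Deterministic direction vector for a k-mer
#'
#' The mock embedder maps each k-mer to a fixed unit direction in
#' `R^dim` derived from a stable seeded string hash (FNV-1a), so the mapping
#' is bit-reproducible across platforms and sessions.
#'
#' @param kmer k-mer string over the 20 standard letters.
#' @param spec An [embedder_spec()] with `name = "mock"`.
#' @return Unit-length numeric vector of length `spec$dim`.
#' @export
kmer_direction <- function(kmer, spec) {
  stopifnot(inherits(spec, "embedder_spec"), spec$name == "mock")
  key <- paste0("dir:", kmer)
  cached <- spec$cache[[key]]
  if (!is.null(cached)) return(cached)
  u <- vapply(seq_len(spec$dim), function(j) {
    hash_unif(sprintf("%s|%d|%d", kmer, spec$seed, j))
  }, numeric(1))
  v <- stats::qnorm(u)
  v <- v / sqrt(sum(v^2))
  spec$cache[[key]] <- v
  v
}

# Per-residue matrix for the mock embedder: residue i carries the sum of the
# directions of every k-mer window covering it. Sequences shorter than the
# k-mer size yield all-zero rows.
mock_residue_matrix <- function(sequence, spec) {
  L <- nchar(sequence)
  k <- spec$kmer_size
  M <- matrix(0, nrow = L, ncol = spec$dim)
  nwin <- L - k + 1L
  if (nwin >= 1L) {
    D <- t(vapply(seq_len(nwin), function(s) {
      kmer_direction(substr(sequence, s, s + k - 1L), spec)
    }, numeric(spec$dim)))
    # residue i is covered by windows starting in [i-k+1, i] (clipped);
    # prefix sums give each residue's covering-window sum in O(L * dim)
    cs <- rbind(0, apply(D, 2L, cumsum))
    for (i in seq_len(L)) {
      lo <- max(1L, i - k + 1L)
      hi <- min(i, nwin)
      if (lo <= hi) M[i, ] <- cs[hi + 1L, ] - cs[lo, ]
    }
  }
  M
}

pool_residue_matrix <- function(M, pooling) {
  switch(pooling,
    mean = colMeans(M),
    max = apply(M, 2L, max),
    first = M[1L, ]
  )
}

#' Embed one protein sequence
#'
#' Produces a fixed-dimension numeric vector for a sequence. Deterministic:
#' identical `(sequence, spec)` always yields an identical vector. For the
#' mock embedder, each overlapping k-mer is hashed to a fixed unit direction,
#' per-residue vectors sum the directions of the k-mers covering that
#' residue, and the sequence vector is the configured pooling of the
#' per-residue vectors. For the `"plm"` adapter, the supplied model function
#' provides the per-residue states and the same pooling applies.
#'
#' @param sequence Non-empty string over the 20 standard one-letter codes.
#' @param spec An [embedder_spec()].
#' @return Numeric vector of length `spec$dim`, all values finite.
#' @export
embed_sequence <- function(sequence, spec = embedder_spec()) {
  stopifnot(inherits(spec, "embedder_spec"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence)) {
    stop(sprintf("sequence contains letters outside the 20 standard codes: %s",
                 gsub("[ACDEFGHIKLMNPQRSTVWY]", "", sequence)), call. = FALSE)
  }
  if (spec$name == "mock") {
    M <- mock_residue_matrix(sequence, spec)
  } else {
    if (!is.function(spec$plm_fun)) {
      stop(paste0(
        "the 'plm' embedder requires plm_fun: a function(sequence) returning ",
        "an L x dim matrix of per-residue hidden states"), call. = FALSE)
    }
    M <- spec$plm_fun(sequence)
    if (!is.matrix(M) || nrow(M) != nchar(sequence) || !all(is.finite(M))) {
      stop("plm_fun must return a finite L x dim matrix (L = sequence length)",
           call. = FALSE)
    }
    if (!is.na(spec$dim) && ncol(M) != spec$dim) {
      stop(sprintf("plm_fun returned dimension %d, spec says %d",
                   ncol(M), spec$dim), call. = FALSE)
    }
  }
  pool_residue_matrix(M, spec$pooling)
}

#' Embed a batch of sequence records
#'
#' Order-preserving, id-aligned map of [embed_sequence()] over a record
#' list; progress is reported every 1000 records.
#'
#' @param records List of [seq_record()] objects.
#' @param spec An [embedder_spec()].
#' @return Numeric matrix, one row per record, record ids as row names.
#' @export
embed_batch <- function(records, spec = embedder_spec()) {
  validate_records(records)
  if (!length(records)) {
    d <- if (is.na(spec$dim)) 0L else spec$dim
    return(matrix(numeric(), nrow = 0L, ncol = d))
  }
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rows[[i]] <- tryCatch(
      embed_sequence(records[[i]]$sequence, spec),
      error = function(e) {
        stop(sprintf("embedding failed for record '%s': %s",
                     records[[i]]$id, conditionMessage(e)), call. = FALSE)
      })
    if (i %% 1000L == 0L) {
      message(sprintf("embed_batch: %d / %d", i, length(records)))
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- record_ids(records)
  m
}
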