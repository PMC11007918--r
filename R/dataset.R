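#' Dataset construction configuration
#'
#' Parameters controlling the data-construction rules: length filtering,
#' KO/non-KO length-distribution balancing, and train/test splitting.
#'
#' @param min_len,max_len Inclusive length bounds in residues (defaults 100
#'   and 600). Sequences strictly shorter than `min_len` or strictly longer
#'   than `max_len` are removed.
#' @param split_fraction Fraction of records assigned to the training set
#'   (default 0.8, i.e. an 8:2 train/test split).
#' @param balance_tolerance Maximum allowed per-bin absolute difference
#'   between the KO and non-KO length distributions (default 0.05).
#' @param length_bin_width Width in residues of the length-histogram bins
#'   used for balancing (default 50).
#' @param seed Integer seed; every stochastic operation derives its own
#'   named stream from it.
#' @return An object of class `dataset_config`.
#' @export
dataset_config <- function(min_len = 100L, max_len = 600L,
                           split_fraction = 0.8, balance_tolerance = 0.05,
                           length_bin_width = 50L, seed = 1L) {
  assert_scalar_number(min_len, "min_len", lower = 1)
  assert_scalar_number(max_len, "max_len", lower = min_len)
  assert_scalar_number(split_fraction, "split_fraction")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  assert_scalar_number(balance_tolerance, "balance_tolerance")
  if (balance_tolerance <= 0) stop("balance_tolerance must be > 0", call. = FALSE)
  assert_scalar_number(length_bin_width, "length_bin_width", lower = 1)
  structure(list(
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    split_fraction = split_fraction, balance_tolerance = balance_tolerance,
    length_bin_width = as.integer(length_bin_width), seed = as.integer(seed)
  ), class = "dataset_config")
}

#' Filter sequence records by length
#'
#' Retains records whose length L satisfies `min_len <= L <= max_len`
#' (boundary lengths are kept: only strictly shorter/longer sequences are
#' removed). Order is preserved and the removal count is reported via
#' `message()`.
#'
#' @param records List of [seq_record()] objects.
#' @param cfg A [dataset_config()].
#' @return The retained records.
#' @export
filter_by_length <- function(records, cfg = dataset_config()) {
  validate_records(records)
  len <- record_lengths(records)
  keep <- len >= cfg$min_len & len <= cfg$max_len
  message(sprintf("filter_by_length: removed %d of %d records (length outside [%d, %d])",
                  sum(!keep), length(records), cfg$min_len, cfg$max_len))
  records[keep]
}

#' Remove sequences containing undefined amino acids
#'
#' Drops records whose sequence contains any letter outside the 20 standard
#' one-letter codes (e.g. X, B, Z, U, O, J).
#'
#' @param records List of [seq_record()] objects.
#' @return The retained records, order preserved.
#' @export
remove_undefined <- function(records) {
  validate_records(records)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", record_seqs(records))
  message(sprintf("remove_undefined: removed %d of %d records (undefined amino acids)",
                  sum(bad), length(records)))
  records[!bad]
}

#' De-duplicate records by sequence, resolving annotation conflicts
#'
#' One record is kept per distinct sequence string: the id of the first
#' occurrence, with the union of all K numbers seen for that sequence. An
#' annotated copy therefore always wins over an unannotated copy; two copies
#' carrying distinct K numbers keep both (downstream evaluation treats truth
#' as a set).
#'
#' @param records List of [seq_record()] objects.
#' @return De-duplicated records in first-occurrence order.
#' @export
deduplicate <- function(records) {
  validate_records(records)
  seqs <- record_seqs(records)
  first_idx <- which(!duplicated(seqs))
  ann_by_seq <- new.env(parent = emptyenv())
  for (r in records) {
    cur <- ann_by_seq[[r$sequence]] %||% character()
    ann_by_seq[[r$sequence]] <- union(cur, r$annotations)
  }
  out <- lapply(first_idx, function(i) {
    r <- records[[i]]
    seq_record(r$id, r$sequence, ann_by_seq[[r$sequence]])
  })
  message(sprintf("deduplicate: %d of %d records kept", length(out),
                  length(records)))
  out
}

bin_breaks <- function(cfg) {
  # consecutive bins of length_bin_width covering [min_len, max_len]
  b <- seq(cfg$min_len, cfg$max_len, by = cfg$length_bin_width)
  if (b[length(b)] < cfg$max_len) b <- c(b, cfg$max_len)
  b
}

bin_of <- function(lengths, cfg) {
  breaks <- bin_breaks(cfg)
  # bins are [lo, lo+w) except the last, which is closed above
  idx <- findInterval(lengths, breaks, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(breaks) - 1L)
}

#' Check KO/non-KO length-distribution balance
#'
#' Bins lengths into consecutive bins of `length_bin_width` residues over
#' `[min_len, max_len]` and reports the maximum over bins of the absolute
#' difference between the two classes' length distributions (each class's
#' per-bin proportions sum to one). The check passes when that maximum
#' deviation is strictly below `balance_tolerance`.
#'
#' @param ko_records,nonko_records Non-empty lists of [seq_record()] objects.
#' @param cfg A [dataset_config()].
#' @return List with `deviation` (max per-bin absolute difference), `pass`
#'   (logical) and `table` (per-bin counts and proportions).
#' @export
check_length_balance <- function(ko_records, nonko_records,
                                 cfg = dataset_config()) {
  if (!length(ko_records) || !length(nonko_records)) {
    stop("both KO and non-KO record sets must be non-empty", call. = FALSE)
  }
  breaks <- bin_breaks(cfg)
  nbin <- length(breaks) - 1L
  kbin <- tabulate(bin_of(record_lengths(ko_records), cfg), nbins = nbin)
  nbin_counts <- tabulate(bin_of(record_lengths(nonko_records), cfg),
                          nbins = nbin)
  pk <- kbin / sum(kbin)
  pn <- nbin_counts / sum(nbin_counts)
  dev <- max(abs(pk - pn))
  list(
    deviation = dev,
    pass = dev < cfg$balance_tolerance,
    table = data.frame(
      bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
      n_ko = kbin, n_nonko = nbin_counts, prop_ko = pk, prop_nonko = pn
    )
  )
}

#' Balance length distributions by per-bin down-sampling
#'
#' Repeatedly finds the length bin with the largest distribution deviation
#' and uniformly down-samples (seeded) the over-represented class in that
#' bin until [check_length_balance()] passes. The removal count per step is
#' the closed-form solution of equalizing the bin's proportions given the
#' shrinking class total. Deterministic given `cfg$seed`.
#'
#' @param ko_records,nonko_records Non-empty lists of [seq_record()] objects.
#' @param cfg A [dataset_config()].
#' @return List with elements `ko` and `nonko`: the down-sampled record
#'   lists (original order preserved).
#' @export
rebalance_by_downsampling <- function(ko_records, nonko_records,
                                      cfg = dataset_config()) {
  set.seed(op_seed(cfg$seed, "rebalance"))
  classes <- list(ko = ko_records, nonko = nonko_records)
  breaks <- bin_breaks(cfg)
  max_steps <- length(ko_records) + length(nonko_records)
  for (step in seq_len(max_steps)) {
    rep <- check_length_balance(classes$ko, classes$nonko, cfg)
    if (rep$pass) break
    tab <- rep$table
    b <- which.max(abs(tab$prop_ko - tab$prop_nonko))
    over <- if (tab$prop_ko[b] > tab$prop_nonko[b]) "ko" else "nonko"
    under <- setdiff(c("ko", "nonko"), over)
    p_under <- if (under == "ko") tab$prop_ko[b] else tab$prop_nonko[b]
    if (p_under == 0) {
      stop(sprintf(
        "cannot balance: length bin [%d, %d] is populated only in the %s class (proportion %.3f >= tolerance %.3f)",
        tab$bin_lo[b], tab$bin_hi[b], over,
        max(tab$prop_ko[b], tab$prop_nonko[b]), cfg$balance_tolerance),
        call. = FALSE)
    }
    n_over <- length(classes[[over]])
    k_over <- if (over == "ko") tab$n_ko[b] else tab$n_nonko[b]
    # ceiling with a small slack so an exact-integer solution is not
    # bumped up by floating-point error
    r <- ceiling((k_over - p_under * n_over) / (1 - p_under) - 1e-9)
    r <- min(max(r, 1L), k_over - 1L)
    in_bin <- which(bin_of(record_lengths(classes[[over]]), cfg) == b)
    drop <- in_bin[sample.int(length(in_bin), r)]
    classes[[over]] <- classes[[over]][-drop]
  }
  rep <- check_length_balance(classes$ko, classes$nonko, cfg)
  if (!rep$pass) {
    stop("rebalance_by_downsampling failed to reach the configured tolerance",
         call. = FALSE)
  }
  message(sprintf(
    "rebalance_by_downsampling: kept %d KO / %d non-KO (deviation %.4f)",
    length(classes$ko), length(classes$nonko), rep$deviation))
  list(ko = classes$ko, nonko = classes$nonko)
}

#' Split records into training and testing sets
#'
#' Seeded uniform shuffle followed by a split at
#' `floor(split_fraction * N)`: an exact partition (no overlap, union equals
#' the input).
#'
#' @param records List of at least two [seq_record()] objects.
#' @param cfg A [dataset_config()].
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(records, cfg = dataset_config()) {
  validate_records(records)
  n <- length(records)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  set.seed(op_seed(cfg$seed, "split"))
  perm <- sample.int(n)
  ntrain <- floor(cfg$split_fraction * n)
  list(train = records[perm[seq_len(ntrain)]],
       test = records[perm[-seq_len(ntrain)]])
}

#' Exclude records from held-out species
#'
#' Drops every record whose id starts with one of the organism prefixes
#' (prefix + `":"`), and additionally any record whose sequence string is
#' identical to a dropped record's sequence — the protocol used to hold two
#' species out of the classifier's training data.
#'
#' @param records List of [seq_record()] objects.
#' @param species_prefixes Character vector of KEGG organism prefixes, e.g.
#'   `c("bjp", "parb")`.
#' @return The retained records, order preserved.
#' @export
exclude_species <- function(records, species_prefixes) {
  validate_records(records)
  if (!length(species_prefixes)) return(records)
  ids <- record_ids(records)
  pat <- paste0("^(", paste(species_prefixes, collapse = "|"), "):")
  direct <- grepl(pat, ids)
  dropped_seqs <- unique(record_seqs(records)[direct])
  keep <- !direct & !(record_seqs(records) %in% dropped_seqs)
  message(sprintf("exclude_species: removed %d of %d records",
                  sum(!keep), length(records)))
  records[keep]
}

#' Apply the full data-construction pipeline
#'
#' Convenience composition: length filter, undefined-residue removal,
#' de-duplication, KO/non-KO balancing, and the train/test split applied to
#' each class.
#'
#' @param records List of [seq_record()] objects (annotations attached).
#' @param cfg A [dataset_config()].
#' @return List with `train`, `test` (record lists) and `report` (counts and
#'   balance deviation).
#' @export
build_dataset <- function(records, cfg = dataset_config()) {
  n0 <- length(records)
  recs <- filter_by_length(records, cfg)
  n_len <- length(recs)
  recs <- remove_undefined(recs)
  n_def <- length(recs)
  recs <- deduplicate(recs)
  n_dedup <- length(recs)
  is_ko <- record_is_ko(recs)
  bal <- rebalance_by_downsampling(recs[is_ko], recs[!is_ko], cfg)
  rep <- check_length_balance(bal$ko, bal$nonko, cfg)
  all_recs <- c(bal$ko, bal$nonko)
  split <- split_train_test(all_recs, cfg)
  list(
    train = split$train, test = split$test,
    report = list(
      n_input = n0,
      n_removed_length = n0 - n_len,
      n_removed_undefined = n_len - n_def,
      n_removed_duplicate = n_def - n_dedup,
      n_removed_balance = n_dedup - length(all_recs),
      n_ko = length(bal$ko), n_nonko = length(bal$nonko),
      balance_deviation = rep$deviation,
      n_train = length(split$train), n_test = length(split$test)
    )
  )
}
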