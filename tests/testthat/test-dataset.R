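cfg_default <- dataset_config()

test_that("length filtering keeps boundary lengths and removes strict outliers", {
  recs <- make_records(vapply(c(99L, 100L, 350L, 600L, 601L), rand_seq,
                              character(1)))
  suppressMessages(kept <- filter_by_length(recs, cfg_default))
  expect_equal(record_lengths(kept), c(100L, 350L, 600L))
  # all-in-range input is the identity
  suppressMessages(expect_identical(filter_by_length(kept, cfg_default), kept))
})

test_that("undefined amino-acid removal drops exactly the tainted records", {
  set.seed(21)
  n <- 10000L
  seqs <- vapply(rep(10L, n), rand_seq, character(1))
  bad_idx <- sample(n, 7L)
  for (i in bad_idx) substr(seqs[i], 5L, 5L) <- "X"
  recs <- make_records(seqs)
  suppressMessages(kept <- remove_undefined(recs))
  expect_equal((n - length(kept)) / n, 0.0007)
  expect_false(any(grepl("X", record_seqs(kept))))
  suppressMessages(expect_length(remove_undefined(make_records("MKXV")), 0L))
  suppressMessages(expect_length(remove_undefined(make_records("MKV")), 1L))
})

test_that("deduplication keeps first id and unions annotations (K number wins over none)", {
  recs <- list(
    seq_record("a1", "MKVLH", "K02030"),
    seq_record("a2", "MKVLH"),                 # unannotated copy
    seq_record("b1", "GGHAA", "K00001"),
    seq_record("b2", "GGHAA", "K00002"),       # conflicting K copy
    seq_record("c1", "TTTTT")
  )
  suppressMessages(out <- deduplicate(recs))
  expect_equal(record_ids(out), c("a1", "b1", "c1"))
  expect_setequal(out[[1]]$annotations, "K02030")
  expect_setequal(out[[2]]$annotations, c("K00001", "K00002"))
  expect_length(out[[3]]$annotations, 0L)
  # all-distinct input is the identity
  suppressMessages(expect_equal(deduplicate(out), out))
})

test_that("length-balance deviation matches a hand-computed per-bin maximum", {
  lens_ko <- c(rep(120L, 30), rep(170L, 50), rep(520L, 20))
  lens_nk <- c(rep(120L, 10), rep(170L, 25), rep(520L, 15))
  ko <- make_records(vapply(lens_ko, rand_seq, character(1)),
                     ids = sprintf("k%03d", seq_along(lens_ko)))
  nk <- make_records(vapply(lens_nk, rand_seq, character(1)),
                     ids = sprintf("n%03d", seq_along(lens_nk)))
  rep_ <- check_length_balance(ko, nk, cfg_default)
  # brute force: proportions per 50-wide bin
  p_ko <- c(30, 50, 20) / 100
  p_nk <- c(10, 25, 15) / 50
  expect_equal(rep_$deviation, max(abs(p_ko - p_nk)))
  expect_false(rep_$pass)

  # identical length multisets: zero deviation
  rep0 <- check_length_balance(ko, ko, cfg_default)
  expect_equal(rep0$deviation, 0)
  expect_true(rep0$pass)

  # disjoint supports: deviation 1
  ko1 <- make_records(vapply(rep(150L, 5), rand_seq, character(1)),
                      ids = paste0("x", 1:5))
  nk1 <- make_records(vapply(rep(550L, 5), rand_seq, character(1)),
                      ids = paste0("y", 1:5))
  rep1 <- check_length_balance(ko1, nk1, cfg_default)
  expect_equal(rep1$deviation, 1)
  expect_false(rep1$pass)

  expect_error(check_length_balance(list(), nk, cfg_default), "non-empty")
})

test_that("down-sampling equalizes a 2:1 bin by halving the larger class", {
  ko <- make_records(vapply(c(rep(120L, 100), rep(170L, 100)), rand_seq,
                            character(1)), ids = sprintf("k%03d", 1:200))
  nk <- make_records(vapply(c(rep(120L, 50), rep(170L, 100)), rand_seq,
                            character(1)), ids = sprintf("n%03d", 1:150))
  suppressMessages(bal <- rebalance_by_downsampling(ko, nk, cfg_default))
  expect_true(check_length_balance(bal$ko, bal$nonko, cfg_default)$pass)
  lens <- record_lengths(bal$ko)
  expect_equal(sum(lens == 120L), 50L)   # larger class halved in that bin
  expect_equal(sum(lens == 170L), 100L)
  expect_equal(length(bal$nonko), 150L)

  # already balanced input is unchanged
  suppressMessages(bal2 <- rebalance_by_downsampling(bal$ko, bal$nonko,
                                                     cfg_default))
  expect_equal(record_ids(bal2$ko), record_ids(bal$ko))
  expect_equal(record_ids(bal2$nonko), record_ids(bal$nonko))

  # determinism: same seed, same output
  suppressMessages(bal3 <- rebalance_by_downsampling(ko, nk, cfg_default))
  expect_identical(record_ids(bal3$ko), record_ids(bal$ko))
})

test_that("down-sampling errors when a bin exists in only one class", {
  ko <- make_records(vapply(c(rep(120L, 60), rep(170L, 40)), rand_seq,
                            character(1)), ids = sprintf("k%03d", 1:100))
  nk <- make_records(vapply(rep(170L, 50), rand_seq, character(1)),
                     ids = sprintf("n%03d", 1:50))
  expect_error(
    suppressMessages(rebalance_by_downsampling(ko, nk, cfg_default)),
    "populated only in the ko class")
})

test_that("train/test split is an exact seeded 8:2 partition", {
  recs <- make_records(vapply(rep(150L, 10), rand_seq, character(1)))
  sp <- split_train_test(recs, cfg_default)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_setequal(c(record_ids(sp$train), record_ids(sp$test)),
                  record_ids(recs))
  expect_length(intersect(record_ids(sp$train), record_ids(sp$test)), 0L)

  sp5 <- split_train_test(recs[1:5], cfg_default)
  expect_length(sp5$train, 4L)
  expect_length(sp5$test, 1L)

  sp2 <- split_train_test(recs, cfg_default)
  expect_identical(record_ids(sp2$train), record_ids(sp$train))

  expect_error(split_train_test(recs[1], cfg_default), "at least 2")
})

test_that("species exclusion drops prefixed ids and identical sequences", {
  shared <- rand_seq(120)
  recs <- list(
    seq_record("bjp:x", shared, "K00001"),
    seq_record("eco:y", shared),            # identical to a dropped sequence
    seq_record("eco:z", rand_seq(120)),
    seq_record("parb:w", rand_seq(130))
  )
  suppressMessages(kept <- exclude_species(recs, c("bjp", "parb")))
  expect_equal(record_ids(kept), "eco:z")
  suppressMessages(expect_identical(exclude_species(recs, character()), recs))
})

test_that("the cleaning pipeline (filter, undefined, dedup) is idempotent", {
  set.seed(33)
  seqs <- c(vapply(sample(80:650, 40, replace = TRUE), rand_seq, character(1)))
  seqs <- c(seqs, seqs[1:5])                       # duplicates
  seqs[10] <- paste0(substr(seqs[10], 1, 50), "X") # undefined letter
  recs <- make_records(seqs)
  clean <- function(r) {
    suppressMessages(deduplicate(remove_undefined(filter_by_length(r, cfg_default))))
  }
  once <- clean(recs)
  twice <- clean(once)
  expect_equal(record_ids(twice), record_ids(once))
  expect_equal(record_seqs(twice), record_seqs(once))
})
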