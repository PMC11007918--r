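test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(71)
  A <- matrix(rnorm(60), 20, 3)
  fit0 <- kabsch_superpose(A, A)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)

  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% Rz + matrix(c(1, 2, 3), 20, 3, byrow = TRUE)
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(A %*% fit$rotation +
                 matrix(fit$translation, 20, 3, byrow = TRUE),
               B, tolerance = 1e-9)

  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "at least 3")
  expect_warning(kabsch_superpose(cbind(1:5, 0, 0), cbind(2 * (1:5), 0, 0)),
                 "degenerate")
})

test_that("least-squares RMSD matches a numerical optimizer over rotations", {
  set.seed(73)
  for (rep_ in 1:3) {
    A <- matrix(rnorm(150), 50, 3)
    B <- matrix(rnorm(150), 50, 3)
    fit <- kabsch_superpose(A, B)
    expect_equal(fit$rmsd, optim_superpose_rmsd(A, B), tolerance = 1e-6)
  }
})

test_that("the d0 scale follows its cube-root formula with a 0.5 A floor", {
  expect_equal(d0_scale(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(d0_scale(100), 3.652, tolerance = 1e-3)
  expect_equal(d0_scale(15), 0.5)
  expect_equal(d0_scale(1), 0.5)
  expect_equal(d0_scale(21), 0.5)  # formula still below the floor here
  v <- vapply(16:1000, d0_scale, numeric(1))
  expect_true(all(diff(v) >= 0))
  expect_error(d0_scale(0), "L_target")
})

test_that("TM-score is exactly 1 for identical traces and rigid-motion invariant", {
  set.seed(79)
  fx <- make_toy_structures(fixture_config(seed = 79L), n_residues = 60L)
  tr <- fx$target
  expect_equal(tm_score(tr, tr)$tm_score, 1)

  res <- tm_score(fx$target, fx$template, fx$correspondence)
  # apply one further common rigid motion to both structures
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -3, 11)
  move <- function(t) ca_trace(t$id, t$coords %*% R +
                                 matrix(shift, nrow(t$coords), 3, byrow = TRUE))
  res2 <- tm_score(move(fx$target), move(fx$template), fx$correspondence)
  expect_equal(res2$tm_score, res$tm_score, tolerance = 1e-9)
})

test_that("a single pair at distance d0 scores 0.5/L_target", {
  L <- 20L
  d0 <- d0_scale(L)
  target <- ca_trace("t", cbind(seq_len(L) * 3.8, 0, 0))
  template <- ca_trace("m", cbind(seq_len(L) * 3.8, d0, 0))
  res <- suppressWarnings(tm_score(target, template,
                                   correspondence = cbind(1L, 1L)))
  expect_equal(res$tm_score, 0.5 / L, tolerance = 1e-12)
  expect_equal(res$L_common, 1L)
  expect_warning(tm_score(target, template, correspondence = cbind(1L, 1L)),
                 "fewer than 3")
})

test_that("TM-score strictly decreases when one pair distance grows", {
  set.seed(83)
  coords <- matrix(rnorm(90) * 5, 30, 3)
  target <- ca_trace("t", coords)
  scores <- vapply(c(0, 1, 2, 4, 8), function(delta) {
    shifted <- coords
    shifted[7, 1] <- shifted[7, 1] + delta
    tm_score(target, ca_trace("m", shifted), superpose = FALSE)$tm_score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("similarity interpretation bands follow the 0.5/0.8 conventions", {
  tr <- ca_trace("t", matrix(rnorm(90), 30, 3))
  expect_equal(tm_score(tr, tr)$interpretation, "highly similar structures")
  fx <- make_toy_structures(fixture_config(seed = 89L), n_residues = 50L,
                            jitter_sigma = 2)
  res <- tm_score(fx$target, fx$template, fx$correspondence)
  expect_equal(res$interpretation,
               if (res$tm_score >= 0.8) "highly similar structures"
               else if (res$tm_score >= 0.5) "similar structural domains"
               else "dissimilar structural domains")
})

test_that("Smith-Waterman matches the reference aligner's score on random pairs", {
  suppressMessages(requireNamespace("Biostrings", quietly = TRUE))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(97)
  for (i in 1:50) {
    q <- rand_seq(30); r <- rand_seq(30)
    mine <- smith_waterman(q, r)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(r),
      substitutionMatrix = e$BLOSUM62, gapOpening = 10, gapExtension = 0.5,
      type = "local")
    expect_equal(mine$score, Biostrings::score(ref), tolerance = 1e-9)
  }
})

test_that("Smith-Waterman identity conventions behave as documented", {
  s <- rand_seq(40)
  self <- smith_waterman(s, s)
  expect_equal(self$identity_percent, 100)
  expect_equal(self$aligned_query, s)
  expect_equal(self$aligned_ref, s)

  none <- smith_waterman("MKV", "AAA")
  expect_equal(none$score, 0)
  expect_equal(none$identity_percent, 0)
  expect_equal(none$aligned_query, "")

  # gaps count in the default denominator but not in "aligned_columns"
  q <- "MKVLHGGHA"
  r <- "MKVLHAGGHA"  # one insertion in the reference
  a_def <- smith_waterman(q, r)
  a_cols <- smith_waterman(q, r, identity_denominator = "aligned_columns")
  expect_lte(a_def$identity_percent, a_cols$identity_percent)
  expect_error(smith_waterman("MKX", "MKV"), "standard letters")
})

test_that("Smith-Waterman score is symmetric for symmetric scoring matrices", {
  set.seed(101)
  for (i in 1:5) {
    q <- rand_seq(25); r <- rand_seq(25)
    expect_equal(smith_waterman(q, r)$score, smith_waterman(r, q)$score)
  }
})

test_that("identity distributions bin into ten-point classes with a closed top bin", {
  ids <- sprintf("g%02d", 1:10)
  all100 <- setNames(rep(100, 10), ids)
  h <- identity_distribution(all100)
  expect_equal(h$count[h$bin_lo == 90], 10L)
  expect_equal(sum(h$count), 10L)

  # half-open edges: 90 joins [90,100]; 10 joins [10,20)
  edge <- setNames(c(90, 10, 9.999, 0), sprintf("e%d", 1:4))
  he <- identity_distribution(edge)
  expect_equal(he$count[he$bin_lo == 90], 1L)
  expect_equal(he$count[he$bin_lo == 10], 1L)
  expect_equal(he$count[he$bin_lo == 0], 2L)

  # grouping by outcome category
  out <- data.frame(id = ids, outcome = rep(c("match", "unmatch"), 5))
  ident <- setNames(seq(5, 95, by = 10), ids)
  hg <- identity_distribution(ident, out)
  expect_setequal(unique(hg$category), c("match", "unmatch"))
  expect_equal(sum(hg$count), 10L)
  expect_error(identity_distribution(ident[1:5], out), "no identity")

  # a uniform sample is roughly flat across bins
  set.seed(103)
  u <- setNames(runif(2000, 0, 100), sprintf("u%04d", 1:2000))
  hu <- identity_distribution(u)
  expect_true(all(hu$count > 120 & hu$count < 280))
})
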