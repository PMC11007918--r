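test_that("sequences encode to alphabetical integer codes with zero padding", {
  expect_identical(encode_sequence("ACD", 6L), c(1L, 2L, 3L, 0L, 0L, 0L))
  expect_identical(encode_sequence("", 4L), integer(4L))
  expect_identical(encode_sequence("Y", 3L)[1], 20L)
  expect_identical(encode_sequence("acd", 4L)[1:3], c(1L, 2L, 3L))
  expect_error(encode_sequence("MKVLH", 3L), "exceeds")
  expect_error(encode_sequence("MXV", 5L), "standard")
})

test_that("model construction is seeded and yields calibrated-range outputs", {
  for (arch in c("mlp", "lstm", "attention")) {
    cfg <- classifier_config(arch, max_len = 20L, seed = 5L)
    m1 <- build_model(cfg, input_dim = 8L)
    m2 <- build_model(cfg, input_dim = 8L)
    expect_identical(m1$params, m2$params)
    x <- if (arch == "mlp") matrix(0, 1L, 8L) else matrix(0L, 1L, 20L)
    p <- predict_ko(m1, x)$score
    expect_true(is.finite(p) && p > 0 && p < 1)
  }
  expect_error(classifier_config("mlp", decision_threshold = 1.5), "between")
})

test_that("a separable two-Gaussian fixture trains to held-out F1* >= 0.99", {
  fx <- two_gaussian_fixture()
  tr <- c(1:160, 201:360)      # 80% of each class
  te <- setdiff(seq_len(400L), tr)
  cfg <- classifier_config("mlp", seed = 7L)
  model <- build_model(cfg, input_dim = 64L)
  model <- train_classifier(model, fx$x[tr, ], fx$y[tr])
  pred <- predict_ko(model, fx$x[te, ])
  cm <- naive_confusion(fx$y[te] == 1, pred$is_ko)
  met <- classifier_metrics(classifier_counts(cm$TP, cm$FP, cm$FN, cm$TN))
  expect_gte(met$f1_star, 0.99)

  # training is deterministic: same seed, identical history
  model2 <- train_classifier(build_model(cfg, input_dim = 64L),
                             fx$x[tr, ], fx$y[tr])
  expect_identical(model2$history, model$history)
})

test_that("early stopping returns the best-on-validation snapshot under divergence", {
  fx <- two_gaussian_fixture(n = 80L, d = 8L, separation = 6, seed = 103L)
  cfg <- classifier_config("mlp", patience = 1L, max_epochs = 10L,
                           learning_rate = 25, seed = 11L)
  model <- train_classifier(build_model(cfg, input_dim = 8L), fx$x, fx$y)
  h <- model$history
  expect_lt(nrow(h), 10L)                        # stopped early
  expect_equal(model$best_epoch, which.min(h$val_loss))
  expect_equal(nrow(h), model$best_epoch + 1L)   # halted right after decline
  # the final epoch failed to improve on the best validation loss
  expect_gte(h$val_loss[nrow(h)], min(h$val_loss))
})

test_that("degenerate labels are rejected", {
  X <- matrix(rnorm(40), 10L, 4L)
  m <- build_model(classifier_config("mlp"), input_dim = 4L)
  expect_error(train_classifier(m, X, rep(1, 10)), "degenerate labels")
  expect_error(train_classifier(m, X, c(0, rep(1, 9))), "degenerate labels")
})

test_that("KO calls use strict score > threshold", {
  cfg <- classifier_config("mlp", seed = 5L)
  m <- build_model(cfg, input_dim = 4L)
  # zero all parameters: the logit is exactly 0, the score exactly 0.5
  m$params <- lapply(m$params, function(p) p * 0)
  pr <- predict_ko(m, rep(1, 4), threshold = 0.5)
  expect_equal(pr$score, 0.5)
  expect_false(pr$is_ko)
  expect_true(predict_ko(m, rep(1, 4), threshold = 0.49)$is_ko)
  expect_true(predict_ko(m, rep(1, 4), threshold = 0)$is_ko)
})

test_that("raising the threshold never increases the number of positives", {
  fx <- two_gaussian_fixture(n = 100L, d = 16L, separation = 4, seed = 107L)
  cfg <- classifier_config("mlp", max_epochs = 20L, seed = 13L)
  model <- train_classifier(build_model(cfg, input_dim = 16L), fx$x, fx$y)
  scores <- predict_ko(model, fx$x)$score
  pos <- vapply(seq(0.05, 0.95, by = 0.05),
                function(th) sum(scores > th), integer(1))
  expect_true(all(diff(pos) <= 0))
})

test_that("classifier metrics match their definitions and limit conventions", {
  m <- classifier_metrics(classifier_counts(2L, 1L, 1L, 0L))
  expect_equal(m$precision_star, 2 / 3)
  expect_equal(m$recall_star, 2 / 3)
  expect_equal(m$f1_star, 2 / 3)

  z <- classifier_metrics(classifier_counts(0L, 5L, 5L, 0L))
  expect_equal(c(z$precision_star, z$recall_star, z$f1_star), c(0, 0, 0))

  u <- classifier_metrics(classifier_counts(0L, 0L, 5L, 5L))
  expect_true(is.nan(u$precision_star))
  expect_true(is.nan(u$f1_star))

  expect_error(classifier_counts(-1L, 0L, 0L), "non-negative")

  # random label/prediction fixtures against a naive confusion recount
  set.seed(19)
  for (rep_ in 1:10) {
    truth <- runif(50) < 0.5
    predicted <- runif(50) < 0.5
    cm <- naive_confusion(truth, predicted)
    met <- classifier_metrics(classifier_counts(cm$TP, cm$FP, cm$FN, cm$TN))
    tp <- sum(truth & predicted)
    if (tp + cm$FP > 0) expect_equal(met$precision_star, tp / (tp + cm$FP))
    if (tp + cm$FN > 0) expect_equal(met$recall_star, tp / (tp + cm$FN))
    # F1* lies between the smaller and larger of the two metrics
    if (!is.nan(met$f1_star)) {
      expect_gte(met$f1_star + 1e-12,
                 min(met$precision_star, met$recall_star))
      expect_lte(met$f1_star - 1e-12,
                 max(met$precision_star, met$recall_star))
    }
  }
})

test_that("the sequence baselines learn a token-separable toy problem", {
  set.seed(23)
  n <- 40L
  seqs <- c(replicate(n / 2, paste(sample(c("A", "C"), 12, TRUE), collapse = "")),
            replicate(n / 2, paste(sample(c("W", "Y"), 12, TRUE), collapse = "")))
  y <- rep(c(0, 1), each = n / 2)
  X <- t(vapply(seqs, encode_sequence, integer(16L), max_len = 16L))
  for (arch in c("lstm", "attention")) {
    cfg <- classifier_config(arch, max_len = 16L, max_epochs = 30L,
                             batch_size = 8L, learning_rate = 0.01,
                             seed = 29L)
    model <- train_classifier(build_model(cfg), X, y)
    acc <- mean(predict_ko(model, X)$is_ko == (y == 1))
    expect_gte(acc, 0.9)
  }
})
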