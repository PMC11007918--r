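#' Classifier configuration
#'
#' Settings for the KO/non-KO gate. The production path is `"mlp"`: a head
#' of two fully connected layers (hidden size 100, rectified) over sequence
#' embeddings with a logistic output. `"lstm"` and `"attention"` are the
#' comparison baselines operating on integer-encoded sequences: a 128-d
#' token embedding, a 1-D convolution with 64 filters (kernel 3, stride 1)
#' and global temporal max pooling feeding the recurrent/attention layer,
#' then a logistic output.
#'
#' @param architecture `"mlp"`, `"lstm"` or `"attention"`.
#' @param hidden_size MLP hidden width (default 100).
#' @param token_embed_dim Token embedding width for the baselines
#'   (default 128).
#' @param conv_filters Convolution filter count (default 64).
#' @param conv_kernel Convolution kernel size (default 3).
#' @param recurrent_units LSTM/attention width (default 100).
#' @param max_len Maximum (padded) sequence length for the baselines
#'   (default 600).
#' @param decision_threshold Score threshold: a sequence is called KO when
#'   its score is strictly greater than this (default 0.5).
#' @param validation_fraction Fraction of the training data reserved as the
#'   validation set for early stopping (default 0.2).
#' @param patience Epochs without validation-loss improvement before
#'   training halts (default 5).
#' @param max_epochs Epoch budget (default 100).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed; initialization, the validation split and
#'   minibatch shuffling all derive named streams from it.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(architecture = c("mlp", "lstm", "attention"),
                              hidden_size = 100L, token_embed_dim = 128L,
                              conv_filters = 64L, conv_kernel = 3L,
                              recurrent_units = 100L, max_len = 600L,
                              decision_threshold = 0.5,
                              validation_fraction = 0.2, patience = 5L,
                              max_epochs = 100L, batch_size = 32L,
                              learning_rate = 1e-3, seed = 1L) {
  architecture <- match.arg(architecture)
  assert_scalar_number(decision_threshold, "decision_threshold")
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("decision_threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  assert_scalar_number(patience, "patience", lower = 1)
  assert_scalar_number(max_epochs, "max_epochs", lower = 1)
  assert_scalar_number(batch_size, "batch_size", lower = 1)
  assert_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  structure(list(
    architecture = architecture, hidden_size = as.integer(hidden_size),
    token_embed_dim = as.integer(token_embed_dim),
    conv_filters = as.integer(conv_filters),
    conv_kernel = as.integer(conv_kernel),
    recurrent_units = as.integer(recurrent_units),
    max_len = as.integer(max_len),
    decision_threshold = decision_threshold,
    validation_fraction = validation_fraction,
    patience = as.integer(patience), max_epochs = as.integer(max_epochs),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    seed = as.integer(seed)
  ), class = "classifier_config")
}

#' Integer-encode a protein sequence
#'
#' Maps the 20 standard amino acids to 1..20 in alphabetical one-letter
#' order (`A`=1, `C`=2, `D`=3, ..., `Y`=20) and right-pads with 0 to
#' `max_len`. This is the input representation of the LSTM/attention
#' baselines.
#'
#' @param sequence String over the standard letters, length at most
#'   `max_len` (the empty string encodes to all zeros).
#' @param max_len Padded length.
#' @return Integer vector of length `max_len`.
#' @export
encode_sequence <- function(sequence, max_len = 600L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L > max_len) {
    stop(sprintf("sequence length %d exceeds max_len %d", L, max_len),
         call. = FALSE)
  }
  out <- integer(max_len)
  if (L > 0L) {
    codes <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], AA_STANDARD)
    if (anyNA(codes)) {
      stop("sequence contains letters outside the 20 standard codes",
           call. = FALSE)
    }
    out[seq_len(L)] <- codes
  }
  out
}

#' Build a KO/non-KO classifier model
#'
#' Constructs an untrained model with seeded parameter initialization.
#' For `"mlp"` the input dimension is that of the embeddings; for the
#' baselines the input is an integer-encoded sequence of length `max_len`.
#'
#' @param cfg A [classifier_config()].
#' @param input_dim Embedding dimension (MLP only; ignored for baselines).
#' @return An object of class `ko_classifier`.
#' @export
build_model <- function(cfg, input_dim = 64L) {
  stopifnot(inherits(cfg, "classifier_config"))
  set.seed(op_seed(cfg$seed, paste0("init:", cfg$architecture)))
  params <- nn_init_params(cfg, as.integer(input_dim))
  structure(list(cfg = cfg, input_dim = as.integer(input_dim),
                 params = params, trained = FALSE, history = NULL),
            class = "ko_classifier")
}

#' @export
print.ko_classifier <- function(x, ...) {
  cat(sprintf("<ko_classifier> %s (%s)\n", x$cfg$architecture,
              if (x$trained) sprintf("trained, best epoch %d", x$best_epoch)
              else "untrained"))
  invisible(x)
}

#' Train the KO/non-KO classifier
#'
#' Binary cross-entropy loss, Adam optimizer, and early stopping on a
#' seeded validation split: a `validation_fraction` share of the input is
#' held out, training halts once the validation loss has failed to improve
#' for `patience` consecutive epochs, and the returned model carries the
#' parameters of the best-on-validation epoch. Fully deterministic given
#' `cfg$seed`.
#'
#' @param model An untrained (or trained) [build_model()] object.
#' @param x Numeric embedding matrix (MLP) or integer encoding matrix
#'   (baselines), one row per example.
#' @param labels Logical or 0/1 vector: `TRUE`/1 for KO. Both classes must
#'   be present with at least 2 examples each.
#' @param cfg Optional [classifier_config()] overriding the model's.
#' @return The trained `ko_classifier`, with `history` (a data frame of
#'   per-epoch train/validation loss) and `best_epoch`.
#' @export
train_classifier <- function(model, x, labels, cfg = model$cfg) {
  stopifnot(inherits(model, "ko_classifier"), is.matrix(x))
  y <- as.numeric(labels)
  if (length(y) != nrow(x)) stop("labels must align with rows of x",
                                 call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be logical or 0/1",
                                 call. = FALSE)
  if (min(table(factor(y, levels = c(0, 1)))) < 2L) {
    stop("degenerate labels: need at least 2 examples of each class",
         call. = FALSE)
  }
  if (cfg$architecture == "mlp" && ncol(x) != model$input_dim) {
    stop(sprintf("embedding dimension %d does not match model input_dim %d",
                 ncol(x), model$input_dim), call. = FALSE)
  }

  n <- nrow(x)
  set.seed(op_seed(cfg$seed, "valsplit"))
  n_val <- max(1L, floor(cfg$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  x_tr <- x[tr_idx, , drop = FALSE]; y_tr <- y[tr_idx]
  x_val <- x[val_idx, , drop = FALSE]; y_val <- y[val_idx]

  params <- model$params
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())

  set.seed(op_seed(cfg$seed, "train"))
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(length(tr_idx))
    starts <- seq(1L, length(perm), by = cfg$batch_size)
    for (s in starts) {
      b <- perm[s:min(s + cfg$batch_size - 1L, length(perm))]
      fw <- nn_forward(params, x_tr[b, , drop = FALSE], cfg)
      p <- sigmoid(fw$logit)
      dlogit <- (p - y_tr[b]) / length(b)
      grads <- nn_backward(params, fw, dlogit, cfg)
      upd <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    train_loss <- bce_loss(sigmoid(nn_forward(params, x_tr, cfg)$logit), y_tr)
    val_loss <- bce_loss(sigmoid(nn_forward(params, x_val, cfg)$logit), y_val)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss))
    if (is.finite(val_loss) && val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }

  model$params <- best$params
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$history <- hist
  model$cfg <- cfg
  model
}

#' Score sequences and call KO / non-KO
#'
#' Forward pass of the trained classifier. A sequence is called KO when its
#' score is strictly greater than the threshold (a score exactly at the
#' threshold is non-KO).
#'
#' @param model A trained [ko_classifier][build_model()].
#' @param x Numeric vector (one example) or matrix (one row per example);
#'   embeddings for `"mlp"`, integer encodings for the baselines.
#' @param threshold Decision threshold (default: the model's configured
#'   one).
#' @return Data frame with columns `score` (in `[0, 1]`) and `is_ko`
#'   (logical), one row per example; row names carry `x`'s row names.
#' @export
predict_ko <- function(model, x, threshold = model$cfg$decision_threshold) {
  stopifnot(inherits(model, "ko_classifier"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (model$cfg$architecture == "mlp" && ncol(x) != model$input_dim) {
    stop(sprintf("embedding dimension %d does not match model input_dim %d",
                 ncol(x), model$input_dim), call. = FALSE)
  }
  score <- sigmoid(nn_forward(model$params, x, model$cfg)$logit)
  data.frame(score = score, is_ko = score > threshold,
             row.names = rownames(x))
}

#' Classifier confusion counts
#'
#' @param TP,FP,FN,TN Non-negative integer counts (KO is the positive
#'   class).
#' @return An object of class `classifier_counts`.
#' @export
classifier_counts <- function(TP, FP, FN, TN = 0L) {
  vals <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(as.list(vals), class = "classifier_counts")
}

#' Classifier precision*, recall* and F1*
#'
#' The starred metrics of the KO/non-KO gate (starred to distinguish them
#' from the whole-pipeline metrics of [pipeline_metrics()]):
#' precision* = TP/(TP+FP), recall* = TP/(TP+FN), and F1* their harmonic
#' mean. A metric whose denominator is zero is reported as `NaN` (and F1*
#' likewise); when precision* and recall* are both zero, F1* is 0 by the
#' limit convention.
#'
#' @param counts A [classifier_counts()] object.
#' @return List of class `classifier_metrics` with elements
#'   `precision_star`, `recall_star`, `f1_star`.
#' @export
classifier_metrics <- function(counts) {
  stopifnot(inherits(counts, "classifier_counts"))
  prec <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP)
          else NaN
  rec <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
         else NaN
  f1 <- if (is.nan(prec) || is.nan(rec)) NaN
        else if (prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
  structure(list(precision_star = prec, recall_star = rec, f1_star = f1),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("precision* %.3f  recall* %.3f  F1* %.3f\n",
              x$precision_star, x$recall_star, x$f1_star))
  invisible(x)
}
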