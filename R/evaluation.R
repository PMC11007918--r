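#' Categorize one prediction against the truth annotation
#'
#' The four-way outcome scheme for annotation-transfer evaluation, plus the
#' true-negative category that no metric uses:
#' \itemize{
#'   \item \strong{match}: truth annotated, prediction made, and the
#'     predicted set intersects the truth set (for singleton sets this is
#'     exact K-number identity);
#'   \item \strong{unmatch}: truth annotated, prediction made, no overlap;
#'   \item \strong{missed}: truth annotated but no prediction;
#'   \item \strong{added}: truth unannotated but a prediction was made;
#'   \item \strong{true_negative}: truth unannotated and no prediction.
#' }
#'
#' @param truth Character vector of truth K numbers (possibly empty).
#' @param prediction Character vector of predicted K numbers, or
#'   `NULL`/empty for no prediction.
#' @return One of `"match"`, `"unmatch"`, `"missed"`, `"added"`,
#'   `"true_negative"`.
#' @export
categorize <- function(truth, prediction) {
  truth <- as.character(truth %||% character())
  prediction <- as.character(prediction %||% character())
  bad <- c(truth[!is_k_number(truth)], prediction[!is_k_number(prediction)])
  if (length(bad)) {
    stop(sprintf("invalid K number(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  has_truth <- length(truth) > 0L
  has_pred <- length(prediction) > 0L
  if (has_truth && has_pred) {
    if (length(intersect(truth, prediction))) "match" else "unmatch"
  } else if (has_truth) {
    "missed"
  } else if (has_pred) {
    "added"
  } else {
    "true_negative"
  }
}

#' Evaluation outcome counts
#'
#' @param match,unmatch,missed,added Non-negative integer counts.
#' @return An object of class `eval_counts`.
#' @export
eval_counts <- function(match = 0L, unmatch = 0L, missed = 0L, added = 0L) {
  vals <- c(match = match, unmatch = unmatch, missed = missed, added = added)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(as.list(vals), class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("match %d  unmatch %d  missed %d  added %d\n",
              x$match, x$unmatch, x$missed, x$added))
  invisible(x)
}

#' Tally categorized outcomes
#'
#' @param outcomes Character vector of outcomes from [categorize()].
#' @return An [eval_counts()] object; true negatives are reported in the
#'   `true_negatives` attribute and excluded from the counts (no metric
#'   uses them).
#' @export
tally <- function(outcomes) {
  outcomes <- as.character(outcomes)
  known <- c("match", "unmatch", "missed", "added", "true_negative")
  bad <- setdiff(unique(outcomes), known)
  if (length(bad)) {
    stop(sprintf("unknown outcome(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  counts <- eval_counts(
    match = sum(outcomes == "match"),
    unmatch = sum(outcomes == "unmatch"),
    missed = sum(outcomes == "missed"),
    added = sum(outcomes == "added")
  )
  attr(counts, "true_negatives") <- sum(outcomes == "true_negative")
  counts
}

#' Pipeline precision, recall and F1 from outcome counts
#'
#' \deqn{Precision = match / (match + unmatch + added)}
#' \deqn{Recall = match / (match + unmatch + missed)}
#' \deqn{F1 = 2 / (Recall^{-1} + Precision^{-1})}
#'
#' Values are kept at full precision; the print method displays them
#' rounded to 3 decimals. When `match` is 0 with positive denominators all
#' three metrics are 0 (limit convention); a metric whose denominator is 0
#' is `NA`, and F1 is `NA` whenever either input metric is.
#'
#' @param counts An [eval_counts()] object.
#' @return Object of class `pipeline_metrics`: list with `precision`,
#'   `recall`, `f1`.
#' @export
pipeline_metrics <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  pden <- counts$match + counts$unmatch + counts$added
  rden <- counts$match + counts$unmatch + counts$missed
  precision <- if (pden > 0) counts$match / pden else NA_real_
  recall <- if (rden > 0) counts$match / rden else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "pipeline_metrics")
}

#' @export
print.pipeline_metrics <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate a prediction run against a truth table
#'
#' Deterministic composition of [categorize()], [tally()] and
#' [pipeline_metrics()] over id-keyed truth and prediction tables. Every
#' truth id is evaluated: ids absent from the prediction table count as
#' no-prediction (missed when annotated, true negative otherwise).
#'
#' @param truth Named list mapping id to its truth K-number set (possibly
#'   `character(0)` for unannotated ids) — the shape of
#'   [read_annotation_table()].
#' @param predictions Named list mapping predicted ids to their K-number
#'   set(s) — the shape of [assignments_to_predictions()]. Every predicted
#'   id must appear in `truth`.
#' @return List with `counts` ([eval_counts()]), `metrics`
#'   ([pipeline_metrics()]) and `outcomes` (data frame `id`, `outcome`,
#'   `truth_ko`, `predicted_ko` for downstream analyses such as identity
#'   distributions).
#' @export
evaluate_run <- function(truth, predictions) {
  stopifnot(is.list(truth), is.list(predictions))
  tids <- names(truth)
  pids <- names(predictions)
  if (is.null(tids) || anyDuplicated(tids)) {
    stop("truth table must be uniquely named by id", call. = FALSE)
  }
  if (length(predictions) && (is.null(pids) || anyDuplicated(pids))) {
    stop("prediction table must be uniquely named by id", call. = FALSE)
  }
  orphans <- setdiff(pids, tids)
  if (length(orphans)) {
    stop(sprintf("prediction id(s) absent from truth: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  outcome <- vapply(tids, function(id) {
    categorize(truth[[id]], predictions[[id]])
  }, character(1))
  counts <- tally(outcome)
  fmt <- function(x) if (length(x)) paste(sort(x), collapse = ",") else ""
  list(
    counts = counts,
    metrics = pipeline_metrics(counts),
    outcomes = data.frame(
      id = tids,
      outcome = unname(outcome),
      truth_ko = vapply(tids, function(id) fmt(truth[[id]]), character(1)),
      predicted_ko = vapply(tids, function(id) fmt(predictions[[id]]),
                            character(1)),
      row.names = NULL
    )
  )
}
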