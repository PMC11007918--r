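#' Euclidean distance between two embeddings
#'
#' `d(x, y) = sqrt(sum_i (x_i - y_i)^2)`: the similarity metric under which
#' annotation is transferred from the nearest reference.
#'
#' @param x,y Numeric vectors of equal length, all values finite.
#' @return Non-negative real; 0 iff `x` equals `y` elementwise.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("dimension mismatch: %d vs %d", length(x), length(y)),
         call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("embeddings must be finite", call. = FALSE)
  }
  sqrt(sum((x - y)^2))
}

#' Build an annotated reference embedding index
#'
#' The reference set is KO-only by construction: every reference id must
#' carry at least one K number.
#'
#' @param ids Character vector of unique reference ids.
#' @param embeddings Numeric matrix, rows aligned with `ids`.
#' @param annotations Named list mapping each id to a non-empty character
#'   vector of K numbers.
#' @return An object of class `reference_index`.
#' @export
build_index <- function(ids, embeddings, annotations) {
  stopifnot(is.character(ids), is.matrix(embeddings), is.list(annotations))
  if (nrow(embeddings) != length(ids)) {
    stop("embeddings row count must equal the number of ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate reference id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(is.finite(embeddings))) {
    stop("reference embeddings must be finite", call. = FALSE)
  }
  for (id in ids) {
    kos <- annotations[[id]]
    if (is.null(kos) || !length(kos)) {
      stop(sprintf("reference id '%s' has no K number (reference set must be KO-only)",
                   id), call. = FALSE)
    }
    if (!all(is_k_number(kos))) {
      stop(sprintf("reference id '%s' has invalid K number(s)", id),
           call. = FALSE)
    }
  }
  rownames(embeddings) <- ids
  structure(list(ids = ids, embeddings = embeddings,
                 annotations = annotations[ids]),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("<reference_index> %d references, dimension %d, %d distinct K numbers\n",
              length(x$ids), ncol(x$embeddings),
              length(unique(unlist(x$annotations)))))
  invisible(x)
}

#' Assign a K number by nearest-neighbour annotation transfer
#'
#' Exhaustive (exact) nearest-neighbour search under Euclidean distance:
#' the reference with the smallest distance is the best match and its K
#' number(s) are transferred. All references within `tie_tol` of the
#' minimum distance are reported, and the assigned K-number set is the
#' union over those ties.
#'
#' @param query Numeric embedding vector.
#' @param index A [build_index()] reference index of matching dimension.
#' @param tie_tol Non-negative distance tolerance for tie reporting
#'   (default 0: exact distance equality).
#' @param query_id Identifier carried into the result.
#' @return An object of class `ko_assignment`: list with `query_id`,
#'   `best_refs` (data frame `ref_id`, `distance`), `k_numbers` and
#'   `distance` (the minimum).
#' @export
assign_ko <- function(query, index, tie_tol = 0, query_id = "query") {
  stopifnot(inherits(index, "reference_index"))
  if (!length(index$ids)) stop("reference index is empty", call. = FALSE)
  if (length(query) != ncol(index$embeddings)) {
    stop(sprintf("dimension mismatch: query %d vs index %d",
                 length(query), ncol(index$embeddings)), call. = FALSE)
  }
  if (!all(is.finite(query))) stop("query embedding must be finite",
                                   call. = FALSE)
  assert_scalar_number(tie_tol, "tie_tol", lower = 0)
  diffs <- sweep(index$embeddings, 2L, query)
  d <- sqrt(rowSums(diffs^2))
  dmin <- min(d)
  best <- which(d <= dmin + tie_tol)
  structure(list(
    query_id = query_id,
    best_refs = data.frame(ref_id = index$ids[best], distance = d[best],
                           row.names = NULL),
    k_numbers = sort(unique(unlist(index$annotations[best]))),
    distance = dmin
  ), class = "ko_assignment")
}

#' @export
print.ko_assignment <- function(x, ...) {
  cat(sprintf("<ko_assignment> %s -> %s (distance %.4g, %d best ref%s)\n",
              x$query_id, paste(x$k_numbers, collapse = ","), x$distance,
              nrow(x$best_refs), if (nrow(x$best_refs) > 1L) "s (tie)" else ""))
  invisible(x)
}

#' Nearest-neighbour assignment with a distance threshold
#'
#' Variant gate without the classifier: the assignment is returned only
#' when the minimum distance is at most `distance_threshold`; otherwise an
#' explicit no-assignment marker is returned and the sequence is treated as
#' non-KO. No default threshold is provided: the value is an explicit
#' choice.
#'
#' @inheritParams assign_ko
#' @param distance_threshold Positive distance cutoff.
#' @return A `ko_assignment`, or an object of class `ko_no_assignment`
#'   (list with `query_id` and the minimum `distance`).
#' @export
assign_with_threshold <- function(query, index, distance_threshold,
                                  tie_tol = 0, query_id = "query") {
  assert_scalar_number(distance_threshold, "distance_threshold",
                       lower = .Machine$double.xmin)
  res <- assign_ko(query, index, tie_tol = tie_tol, query_id = query_id)
  if (res$distance <= distance_threshold) res
  else structure(list(query_id = query_id, distance = res$distance),
                 class = "ko_no_assignment")
}

#' @export
print.ko_no_assignment <- function(x, ...) {
  cat(sprintf("<ko_no_assignment> %s (min distance %.4g above threshold)\n",
              x$query_id, x$distance))
  invisible(x)
}

#' Assign a batch of query embeddings
#'
#' Order-preserving map of [assign_ko()] (or [assign_with_threshold()] when a
#' threshold is given) over the rows of a query matrix; each row's result
#' equals the corresponding single-query call.
#'
#' @param queries Numeric matrix of query embeddings, ids as row names.
#' @param index A [build_index()] reference index.
#' @param tie_tol Tie tolerance passed through.
#' @param distance_threshold Optional threshold enabling the
#'   no-assignment variant.
#' @return List of `ko_assignment` / `ko_no_assignment`, one per query row.
#' @export
assign_batch <- function(queries, index, tie_tol = 0,
                         distance_threshold = NULL) {
  stopifnot(is.matrix(queries))
  ids <- rownames(queries) %||% paste0("query", seq_len(nrow(queries)))
  lapply(seq_len(nrow(queries)), function(i) {
    if (is.null(distance_threshold)) {
      assign_ko(queries[i, ], index, tie_tol = tie_tol, query_id = ids[i])
    } else {
      assign_with_threshold(queries[i, ], index, distance_threshold,
                            tie_tol = tie_tol, query_id = ids[i])
    }
  })
}

#' Convert batch assignments to a prediction table
#'
#' @param assignments List returned by [assign_batch()].
#' @return Named list mapping each assigned query id to its K-number set;
#'   queries with no assignment are omitted (treated as non-KO downstream).
#' @export
assignments_to_predictions <- function(assignments) {
  out <- list()
  for (a in assignments) {
    if (inherits(a, "ko_assignment")) out[[a$query_id]] <- a$k_numbers
  }
  out
}
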