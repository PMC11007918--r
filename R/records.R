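#' Create a sequence record
#'
#' The pipeline's basic data carrier: an identified amino-acid sequence with
#' an optional set of KEGG Orthology (KO) annotations. A record whose
#' annotation set is non-empty is "KO data"; one with an empty set is
#' "non-KO data".
#'
#' @param id Non-empty identifier string (KEGG-style `"org:gene"` ids such as
#'   `"ppu:PP_4955"` are treated as opaque tokens).
#' @param sequence Non-empty string; uppercased on construction. Letters
#'   outside the 20 standard one-letter codes are permitted at this level
#'   (they are what [remove_undefined()] filters out).
#' @param annotations Character vector of K numbers (`K` + 5 digits),
#'   possibly empty. Duplicates are dropped.
#' @return An object of class `seq_record`: a list with elements `id`,
#'   `sequence` and `annotations`.
#' @examples
#' seq_record("ppu:PP_4955", "MKVLH", "K02030")
#' @export
seq_record <- function(id, sequence, annotations = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("record id must be a non-empty string", call. = FALSE)
  }
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop(sprintf("record '%s': sequence must be a non-empty string", id),
         call. = FALSE)
  }
  annotations <- unique(as.character(annotations))
  annotations <- annotations[nzchar(annotations)]
  bad <- annotations[!is_k_number(annotations)]
  if (length(bad)) {
    stop(sprintf("record '%s': invalid K number(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(id = id, sequence = toupper(sequence), annotations = annotations),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  ann <- if (length(x$annotations)) paste(x$annotations, collapse = ",")
         else "(none)"
  cat(sprintf("<seq_record> %s  [%d aa]  KO: %s\n",
              x$id, nchar(x$sequence), ann))
  invisible(x)
}

# Vector accessors over a list of seq_record objects ------------------------

#' Accessors for collections of sequence records
#'
#' Helpers extracting vectors from a list of [seq_record()] objects.
#'
#' @param records List of `seq_record` objects.
#' @return `record_ids()` and `record_seqs()` return character vectors;
#'   `record_lengths()` an integer vector; `record_is_ko()` a logical vector
#'   (`TRUE` where the annotation set is non-empty).
#' @export
record_ids <- function(records) {
  vapply(records, function(r) r$id, character(1))
}

#' @rdname record_ids
#' @export
record_seqs <- function(records) {
  vapply(records, function(r) r$sequence, character(1))
}

#' @rdname record_ids
#' @export
record_lengths <- function(records) {
  nchar(record_seqs(records))
}

#' @rdname record_ids
#' @export
record_is_ko <- function(records) {
  vapply(records, function(r) length(r$annotations) > 0L, logical(1))
}

# Validate a collection: list of seq_record with unique ids.
validate_records <- function(records, what = "records") {
  if (!is.list(records)) stop(sprintf("%s must be a list", what), call. = FALSE)
  ok <- vapply(records, inherits, logical(1), what = "seq_record")
  if (length(records) && !all(ok)) {
    stop(sprintf("%s must all be seq_record objects", what), call. = FALSE)
  }
  ids <- record_ids(records)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(records)
}

#' Attach annotations from a table to sequence records
#'
#' @param records List of `seq_record` objects.
#' @param annotations Named list mapping id to a character vector of
#'   K numbers (the shape returned by [read_annotation_table()]). Ids absent
#'   from the list keep their current annotations.
#' @return The records with annotation sets replaced where the table has an
#'   entry.
#' @export
annotate_records <- function(records, annotations) {
  validate_records(records)
  stopifnot(is.list(annotations))
  lapply(records, function(r) {
    if (r$id %in% names(annotations)) {
      seq_record(r$id, r$sequence, annotations[[r$id]])
    } else r
  })
}
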