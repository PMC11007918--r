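#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()] after a light
#' structural pre-scan so that a file whose first non-blank line is sequence
#' data (no header) is rejected with the offending line number. The header
#' token up to the first whitespace becomes the record id; sequences are
#' uppercased; annotation sets start empty.
#'
#' @param path Path to a FASTA file.
#' @return List of [seq_record()] objects (empty list for an empty file).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(list())
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA in '%s': sequence data before any header at line %d",
                 path, first), call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) return(list())
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  recs <- mapply(seq_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  validate_records(recs, sprintf("records read from '%s'", path))
  recs
}

#' Write sequence records to a FASTA file
#'
#' Sequence lines are wrapped at 60 columns. Annotations are not serialized
#' here; use [write_annotation_table()] for the id-to-K-number table.
#'
#' @param records List of [seq_record()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  validate_records(records)
  aa <- Biostrings::AAStringSet(record_seqs(records))
  names(aa) <- record_ids(records)
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}

#' Read an id-to-K-number annotation table
#'
#' Tab-separated table with columns `id` and `ko`. The `ko` column holds a
#' single K number per row, or the literal `"none"` for an unannotated id;
#' multiple rows for one id accumulate into its set.
#'
#' @param path Path to a TSV file with header columns `id` and `ko`.
#' @return Named list mapping each id to a character vector of K numbers
#'   (`character(0)` for ids annotated `"none"`).
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("id", "ko") %in% names(df))) {
    stop(sprintf("annotation table '%s' must have columns 'id' and 'ko'",
                 path), call. = FALSE)
  }
  bad <- which(!(df$ko == "none" | is_k_number(df$ko)))
  if (length(bad)) {
    stop(sprintf(
      "annotation table '%s': invalid ko value '%s' at data row %d (expected K + 5 digits or 'none')",
      path, df$ko[bad[1L]], bad[1L]), call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$id[i]
    cur <- out[[id]] %||% character()
    if (df$ko[i] != "none") cur <- union(cur, df$ko[i])
    out[[id]] <- cur
  }
  out
}

#' @rdname read_annotation_table
#' @param annotations Named list mapping id to a character vector of
#'   K numbers (possibly empty).
#' @return `write_annotation_table()` returns `path` invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  stopifnot(is.list(annotations), length(names(annotations)) == length(annotations))
  rows <- lapply(names(annotations), function(id) {
    kos <- annotations[[id]]
    if (!length(kos)) data.frame(id = id, ko = "none")
    else data.frame(id = id, ko = sort(unique(kos)))
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- data.frame(id = character(), ko = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts one (x, y, z) coordinate per CA `ATOM` record of the first
#' model's first chain, in residue order, via [bio3d::read.pdb()]. Alternate
#' locations other than blank or `"A"` are skipped. This deliberately minimal
#' dialect (single model, single chain, CA only) is all the TM-score
#' calculator needs.
#'
#' @param path Path to a PDB-format file.
#' @param id Identifier for the trace; defaults to the file name without
#'   extension.
#' @return An object of class `ca_trace`: list with `id` and an `n x 3`
#'   coordinate matrix `coords` (angstroms).
#' @export
read_ca_trace <- function(path, id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety == "CA" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("empty trace: no CA atoms in '%s'", path),
                      call. = FALSE)
  first_chain <- at$chain[1L]
  same_chain <- is.na(at$chain) == is.na(first_chain) &
    (is.na(at$chain) | at$chain == first_chain)
  at <- at[same_chain, , drop = FALSE]
  ca_trace(id %||% sub("\\.[^.]*$", "", basename(path)),
           cbind(at$x, at$y, at$z))
}

#' Construct a C-alpha trace object
#'
#' @param id Identifier string.
#' @param coords Numeric `n x 3` matrix of CA coordinates in angstroms,
#'   one row per residue, all finite, `n >= 1`.
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(id, coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) < 1L) {
    stop("coords must be a numeric matrix with 3 columns and >= 1 row",
         call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coords must all be finite", call. = FALSE)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, coords = coords), class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %s  %d residues\n", x$id, nrow(x$coords)))
  invisible(x)
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' Emits one CA `ATOM` record per residue (chain A, residue type `ALA`
#' placeholder, occupancy 1.00) followed by `TER`/`END`. Sufficient for
#' round-tripping through [read_ca_trace()].
#'
#' @param trace A [ca_trace()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ca_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ca_trace"))
  xyz <- trace$coords
  lines <- vapply(seq_len(nrow(xyz)), function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read and write embedding matrices
#'
#' Embedding collections are stored as a portable binary container:
#' `<path>` holds two little-endian int32 values (rows, columns) followed by
#' the row-major float64 matrix entries (bit-exact storage), and a plain-text
#' sidecar `<path>.ids` holds one id per line, row-aligned.
#'
#' @param path Container path (the sidecar derives from it).
#' @return `read_embeddings()` returns a numeric matrix with ids as row
#'   names.
#' @export
read_embeddings <- function(path) {
  ids_path <- paste0(path, ".ids")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (!file.exists(ids_path)) stop(sprintf("id sidecar not found: %s", ids_path),
                                   call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  vals <- readBin(con, "double", n = dims[1L] * dims[2L], size = 8L,
                  endian = "little")
  m <- matrix(vals, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
  ids <- readLines(ids_path)
  if (length(ids) != nrow(m)) {
    stop(sprintf("id sidecar '%s' has %d ids for %d rows",
                 ids_path, length(ids), nrow(m)), call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' @rdname read_embeddings
#' @param embeddings Numeric matrix, one row per sequence, ids as row names,
#'   all values finite.
#' @return `write_embeddings()` returns `path` invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(is.matrix(embeddings), is.numeric(embeddings))
  if (is.null(rownames(embeddings))) {
    stop("embeddings matrix must carry ids as row names", call. = FALSE)
  }
  if (!all(is.finite(embeddings))) {
    stop("embedding values must all be finite", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(dim(embeddings)), con, size = 4L, endian = "little")
  writeBin(as.double(t(embeddings)), con, size = 8L, endian = "little")
  writeLines(rownames(embeddings), paste0(path, ".ids"))
  invisible(path)
}
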