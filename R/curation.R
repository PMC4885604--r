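# Curation-table export: the per-abstract listing of supporting sentences
# and their binary relations, one row per extracted relation.

.curation_cols <- c("doc_id", "sentence_text", "subject_surface",
                    "subject_type", "subject_id", "relation_type",
                    "object_surface", "object_type", "object_id")

#' Export the curation table for an extraction result
#'
#' One row per extracted binary relation, ordered by sentence index and
#' then pattern-match order.
#'
#' @param result Output of [extract_relations()] (a list containing a
#'   `relations` frame), or a relation-instance frame directly.
#' @return A data frame with the fixed 9-column curation layout: `doc_id`,
#'   `sentence_text`, subject surface/type/id, `relation_type`, object
#'   surface/type/id.
#' @export
export_curation_table <- function(result) {
  relations <- if (is.data.frame(result)) result else result$relations
  relations <- relations[order(relations$sentence_index), , drop = FALSE]
  out <- relations[, .curation_cols, drop = FALSE]
  row.names(out) <- NULL
  out
}

# tab/newline/backslash escaping keeps the TSV lossless for arbitrary
# sentence text
escape_tsv_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_tsv_field <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1L]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        buf <- c(buf, switch(nxt, t = "\t", n = "\n", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, chars[j])
        j <- j + 1L
      }
    }
    out[i] <- paste0(buf, collapse = "")
  }
  out
}

#' Read and write curation tables as TSV
#'
#' Tab-delimited with the fixed 9-column header; tabs, newlines and
#' backslashes inside fields are backslash-escaped, so serialization
#' round-trips losslessly.  An empty table writes (and reads back from) a
#' header-only file.
#'
#' @param table A curation table from [export_curation_table()].
#' @param path File path.
#' @export
write_curation_tsv <- function(table, path) {
  stopifnot(identical(names(table), .curation_cols))
  lines <- paste(.curation_cols, collapse = "\t")
  for (i in seq_len(nrow(table))) {
    fields <- vapply(.curation_cols, function(col) {
      escape_tsv_field(as.character(table[[col]][i]))
    }, character(1))
    lines <- c(lines, paste(fields, collapse = "\t"))
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_curation_tsv
#' @export
read_curation_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, .curation_cols)) {
    stop("'", path, "' is not a curation table (bad header)",
         call. = FALSE)
  }
  rows <- lapply(lines[-1L], function(l) {
    fields <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(.curation_cols)) {
      stop("'", path, "': malformed row with ", length(fields),
           " fields", call. = FALSE)
    }
    as.data.frame(as.list(unescape_tsv_field(fields)),
                  col.names = .curation_cols, stringsAsFactors = FALSE)
  })
  out <- rbind_records(rows, {
    empty <- data.frame(matrix(character(0), nrow = 0,
                               ncol = length(.curation_cols)),
                        stringsAsFactors = FALSE)
    names(empty) <- .curation_cols
    empty
  })
  out
}
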