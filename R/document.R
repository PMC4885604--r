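#' Split text into sentences
#'
#' Splits at sentence-terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace and an uppercase letter or digit.  A guard list of common
#' scientific abbreviations ("et al.", "Fig.", "vs.", ...) suppresses
#' spurious splits.
#'
#' @param text A single character string.
#' @return A data frame with one row per sentence and columns `index`
#'   (0-based), `char_start`, `char_end` (0-based half-open offsets into
#'   `text`) and `text`.
#' @export
#' @examples
#' split_sentences("TGF-beta induces EMT. Metastasis follows.")
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(index = integer(0), char_start = integer(0),
                      char_end = integer(0), text = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(empty)
  }
  cand <- gregexpr("[.!?](?=\\s+[[:upper:]0-9])", text, perl = TRUE)[[1L]]
  splits <- integer(0)
  if (cand[1L] != -1L) {
    for (p in as.integer(cand)) {
      prefix <- substr(text, 1L, p)
      tail_tok <- regmatches(prefix, regexpr("\\S+$", prefix))
      # ignore opening brackets/quotes so "(Fig." still matches the guard
      tail_tok <- sub("^[^[:alnum:]]+", "", tail_tok)
      if (length(tail_tok) == 1L && tail_tok %in% .abbrev_guard) next
      splits <- c(splits, p)
    }
  }
  n <- nchar(text)
  bounds <- c(splits, n)          # 1-based inclusive sentence end candidates
  out <- empty
  cursor <- 1L
  for (b in bounds) {
    # skip leading whitespace
    while (cursor <= b && grepl("^\\s$", substr(text, cursor, cursor))) {
      cursor <- cursor + 1L
    }
    if (cursor > b) next
    end <- b
    # drop trailing whitespace (only relevant for the final fragment)
    while (end > cursor && grepl("^\\s$", substr(text, end, end))) {
      end <- end - 1L
    }
    out <- rbind(out, data.frame(
      index = nrow(out), char_start = cursor - 1L, char_end = end,
      text = substr(text, cursor, end), stringsAsFactors = FALSE))
    cursor <- b + 1L
  }
  out
}

.abbrev_guard <- c(
  "al.", "et al.", "Fig.", "Figs.", "fig.", "figs.", "vs.", "e.g.",
  "i.e.", "cf.", "ca.", "approx.", "Dr.", "No.", "no.", "St.", "resp.",
  "Ref.", "refs."
)

#' Construct a document from plain abstract text
#'
#' @param text Abstract body text.
#' @param doc_id Document identifier (a PMID or synthetic ID).
#' @param title Optional title; stored but not mined by default.
#' @return A `met_document`: list with `doc_id`, `title`, `abstract_text`
#'   and a `sentences` data frame (see [split_sentences()]).
#' @export
#' @examples
#' doc <- read_plain("TGF-beta induces EMT. Metastasis follows.", "X1")
#' doc$sentences$text
read_plain <- function(text, doc_id, title = "") {
  stopifnot(is.character(text), length(text) == 1L,
            is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (is.na(text) || !nzchar(trimws(text))) {
    stop("no content: document '", doc_id, "' has empty abstract text",
         call. = FALSE)
  }
  structure(
    list(doc_id = doc_id, title = title, abstract_text = text,
         sentences = split_sentences(text)),
    class = "met_document")
}

#' Read a plain-text abstract file
#'
#' Format: first line the document id, second line the title, remaining
#' lines the abstract body.
#'
#' @param path Path to the file.
#' @return A `met_document`.
#' @export
read_abstract_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 3L) {
    stop("abstract file '", path,
         "' must have id, title and body lines", call. = FALSE)
  }
  body <- trimws(paste(lines[-c(1L, 2L)], collapse = " "))
  read_plain(body, doc_id = trimws(lines[1L]), title = trimws(lines[2L]))
}

#' @export
print.met_document <- function(x, ...) {
  cat("<met_document> ", x$doc_id, "\n", sep = "")
  if (nzchar(x$title)) cat("  title: ", x$title, "\n", sep = "")
  cat("  sentences: ", nrow(x$sentences),
      ", characters: ", nchar(x$abstract_text), "\n", sep = "")
  invisible(x)
}

# Sentence row containing a document offset, or NA
sentence_index_at <- function(document, offset0) {
  s <- document$sentences
  hit <- which(s$char_start <= offset0 & offset0 < s$char_end)
  if (length(hit) == 0L) NA_integer_ else s$index[hit[1L]]
}
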