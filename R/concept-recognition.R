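# Dictionary and rule-based concept recognition.
#
# Matching operates on Greek-normalized text ("TGF-β" and "TGF-beta" are the
# same key), is anchored at token boundaries, and resolves overlaps left to
# right with longest-match-wins; ties at equal length fall back to lexicon
# order.  Short or digit-bearing surfaces (gene-symbol-like, e.g. "MET")
# match case-sensitively, everything else case-insensitively.

# normalize a sentence-like argument: accepts a character scalar or a row
# of a document's sentences data frame
as_sentence <- function(sentence) {
  if (is.character(sentence)) {
    data.frame(index = 0L, char_start = 0L, char_end = nchar(sentence),
               text = sentence, stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("index", "char_start", "char_end", "text") %in%
                    names(sentence)), nrow(sentence) == 1L)
    sentence
  }
}

#' Dictionary-based concept recognition for one sentence
#'
#' @param sentence A character string, or one row of a document's
#'   `sentences` data frame (offsets then refer to document coordinates).
#' @param lexicon A `met_lexicon` from [load_lexicon()].
#' @param doc_id Document identifier recorded on the mentions.
#' @return A concept-mention data frame (see [concept_mentions()]),
#'   non-overlapping, sorted by `char_start`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' recognize_dictionary("Liver cancer often recurs.", lex)
recognize_dictionary <- function(sentence, lexicon, doc_id = "DOC") {
  sent <- as_sentence(sentence)
  cand <- dictionary_candidates(sent$text, lexicon)
  picked <- resolve_left_to_right(cand)
  mentions_from_candidates(picked, sent, lexicon, doc_id,
                           provenance = "dictionary")
}

# All token-bounded lexicon hits in `text`, in local 0-based coordinates.
dictionary_candidates <- function(text, lexicon) {
  norm <- normalize_greek(text)
  ntext <- norm$text
  ltext <- tolower(ntext)
  out <- list()
  for (i in seq_len(nrow(lexicon))) {
    key <- lexicon$key[i]
    hay <- if (lexicon$case_sensitive[i]) ntext else ltext
    needle <- if (lexicon$case_sensitive[i]) key else tolower(key)
    m <- gregexpr(needle, hay, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (s in as.integer(m)) {
      e <- s + nchar(needle) - 1L            # 1-based inclusive, normalized
      if (!at_token_boundary(ntext, s - 1L, e)) next
      start0 <- norm$map[s] - 1L
      end0 <- norm$map[e]
      out[[length(out) + 1L]] <- data.frame(
        start = start0, end = end0, entry = i,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      entry = integer(0)))
  }
  do.call(rbind, out)
}

# Left-to-right scan: at each position the longest candidate wins, ties by
# lexicon order; candidates overlapping an accepted span are dropped.
resolve_left_to_right <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  ord <- order(cand$start, -(cand$end - cand$start), cand$entry)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  cand[keep, , drop = FALSE]
}

mentions_from_candidates <- function(cand, sent, lexicon, doc_id,
                                     provenance) {
  if (nrow(cand) == 0L) return(empty_mentions())
  concept_mentions(
    doc_id = rep(doc_id, nrow(cand)),
    sentence_index = rep(sent$index, nrow(cand)),
    char_start = sent$char_start + cand$start,
    char_end = sent$char_start + cand$end,
    surface = substring(sent$text, cand$start + 1L, cand$end),
    concept_type = lexicon$concept_type[cand$entry],
    normalized_id = lexicon$normalized_id[cand$entry],
    provenance = rep(provenance, nrow(cand)),
    ambiguous = lexicon$ambiguous[cand$entry])
}

# token-anchored microRNA name shape, e.g. "miR-181a", "miR-200b/200c",
# "let-7a", "microRNA-21"
.mirna_pattern <- paste0(
  "(?<![\\p{L}\\p{N}\u2010/-])",
  "(?i:miR|microRNA|miRNA|mir|let)[- \u2010]?",
  "[0-9]+[a-z]?(?:[-/][0-9]+[a-z]?)*",
  "(?:\\*| star)?",
  "(?![\\p{L}\\p{N}\u2010/-])")

#' Rule-based microRNA recognition
#'
#' Matches microRNA name shapes (`miR-21`, `microRNA-155`, `let-7a`,
#' cluster forms like `miR-200b/200c`, and starred passenger strands) at
#' token boundaries.  The mention is normalized through the lexicon when
#' the surface is listed there, otherwise it carries `UNNORMALIZED`.
#'
#' @inheritParams recognize_dictionary
#' @param lexicon Optional `met_lexicon` used for normalization lookup.
#' @return A concept-mention data frame of `MicroRNA` mentions.
#' @export
#' @examples
#' recognize_mirna("miR-181a suppresses EMT.")
recognize_mirna <- function(sentence, lexicon = NULL, doc_id = "DOC") {
  sent <- as_sentence(sentence)
  m <- gregexpr(.mirna_pattern, sent$text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty_mentions())
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  surface <- substring(sent$text, start1, start1 + len - 1L)
  ids <- rep(UNNORMALIZED, length(surface))
  ambiguous <- rep(FALSE, length(surface))
  if (!is.null(lexicon)) {
    mir <- lexicon[lexicon$concept_type == "MicroRNA", , drop = FALSE]
    for (i in seq_along(surface)) {
      key <- norm_key(surface[i])
      hit <- which(ifelse(mir$case_sensitive, mir$key == key,
                          tolower(mir$key) == tolower(key)))
      if (length(hit) > 0L) {
        ids[i] <- mir$normalized_id[hit[1L]]
        ambiguous[i] <- mir$ambiguous[hit[1L]]
      }
    }
  }
  concept_mentions(
    doc_id = rep(doc_id, length(surface)),
    sentence_index = rep(sent$index, length(surface)),
    char_start = sent$char_start + start1 - 1L,
    char_end = sent$char_start + start1 - 1L + len,
    surface = surface,
    concept_type = rep("MicroRNA", length(surface)),
    normalized_id = ids,
    provenance = rep("mirna_rule", length(surface)),
    ambiguous = ambiguous)
}

#' Merge dictionary and microRNA mentions
#'
#' The rule-based microRNA recognizer is the more specific source: on any
#' overlap (including identical spans) its mention wins over a dictionary
#' mention.  Disjoint mentions are concatenated and sorted by `char_start`.
#'
#' @param dictionary_mentions,mirna_mentions Per-sentence mention frames.
#' @return Non-overlapping mention data frame sorted by `char_start`.
#' @export
resolve_conflicts <- function(dictionary_mentions, mirna_mentions) {
  keep_dict <- rep(TRUE, nrow(dictionary_mentions))
  for (i in seq_len(nrow(dictionary_mentions))) {
    d <- dictionary_mentions[i, ]
    overlap <- mirna_mentions$char_start < d$char_end &
      d$char_start < mirna_mentions$char_end
    if (any(overlap)) keep_dict[i] <- FALSE
  }
  out <- rbind_records(
    list(dictionary_mentions[keep_dict, , drop = FALSE], mirna_mentions),
    empty_mentions())
  out[order(out$char_start), , drop = FALSE]
}

#' Recognize all concept mentions in a document
#'
#' Runs the dictionary recognizer and the microRNA recognizer on every
#' sentence and merges the results with [resolve_conflicts()].
#'
#' @param document A `met_document`.
#' @param lexicon A `met_lexicon`.
#' @return A concept-mention data frame in document coordinates.
#' @export
#' @examples
#' doc <- read_plain("TGF-beta induces Snail. miR-21 is elevated.", "X1")
#' recognize_concepts(doc, default_lexicon())
recognize_concepts <- function(document, lexicon) {
  stopifnot(inherits(document, "met_document"))
  per_sentence <- lapply(seq_len(nrow(document$sentences)), function(i) {
    sent <- document$sentences[i, , drop = FALSE]
    resolve_conflicts(
      recognize_dictionary(sent, lexicon, doc_id = document$doc_id),
      recognize_mirna(sent, lexicon, doc_id = document$doc_id))
  })
  out <- rbind_records(per_sentence, empty_mentions())
  validate_mentions(out, document)
  out
}
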