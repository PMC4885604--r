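# Pattern-based relation extraction: sentences are tokenized, concept
# mentions collapse to single tagged tokens, remaining tokens are matched
# against the trigger lexicon by lemma, and slot patterns are matched over
# the resulting tag sequence.

#' Tag a sentence with concept and trigger slots
#'
#' Tokenizes the sentence, collapses each concept mention to a single
#' tagged token covering its full span, and tags remaining tokens whose
#' lemma (inflections `-s`, `-ed`, `-ing`, `-ion`/`-tion` stripped) is in
#' the trigger lexicon.  Everything else is `PLAIN`.
#'
#' @param sentence A character string or one row of a document's
#'   `sentences` frame.
#' @param mentions Non-overlapping mention frame lying inside the sentence.
#' @param triggers A `met_triggers` from [load_triggers()].
#' @return A data frame of tagged tokens: `token_index`, `char_start`,
#'   `char_end` (same coordinate frame as the sentence), `surface`, `tag`
#'   (a concept tag, a trigger class, or `"PLAIN"`), `mention` (row index
#'   into `mentions` or `NA`) and `trigger_lemma`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' trg <- default_triggers()
#' sent <- "TGF-beta induces Snail."
#' m <- recognize_dictionary(sent, lex)
#' tag_sentence(sent, m, trg)$tag
tag_sentence <- function(sentence, mentions, triggers) {
  sent <- as_sentence(sentence)
  if (nrow(mentions) > 0L) {
    outside <- mentions$char_start < sent$char_start |
      mentions$char_end > sent$char_end
    if (any(outside)) {
      stop("mention '", mentions$surface[which(outside)[1L]],
           "' lies outside the sentence span", call. = FALSE)
    }
  }
  toks <- token_spans(sent$text)
  toks$start <- toks$start + sent$char_start
  toks$end <- toks$end + sent$char_start

  rows <- list()
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    hit <- which(mentions$char_start < toks$end[i] &
                   toks$start[i] < mentions$char_end)
    if (length(hit) > 0L) {
      mi <- hit[1L]
      # consume every token the mention covers
      j <- i
      while (j < n && toks$start[j + 1L] < mentions$char_end[mi]) {
        j <- j + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        char_start = mentions$char_start[mi],
        char_end = mentions$char_end[mi],
        surface = mentions$surface[mi],
        tag = unname(concept_tags()[mentions$concept_type[mi]]),
        mention = mi, trigger_lemma = NA_character_,
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else {
      lem <- lemma_candidates(toks$surface[i])
      t_hit <- which(triggers$surface %in% lem)
      if (length(t_hit) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          char_start = toks$start[i], char_end = toks$end[i],
          surface = toks$surface[i],
          tag = triggers$trigger_class[t_hit[1L]],
          mention = NA_integer_,
          trigger_lemma = triggers$surface[t_hit[1L]],
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          char_start = toks$start[i], char_end = toks$end[i],
          surface = toks$surface[i], tag = "PLAIN",
          mention = NA_integer_, trigger_lemma = NA_character_,
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(char_start = integer(0), char_end = integer(0),
               surface = character(0), tag = character(0),
               mention = integer(0), trigger_lemma = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out <- cbind(token_index = seq_len(nrow(out)), out)
  out
}

#' Enumerate slot-to-token assignments for one rule
#'
#' The matcher core: consecutive slots must bind consecutive tagged
#' (non-`PLAIN`) tokens, with at most `max_gap` plain tokens in between;
#' tagged tokens are never skipped.  Exposed so the matcher can be checked
#' against a brute-force subsequence oracle.
#'
#' @param tags Character vector of token tags (`"PLAIN"`, concept tags or
#'   trigger classes).
#' @param rule A single validated pattern rule.
#' @return Integer matrix, one row per assignment, one column per slot.
#' @export
find_slot_assignments <- function(tags, rule) {
  k <- length(rule$slots)
  n <- length(tags)
  accepts <- lapply(rule$slots, slot_accepts)
  tagged <- which(tags != "PLAIN")
  out <- list()
  if (length(tagged) < k) {
    return(matrix(integer(0), ncol = k))
  }
  for (s in seq_len(length(tagged) - k + 1L)) {
    pos <- tagged[s:(s + k - 1L)]
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(tags[pos[j]] %in% accepts[[j]])) { ok <- FALSE; break }
      if (j > 1L && pos[j] - pos[j - 1L] - 1L > rule$max_gap) {
        ok <- FALSE
        break
      }
    }
    if (ok) out[[length(out) + 1L]] <- pos
  }
  if (length(out) == 0L) {
    return(matrix(integer(0), ncol = k))
  }
  do.call(rbind, out)
}

#' Match pattern rules against a tagged sentence
#'
#' A rule matches when its slot tags occur in order over the tagged tokens
#' with at most `max_gap` plain tokens between consecutive slots (tagged
#' tokens may not be skipped).  Every distinct slot-to-token assignment
#' yields one relation instance; duplicates with identical subject, object,
#' trigger and relation type collapse onto the first matching rule in file
#' order.  Output is ordered by (rule order, leftmost slot position).
#'
#' @param tagged Output of [tag_sentence()].
#' @param rules A `met_patterns` list from [load_patterns()].
#' @param mentions The mention frame `tagged` was built against.
#' @param doc_id,sentence Provenance: document id and the sentence (string
#'   or sentences-frame row) the tokens came from.
#' @return A relation-instance data frame.
#' @export
match_patterns <- function(tagged, rules, mentions,
                           doc_id = "DOC", sentence = "") {
  sent <- as_sentence(sentence)
  out <- list()
  for (rule in rules) {
    assign_mat <- find_slot_assignments(tagged$tag, rule)
    for (r in seq_len(nrow(assign_mat))) {
      pos <- assign_mat[r, ]
      subj <- mentions[tagged$mention[pos[rule$subject_slot]], ]
      obj <- mentions[tagged$mention[pos[rule$object_slot]], ]
      trig <- tagged[pos[rule$trigger_slot], ]
      out[[length(out) + 1L]] <- data.frame(
        doc_id = doc_id, sentence_index = sent$index,
        subject_start = subj$char_start, subject_end = subj$char_end,
        subject_surface = subj$surface, subject_type = subj$concept_type,
        subject_id = subj$normalized_id,
        object_start = obj$char_start, object_end = obj$char_end,
        object_surface = obj$surface, object_type = obj$concept_type,
        object_id = obj$normalized_id,
        trigger_start = trig$char_start, trigger_end = trig$char_end,
        trigger_surface = trig$surface, trigger_class = trig$tag,
        relation_type = rule$relation_type, rule_id = rule$rule_id,
        sentence_text = sent$text,
        stringsAsFactors = FALSE)
    }
  }
  rel <- rbind_records(out, empty_relations())
  if (nrow(rel) > 1L) {
    key <- paste(rel$subject_start, rel$subject_end, rel$object_start,
                 rel$object_end, rel$trigger_start, rel$trigger_end,
                 rel$relation_type)
    rel <- rel[!duplicated(key), , drop = FALSE]
    row.names(rel) <- NULL
  }
  validate_relations(rel)
  rel
}

#' Extract relations from a document
#'
#' Full per-sentence pipeline: sentence splitting (already held by the
#' document), concept recognition (unless `mentions` supplies e.g. gold
#' boundaries), trigger tagging and pattern matching.
#'
#' @param document A `met_document`.
#' @param lexicon,triggers,patterns Loaded resources; defaults are the
#'   bundled ones.
#' @param mentions Optional pre-computed mention frame (gold boundaries);
#'   when `NULL`, [recognize_concepts()] is run.
#' @return A list with `mentions` and `relations` data frames.
#' @export
#' @examples
#' doc <- read_plain("TGF-beta induces Snail. Snail promotes metastasis.",
#'                   "X1")
#' res <- extract_relations(doc)
#' res$relations[, c("subject_surface", "relation_type", "object_surface")]
extract_relations <- function(document,
                              lexicon = default_lexicon(),
                              triggers = default_triggers(),
                              patterns = default_patterns(),
                              mentions = NULL) {
  stopifnot(inherits(document, "met_document"))
  if (is.null(mentions)) {
    mentions <- recognize_concepts(document, lexicon)
  } else {
    validate_mentions(
      mentions[mentions$sentence_index >= 0L, , drop = FALSE], document)
  }
  rel_list <- lapply(seq_len(nrow(document$sentences)), function(i) {
    sent <- document$sentences[i, , drop = FALSE]
    in_sent <- mentions[mentions$sentence_index == sent$index, ,
                        drop = FALSE]
    tagged <- tag_sentence(sent, in_sent, triggers)
    match_patterns(tagged, patterns, in_sent,
                   doc_id = document$doc_id, sentence = sent)
  })
  relations <- rbind_records(rel_list, empty_relations())
  list(document = document, mentions = mentions, relations = relations)
}
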