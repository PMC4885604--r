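# Tabular record types.  Concept mentions and relation instances are plain
# data frames with fixed column sets, which keeps them easy to filter,
# export and test; constructors below guarantee the column contract.

.mention_cols <- c("doc_id", "sentence_index", "char_start", "char_end",
                   "surface", "concept_type", "normalized_id", "provenance",
                   "ambiguous", "unknown_type")

.relation_cols <- c(
  "doc_id", "sentence_index",
  "subject_start", "subject_end", "subject_surface", "subject_type",
  "subject_id",
  "object_start", "object_end", "object_surface", "object_type",
  "object_id",
  "trigger_start", "trigger_end", "trigger_surface", "trigger_class",
  "relation_type", "rule_id", "sentence_text")

#' Construct a concept-mention table
#'
#' @param doc_id,sentence_index,char_start,char_end,surface,concept_type,normalized_id
#'   Parallel vectors; offsets are 0-based half-open document coordinates.
#' @param provenance One of `"dictionary"`, `"mirna_rule"`, `"gold"`.
#' @param ambiguous Logical; surface maps to several lexicon identifiers.
#' @param unknown_type Logical; type came from an unrecognized BioC infon.
#' @return Data frame with the canonical mention columns.
#' @export
concept_mentions <- function(doc_id = character(0),
                             sentence_index = integer(0),
                             char_start = integer(0),
                             char_end = integer(0),
                             surface = character(0),
                             concept_type = character(0),
                             normalized_id = character(0),
                             provenance = character(0),
                             ambiguous = logical(0),
                             unknown_type = logical(0)) {
  n <- length(surface)
  if (length(ambiguous) == 0L && n > 0L) ambiguous <- rep(FALSE, n)
  if (length(unknown_type) == 0L && n > 0L) unknown_type <- rep(FALSE, n)
  out <- data.frame(
    doc_id = as.character(doc_id),
    sentence_index = as.integer(sentence_index),
    char_start = as.integer(char_start),
    char_end = as.integer(char_end),
    surface = as.character(surface),
    concept_type = as.character(concept_type),
    normalized_id = as.character(normalized_id),
    provenance = as.character(provenance),
    ambiguous = as.logical(ambiguous),
    unknown_type = as.logical(unknown_type),
    stringsAsFactors = FALSE)
  bad <- !out$unknown_type & !(out$concept_type %in% concept_types())
  if (any(bad)) {
    stop("unknown concept type(s): ",
         paste(unique(out$concept_type[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname concept_mentions
#' @export
empty_mentions <- function() concept_mentions()

#' Empty relation-instance table
#'
#' The canonical zero-row relation frame; see the package overview for the
#' column contract.
#' @return A zero-row data frame with the relation columns.
#' @export
empty_relations <- function() {
  out <- data.frame(matrix(nrow = 0L, ncol = length(.relation_cols)))
  names(out) <- .relation_cols
  for (col in .relation_cols) out[[col]] <- character(0)
  int_cols <- c("sentence_index", "subject_start", "subject_end",
                "object_start", "object_end", "trigger_start", "trigger_end")
  for (col in int_cols) out[[col]] <- integer(0)
  out
}

rbind_records <- function(lst, empty) {
  lst <- lst[vapply(lst, function(x) NROW(x) > 0L, logical(1))]
  if (length(lst) == 0L) return(empty)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# Every mention must slice out of the document exactly and lie inside its
# sentence; used after BioC import and by the extraction pipeline.
validate_mentions <- function(mentions, document) {
  if (nrow(mentions) == 0L) return(invisible(mentions))
  stopifnot(all(mentions$doc_id == document$doc_id))
  got <- slice0(document$abstract_text, mentions$char_start,
                mentions$char_end)
  bad <- which(got != mentions$surface)
  if (length(bad) > 0L) {
    stop("mention surface/span mismatch in document '", document$doc_id,
         "' at offset ", mentions$char_start[bad[1L]], ": expected '",
         mentions$surface[bad[1L]], "', text has '", got[bad[1L]], "'",
         call. = FALSE)
  }
  s <- document$sentences
  for (i in seq_len(nrow(mentions))) {
    idx <- mentions$sentence_index[i]
    row <- s[s$index == idx, , drop = FALSE]
    if (nrow(row) != 1L || mentions$char_start[i] < row$char_start ||
        mentions$char_end[i] > row$char_end) {
      stop("mention '", mentions$surface[i],
           "' lies outside sentence ", idx, " of document '",
           document$doc_id, "'", call. = FALSE)
    }
  }
  invisible(mentions)
}

# Type-compatibility invariant for relation instances: a metastasis relation
# always runs Neoplasms => Tissues | Organ.
validate_relations <- function(relations) {
  if (nrow(relations) == 0L) return(invisible(relations))
  stopifnot(all(relations$relation_type %in% relation_types()))
  met <- relations$relation_type == "metastasis"
  bad <- met & !(relations$subject_type == "Neoplasms" &
                   relations$object_type %in% c("Tissues", "Organ"))
  if (any(bad)) {
    stop("metastasis relation must link Neoplasms to Tissues/Organ (rule ",
         relations$rule_id[which(bad)[1L]], ")", call. = FALSE)
  }
  same <- relations$subject_start == relations$object_start &
    relations$subject_end == relations$object_end
  if (any(same)) {
    stop("relation subject and object must be distinct mentions",
         call. = FALSE)
  }
  invisible(relations)
}
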