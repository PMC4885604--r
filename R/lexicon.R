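#' Load a concept lexicon
#'
#' Reads a tab-delimited dictionary with a `surface<TAB>type<TAB>id` header
#' line.  `type` must be one of the nine [concept_types()]; `id` is a
#' namespaced identifier (`EntrezGene:<n>` for Gene/MicroRNA, `MeSH:<id>`
#' for the seven other types) or the sentinel `UNNORMALIZED`.
#'
#' Duplicate `(surface, type)` records are collapsed onto the first
#' occurrence with a warning; when the collapsed records disagree on the
#' identifier the retained entry is flagged ambiguous, and mentions it
#' produces carry that flag.
#'
#' @param source Path to the TSV file.
#' @return A `met_lexicon` data frame with columns `surface`,
#'   `concept_type`, `normalized_id`, `ambiguous`, plus matching metadata
#'   (`key`, `case_sensitive`, `order`).
#' @seealso [default_lexicon()], [write_lexicon()]
#' @export
load_lexicon <- function(source) {
  raw <- utils::read.delim(source, header = TRUE, sep = "\t",
                           quote = "", comment.char = "#",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("surface", "type", "id") %in% names(raw))) {
    stop("lexicon '", source, "': expected columns surface, type, id",
         call. = FALSE)
  }
  raw$surface <- trimws(as.character(raw$surface))
  raw$surface[is.na(raw$surface)] <- ""
  line_no <- seq_len(nrow(raw)) + 1L   # header is line 1
  if (any(!nzchar(raw$surface))) {
    stop("lexicon '", source, "': empty surface form at line ",
         line_no[which(!nzchar(raw$surface))[1L]], call. = FALSE)
  }
  bad_type <- !(raw$type %in% concept_types())
  if (any(bad_type)) {
    i <- which(bad_type)[1L]
    stop("lexicon '", source, "': unknown concept type '", raw$type[i],
         "' at line ", line_no[i], call. = FALSE)
  }
  ns <- id_namespace(raw$type)
  ok_id <- raw$id == UNNORMALIZED | startsWith(raw$id, paste0(ns, ":"))
  if (any(!ok_id)) {
    i <- which(!ok_id)[1L]
    stop("lexicon '", source, "': id '", raw$id[i], "' at line ",
         line_no[i], " must be in the ", ns[i],
         " namespace or UNNORMALIZED", call. = FALSE)
  }

  pair <- paste(tolower(raw$surface), raw$type, sep = "\r")
  dup <- duplicated(pair)
  ambiguous <- rep(FALSE, nrow(raw))
  if (any(dup)) {
    for (p in unique(pair[dup])) {
      rows <- which(pair == p)
      if (length(unique(raw$id[rows])) > 1L) {
        ambiguous[rows[1L]] <- TRUE
      }
    }
    warning("lexicon '", source, "': collapsed ", sum(dup),
            " duplicate (surface, type) record(s)", call. = FALSE)
  }
  keep <- !dup
  out <- data.frame(
    surface = raw$surface[keep],
    concept_type = raw$type[keep],
    normalized_id = raw$id[keep],
    ambiguous = ambiguous[keep],
    stringsAsFactors = FALSE)
  out$order <- seq_len(nrow(out))
  out$key <- norm_key(out$surface)
  out$case_sensitive <- case_sensitive_surface(out$surface)
  class(out) <- c("met_lexicon", "data.frame")
  out
}

#' @param lexicon A `met_lexicon`.
#' @param path Output path.
#' @rdname load_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  out <- data.frame(surface = lexicon$surface, type = lexicon$concept_type,
                    id = lexicon$normalized_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Adverbs/quantifiers that curation guidelines exclude as triggers: a
# trigger must be a verb or nominal verb causing a direct relation.
.trigger_stoplist <- c(
  "more", "most", "less", "least", "very", "highly", "frequently",
  "significantly", "strongly", "often", "greater", "higher", "lower")

#' Load a trigger lexicon
#'
#' Reads a tab-delimited `surface<TAB>class` file.  `class` must be one of
#' [trigger_classes()].  Surfaces on the bundled stop-adverb list (e.g.
#' "more") are rejected: a trigger word must be a verb or nominal verb,
#' not an adverb.
#'
#' @param source Path to the TSV file.
#' @return A `met_triggers` data frame with columns `surface`,
#'   `trigger_class`.
#' @export
load_triggers <- function(source) {
  raw <- utils::read.delim(source, header = TRUE, sep = "\t",
                           quote = "", comment.char = "#",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("surface", "class") %in% names(raw))) {
    stop("trigger lexicon '", source,
         "': expected columns surface, class", call. = FALSE)
  }
  raw$surface <- trimws(tolower(as.character(raw$surface)))
  raw$surface[is.na(raw$surface)] <- ""
  line_no <- seq_len(nrow(raw)) + 1L
  if (any(!nzchar(raw$surface))) {
    stop("trigger lexicon '", source, "': empty surface at line ",
         line_no[which(!nzchar(raw$surface))[1L]], call. = FALSE)
  }
  bad_class <- !(raw$class %in% trigger_classes())
  if (any(bad_class)) {
    i <- which(bad_class)[1L]
    stop("trigger lexicon '", source, "': unknown trigger class '",
         raw$class[i], "' at line ", line_no[i], call. = FALSE)
  }
  stopped <- raw$surface %in% .trigger_stoplist
  if (any(stopped)) {
    i <- which(stopped)[1L]
    stop("trigger lexicon '", source, "': '", raw$surface[i],
         "' at line ", line_no[i],
         " is an adverb/quantifier, not a verbal trigger", call. = FALSE)
  }
  dup <- duplicated(raw$surface)
  if (any(dup)) {
    warning("trigger lexicon '", source, "': collapsed ", sum(dup),
            " duplicate surface(s)", call. = FALSE)
  }
  out <- data.frame(surface = raw$surface[!dup],
                    trigger_class = raw$class[!dup],
                    stringsAsFactors = FALSE)
  class(out) <- c("met_triggers", "data.frame")
  out
}

#' @param triggers A `met_triggers`.
#' @rdname load_triggers
#' @export
write_triggers <- function(triggers, path) {
  out <- data.frame(surface = triggers$surface,
                    class = triggers$trigger_class, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load pattern rules
#'
#' Patterns are JSON records with fields `rule_id`, `slots` (ordered tags,
#' each a concept-type tag such as `"GENE"`/`"METASTASIS"` or a trigger
#' class such as `"POSITIVE_REG"`), 1-based `subject_slot`, `trigger_slot`,
#' `object_slot`, a `relation_type`, and `max_gap` — the number of plain
#' (untagged) tokens tolerated between consecutive slots.
#'
#' Validation enforces: subject/object slots point at concept tags and
#' differ, the trigger slot points at a trigger tag, and `relation_type`
#' agrees with the trigger class (POSITIVE_REG implies positive_regulation
#' and so on).  Rule order is preserved and used as the deterministic
#' tie-break downstream.
#'
#' @param source Path to the JSON file.
#' @return A `met_patterns` list of validated rules.
#' @export
load_patterns <- function(source) {
  raw <- jsonlite::fromJSON(source, simplifyDataFrame = FALSE)
  rules <- lapply(raw, function(r) {
    r$max_gap <- if (is.null(r$max_gap)) 3L else as.integer(r$max_gap)
    r$subject_slot <- as.integer(r$subject_slot)
    r$object_slot <- as.integer(r$object_slot)
    r$trigger_slot <- as.integer(r$trigger_slot)
    r$slots <- as.character(unlist(r$slots))
    validate_pattern_rule(r)
    r
  })
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids)) {
    stop("pattern file '", source, "': duplicate rule_id '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  structure(rules, class = "met_patterns")
}

validate_pattern_rule <- function(r) {
  req <- c("rule_id", "slots", "subject_slot", "object_slot",
           "trigger_slot", "relation_type", "max_gap")
  missing <- setdiff(req, names(r))
  if (length(missing) > 0L) {
    stop("pattern rule is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  id <- r$rule_id
  known <- c(unname(concept_tags()), trigger_classes())
  if (!all(r$slots %in% known)) {
    stop("rule '", id, "': unknown slot tag(s) ",
         paste(setdiff(r$slots, known), collapse = ", "), call. = FALSE)
  }
  k <- length(r$slots)
  idx <- c(r$subject_slot, r$object_slot, r$trigger_slot)
  if (any(idx < 1L | idx > k)) {
    stop("rule '", id, "': slot index out of range", call. = FALSE)
  }
  if (r$subject_slot == r$object_slot) {
    stop("rule '", id, "': subject_slot and object_slot must differ",
         call. = FALSE)
  }
  if (!is_concept_tag(r$slots[r$subject_slot]) ||
      !is_concept_tag(r$slots[r$object_slot])) {
    stop("rule '", id,
         "': subject/object slots must carry concept-type tags",
         call. = FALSE)
  }
  trig_tag <- r$slots[r$trigger_slot]
  if (!is_trigger_tag(trig_tag)) {
    stop("rule '", id, "': trigger_slot must carry a trigger-class tag",
         call. = FALSE)
  }
  if (!identical(unname(.trigger_relation[trig_tag]), r$relation_type)) {
    stop("rule '", id, "': relation_type '", r$relation_type,
         "' is inconsistent with trigger class ", trig_tag, call. = FALSE)
  }
  if (is.na(r$max_gap) || r$max_gap < 0L) {
    stop("rule '", id, "': max_gap must be a non-negative integer",
         call. = FALSE)
  }
  invisible(r)
}

#' @param patterns A `met_patterns` list.
#' @rdname load_patterns
#' @export
write_patterns <- function(patterns, path) {
  jsonlite::write_json(unclass(patterns), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

met_extdata <- function(file) {
  path <- system.file("extdata", file, package = "metminer")
  if (!nzchar(path)) {
    stop("bundled resource '", file, "' not found", call. = FALSE)
  }
  path
}

#' Bundled default resources
#'
#' The package ships a small curated lexicon (covering the schema's
#' example instances and common EMT/metastasis vocabulary), a verbal
#' trigger lexicon, a pattern set covering the four decomposed relation
#' forms, and the sentence-template library used by the synthetic-corpus
#' generator.  These defaults are illustrative working sets, not a
#' reconstruction of any production dictionary.
#'
#' @return The loaded resource.
#' @export
default_lexicon <- function() load_lexicon(met_extdata("lexicon.tsv"))

#' @rdname default_lexicon
#' @export
default_triggers <- function() load_triggers(met_extdata("triggers.tsv"))

#' @rdname default_lexicon
#' @export
default_patterns <- function() load_patterns(met_extdata("patterns.json"))
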