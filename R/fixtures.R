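# Synthetic-corpus generator.  Sentence templates carry typed placeholders
# ("{Gene:1}", "{POS:1}", ...) that are filled from the lexicon and trigger
# lexicon under a seeded RNG, yielding abstracts with exactly known gold
# mentions and relations.  Covered templates instantiate a bundled pattern;
# distractor templates contain mentions but no trigger (or no placeholders
# at all) and must never produce a relation.

.trigger_shorthand <- c(POS = "POSITIVE_REG", NEG = "NEGATIVE_REG",
                        NEU = "NEUTRAL_REG", MET = "METASTASIS_TRIGGER")

# parse "{Type:var}" placeholders out of a template sentence; returns
# literal segments and placeholder descriptors in order
parse_template_sentence <- function(text) {
  pat <- "\\{([A-Za-z]+)(?::([0-9]+))?\\}"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  parts <- list()
  cursor <- 1L
  if (m[1L] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      if (starts[i] > cursor) {
        parts[[length(parts) + 1L]] <- list(
          kind = "literal",
          text = substr(text, cursor, starts[i] - 1L))
      }
      ph <- substr(text, starts[i], starts[i] + lens[i] - 1L)
      inner <- sub("^\\{", "", sub("\\}$", "", ph))
      bits <- strsplit(inner, ":", fixed = TRUE)[[1L]]
      type <- bits[1L]
      var <- if (length(bits) > 1L) bits[2L] else "1"
      if (type %in% names(.trigger_shorthand)) {
        parts[[length(parts) + 1L]] <- list(
          kind = "trigger", class = unname(.trigger_shorthand[type]),
          label = paste0(type, ":", var))
      } else if (type %in% concept_types()) {
        parts[[length(parts) + 1L]] <- list(
          kind = "concept", type = type, label = paste0(type, ":", var))
      } else {
        stop("template placeholder '", ph, "' has unknown type '", type,
             "'", call. = FALSE)
      }
      cursor <- starts[i] + lens[i]
    }
  }
  if (cursor <= nchar(text)) {
    parts[[length(parts) + 1L]] <- list(
      kind = "literal", text = substr(text, cursor, nchar(text)))
  }
  parts
}

#' Load sentence templates
#'
#' Templates are JSON records with `id`, a `covered` flag (does the
#' template instantiate a bundled pattern rule?), `sentences` (one or more
#' sentence strings with `{Type:var}` placeholders; multi-sentence
#' templates plant event chains by reusing variables) and `relations`
#' (subject/trigger/object placeholder labels per sentence).
#'
#' @param source Path to the JSON file.
#' @return A `met_templates` list.
#' @export
load_templates <- function(source) {
  raw <- jsonlite::fromJSON(source, simplifyDataFrame = FALSE)
  tpls <- lapply(raw, function(t) {
    stopifnot(is.character(t$id), length(t$sentences) >= 1L)
    t$covered <- isTRUE(t$covered)
    t$parsed <- lapply(unlist(t$sentences), parse_template_sentence)
    labels_by_sentence <- lapply(t$parsed, function(parts) {
      vapply(Filter(function(p) p$kind != "literal", parts),
             `[[`, character(1), "label")
    })
    for (r in t$relations) {
      avail <- labels_by_sentence[[r$sentence]]
      missing <- setdiff(c(r$subject, r$trigger, r$object), avail)
      if (length(missing) > 0L) {
        stop("template '", t$id, "': relation references placeholder '",
             missing[1L], "' absent from sentence ", r$sentence,
             call. = FALSE)
      }
    }
    t
  })
  structure(tpls, class = "met_templates")
}

#' @rdname default_lexicon
#' @export
default_templates <- function() load_templates(met_extdata("templates.json"))

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Fill one template: returns realized sentences plus local (per-template)
# mention and relation records with offsets relative to each sentence.
instantiate_template <- function(tpl, lexicon, triggers) {
  fillers <- list()     # label -> lexicon row (concepts)
  trig_fill <- list()   # label -> list(lemma, class, surface)
  used_by_type <- list()
  sentences <- character(0)
  mention_rows <- list()
  trig_spans <- list()  # label -> c(sentence, start, end)

  for (si in seq_along(tpl$parsed)) {
    text <- ""
    for (p in tpl$parsed[[si]]) {
      if (p$kind == "literal") {
        text <- paste0(text, p$text)
      } else if (p$kind == "concept") {
        if (is.null(fillers[[p$label]])) {
          pool <- which(lexicon$concept_type == p$type)
          pool <- setdiff(pool, used_by_type[[p$type]])
          if (length(pool) == 0L) {
            stop("lexicon has no unused entry of type '", p$type,
                 "' for template '", tpl$id, "'", call. = FALSE)
          }
          pick <- sample_one(pool)
          used_by_type[[p$type]] <- c(used_by_type[[p$type]], pick)
          fillers[[p$label]] <- lexicon[pick, ]
        }
        entry <- fillers[[p$label]]
        start0 <- nchar(text)
        text <- paste0(text, entry$surface)
        mention_rows[[length(mention_rows) + 1L]] <- data.frame(
          sentence_rel = si, start = start0,
          end = start0 + nchar(entry$surface),
          surface = entry$surface, concept_type = entry$concept_type,
          normalized_id = entry$normalized_id,
          ambiguous = entry$ambiguous, label = p$label,
          stringsAsFactors = FALSE)
      } else {
        if (is.null(trig_fill[[p$label]])) {
          pool <- which(triggers$trigger_class == p$class)
          if (length(pool) == 0L) {
            stop("trigger lexicon has no entry of class '", p$class,
                 "'", call. = FALSE)
          }
          pick <- sample_one(pool)
          trig_fill[[p$label]] <- list(
            lemma = triggers$surface[pick], class = p$class,
            surface = inflect_third_person(triggers$surface[pick]))
        }
        tf <- trig_fill[[p$label]]
        start0 <- nchar(text)
        text <- paste0(text, tf$surface)
        trig_spans[[p$label]] <- list(sentence_rel = si, start = start0,
                                      end = start0 + nchar(tf$surface),
                                      surface = tf$surface,
                                      class = tf$class)
      }
    }
    sentences <- c(sentences, text)
  }
  mentions <- rbind_records(mention_rows, data.frame(
    sentence_rel = integer(0), start = integer(0), end = integer(0),
    surface = character(0), concept_type = character(0),
    normalized_id = character(0), ambiguous = logical(0),
    label = character(0), stringsAsFactors = FALSE))
  list(template_id = tpl$id, sentences = sentences, mentions = mentions,
       relations = tpl$relations, trigger_spans = trig_spans)
}

#' Generate one synthetic abstract with gold annotations
#'
#' Sentences are sampled from the template library under a local seeded
#' RNG; concept placeholders are filled uniformly from the lexicon
#' (without replacement within a template) and trigger placeholders from
#' the trigger lexicon of the matching class.  Distractor sentences
#' (uncovered templates) are inserted at the requested fraction.  Gold
#' mentions and relations carry exact character offsets, verified against
#' the assembled text.
#'
#' @param seed Integer seed; identical seeds reproduce the abstract
#'   byte-identically.
#' @param templates A `met_templates` library.
#' @param lexicon,triggers Loaded resources.
#' @param n_sentences Number of sentences to generate.
#' @param distractor_fraction Probability that a sentence slot draws a
#'   distractor (uncovered) template.
#' @param doc_id Identifier for the generated document.
#' @return A list with `document`, `mentions` (gold, provenance `"gold"`)
#'   and `relations`.
#' @export
#' @examples
#' g <- generate_abstract(seed = 1, n_sentences = 3)
#' g$document$sentences$text
generate_abstract <- function(seed,
                              templates = default_templates(),
                              lexicon = default_lexicon(),
                              triggers = default_triggers(),
                              n_sentences = 5L,
                              distractor_fraction = 0,
                              doc_id = "SYN0001") {
  covered <- Filter(function(t) t$covered, templates)
  distract <- Filter(function(t) !t$covered, templates)
  if (distractor_fraction < 1 && length(covered) == 0L) {
    stop("no covered templates available", call. = FALSE)
  }
  if (distractor_fraction > 0 && length(distract) == 0L) {
    stop("no distractor templates available", call. = FALSE)
  }
  with_seed(seed, {
    insts <- list()
    total <- 0L
    while (total < n_sentences) {
      remaining <- n_sentences - total
      use_distractor <- distractor_fraction > 0 &&
        stats::runif(1) < distractor_fraction
      pool <- if (use_distractor) distract else covered
      pool <- Filter(function(t) length(t$sentences) <= remaining, pool)
      if (length(pool) == 0L) pool <- Filter(
        function(t) length(t$sentences) <= remaining,
        if (use_distractor) covered else distract)
      if (length(pool) == 0L) break
      tpl <- pool[[sample_one(seq_along(pool))]]
      insts[[length(insts) + 1L]] <-
        instantiate_template(tpl, lexicon, triggers)
      total <- total + length(tpl$sentences)
    }
    assemble_abstract(insts, doc_id)
  })
}

# Join instantiated sentences into a document; convert local offsets to
# document coordinates and cross-check against the sentence splitter.
assemble_abstract <- function(insts, doc_id) {
  sentence_texts <- unlist(lapply(insts, `[[`, "sentences"))
  if (length(sentence_texts) == 0L) {
    stop("no content: zero sentences generated", call. = FALSE)
  }
  starts <- integer(length(sentence_texts))
  off <- 0L
  for (i in seq_along(sentence_texts)) {
    starts[i] <- off
    off <- off + nchar(sentence_texts[i]) + 1L   # joined by one space
  }
  text <- paste(sentence_texts, collapse = " ")
  doc <- read_plain(text, doc_id)
  if (nrow(doc$sentences) != length(sentence_texts) ||
      !identical(doc$sentences$char_start, starts)) {
    stop("generated text disagrees with the sentence splitter; ",
         "check template punctuation/capitalization", call. = FALSE)
  }

  mention_list <- list()
  relation_list <- list()
  base_sentence <- 0L
  for (inst in insts) {
    sent_abs <- base_sentence + seq_along(inst$sentences)   # 1-based
    m <- inst$mentions
    if (nrow(m) > 0L) {
      abs_start <- starts[sent_abs[m$sentence_rel]] + m$start
      mention_list[[length(mention_list) + 1L]] <- concept_mentions(
        doc_id = rep(doc_id, nrow(m)),
        sentence_index = sent_abs[m$sentence_rel] - 1L,
        char_start = abs_start, char_end = abs_start + (m$end - m$start),
        surface = m$surface, concept_type = m$concept_type,
        normalized_id = m$normalized_id,
        provenance = rep("gold", nrow(m)),
        ambiguous = m$ambiguous)
    }
    for (r in inst$relations) {
      subj <- m[m$label == r$subject & m$sentence_rel == r$sentence, ][1L, ]
      obj <- m[m$label == r$object & m$sentence_rel == r$sentence, ][1L, ]
      tr <- inst$trigger_spans[[r$trigger]]
      s0 <- starts[sent_abs[r$sentence]]
      relation_list[[length(relation_list) + 1L]] <- data.frame(
        doc_id = doc_id, sentence_index = sent_abs[r$sentence] - 1L,
        subject_start = s0 + subj$start, subject_end = s0 + subj$end,
        subject_surface = subj$surface, subject_type = subj$concept_type,
        subject_id = subj$normalized_id,
        object_start = s0 + obj$start, object_end = s0 + obj$end,
        object_surface = obj$surface, object_type = obj$concept_type,
        object_id = obj$normalized_id,
        trigger_start = s0 + tr$start, trigger_end = s0 + tr$end,
        trigger_surface = tr$surface, trigger_class = tr$class,
        relation_type = unname(.trigger_relation[tr$class]),
        rule_id = "gold",
        sentence_text = sentence_texts[sent_abs[r$sentence]],
        stringsAsFactors = FALSE)
    }
    base_sentence <- base_sentence + length(inst$sentences)
  }
  mentions <- rbind_records(mention_list, empty_mentions())
  relations <- rbind_records(relation_list, empty_relations())
  validate_mentions(mentions, doc)
  validate_relations(relations)
  list(document = doc, mentions = mentions, relations = relations)
}

#' Generate a synthetic corpus
#'
#' Independent abstracts with per-document seeds derived as
#' `seed + document index`, so the corpus is reproducible and any single
#' document can be regenerated in isolation.
#'
#' @param n_docs Number of abstracts.
#' @param seed Base seed.
#' @inheritParams generate_abstract
#' @return A `met_corpus`: `documents` (named list), `gold_mentions`,
#'   `gold_relations`, and the generator `params`.
#' @export
#' @examples
#' corpus <- generate_corpus(3, seed = 42)
#' names(corpus$documents)
generate_corpus <- function(n_docs, seed,
                            templates = default_templates(),
                            lexicon = default_lexicon(),
                            triggers = default_triggers(),
                            n_sentences = 5L,
                            distractor_fraction = 0) {
  docs <- list()
  mention_list <- list()
  relation_list <- list()
  for (i in seq_len(n_docs)) {
    g <- generate_abstract(seed + i, templates, lexicon, triggers,
                           n_sentences, distractor_fraction,
                           doc_id = sprintf("SYN%04d", i))
    docs[[g$document$doc_id]] <- g$document
    mention_list[[i]] <- g$mentions
    relation_list[[i]] <- g$relations
  }
  structure(
    list(documents = docs,
         gold_mentions = rbind_records(mention_list, empty_mentions()),
         gold_relations = rbind_records(relation_list, empty_relations()),
         params = list(n_docs = n_docs, seed = seed,
                       n_sentences = n_sentences,
                       distractor_fraction = distractor_fraction)),
    class = "met_corpus")
}

#' @export
print.met_corpus <- function(x, ...) {
  cat("<met_corpus> ", length(x$documents), " document(s), ",
      nrow(x$gold_mentions), " gold mention(s), ",
      nrow(x$gold_relations), " gold relation(s)\n", sep = "")
  invisible(x)
}
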