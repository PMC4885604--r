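# Shared test machinery: tiny resource builders, a brute-force pattern
# oracle, relation-row builders and network equality.

write_tmp_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

tiny_lexicon <- function(extra = character(0)) {
  load_lexicon(write_tmp_lines(c(
    "surface\ttype\tid",
    "TGF-beta\tGene\tEntrezGene:7040",
    "Snail\tGene\tEntrezGene:6615",
    "Liver cancer\tNeoplasms\tMeSH:D008113",
    "Liver\tOrgan\tMeSH:D008099",
    extra)))
}

tiny_triggers <- function(extra = character(0)) {
  load_triggers(write_tmp_lines(c(
    "surface\tclass",
    "induce\tPOSITIVE_REG",
    "inhibit\tNEGATIVE_REG",
    "regulate\tNEUTRAL_REG",
    "metastasize\tMETASTASIS_TRIGGER",
    extra)))
}

make_rule <- function(rule_id, slots, subject_slot, trigger_slot,
                      object_slot, relation_type, max_gap = 3L) {
  r <- list(rule_id = rule_id, slots = slots,
            subject_slot = as.integer(subject_slot),
            object_slot = as.integer(object_slot),
            trigger_slot = as.integer(trigger_slot),
            relation_type = relation_type, max_gap = as.integer(max_gap))
  metminer:::validate_pattern_rule(r)
  r
}

# Independent oracle for the pattern matcher: test EVERY index subsequence
# of the right length against the slot and gap constraints directly.
oracle_assignments <- function(tags, rule) {
  k <- length(rule$slots)
  n <- length(tags)
  accepts <- lapply(rule$slots, metminer:::slot_accepts)
  if (n < k) return(matrix(integer(0), ncol = k))
  combos <- utils::combn(n, k)
  hits <- list()
  for (c_i in seq_len(ncol(combos))) {
    pos <- combos[, c_i]
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(tags[pos[j]] %in% accepts[[j]])) { ok <- FALSE; break }
      if (j > 1L) {
        between <- seq_len(n) > pos[j - 1L] & seq_len(n) < pos[j]
        if (any(tags[between] != "PLAIN") ||
            sum(between) > rule$max_gap) { ok <- FALSE; break }
      }
    }
    if (ok) hits[[length(hits) + 1L]] <- pos
  }
  if (length(hits) == 0L) return(matrix(integer(0), ncol = k))
  do.call(rbind, hits)
}

sort_assignment_matrix <- function(m) {
  if (nrow(m) <= 1L) return(unname(m))
  unname(m[do.call(order, as.data.frame(m)), , drop = FALSE])
}

full_tag_alphabet <- function() {
  c("PLAIN", unname(concept_tags()), trigger_classes())
}

# minimal relation row for evaluation tests
make_rel <- function(doc_id, s_start, o_start, type,
                     sentence_index = 0L) {
  data.frame(doc_id = doc_id, sentence_index = sentence_index,
             subject_start = s_start, subject_end = s_start + 4L,
             subject_surface = "S", subject_type = "Gene",
             subject_id = "EntrezGene:1",
             object_start = o_start, object_end = o_start + 4L,
             object_surface = "O", object_type = "Gene",
             object_id = "EntrezGene:2",
             trigger_start = s_start + 5L, trigger_end = s_start + 8L,
             trigger_surface = "t", trigger_class = "POSITIVE_REG",
             relation_type = type, rule_id = "x", sentence_text = "s",
             stringsAsFactors = FALSE)
}

expect_network_equal <- function(a, b) {
  a <- metminer:::canonicalize_network(a)
  b <- metminer:::canonicalize_network(b)
  expect_identical(a$nodes$node_key, b$nodes$node_key)
  expect_identical(a$nodes$label, b$nodes$label)
  expect_identical(a$nodes$concept_type, b$nodes$concept_type)
  expect_identical(a$nodes$evidence_doc_ids, b$nodes$evidence_doc_ids)
  expect_identical(a$edges$source_key, b$edges$source_key)
  expect_identical(a$edges$target_key, b$edges$target_key)
  expect_identical(a$edges$relation_type, b$edges$relation_type)
  expect_equal(a$edges$evidence, b$edges$evidence)
}

# random little network built from synthetic relation rows
random_network <- function(n_rel = 5L) {
  genes <- paste0("EntrezGene:", 1:6)
  rel <- do.call(rbind, lapply(seq_len(n_rel), function(i) {
    r <- make_rel(sample(c("D1", "D2", "D3"), 1L),
                  sample.int(50L, 1L), 60L + sample.int(50L, 1L),
                  sample(c("positive_regulation", "negative_regulation",
                           "neutral_regulation"), 1L),
                  sentence_index = sample.int(4L, 1L) - 1L)
    r$subject_id <- sample(genes, 1L)
    r$object_id <- sample(genes, 1L)
    r$subject_surface <- sub("EntrezGene:", "G", r$subject_id)
    r$object_surface <- sub("EntrezGene:", "G", r$object_id)
    r
  }))
  build_network(rel)
}

canonical_mentions <- function(m) {
  m <- m[order(m$doc_id, m$char_start, m$char_end, m$concept_type), ]
  row.names(m) <- NULL
  m
}

canonical_relations <- function(r) {
  r <- r[order(r$doc_id, r$sentence_index, r$subject_start,
               r$object_start, r$trigger_start, r$relation_type), ]
  row.names(r) <- NULL
  r
}
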