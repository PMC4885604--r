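test_that("tag_sentence collapses mentions and lemmatizes triggers", {
  lex <- tiny_lexicon("Slug\tGene\tEntrezGene:6591")
  trg <- tiny_triggers()
  sent <- "TGF-beta induces Snail."
  m <- recognize_dictionary(sent, lex)
  tags <- tag_sentence(sent, m, trg)
  expect_identical(tags$tag, c("GENE", "POSITIVE_REG", "GENE"))
  expect_identical(tags$surface[2L], "induces")
  expect_identical(tags$trigger_lemma[2L], "induce")

  # no mentions, no triggers: everything PLAIN
  plain <- tag_sentence("Nothing of note happened here.",
                        empty_mentions(), trg)
  expect_true(all(plain$tag == "PLAIN"))

  # nominalization: "inhibition" maps to the "inhibit" trigger
  t2 <- tag_sentence("inhibition of growth", empty_mentions(), trg)
  expect_identical(t2$tag[1L], "NEGATIVE_REG")

  # multi-token mention collapses to one token
  m3 <- recognize_dictionary("Liver cancer metastasizes to the Liver.",
                             lex)
  t3 <- tag_sentence("Liver cancer metastasizes to the Liver.", m3, trg)
  expect_identical(t3$tag,
                   c("NEOPLASMS", "METASTASIS_TRIGGER", "PLAIN", "PLAIN",
                     "ORGAN"))
  expect_identical(t3$surface[1L], "Liver cancer")

  # mention outside the sentence span is an error
  bad <- m
  bad$char_start <- 500L
  bad$char_end <- 505L
  expect_error(tag_sentence(sent, bad, trg), "outside the sentence")
})

test_that("match_patterns honours order, gaps and role slots", {
  trg <- tiny_triggers()
  rule <- make_rule("r_pos", c("GENE", "POSITIVE_REG", "GENE"), 1, 2, 3,
                    "positive_regulation")
  lex <- tiny_lexicon("Slug\tGene\tEntrezGene:6591")
  sent <- "TGF-beta induces Slug."
  m <- recognize_dictionary(sent, lex)
  tagged <- tag_sentence(sent, m, trg)
  rel <- match_patterns(tagged, structure(list(rule),
                                          class = "met_patterns"),
                        m, doc_id = "D", sentence = sent)
  expect_equal(nrow(rel), 1L)
  expect_identical(rel$subject_surface, "TGF-beta")
  expect_identical(rel$object_surface, "Slug")

  # gap of 4 plain tokens exceeds max_gap 3
  tags_far <- c("GENE", rep("PLAIN", 4L), "POSITIVE_REG", "GENE")
  expect_equal(nrow(find_slot_assignments(tags_far, rule)), 0L)
  tags_near <- c("GENE", rep("PLAIN", 3L), "POSITIVE_REG", "GENE")
  expect_equal(nrow(find_slot_assignments(tags_near, rule)), 1L)

  # a tagged token inside the gap blocks the match
  tags_blocked <- c("GENE", "NEGATIVE_REG", "POSITIVE_REG", "GENE")
  expect_equal(nrow(find_slot_assignments(tags_blocked, rule)), 0L)

  # role-by-slot supports passive-style object-before-subject rules
  passive <- make_rule("r_pass", c("GENE", "POSITIVE_REG", "GENE"),
                       3, 2, 1, "positive_regulation")
  rel_p <- match_patterns(tagged, structure(list(passive),
                                            class = "met_patterns"),
                          m, doc_id = "D", sentence = sent)
  expect_identical(rel_p$subject_surface, "Slug")
  expect_identical(rel_p$object_surface, "TGF-beta")
})

test_that("extract_relations composes the pipeline deterministically", {
  doc <- read_plain("TGF-beta induces Snail. Snail promotes metastasis.",
                    "X1")
  res <- extract_relations(doc)
  expect_equal(nrow(res$relations), 2L)
  expect_identical(res$relations$relation_type,
                   rep("positive_regulation", 2L))
  expect_identical(res$relations$object_type,
                   c("Gene", "NeoplasmMetastasis"))
  expect_identical(res$relations, extract_relations(doc)$relations)

  # no triggers, no relations
  expect_equal(nrow(extract_relations(
    read_plain("Snail and Slug are transcription factors.",
               "X2"))$relations), 0L)

  # adverbs like "more" are not triggers: no relation from this sentence
  rel <- extract_relations(read_plain(
    paste("Metachronous metastasis was observed more frequently in the",
          "cases with high PRL-3 expression."), "X3"))$relations
  expect_equal(nrow(rel), 0L)
})

test_that("matcher equals the brute-force oracle on random tag sequences", {
  rules <- default_patterns()
  alphabet <- full_tag_alphabet()
  set.seed(7)
  for (i in seq_len(300L)) {
    n <- sample(1:8, 1L)
    tags <- sample(alphabet, n, replace = TRUE)
    for (rule in rules) {
      expect_identical(
        sort_assignment_matrix(find_slot_assignments(tags, rule)),
        sort_assignment_matrix(oracle_assignments(tags, rule)),
        info = paste(paste(tags, collapse = ","), rule$rule_id))
    }
  }
})

test_that("adding a rule never removes previously emitted relations", {
  lex <- default_lexicon()
  trg <- default_triggers()
  rules <- default_patterns()
  corpus <- generate_corpus(5, seed = 3)
  subset_rules <- structure(rules[1:4], class = "met_patterns")
  for (doc in corpus$documents) {
    before <- extract_relations(doc, lex, trg, subset_rules)$relations
    after <- extract_relations(doc, lex, trg, rules)$relations
    key <- function(r) paste(r$doc_id, r$subject_start, r$object_start,
                             r$trigger_start, r$relation_type)
    expect_true(all(key(before) %in% key(after)))
  }
})

test_that("emitted relations always satisfy type compatibility", {
  corpus <- generate_corpus(10, seed = 5, distractor_fraction = 0.3)
  for (doc in corpus$documents) {
    rel <- extract_relations(doc)$relations
    expect_silent(metminer:::validate_relations(rel))
    met <- rel[rel$relation_type == "metastasis", ]
    if (nrow(met) > 0L) {
      expect_true(all(met$subject_type == "Neoplasms"))
      expect_true(all(met$object_type %in% c("Tissues", "Organ")))
    }
  }
})
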