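test_that("split_sentences handles terminal punctuation and abbreviations", {
  cases <- list(
    list(text = "A binds B. C binds D.", n = 2L),
    list(text = "Smith et al. showed X.", n = 1L),
    list(text = "miR-21 is induced (Fig. 2). EMT follows.", n = 2L),
    list(text = "Does it spread? Yes! It does.", n = 3L),
    list(text = "Increased vs. decreased expression was seen.", n = 1L),
    list(text = "", n = 0L))
  for (cs in cases) {
    s <- split_sentences(cs$text)
    expect_equal(nrow(s), cs$n, info = cs$text)
    if (cs$n > 0L) {
      expect_identical(
        s$text, substring(cs$text, s$char_start + 1L, s$char_end))
      expect_identical(s$index, seq_len(cs$n) - 1L)
      # ordered, non-overlapping spans
      expect_true(all(diff(s$char_start) > 0))
      expect_true(all(s$char_end[-cs$n] <= s$char_start[-1L]))
    }
  }
})

test_that("dictionary matching is longest-match, token-anchored, typed", {
  lex <- tiny_lexicon()
  m <- recognize_dictionary("Liver cancer metastasizes.", lex)
  expect_equal(nrow(m), 1L)
  expect_identical(m$surface, "Liver cancer")
  expect_identical(m$concept_type, "Neoplasms")
  expect_identical(m$normalized_id, "MeSH:D008113")

  # token anchoring: no substring hits inside longer tokens
  expect_equal(nrow(recognize_dictionary("Liverpool is a city.", lex)), 0L)
  # hyphens are word-internal: "Snail" must not match inside "Snail-like"
  expect_equal(nrow(recognize_dictionary("A Snail-like factor.", lex)), 0L)

  # Greek normalization: β and beta hit the same entry, span stays exact
  m <- recognize_dictionary("TGF-β signals.", lex)
  expect_identical(m$surface, "TGF-β")
  expect_identical(m$normalized_id, "EntrezGene:7040")
  m2 <- recognize_dictionary("TGF-beta signals.", lex)
  expect_identical(m2$normalized_id, "EntrezGene:7040")

  # short surfaces are case-sensitive, long ones case-folded
  lex2 <- tiny_lexicon("MET\tGene\tEntrezGene:4233")
  expect_equal(nrow(recognize_dictionary("They met yesterday.", lex2)), 0L)
  expect_equal(nrow(recognize_dictionary("MET amplification.", lex2)), 1L)
  expect_equal(nrow(recognize_dictionary("LIVER CANCER spreads.", lex2)),
               1L)
})

test_that("schema example instances are recognized with their types", {
  lex <- default_lexicon()
  cases <- list(
    c("TGF-β was overexpressed.", "TGF-β", "Gene"),
    c("Loss of miR-181a was noted.", "miR-181a", "MicroRNA"),
    c("Metastasis was observed.", "Metastasis", "NeoplasmMetastasis"),
    c("Stress fiber formation increased.", "Stress fiber",
      "Cytoskeleton"),
    c("Cell aggregation was quantified.", "Cell aggregation",
      "CellMovement"),
    c("Cell adhesion was lost.", "Cell adhesion", "CellAdhesion"),
    c("Liver cancer was diagnosed.", "Liver cancer", "Neoplasms"),
    c("Lesions in the liver were found.", "liver", "Organ"),
    c("Adipose tissue was sampled.", "Adipose tissue", "Tissues"))
  for (cs in cases) {
    doc <- read_plain(cs[1L], "T")
    m <- recognize_concepts(doc, lex)
    expect_true(any(m$surface == cs[2L] & m$concept_type == cs[3L]),
                info = cs[1L])
  }
})

test_that("microRNA recognizer matches name shapes at token boundaries", {
  expect_identical(recognize_mirna("miR-181a is induced.")$surface,
                   "miR-181a")
  expect_equal(nrow(recognize_mirna("It was a miracle.")), 0L)
  m <- recognize_mirna("The miR-200b/200c cluster is lost.")
  expect_identical(m$surface, "miR-200b/200c")
  expect_identical(recognize_mirna("microRNA-21 and let-7a act.")$surface,
                   c("microRNA-21", "let-7a"))
  expect_identical(recognize_mirna("miR-21* accumulates.")$surface,
                   "miR-21*")
  # no digits, no match
  expect_equal(nrow(recognize_mirna("The miR family.")), 0L)
  # lexicon lookup normalizes known surfaces
  m <- recognize_mirna("miR-181a is induced.", default_lexicon())
  expect_identical(m$normalized_id, "EntrezGene:406995")
  expect_identical(
    recognize_mirna("miR-9999 is novel.", default_lexicon())$normalized_id,
    UNNORMALIZED)
})

test_that("resolve_conflicts prefers the microRNA rule and sorts output", {
  dict <- concept_mentions(
    doc_id = "D", sentence_index = 0L, char_start = 0L, char_end = 3L,
    surface = "miR", concept_type = "Gene",
    normalized_id = "EntrezGene:1", provenance = "dictionary")
  rule <- concept_mentions(
    doc_id = "D", sentence_index = 0L, char_start = 0L, char_end = 8L,
    surface = "miR-181a", concept_type = "MicroRNA",
    normalized_id = UNNORMALIZED, provenance = "mirna_rule")
  merged <- resolve_conflicts(dict, rule)
  expect_equal(nrow(merged), 1L)
  expect_identical(merged$concept_type, "MicroRNA")

  # identical spans: single mention, MicroRNA type
  dict2 <- dict
  dict2$char_end <- 8L
  dict2$surface <- "miR-181a"
  expect_identical(resolve_conflicts(dict2, rule)$concept_type, "MicroRNA")

  # disjoint mentions concatenate sorted
  far <- dict
  far$char_start <- 20L
  far$char_end <- 23L
  merged <- resolve_conflicts(far, rule)
  expect_identical(merged$char_start, c(0L, 20L))
})

test_that("recognition is deterministic with non-overlapping exact spans", {
  lex <- default_lexicon()
  corpus <- generate_corpus(6, seed = 99, distractor_fraction = 0.4)
  for (doc in corpus$documents) {
    m <- recognize_concepts(doc, lex)
    expect_identical(m, recognize_concepts(doc, lex))
    # span fidelity
    expect_identical(
      m$surface,
      substring(doc$abstract_text, m$char_start + 1L, m$char_end))
    # pairwise non-overlap within each sentence
    for (s in unique(m$sentence_index)) {
      ms <- m[m$sentence_index == s, ]
      ms <- ms[order(ms$char_start), ]
      if (nrow(ms) > 1L) {
        expect_true(all(ms$char_end[-nrow(ms)] <= ms$char_start[-1L]))
      }
    }
  }
})
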