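test_that("read_plain builds documents and rejects empty input", {
  doc <- read_plain("TGF-β induces EMT. Metastasis follows.", "X1")
  expect_s3_class(doc, "met_document")
  expect_equal(nrow(doc$sentences), 2L)
  # span fidelity and reconstruction invariants
  with(doc$sentences, expect_identical(
    text, substring(doc$abstract_text, char_start + 1L, char_end)))
  expect_true(all(doc$sentences$char_start < doc$sentences$char_end))

  expect_error(read_plain("", "X2"), "no content")
  expect_error(read_plain("   \n ", "X2b"), "no content")

  one <- read_plain("a single sentence without terminal punctuation", "X3")
  expect_equal(nrow(one$sentences), 1L)
  expect_identical(one$sentences$text, one$abstract_text)

  # idempotent for identical input
  expect_identical(read_plain("A binds B. C binds D.", "X4"),
                   read_plain("A binds B. C binds D.", "X4"))
})

test_that("abstract files round-trip through the 3-line plain format", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("PMID123", "A title", "Snail induces Slug. EMT follows."),
             path)
  doc <- read_abstract_file(path)
  expect_identical(doc$doc_id, "PMID123")
  expect_identical(doc$title, "A title")
  expect_equal(nrow(doc$sentences), 2L)
  expect_error(read_abstract_file(write_tmp_lines(c("id", "title"))),
               "id, title and body")
})

test_that("BioC write/read is the identity on a small annotated corpus", {
  corpus <- generate_corpus(4, seed = 11, distractor_fraction = 0.3)
  path <- tempfile(fileext = ".xml")
  write_bioc(corpus$documents, corpus$gold_mentions,
             corpus$gold_relations, path)
  rt <- read_bioc(path)
  expect_identical(names(rt$documents), names(corpus$documents))
  for (id in names(rt$documents)) {
    expect_identical(rt$documents[[id]]$abstract_text,
                     corpus$documents[[id]]$abstract_text)
    expect_identical(rt$documents[[id]]$sentences,
                     corpus$documents[[id]]$sentences)
  }
  expect_identical(canonical_mentions(rt$mentions),
                   canonical_mentions(corpus$gold_mentions))
  expect_identical(canonical_relations(rt$relations),
                   canonical_relations(corpus$gold_relations))
})

test_that("BioC edge cases: empty corpus, duplicate spans, bad spans", {
  path <- tempfile(fileext = ".xml")
  write_bioc(list(), path = path)
  rt <- read_bioc(path)
  expect_length(rt$documents, 0L)
  expect_equal(nrow(rt$mentions), 0L)

  # two mentions at identical spans with different types both survive
  doc <- read_plain("Cell adhesion was lost.", "D1")
  m <- concept_mentions(
    doc_id = c("D1", "D1"), sentence_index = c(0L, 0L),
    char_start = c(0L, 0L), char_end = c(13L, 13L),
    surface = rep("Cell adhesion", 2),
    concept_type = c("CellAdhesion", "NeoplasmMetastasis"),
    normalized_id = c("MeSH:D002448", "UNNORMALIZED"),
    provenance = c("gold", "gold"))
  write_bioc(doc, m, path = path)
  rt <- read_bioc(path)
  expect_equal(nrow(rt$mentions), 2L)
  expect_setequal(rt$mentions$concept_type,
                  c("CellAdhesion", "NeoplasmMetastasis"))

  # annotation extending past the passage end is rejected by name
  txt <- paste(readLines(path), collapse = "\n")
  writeLines(sub('length="13"', 'length="99"', txt, fixed = TRUE), path)
  expect_error(read_bioc(path), "A1")

  expect_error(read_bioc(write_tmp_lines("<collection><oops")),
               "malformed BioC XML")
})

test_that("read_bioc flags unknown concept types but preserves them", {
  doc <- read_plain("Aspirin was given.", "D9")
  path <- tempfile(fileext = ".xml")
  write_bioc(doc, path = path)
  txt <- paste(readLines(path), collapse = "\n")
  ann <- paste0(
    '<annotation id="A1"><infon key="type">Drug</infon>',
    '<infon key="identifier">UNNORMALIZED</infon>',
    '<location offset="0" length="7"/><text>Aspirin</text></annotation>')
  txt <- sub("<text>Aspirin was given.</text>",
             paste0("<text>Aspirin was given.</text>", ann),
             txt, fixed = TRUE)
  writeLines(txt, path)
  expect_warning(rt <- read_bioc(path), "unknown concept type")
  expect_true(rt$mentions$unknown_type[1L])
  expect_identical(rt$mentions$concept_type[1L], "Drug")
})

test_that("write_bioc rejects dangling references", {
  doc <- read_plain("Snail induces Slug.", "D1")
  rel <- make_rel("D1", 0L, 14L, "positive_regulation")
  expect_error(write_bioc(doc, empty_mentions(), rel, tempfile()),
               "not in the mention set")
  expect_error(write_bioc(doc, make_gold <- concept_mentions(
    doc_id = "OTHER", sentence_index = 0L, char_start = 0L,
    char_end = 5L, surface = "Snail", concept_type = "Gene",
    normalized_id = "UNNORMALIZED", provenance = "gold"),
    path = tempfile()), "unknown document")
})

test_that("curation table export matches relations and round-trips TSV", {
  doc <- read_plain("TGF-beta induces Snail.", "D1")
  res <- extract_relations(doc)
  tab <- export_curation_table(res)
  expect_equal(nrow(tab), nrow(res$relations))
  expect_identical(tab$relation_type, "positive_regulation")
  expect_identical(names(tab), metminer:::.curation_cols)

  # empty result: header-only file that reads back as an empty table
  empty_tab <- export_curation_table(
    extract_relations(read_plain("Nothing to see here.", "D2")))
  path <- tempfile(fileext = ".tsv")
  write_curation_tsv(empty_tab, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_curation_tsv(path)), 0L)

  # delimiter characters inside fields survive the round trip
  tricky <- tab
  tricky$sentence_text <- "has\ttab and\nnewline and \\slash"
  write_curation_tsv(tricky, path)
  back <- read_curation_tsv(path)
  expect_identical(back$sentence_text, tricky$sentence_text)
  expect_identical(back$subject_surface, tricky$subject_surface)
})
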