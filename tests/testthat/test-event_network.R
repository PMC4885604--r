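ggno_fixture <- function() {
  doc <- read_plain(paste(
    "ZEB1 activates Snail.",
    "Snail promotes Liver cancer, which metastasizes to the Liver."),
    "EV1")
  extract_relations(doc)
}

test_that("event composition realizes both chain templates", {
  # GGM: gene -> gene -> metastasis concept
  res <- extract_relations(read_plain(
    "TGF-beta induces Snail. Snail promotes metastasis.", "E1"))
  ev <- compose_events(res$relations)
  expect_length(ev, 1L)
  expect_identical(ev[[1L]]$event_type, "GGM")
  expect_identical(ev[[1L]]$participants$surface,
                   c("TGF-beta", "Snail", "metastasis"))

  # GGNO: gene -> gene -> neoplasm => organ
  res <- ggno_fixture()
  expect_equal(nrow(res$relations), 3L)
  ev <- compose_events(res$relations)
  expect_length(ev, 1L)
  expect_identical(ev[[1L]]$event_type, "GGNO")
  expect_identical(ev[[1L]]$participants$role,
                   c("gene_a", "gene_b", "neoplasm", "site"))
  # contributing relations are all drawn from the input
  expect_true(all(ev[[1L]]$relations$rule_id %in% res$relations$rule_id))

  # incomplete chains yield no events
  one <- res$relations[1L, , drop = FALSE]
  expect_length(compose_events(one), 0L)
  # chains span sentences within a document, never across documents
  other <- res$relations
  other$doc_id <- c("EV1", "EV2", "EV1")
  expect_error(compose_events(other), "single document")
})

test_that("removing any contributing relation dissolves the GGNO event", {
  rel <- ggno_fixture()$relations
  expect_length(compose_events(rel), 1L)
  for (drop in seq_len(nrow(rel))) {
    expect_length(compose_events(rel[-drop, , drop = FALSE]), 0L)
  }
})

test_that("build_network merges nodes by key and attaches evidence", {
  res <- extract_relations(read_plain(
    "TGF-beta induces Snail. Snail promotes metastasis.", "N1"))
  net <- build_network(res$relations)
  # two relations sharing the Snail node: 3 nodes, 2 edges
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(vapply(net$edges$evidence, nrow, integer(1)) > 0L))
  expect_true(all(net$edges$source_key %in% net$nodes$node_key))

  one <- build_network(res$relations[1L, , drop = FALSE])
  expect_equal(nrow(one$nodes), 2L)
  expect_equal(nrow(one$edges), 1L)

  empty <- build_network(metminer:::empty_relations())
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)

  # opposite polarities between the same pair stay distinct edges
  r2 <- rbind(make_rel("D", 0L, 20L, "positive_regulation"),
              make_rel("D", 0L, 20L, "negative_regulation"))
  net2 <- build_network(r2)
  expect_equal(nrow(net2$edges), 2L)
})

test_that("unnormalized mentions merge only on surface plus type", {
  r <- rbind(make_rel("D1", 0L, 20L, "positive_regulation"),
             make_rel("D2", 0L, 20L, "positive_regulation"))
  r$subject_id <- UNNORMALIZED
  r$subject_surface <- c("NovelGene", "NOVELGENE")   # case-folded merge
  net <- build_network(r)
  expect_equal(nrow(net$nodes), 2L)
  r$subject_surface <- c("NovelGene", "OtherGene")
  expect_equal(nrow(build_network(r)$nodes), 3L)
})

test_that("network integration is idempotent, commutative, associative", {
  res1 <- extract_relations(read_plain("TGF-beta induces Snail.", "A1"))
  res2 <- extract_relations(read_plain("TGF-beta inhibits Slug.", "A2"))
  n1 <- build_network(res1$relations)
  n2 <- build_network(res2$relations)
  merged <- integrate_networks(list(n1, n2))
  # shared TGF-beta node merges with both doc ids as evidence
  expect_equal(nrow(merged$nodes),
               nrow(n1$nodes) + nrow(n2$nodes) - 1L)
  tg <- merged$nodes[merged$nodes$node_key == "EntrezGene:7040", ]
  expect_setequal(tg$evidence_doc_ids[[1L]], c("A1", "A2"))

  expect_network_equal(integrate_networks(list(n1, n1)), n1)
  expect_network_equal(integrate_networks(list(n1, n2)),
                       integrate_networks(list(n2, n1)))
  empty <- integrate_networks(list())
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("graph JSON round-trips and GraphML is well-formed", {
  res <- ggno_fixture()
  net <- build_network(res$relations, compose_events(res$relations))
  path <- tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_network_equal(net, back)
  expect_length(back$events, 1L)

  # deterministic bytes
  path2 <- tempfile(fileext = ".json")
  write_network_json(net, path2)
  expect_identical(readLines(path), readLines(path2))

  # an edge without its endpoint is rejected
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  raw$nodes <- raw$nodes[-1L]
  jsonlite::write_json(raw, path, auto_unbox = TRUE)
  expect_error(read_network_json(path), "has no node")

  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  doc <- xml2::read_xml(gml)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)),
               nrow(net$nodes))
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)),
               nrow(net$edges))
})
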