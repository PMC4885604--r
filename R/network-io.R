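# Network serialization.  The JSON schema is the package's interchange
# format; GraphML export carries the same fields as attributes for generic
# graph viewers.

#' Read and write metastasis networks as graph JSON
#'
#' Schema: `{"nodes": [{"node_key", "label", "concept_type",
#' "evidence_doc_ids": []}], "edges": [{"source_key", "target_key",
#' "relation_type", "evidence": [{"doc_id", "sentence_index",
#' "sentence_text"}]}], "events": [{"event_type", "chain": []}]}`.
#' Output is canonically ordered, so identical networks serialize to
#' identical bytes.
#'
#' @param network A `met_network`.
#' @param path File path.
#' @return `read_network_json` returns a `met_network`;
#'   `write_network_json` returns `path` invisibly.
#' @export
write_network_json <- function(network, path) {
  net <- canonicalize_network(network)
  nodes <- lapply(seq_len(nrow(net$nodes)), function(i) {
    list(node_key = net$nodes$node_key[i],
         label = net$nodes$label[i],
         concept_type = net$nodes$concept_type[i],
         evidence_doc_ids = as.list(net$nodes$evidence_doc_ids[[i]]))
  })
  edges <- lapply(seq_len(nrow(net$edges)), function(i) {
    ev <- net$edges$evidence[[i]]
    list(source_key = net$edges$source_key[i],
         target_key = net$edges$target_key[i],
         relation_type = net$edges$relation_type[i],
         evidence = lapply(seq_len(nrow(ev)), function(j) {
           list(doc_id = ev$doc_id[j],
                sentence_index = ev$sentence_index[j],
                sentence_text = ev$sentence_text[j])
         }))
  })
  payload <- list(nodes = nodes, edges = edges)
  if (!is.null(net$events)) {
    payload$events <- lapply(net$events, function(e) {
      list(event_type = e$event_type, chain = as.list(e$chain))
    })
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.list(raw) || !all(c("nodes", "edges") %in% names(raw))) {
    stop("graph JSON '", path, "': expected top-level nodes and edges",
         call. = FALSE)
  }
  net <- empty_network()
  if (length(raw$nodes) > 0L) {
    net$nodes <- data.frame(
      node_key = vapply(raw$nodes, `[[`, character(1), "node_key"),
      label = vapply(raw$nodes, `[[`, character(1), "label"),
      concept_type = vapply(raw$nodes, `[[`, character(1), "concept_type"),
      stringsAsFactors = FALSE)
    net$nodes$evidence_doc_ids <- lapply(raw$nodes, function(n) {
      as.character(unlist(n$evidence_doc_ids))
    })
  }
  if (length(raw$edges) > 0L) {
    net$edges <- data.frame(
      source_key = vapply(raw$edges, `[[`, character(1), "source_key"),
      target_key = vapply(raw$edges, `[[`, character(1), "target_key"),
      relation_type = vapply(raw$edges, `[[`, character(1),
                             "relation_type"),
      stringsAsFactors = FALSE)
    net$edges$evidence <- lapply(raw$edges, function(e) {
      data.frame(
        doc_id = vapply(e$evidence, `[[`, character(1), "doc_id"),
        sentence_index = vapply(e$evidence, function(x) {
          as.integer(x$sentence_index)
        }, integer(1)),
        sentence_text = vapply(e$evidence, `[[`, character(1),
                               "sentence_text"),
        stringsAsFactors = FALSE)
    })
  }
  if (!is.null(raw$events) && length(raw$events) > 0L) {
    net$events <- lapply(raw$events, function(e) {
      list(event_type = e$event_type, chain = as.character(unlist(e$chain)))
    })
  }
  bad <- setdiff(c(net$edges$source_key, net$edges$target_key),
                 net$nodes$node_key)
  if (length(bad) > 0L) {
    stop("graph JSON '", path, "': edge endpoint '", bad[1L],
         "' has no node", call. = FALSE)
  }
  canonicalize_network(net)
}

#' Export a network as GraphML
#'
#' Node attributes: `label`, `concept_type`, `evidence_doc_ids`
#' (semicolon-joined); edge attributes: `relation_type`,
#' `evidence_count`, `evidence` (JSON-encoded list).
#'
#' @inheritParams write_network_json
#' @export
write_graphml <- function(network, path) {
  net <- canonicalize_network(network)
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c("d_label", "node", "label", "string"),
    c("d_ctype", "node", "concept_type", "string"),
    c("d_docs", "node", "evidence_doc_ids", "string"),
    c("d_rtype", "edge", "relation_type", "string"),
    c("d_evn", "edge", "evidence_count", "int"),
    c("d_ev", "edge", "evidence", "string"))
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1L], `for` = k[2L],
                        attr.name = k[3L], attr.type = k[4L])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "met", edgedefault = "directed")
  for (i in seq_len(nrow(net$nodes))) {
    n <- xml2::xml_add_child(g, "node", id = net$nodes$node_key[i])
    add_data <- function(parent, key, value) {
      d <- xml2::xml_add_child(parent, "data", key = key)
      xml2::xml_text(d) <- as.character(value)
    }
    add_data(n, "d_label", net$nodes$label[i])
    add_data(n, "d_ctype", net$nodes$concept_type[i])
    add_data(n, "d_docs",
             paste(net$nodes$evidence_doc_ids[[i]], collapse = ";"))
  }
  for (i in seq_len(nrow(net$edges))) {
    e <- xml2::xml_add_child(g, "edge",
                             source = net$edges$source_key[i],
                             target = net$edges$target_key[i])
    d <- xml2::xml_add_child(e, "data", key = "d_rtype")
    xml2::xml_text(d) <- net$edges$relation_type[i]
    d <- xml2::xml_add_child(e, "data", key = "d_evn")
    xml2::xml_text(d) <- as.character(nrow(net$edges$evidence[[i]]))
    d <- xml2::xml_add_child(e, "data", key = "d_ev")
    xml2::xml_text(d) <- as.character(
      jsonlite::toJSON(net$edges$evidence[[i]], auto_unbox = TRUE))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
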