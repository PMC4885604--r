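# Event composition and network assembly.
#
# Nodes are keyed on the normalized identifier when one exists; mentions
# without an identifier merge only on (concept type, case-folded
# Greek-normalized surface).  Edge identity includes the relation type, so
# a positive and a negative regulation between the same pair stay distinct.

node_key <- function(concept_type, surface, normalized_id) {
  ifelse(normalized_id != UNNORMALIZED, normalized_id,
         paste0(concept_type, ":", tolower(norm_key(surface))))
}

.metastasis_umbrella <- c("NeoplasmMetastasis", "Cytoskeleton",
                          "CellMovement", "CellAdhesion")
.gene_like <- c("Gene", "MicroRNA")
.regulation_types <- c("positive_regulation", "negative_regulation",
                       "neutral_regulation")

#' Compose binary relations into metastasis events
#'
#' Two event templates are recognized over the relations of a single
#' document (relations from different sentences may chain):
#' * `GGM`  — gene regulates gene, which regulates a metastasis-process
#'   concept (metastasis, cytoskeleton, cell movement or cell adhesion);
#' * `GGNO` — gene regulates gene, which regulates a cancer, which
#'   metastasizes to a tissue or organ.
#' Chains share their middle participants by node key.  Relations that do
#' not complete a chain stay bare relations and emit no event.
#'
#' @param relations Relation-instance frame for one document.
#' @return A `met_events` list; each event has `event_type`, a
#'   `participants` data frame (role, surface, concept_type, normalized_id,
#'   node_key) and `relations` (the contributing relation rows).
#' @export
compose_events <- function(relations) {
  ev <- list()
  if (nrow(relations) > 0L &&
      length(unique(relations$doc_id)) > 1L) {
    stop("compose_events expects relations from a single document",
         call. = FALSE)
  }
  skey <- node_key(relations$subject_type, relations$subject_surface,
                   relations$subject_id)
  okey <- node_key(relations$object_type, relations$object_surface,
                   relations$object_id)
  is_reg <- relations$relation_type %in% .regulation_types
  gg <- which(is_reg & relations$subject_type %in% .gene_like &
                relations$object_type %in% .gene_like)
  gm <- which(is_reg & relations$subject_type %in% .gene_like &
                relations$object_type %in% .metastasis_umbrella)
  gn <- which(is_reg & relations$subject_type %in% .gene_like &
                relations$object_type == "Neoplasms")
  nm <- which(relations$relation_type == "metastasis")

  participant <- function(role, i, side) {
    if (side == "subject") {
      data.frame(role = role, surface = relations$subject_surface[i],
                 concept_type = relations$subject_type[i],
                 normalized_id = relations$subject_id[i],
                 node_key = skey[i], stringsAsFactors = FALSE)
    } else {
      data.frame(role = role, surface = relations$object_surface[i],
                 concept_type = relations$object_type[i],
                 normalized_id = relations$object_id[i],
                 node_key = okey[i], stringsAsFactors = FALSE)
    }
  }

  seen <- character(0)
  add_event <- function(type, parts, rel_rows) {
    sig <- paste(type, paste(parts$node_key, collapse = "|"))
    if (sig %in% seen) return()
    seen <<- c(seen, sig)
    ev[[length(ev) + 1L]] <<- list(
      event_type = type, participants = parts,
      relations = relations[rel_rows, , drop = FALSE])
  }

  for (i in gg) {
    for (j in gm) {
      if (okey[i] == skey[j]) {
        add_event("GGM", rbind(participant("gene_a", i, "subject"),
                               participant("gene_b", i, "object"),
                               participant("metastasis_concept", j,
                                           "object")),
                  c(i, j))
      }
    }
    for (j in gn) {
      if (okey[i] != skey[j]) next
      for (k in nm) {
        if (okey[j] == skey[k]) {
          add_event("GGNO", rbind(participant("gene_a", i, "subject"),
                                  participant("gene_b", i, "object"),
                                  participant("neoplasm", j, "object"),
                                  participant("site", k, "object")),
                    c(i, j, k))
        }
      }
    }
  }
  structure(ev, class = "met_events")
}

#' @export
print.met_events <- function(x, ...) {
  cat("<met_events> ", length(x), " event(s)\n", sep = "")
  for (e in x) {
    cat("  ", e$event_type, ": ",
        paste(e$participants$surface, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

empty_network <- function() {
  nodes <- data.frame(node_key = character(0), label = character(0),
                      concept_type = character(0), stringsAsFactors = FALSE)
  nodes$evidence_doc_ids <- list()
  edges <- data.frame(source_key = character(0), target_key = character(0),
                      relation_type = character(0), stringsAsFactors = FALSE)
  edges$evidence <- list()
  structure(list(nodes = nodes, edges = edges), class = "met_network")
}

#' Build a metastasis network from relations
#'
#' Every relation contributes its two endpoint nodes and one edge keyed on
#' (source node, target node, relation type); the supporting sentence is
#' attached as edge evidence.  Composed events, when supplied, are recorded
#' as participant-key chains alongside the graph.
#'
#' @param relations Relation-instance frame.
#' @param events Optional `met_events` from [compose_events()].
#' @param doc_id Unused except for labelling; networks can span documents.
#' @return A `met_network`: `nodes` (`node_key`, `label`, `concept_type`,
#'   `evidence_doc_ids` list column) and `edges` (`source_key`,
#'   `target_key`, `relation_type`, `evidence` list column of
#'   doc/sentence/text records), plus `events` chains.
#' @export
build_network <- function(relations, events = NULL, doc_id = NULL) {
  net <- empty_network()
  nodes <- list()
  edges <- list()
  for (i in seq_len(nrow(relations))) {
    r <- relations[i, ]
    sk <- node_key(r$subject_type, r$subject_surface, r$subject_id)
    ok <- node_key(r$object_type, r$object_surface, r$object_id)
    for (side in list(c(sk, r$subject_surface, r$subject_type),
                      c(ok, r$object_surface, r$object_type))) {
      k <- side[1L]
      if (is.null(nodes[[k]])) {
        nodes[[k]] <- list(node_key = k, label = side[2L],
                           concept_type = side[3L],
                           evidence_doc_ids = character(0))
      }
      nodes[[k]]$evidence_doc_ids <-
        union(nodes[[k]]$evidence_doc_ids, r$doc_id)
    }
    ek <- paste(sk, ok, r$relation_type, sep = "\r")
    if (is.null(edges[[ek]])) {
      edges[[ek]] <- list(source_key = sk, target_key = ok,
                          relation_type = r$relation_type,
                          evidence = data.frame(
                            doc_id = character(0),
                            sentence_index = integer(0),
                            sentence_text = character(0),
                            stringsAsFactors = FALSE))
    }
    evi <- edges[[ek]]$evidence
    if (!any(evi$doc_id == r$doc_id &
               evi$sentence_index == r$sentence_index)) {
      edges[[ek]]$evidence <- rbind(evi, data.frame(
        doc_id = r$doc_id, sentence_index = r$sentence_index,
        sentence_text = r$sentence_text, stringsAsFactors = FALSE))
    }
  }
  if (length(nodes) > 0L) {
    net$nodes <- data.frame(
      node_key = vapply(nodes, `[[`, character(1), "node_key"),
      label = vapply(nodes, `[[`, character(1), "label"),
      concept_type = vapply(nodes, `[[`, character(1), "concept_type"),
      stringsAsFactors = FALSE)
    net$nodes$evidence_doc_ids <-
      unname(lapply(nodes, `[[`, "evidence_doc_ids"))
  }
  if (length(edges) > 0L) {
    net$edges <- data.frame(
      source_key = vapply(edges, `[[`, character(1), "source_key"),
      target_key = vapply(edges, `[[`, character(1), "target_key"),
      relation_type = vapply(edges, `[[`, character(1), "relation_type"),
      stringsAsFactors = FALSE)
    net$edges$evidence <- unname(lapply(edges, `[[`, "evidence"))
  }
  if (!is.null(events) && length(events) > 0L) {
    net$events <- lapply(events, function(e) {
      list(event_type = e$event_type, chain = e$participants$node_key)
    })
  }
  canonicalize_network(net)
}

# Deterministic ordering of nodes, edges and evidence; the basis for
# network equality in tests and for serialization.
canonicalize_network <- function(net) {
  n <- net$nodes
  if (nrow(n) > 0L) {
    ord <- order(n$node_key)
    n <- n[ord, , drop = FALSE]
    n$evidence_doc_ids <- lapply(n$evidence_doc_ids,
                                 function(x) sort(unique(x)))
    row.names(n) <- NULL
  }
  e <- net$edges
  if (nrow(e) > 0L) {
    ord <- order(e$source_key, e$target_key, e$relation_type)
    e <- e[ord, , drop = FALSE]
    e$evidence <- lapply(e$evidence, function(ev) {
      ev <- ev[!duplicated(paste(ev$doc_id, ev$sentence_index)), ,
               drop = FALSE]
      ev <- ev[order(ev$doc_id, ev$sentence_index), , drop = FALSE]
      row.names(ev) <- NULL
      ev
    })
    row.names(e) <- NULL
  }
  net$nodes <- n
  net$edges <- e
  if (!is.null(net$events) && length(net$events) > 0L) {
    sig <- vapply(net$events, function(x) {
      paste(x$event_type, paste(x$chain, collapse = "|"))
    }, character(1))
    net$events <- net$events[order(sig)]
    net$events <- net$events[!duplicated(sort(sig))]
  }
  net
}

#' Integrate networks from several documents
#'
#' Node-key based union: node evidence document sets are unioned, edge
#' evidence lists concatenated and deduplicated.  The operation is
#' idempotent, commutative and associative up to canonical ordering.
#'
#' @param networks A list of `met_network` objects.
#' @return The merged `met_network`.
#' @export
integrate_networks <- function(networks) {
  nodes <- list()
  edges <- list()
  all_events <- list()
  for (net in networks) {
    stopifnot(inherits(net, "met_network"))
    for (i in seq_len(nrow(net$nodes))) {
      k <- net$nodes$node_key[i]
      if (is.null(nodes[[k]])) {
        nodes[[k]] <- list(node_key = k, label = net$nodes$label[i],
                           concept_type = net$nodes$concept_type[i],
                           evidence_doc_ids = character(0))
      }
      nodes[[k]]$evidence_doc_ids <- union(
        nodes[[k]]$evidence_doc_ids, net$nodes$evidence_doc_ids[[i]])
    }
    for (i in seq_len(nrow(net$edges))) {
      k <- paste(net$edges$source_key[i], net$edges$target_key[i],
                 net$edges$relation_type[i], sep = "\r")
      if (is.null(edges[[k]])) {
        edges[[k]] <- list(source_key = net$edges$source_key[i],
                           target_key = net$edges$target_key[i],
                           relation_type = net$edges$relation_type[i],
                           evidence = net$edges$evidence[[i]])
      } else {
        edges[[k]]$evidence <- rbind(edges[[k]]$evidence,
                                     net$edges$evidence[[i]])
      }
    }
    if (!is.null(net$events)) {
      all_events <- c(all_events, net$events)
    }
  }
  out <- empty_network()
  if (length(nodes) > 0L) {
    out$nodes <- data.frame(
      node_key = vapply(nodes, `[[`, character(1), "node_key"),
      label = vapply(nodes, `[[`, character(1), "label"),
      concept_type = vapply(nodes, `[[`, character(1), "concept_type"),
      stringsAsFactors = FALSE)
    out$nodes$evidence_doc_ids <-
      unname(lapply(nodes, `[[`, "evidence_doc_ids"))
  }
  if (length(edges) > 0L) {
    out$edges <- data.frame(
      source_key = vapply(edges, `[[`, character(1), "source_key"),
      target_key = vapply(edges, `[[`, character(1), "target_key"),
      relation_type = vapply(edges, `[[`, character(1), "relation_type"),
      stringsAsFactors = FALSE)
    out$edges$evidence <- unname(lapply(edges, `[[`, "evidence"))
  }
  if (length(all_events) > 0L) out$events <- all_events
  canonicalize_network(out)
}

#' @export
print.met_network <- function(x, ...) {
  cat("<met_network> ", nrow(x$nodes), " node(s), ", nrow(x$edges),
      " edge(s)\n", sep = "")
  invisible(x)
}
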