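# BioC XML interchange.
#
# Infon keys used by this package (the format reference for our BioC
# output): annotations carry "type" (concept type), "identifier"
# (namespaced id or UNNORMALIZED), "provenance" and "ambiguous"; relations
# carry "type" (relation type), "rule_id", "trigger_class",
# "trigger_offset", "trigger_length", "trigger_text" and "sentence_index",
# and reference their subject/object annotations through <node> elements.
# BioC locations are offset+length; they are converted to the package's
# 0-based half-open character offsets at this boundary.

bioc_abstract_offset <- function(title) {
  if (nzchar(title)) nchar(title) + 1L else 0L
}

#' Write a BioC XML collection
#'
#' @param documents A `met_document` or list of them.
#' @param mentions Concept-mention frame covering the documents.
#' @param relations Relation-instance frame; each relation's subject and
#'   object must exist in `mentions` (same span and type), otherwise an
#'   error names the offending relation.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bioc <- function(documents, mentions = empty_mentions(),
                       relations = empty_relations(), path) {
  if (inherits(documents, "met_document")) documents <- list(documents)
  ids <- vapply(documents, `[[`, character(1), "doc_id")
  documents <- documents[order(ids)]
  ids <- sort(ids)
  stray <- setdiff(unique(c(mentions$doc_id, relations$doc_id)), ids)
  if (length(stray) > 0L) {
    stop("annotations reference unknown document '", stray[1L], "'",
         call. = FALSE)
  }
  root <- xml2::xml_new_root("collection")
  xml2::xml_add_child(root, "source", "metminer")
  xml2::xml_add_child(root, "date", "")
  xml2::xml_add_child(root, "key", "metminer.key")

  for (doc in documents) {
    dnode <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(dnode, "id", doc$doc_id)
    tpass <- xml2::xml_add_child(dnode, "passage")
    add_infon(tpass, "section", "title")
    xml2::xml_add_child(tpass, "offset", "0")
    xml2::xml_add_child(tpass, "text", doc$title)
    apass <- xml2::xml_add_child(dnode, "passage")
    add_infon(apass, "section", "abstract")
    shift <- bioc_abstract_offset(doc$title)
    xml2::xml_add_child(apass, "offset", as.character(shift))
    xml2::xml_add_child(apass, "text", doc$abstract_text)

    dm <- mentions[mentions$doc_id == doc$doc_id, , drop = FALSE]
    dm <- dm[order(dm$char_start, dm$char_end, dm$concept_type), ,
             drop = FALSE]
    ann_key <- character(0)
    for (i in seq_len(nrow(dm))) {
      aid <- paste0("A", i)
      ann_key[aid] <- mention_key(dm[i, ])
      a <- xml2::xml_add_child(apass, "annotation", id = aid)
      add_infon(a, "type", dm$concept_type[i])
      add_infon(a, "identifier", dm$normalized_id[i])
      add_infon(a, "provenance", dm$provenance[i])
      add_infon(a, "ambiguous", tolower(as.character(dm$ambiguous[i])))
      xml2::xml_add_child(a, "location",
                          offset = as.character(dm$char_start[i] + shift),
                          length = as.character(dm$char_end[i] -
                                                  dm$char_start[i]))
      xml2::xml_add_child(a, "text", dm$surface[i])
    }

    dr <- relations[relations$doc_id == doc$doc_id, , drop = FALSE]
    dr <- dr[order(dr$sentence_index, dr$subject_start, dr$object_start,
                   dr$trigger_start, dr$relation_type), , drop = FALSE]
    for (i in seq_len(nrow(dr))) {
      r <- dr[i, ]
      sidx <- match(paste(r$subject_start, r$subject_end, r$subject_type),
                    unname(ann_key))
      oidx <- match(paste(r$object_start, r$object_end, r$object_type),
                    unname(ann_key))
      if (is.na(sidx) || is.na(oidx)) {
        stop("relation ", i, " (", r$rule_id, ") in document '",
             doc$doc_id,
             "' references a mention that is not in the mention set",
             call. = FALSE)
      }
      sid <- names(ann_key)[sidx]
      oid <- names(ann_key)[oidx]
      rel <- xml2::xml_add_child(apass, "relation", id = paste0("R", i))
      add_infon(rel, "type", r$relation_type)
      add_infon(rel, "rule_id", r$rule_id)
      add_infon(rel, "trigger_class", r$trigger_class)
      add_infon(rel, "trigger_offset",
                as.character(r$trigger_start + shift))
      add_infon(rel, "trigger_length",
                as.character(r$trigger_end - r$trigger_start))
      add_infon(rel, "trigger_text", r$trigger_surface)
      add_infon(rel, "sentence_index", as.character(r$sentence_index))
      xml2::xml_add_child(rel, "node", refid = sid, role = "subject")
      xml2::xml_add_child(rel, "node", refid = oid, role = "object")
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

add_infon <- function(node, key, value) {
  inf <- xml2::xml_add_child(node, "infon", key = key)
  xml2::xml_text(inf) <- value
  inf
}

mention_key <- function(m) paste(m$char_start, m$char_end, m$concept_type)

infon <- function(node, key, default = "") {
  v <- xml2::xml_text(xml2::xml_find_first(
    node, sprintf("./infon[@key='%s']", key)))
  if (is.na(v)) default else v
}

#' Read a BioC XML collection
#'
#' @param path Path to a BioC XML file.
#' @return A list with `documents` (named list of `met_document`),
#'   `mentions` and `relations` data frames in 0-based half-open document
#'   coordinates.  Annotations whose "type" infon is not one of the nine
#'   concept types are preserved with `unknown_type = TRUE` and a warning.
#' @export
read_bioc <- function(path) {
  xml <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("malformed BioC XML in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  documents <- list()
  mention_list <- list()
  relation_list <- list()
  for (dnode in xml2::xml_find_all(xml, "./document")) {
    doc_id <- xml2::xml_text(xml2::xml_find_first(dnode, "./id"))
    passages <- xml2::xml_find_all(dnode, "./passage")
    sections <- vapply(passages, infon, character(1), key = "section")
    title <- ""
    if (any(sections == "title")) {
      title <- xml2::xml_text(xml2::xml_find_first(
        passages[[which(sections == "title")[1L]]], "./text"))
    }
    apass <- if (any(sections == "abstract")) {
      passages[[which(sections == "abstract")[1L]]]
    } else {
      passages[[length(passages)]]
    }
    abstract <- xml2::xml_text(xml2::xml_find_first(apass, "./text"))
    shift <- as.integer(xml2::xml_text(
      xml2::xml_find_first(apass, "./offset")))
    doc <- read_plain(abstract, doc_id, title)
    documents[[doc_id]] <- doc

    ann_nodes <- xml2::xml_find_all(apass, "./annotation")
    ann_by_id <- list()
    unknown_seen <- character(0)
    for (a in ann_nodes) {
      aid <- xml2::xml_attr(a, "id")
      loc <- xml2::xml_find_first(a, "./location")
      off <- as.integer(xml2::xml_attr(loc, "offset"))
      len <- as.integer(xml2::xml_attr(loc, "length"))
      start0 <- off - shift
      end0 <- start0 + len
      if (is.na(start0) || start0 < 0L || end0 > nchar(abstract) ||
          len <= 0L) {
        stop("annotation '", aid, "' in document '", doc_id,
             "' has a span outside the passage text", call. = FALSE)
      }
      surface <- xml2::xml_text(xml2::xml_find_first(a, "./text"))
      got <- slice0(abstract, start0, end0)
      if (!identical(surface, got)) {
        stop("annotation '", aid, "' in document '", doc_id,
             "': text '", surface, "' does not match passage slice '",
             got, "'", call. = FALSE)
      }
      ctype <- infon(a, "type")
      unknown <- !(ctype %in% concept_types())
      if (unknown) unknown_seen <- c(unknown_seen, ctype)
      m <- concept_mentions(
        doc_id = doc_id,
        sentence_index = sentence_index_at(doc, start0),
        char_start = start0, char_end = end0, surface = surface,
        concept_type = ctype,
        normalized_id = infon(a, "identifier", UNNORMALIZED),
        provenance = infon(a, "provenance", "gold"),
        ambiguous = identical(infon(a, "ambiguous", "false"), "true"),
        unknown_type = unknown)
      mention_list[[length(mention_list) + 1L]] <- m
      ann_by_id[[aid]] <- m
    }
    if (length(unknown_seen) > 0L) {
      warning("document '", doc_id, "': unknown concept type infon(s) ",
              paste(unique(unknown_seen), collapse = ", "),
              " preserved but flagged", call. = FALSE)
    }

    for (rnode in xml2::xml_find_all(apass, "./relation")) {
      rid <- xml2::xml_attr(rnode, "id")
      refs <- xml2::xml_find_all(rnode, "./node")
      roles <- xml2::xml_attr(refs, "role")
      refids <- xml2::xml_attr(refs, "refid")
      subj <- ann_by_id[[refids[roles == "subject"][1L]]]
      obj <- ann_by_id[[refids[roles == "object"][1L]]]
      if (is.null(subj) || is.null(obj)) {
        stop("relation '", rid, "' in document '", doc_id,
             "' references a missing annotation", call. = FALSE)
      }
      tro <- as.integer(infon(rnode, "trigger_offset", "0")) - shift
      trl <- as.integer(infon(rnode, "trigger_length", "0"))
      sidx <- as.integer(infon(
        rnode, "sentence_index",
        as.character(sentence_index_at(doc, subj$char_start))))
      srow <- doc$sentences[doc$sentences$index == sidx, , drop = FALSE]
      relation_list[[length(relation_list) + 1L]] <- data.frame(
        doc_id = doc_id, sentence_index = sidx,
        subject_start = subj$char_start, subject_end = subj$char_end,
        subject_surface = subj$surface, subject_type = subj$concept_type,
        subject_id = subj$normalized_id,
        object_start = obj$char_start, object_end = obj$char_end,
        object_surface = obj$surface, object_type = obj$concept_type,
        object_id = obj$normalized_id,
        trigger_start = tro, trigger_end = tro + trl,
        trigger_surface = infon(rnode, "trigger_text"),
        trigger_class = infon(rnode, "trigger_class"),
        relation_type = infon(rnode, "type"),
        rule_id = infon(rnode, "rule_id"),
        sentence_text = if (nrow(srow) == 1L) srow$text else "",
        stringsAsFactors = FALSE)
    }
  }
  list(documents = documents,
       mentions = rbind_records(mention_list, empty_mentions()),
       relations = rbind_records(relation_list, empty_relations()))
}
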