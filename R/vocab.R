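#' Concept types, trigger classes and relation types
#'
#' The annotation schema is a closed vocabulary: nine concept types
#' (genes/microRNAs, four metastasis-process types, cancers, organs and
#' tissues), four trigger classes and four relation types.  No other value
#' is accepted anywhere in the package.
#'
#' @return Character vector of the legal values.
#' @export
#' @examples
#' concept_types()
concept_types <- function() {
  c("Gene", "MicroRNA", "NeoplasmMetastasis", "Cytoskeleton",
    "CellMovement", "CellAdhesion", "Neoplasms", "Organ", "Tissues")
}

#' @rdname concept_types
#' @export
trigger_classes <- function() {
  c("POSITIVE_REG", "NEGATIVE_REG", "NEUTRAL_REG", "METASTASIS_TRIGGER")
}

#' @rdname concept_types
#' @export
relation_types <- function() {
  c("positive_regulation", "negative_regulation", "neutral_regulation",
    "metastasis")
}

#' @rdname concept_types
#' @export
concept_tags <- function() {
  c(Gene = "GENE", MicroRNA = "MIRNA", NeoplasmMetastasis = "METASTASIS",
    Cytoskeleton = "CYTOSKELETON", CellMovement = "CELL_MOVEMENT",
    CellAdhesion = "CELL_ADHESION", Neoplasms = "NEOPLASMS",
    Organ = "ORGAN", Tissues = "TISSUES")
}

# relation type implied by each trigger class
.trigger_relation <- c(
  POSITIVE_REG = "positive_regulation",
  NEGATIVE_REG = "negative_regulation",
  NEUTRAL_REG = "neutral_regulation",
  METASTASIS_TRIGGER = "metastasis"
)

#' Sentinel for mentions without a database identifier
#' @export
UNNORMALIZED <- "UNNORMALIZED"

# Concept types a pattern slot tag accepts.  Two umbrella rules mirror the
# curation schema: regulation between "genes" includes microRNAs, and the
# metastasis process umbrella covers cytoskeleton, cell movement and cell
# adhesion in addition to metastasis proper.
slot_accepts <- function(slot_tag) {
  switch(slot_tag,
    GENE = c("GENE", "MIRNA"),
    MIRNA = "MIRNA",
    METASTASIS = c("METASTASIS", "CYTOSKELETON", "CELL_MOVEMENT",
                   "CELL_ADHESION"),
    slot_tag
  )
}

is_concept_tag <- function(tag) tag %in% unname(concept_tags())
is_trigger_tag <- function(tag) tag %in% trigger_classes()

# expected identifier namespace per concept type
id_namespace <- function(concept_type) {
  ifelse(concept_type %in% c("Gene", "MicroRNA"), "EntrezGene", "MeSH")
}
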