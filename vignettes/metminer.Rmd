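---
title: "Mining metastasis networks from abstracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining metastasis networks from abstracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metminer)
```

## The problem

Metastasis research produces statements of a recurring shape: a gene or
microRNA regulates another gene; that regulation promotes or suppresses a
metastatic process (cell movement, adhesion, cytoskeletal remodelling) or
a cancer; a cancer metastasizes to an organ or tissue.  `metminer`
extracts these statements from abstract text, normalizes the participants
to database identifiers, and assembles them into networks whose every
edge can be traced back to a supporting sentence.  This vignette explains
the model, the tunable parameters, the numerical and tie-breaking
conventions, and the limits of what a passing test establishes.

## The annotation schema

Nine concept types form a closed vocabulary: `Gene`, `MicroRNA`,
`NeoplasmMetastasis`, `Cytoskeleton`, `CellMovement`, `CellAdhesion`,
`Neoplasms`, `Organ`, `Tissues`.  The middle four deserve comment:
metastasis is a process composed of sub-processes, so cytoskeleton,
cell-movement and cell-adhesion mentions are treated as instances of the
metastasis-process umbrella wherever a pattern slot asks for
`<METASTASIS>`, while retaining their finer type on the mention itself.
Genes and microRNAs are normalized to Entrez Gene identifiers
(`EntrezGene:7040`), everything else to MeSH (`MeSH:D009362`); a mention
the lexicon cannot resolve carries the sentinel `UNNORMALIZED`.

Relations come in four types: `positive_regulation`,
`negative_regulation`, `neutral_regulation` (used when the direction of
control cannot be determined from context) and `metastasis`, which is
constrained to run from a `Neoplasms` subject to a `Tissues` or `Organ`
object.  Each relation is anchored to exactly one supporting sentence.

## Concept recognition

**Sentence segmentation** splits at `.`, `!` or `?` followed by
whitespace and an uppercase letter or digit; a guard list of scientific
abbreviations ("et al.", "Fig.", "vs.", "e.g.", ...) suppresses false
splits, ignoring any opening bracket in front of the abbreviation.  All
offsets in the package are 0-based, half-open, character (not byte)
offsets; BioC's offset+length convention is converted at the I/O
boundary and nowhere else.

**Dictionary matching** is token-boundary-anchored exact matching over
Greek-normalized text.  Greek letters expand to their spelled-out forms
before lookup (with an offset map back to the original text), so
`TGF-β` and `TGF-beta` hit the same entry while the reported span stays
exact.  A match must start and end at transitions between word
characters (letters, digits) and non-word characters; hyphens
(ASCII and U+2010) and slashes are word-internal, which blocks substring
hits such as `Snail` inside `Snail-like`.  Case policy: surfaces of at
most 4 characters or containing a digit (gene-symbol-like, e.g. `MET`,
`AKT1`) match case-sensitively; longer surfaces match case-folded.
Overlaps resolve left to right with longest-match-wins; equal-length ties
fall back to lexicon order, which is therefore part of the documented
contract, not an accident of implementation.  Surfaces mapping to
several identifiers take the first lexicon entry and flag the mention
`ambiguous` — there is deliberately no multistage disambiguation here.

**MicroRNA recognition** is rule-based: a token-anchored pattern over the
`miR`/`microRNA`/`miRNA`/`let` prefixes, digit groups with optional
letter suffixes, cluster forms (`miR-200b/200c`) and starred passenger
strands.  On any overlap with a dictionary mention the rule-based mention
wins as the more specific source; its identifier is filled from the
lexicon when the surface is listed there.  Mentions never cross sentence
boundaries, because relations are sentence-scoped.

## Relation extraction

Sentences are tokenized on word-character runs; each concept mention
collapses to a single tagged token covering its whole span, so the
inside of a mention can never be re-tagged.  Remaining tokens are looked
up in the trigger lexicon by lemma: the candidate set strips `-s`/`-es`,
`-ed`/`-d`, `-ing` (with `e` restoration) and `-ion`/`-tion`→`-te`, so
"inhibition" finds `inhibit` and "regulation" finds `regulate`.  Trigger
entries are verbs or nominal verbs by definition; the loader rejects a
bundled stop list of adverbs and quantifiers ("more", "frequently", ...)
because words like "more" in "was observed more frequently" signal
comparison, not a direct relation.

A pattern rule is an ordered list of slot tags — concept tags or trigger
classes — with designated subject, trigger and object slots and a
`max_gap`.  Matching semantics: consecutive slots must bind consecutive
*tagged* tokens, with at most `max_gap` plain tokens between them.  Two
consequences are intentional: a tagged token can never be skipped (an
intervening concept or trigger blocks the match), and subject/object
roles come from the rule's slot indices rather than surface order, so
passive-voice rules with the object first are expressible.  The bundled
rule set covers the four decomposed relation forms with `max_gap = 3`, a
small allowance for determiners and modifiers ("the growth of");
adjacency-only behaviour is available by setting `max_gap = 0`.  The
`<GENE>` slot accepts both `Gene` and `MicroRNA` mentions, mirroring the
schema's reading that regulation "between genes" includes microRNAs;
`<METASTASIS>` accepts the four process types.  Duplicate matches (same
subject, object, trigger and type) collapse onto the first rule in file
order; output is ordered by rule order then position, making extraction
deterministic end to end.

Negation is *not* handled: a plain "not" inside the gap does not block a
match.  This is a documented limitation rather than an oversight — no
principled treatment is possible without syntax, which is out of scope.

## Events and networks

Within one document (chains may span sentences, since few abstracts put a
whole pathway in one sentence), relations compose into two event shapes:

* **GGM** — `gene → gene → metastasis-process concept`;
* **GGNO** — `gene → gene → neoplasm ⇒ tissue/organ`.

Participants chain by *node key*: the normalized identifier when one
exists, otherwise concept type plus case-folded, Greek-normalized
surface.  The same keys drive network construction, so two abstracts
mentioning `TGF-β` and `TGF-beta` contribute to a single node.  Edge
identity includes the relation type — a positive and a negative
regulation between the same pair are different biology and stay distinct
edges — and each edge carries its deduplicated list of supporting
(document, sentence) evidence.  `integrate_networks()` is a node-key
union with evidence merging; it is idempotent, commutative and
associative up to canonical ordering, which the test suite checks as an
algebraic property.  Networks serialize to a documented graph JSON (the
canonical ordering makes serialization byte-deterministic) and to
GraphML; both carry the raw relation layer and the composed event chains,
leaving the choice of display layer to the consumer.

## Evaluation protocol

Scoring follows the gold-concept-boundaries protocol: the recognizer is
bypassed, sentences are tagged from gold mentions and the pattern matcher
alone is scored.  A prediction is a true positive iff a gold relation
shares document, subject span, object span and relation type; the
trigger is not part of the key, so two triggers yielding the same typed
relation count once.  `relaxed` mode collapses the three regulation
polarities before matching.  Each gold relation can be claimed by at most
one prediction, greedily in document order.  Ratios with a zero
denominator are defined as 0 and flagged in the report — explicit beats
NaN propagation.  Both modes are always reported because published
evaluations of this kind rarely state which convention they used.

## The synthetic corpus: what it does and does not establish

`generate_corpus()` emulates abstracts as sequences of template
sentences.  Covered templates realize exactly one binary relation each
(subject mention, one inflected trigger, object mention, with plain
filler words chosen to collide with neither the lexicon nor the trigger
lemmas); two multi-sentence templates plant the GGM and GGNO chains;
distractor templates contain concept mentions but no trigger, or no
placeholders at all.  Fillers are drawn uniformly (seeded, without
replacement within a template) from the bundled lexicon, so recognition
and extraction are exercised together.  Defaults — 5 sentences per
abstract, distractor fraction 0 unless stated, per-document seeds
`seed + index` — were fixed once, before any acceptance measurement, and
reproduce byte-identically.

A green planted-recovery test establishes that the pipeline is *sound
and complete over its own stated competence*: exact dictionary surfaces,
single-trigger active-voice sentences, gaps within `max_gap`.  It does
not establish performance on real prose, which contains anaphora,
coordination ("A and B inhibit C"), passives, negation, unseen synonyms
and boundary ambiguity.  The original deployed system's corpus-level
figures were measured on externally curated abstracts that cannot be
reconstructed offline, which is exactly why acceptance here is
property-based rather than score-based.

## Numerical and format choices

* Pattern files use 1-based slot indices (R convention), documented in
  `load_patterns()`; validation enforces trigger-class/relation-type
  consistency per rule.
* BioC infon keys: `type`, `identifier`, `provenance`, `ambiguous` on
  annotations; `type`, `rule_id`, `trigger_class`, `trigger_offset`,
  `trigger_length`, `trigger_text`, `sentence_index` on relations.  The
  original dataset's key choice is unspecified, so these are this
  package's documented convention.  Unknown `type` infons are preserved
  and flagged (`unknown_type`), never silently dropped.
* Curation tables are tab-delimited with a fixed 9-column header;
  backslash escaping of tabs/newlines makes the format lossless for
  arbitrary sentence text.
* Titles are stored but not mined by default (the pipeline mines
  abstract bodies); `--include-title` prepends the title as sentence
  `-1` of a combined in-memory document.  Serializing such a combined
  document through BioC renumbers its sentences on re-read — title
  mining is an in-memory convenience, and round-trip guarantees apply to
  the default configuration.

## Known limitations

Dictionary recall is bounded by the bundled lexicon (an illustrative
working set, not a reconstruction of any production dictionary); there
is no abbreviation detection, coreference, negation handling or
syntactic analysis; relations are strictly intra-sentential and event
chaining strictly intra-document; and pattern induction is out of scope
— patterns are configuration, supplied and versioned as data.
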