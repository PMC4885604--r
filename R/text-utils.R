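# Low-level text machinery shared by sentence splitting, dictionary
# matching and tagging.  All public offsets in the package are 0-based,
# half-open, character (not byte) offsets.

# Greek letters are normalized to their spelled-out Latin forms before any
# dictionary lookup, so "TGF-\u03b2" and "TGF-beta" hit the same entry.
.greek_map <- c(
  "\u03b1" = "alpha",   "\u0391" = "alpha",
  "\u03b2" = "beta",    "\u0392" = "beta",
  "\u03b3" = "gamma",   "\u0393" = "gamma",
  "\u03b4" = "delta",   "\u0394" = "delta",
  "\u03b5" = "epsilon", "\u0395" = "epsilon",
  "\u03ba" = "kappa",   "\u039a" = "kappa",
  "\u03bb" = "lambda",  "\u039b" = "lambda",
  "\u03bc" = "mu",      "\u039c" = "mu",
  "\u03c3" = "sigma",   "\u03a3" = "sigma"
)

# Expand Greek letters; returns the normalized string plus, for each
# normalized character, the 1-based index of the original character it came
# from (used to translate match spans back to original coordinates).
normalize_greek <- function(text) {
  chars <- strsplit(text, "", fixed = FALSE)[[1L]]
  hit <- chars %in% names(.greek_map)
  if (!any(hit)) {
    return(list(text = text, map = seq_along(chars)))
  }
  out <- as.character(chars)
  out[hit] <- .greek_map[chars[hit]]
  lens <- nchar(out)
  list(text = paste0(out, collapse = ""),
       map = rep(seq_along(chars), lens))
}

# Normalized key used for dictionary indexing (Greek expanded; case folding
# is decided per entry, see case_sensitive_surface()).
norm_key <- function(x) {
  vapply(x, function(s) normalize_greek(s)$text, character(1),
         USE.NAMES = FALSE)
}

# Short gene-symbol-like surfaces ("MET", "AKT1") match case-sensitively to
# avoid hitting ordinary words; longer phrases match case-insensitively.
case_sensitive_surface <- function(surface) {
  nchar(surface) <= 4L | grepl("[0-9]", surface)
}

.word_class <- "\\p{L}\\p{N}"
# hyphen (ASCII and U+2010) and slash are word-internal: they join tokens
.join_class <- "/\u2010-"

# Maximal word-character runs, with internal hyphens/slashes.
# Returns 0-based half-open spans relative to `text`.
token_spans <- function(text) {
  pat <- sprintf("[%s](?:[%s%s]*[%s])?",
                 .word_class, .word_class, .join_class, .word_class)
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      surface = character(0), stringsAsFactors = FALSE))
  }
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start = start1 - 1L, end = start1 - 1L + len,
             surface = substring(text, start1, start1 + len - 1L),
             stringsAsFactors = FALSE)
}

# TRUE when the characters flanking [start, end) are token boundaries, i.e.
# not word characters and not word-internal joiners.
at_token_boundary <- function(text, start0, end0) {
  n <- nchar(text)
  boundary_pat <- sprintf("[%s%s]", .word_class, .join_class)
  before_ok <- start0 <= 0L ||
    !grepl(boundary_pat, substr(text, start0, start0), perl = TRUE)
  after_ok <- end0 >= n ||
    !grepl(boundary_pat, substr(text, end0 + 1L, end0 + 1L), perl = TRUE)
  before_ok && after_ok
}

# Candidate lemmas for trigger lookup: strips common inflections
# (-s/-es, -ed/-d, -ing with e-restoration, -ion/-tion<->-te), so
# "inhibition" -> "inhibit", "regulation" -> "regulate",
# "promoting" -> "promote", "metastasizes" -> "metastasize".
lemma_candidates <- function(token) {
  t <- tolower(token)
  out <- t
  n <- nchar(t)
  chop <- function(suffix, add = "") {
    k <- nchar(suffix)
    if (n > k + 2L && endsWith(t, suffix)) {
      paste0(substr(t, 1L, n - k), add)
    } else {
      NA_character_
    }
  }
  out <- c(out,
           chop("s"), chop("es"),
           chop("ed"), chop("d"),
           chop("ing"), chop("ing", "e"),
           chop("ion"), chop("tion", "te"))
  unique(out[!is.na(out)])
}

# Third-person singular present, used by the fixture generator to realize
# trigger lemmas in carrier sentences ("suppress" -> "suppresses").
inflect_third_person <- function(lemma) {
  vapply(lemma, function(w) {
    if (grepl("(s|x|z|ch|sh)$", w)) {
      paste0(w, "es")
    } else if (grepl("[^aeiou]y$", w)) {
      paste0(substr(w, 1L, nchar(w) - 1L), "ies")
    } else {
      paste0(w, "s")
    }
  }, character(1), USE.NAMES = FALSE)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# substring in 0-based half-open coordinates
slice0 <- function(text, start0, end0) {
  substring(text, start0 + 1L, end0)
}
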