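#' Text normalization for screen-text analytics
#'
#' Screen text is normalized before any dictionary is applied: case reduction,
#' removal of punctuation and numbers (tokens are split on any non-alphabetic
#' character), and lemmatization. Lexicons are stored in the same normalized
#' form, so matching is invariant to which lemmatizer produced them provided
#' text and lexicon share one normalizer.
#'
#' The default lemmatizer is a compact rule-based English suffix stripper:
#' a short irregular-form table plus plural/-ed/-ing rules with
#' doubled-consonant undoing ("running" -> "run") and final-e restoration on
#' short stems ("taking" -> "take"). It is deterministic and idempotent on its
#' own output, which is the property the pipeline relies on; it is not a full
#' dictionary lemmatizer.
#'
#' @param lemmatize Apply lemmatization after case/punctuation reduction?
#' @return `make_normalizer()` returns a function mapping a character vector
#'   of raw texts to a list of token character vectors.
#' @examples
#' norm <- make_normalizer()
#' norm("Crying, again 100x!!")[[1]]
#' @export
make_normalizer <- function(lemmatize = TRUE) {
  force(lemmatize)
  function(texts) {
    toks <- tokenize_text(texts)
    if (!lemmatize) return(toks)
    flat <- unlist(toks, use.names = FALSE)
    if (length(flat) == 0L) return(toks)
    lem <- lemmatize_tokens(flat)
    utils::relist(lem, toks)
  }
}

#' @rdname make_normalizer
#' @export
default_normalizer <- function() make_normalizer(lemmatize = TRUE)

#' Lowercase and split text into alphabetic tokens
#'
#' @param texts Character vector.
#' @return List of character vectors (one per input element); punctuation and
#'   digits act as separators and never appear inside a token.
#' @export
tokenize_text <- function(texts) {
  texts[is.na(texts)] <- ""
  x <- tolower(texts)
  x <- gsub("[^a-z]+", " ", x)
  x <- trimws(x)
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

# Irregular forms resolved before suffix rules. Deliberately small: enough for
# the fixture lexicons and common screen text.
.irregular_lemmas <- c(
  am = "be", is = "be", are = "be", was = "be", were = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have", does = "do",
  did = "do", done = "do", goes = "go", went = "go", gone = "go",
  dying = "die", dies = "die", died = "die", lying = "lie",
  felt = "feel", thought = "think", said = "say", told = "tell",
  made = "make", got = "get", gotten = "get", taken = "take", took = "take",
  children = "child", men = "man", women = "woman", people = "person",
  lives = "life", worse = "bad", worst = "bad", better = "good",
  best = "good"
)

.vowels <- c("a", "e", "i", "o", "u")

.is_cons <- function(ch) !(ch %in% .vowels)

# Undo doubling / restore final e after stripping -ed/-ing.
.fix_stem <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(stem)
  last <- substr(stem, n, n)
  prev <- substr(stem, n - 1L, n - 1L)
  if (n >= 3L && last == prev && .is_cons(last) && !(last %in% c("l", "s", "z"))) {
    return(substr(stem, 1L, n - 1L))
  }
  if (n >= 3L && n <= 5L) {
    p2 <- substr(stem, n - 2L, n - 2L)
    if (.is_cons(last) && !(last %in% c("w", "x", "y")) &&
        !.is_cons(prev) && .is_cons(p2)) {
      return(paste0(stem, "e"))
    }
  }
  stem
}

.lemma_one <- function(w) {
  hit <- .irregular_lemmas[w]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(w)
  # plural reduction
  if (n > 4L && endsWith(w, "ies")) return(paste0(substr(w, 1L, n - 3L), "y"))
  if (n > 4L && endsWith(w, "sses")) return(substr(w, 1L, n - 2L))
  if (n > 3L && endsWith(w, "s") &&
      !endsWith(w, "ss") && !endsWith(w, "us") && !endsWith(w, "is")) {
    w <- substr(w, 1L, n - 1L)
    n <- n - 1L
    hit <- .irregular_lemmas[w]
    if (!is.na(hit)) return(unname(hit))
  }
  if (n > 5L && endsWith(w, "ing")) return(.fix_stem(substr(w, 1L, n - 3L)))
  if (n > 4L && endsWith(w, "ied")) return(paste0(substr(w, 1L, n - 3L), "y"))
  if (n > 4L && endsWith(w, "ed")) return(.fix_stem(substr(w, 1L, n - 2L)))
  w
}

#' Rule-based English lemmatization
#'
#' @param tokens Character vector of lowercase alphabetic tokens.
#' @return Character vector of lemmas, same length.
#' @examples
#' lemmatize_tokens(c("crying", "trapped", "taking", "studies"))
#' @export
lemmatize_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  u <- unique(tokens)
  lem <- vapply(u, .lemma_one, character(1), USE.NAMES = FALSE)
  lem[match(tokens, u)]
}
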