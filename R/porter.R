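# Porter (1980) suffix-stripping stemmer.
#
# Implemented from the algorithm definition: letters are classed as
# consonants/vowels (y is a vowel when preceded by a consonant), words are
# viewed as [C](VC)^m[V], and five suffix-rewriting steps are applied with
# longest-suffix matching inside each step. Within a step, once the longest
# matching suffix is found its condition decides the rewrite and the step
# ends, whether or not the condition held.

.porter_is_cons <- function(chs, i) {
  ch <- chs[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.porter_is_cons(chs, i - 1L))
  }
  TRUE
}

.porter_cv <- function(word) {
  chs <- strsplit(word, "", fixed = TRUE)[[1]]
  vapply(seq_along(chs), function(i) {
    if (.porter_is_cons(chs, i)) "c" else "v"
  }, character(1))
}

# m in [C](VC)^m[V]: number of v-run -> c-run transitions
.porter_m <- function(word) {
  if (!nzchar(word)) return(0L)
  runs <- rle(.porter_cv(word))$values
  if (length(runs) < 2L) return(0L)
  sum(runs[-length(runs)] == "v" & runs[-1L] == "c")
}

.porter_has_vowel <- function(word) {
  nzchar(word) && any(.porter_cv(word) == "v")
}

.porter_ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  a == b && .porter_is_cons(strsplit(word, "", fixed = TRUE)[[1]], n)
}

# *o: stem ends cvc where the final consonant is not w, x or y
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chs <- strsplit(word, "", fixed = TRUE)[[1]]
  last <- chs[n]
  .porter_is_cons(chs, n - 2L) && !.porter_is_cons(chs, n - 1L) &&
    .porter_is_cons(chs, n) && !(last %in% c("w", "x", "y"))
}

.ends <- function(word, suffix) {
  n <- nchar(word)
  ns <- nchar(suffix)
  n >= ns && substr(word, n - ns + 1L, n) == suffix
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# Apply the first (longest) matching rule from a suffix->replacement table,
# guarded by a measure condition on the remaining stem.
.porter_rule_table <- function(word, rules, min_m) {
  ord <- order(-nchar(names(rules)))
  for (sfx in names(rules)[ord]) {
    if (.ends(word, sfx)) {
      stem <- .chop(word, nchar(sfx))
      if (.porter_m(stem) > min_m) word <- paste0(stem, rules[[sfx]])
      return(word)
    }
  }
  word
}

#' Porter stem of a single word
#'
#' Classic Porter suffix-stripping stemmer used by the corpus preprocessing
#' pipeline. Words of two characters or fewer are returned unchanged.
#'
#' @param word a single lowercase word.
#' @return the stemmed word.
#' @examples
#' porter_stem("elevated")  # "elev"
#' porter_stem("mortality") # "mortal"
#' @export
porter_stem <- function(word) {
  w <- word
  if (nchar(w) <= 2L) return(w)

  # step 1a
  if (.ends(w, "sses")) {
    w <- .chop(w, 2L)
  } else if (.ends(w, "ies")) {
    w <- .chop(w, 2L)
  } else if (!.ends(w, "ss") && .ends(w, "s")) {
    w <- .chop(w, 1L)
  }

  # step 1b
  removed <- FALSE
  if (.ends(w, "eed")) {
    if (.porter_m(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else if (.ends(w, "ed") && .porter_has_vowel(.chop(w, 2L))) {
    w <- .chop(w, 2L)
    removed <- TRUE
  } else if (.ends(w, "ing") && .porter_has_vowel(.chop(w, 3L))) {
    w <- .chop(w, 3L)
    removed <- TRUE
  }
  if (removed) {
    if (.ends(w, "at") || .ends(w, "bl") || .ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_ends_double_cons(w) &&
               !(.ends(w, "l") || .ends(w, "s") || .ends(w, "z"))) {
      w <- .chop(w, 1L)
    } else if (.porter_m(w) == 1L && .porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (.ends(w, "y") && .porter_has_vowel(.chop(w, 1L))) {
    w <- paste0(.chop(w, 1L), "i")
  }

  # step 2
  w <- .porter_rule_table(w, c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), min_m = 0L)

  # step 3
  w <- .porter_rule_table(w, c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  ), min_m = 0L)

  # step 4 (ion only after s or t)
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
             "ic", "ou")
  for (sfx in step4[order(-nchar(step4))]) {
    if (.ends(w, sfx)) {
      stem <- .chop(w, nchar(sfx))
      ok <- .porter_m(stem) > 1L
      if (sfx == "ion") ok <- ok && (.ends(stem, "s") || .ends(stem, "t"))
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (.ends(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) w <- stem
  }
  # step 5b
  if (.porter_m(w) > 1L && .porter_ends_double_cons(w) && .ends(w, "l")) {
    w <- .chop(w, 1L)
  }
  w
}

#' Porter stems of a token vector
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of stems.
#' @export
porter_stems <- function(tokens) {
  vapply(tokens, porter_stem, character(1), USE.NAMES = FALSE)
}
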