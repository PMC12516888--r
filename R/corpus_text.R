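# Corpus ingestion, validation and preprocessing.
#
# One document per clinical feature describes how that feature affects ICU
# mortality of mechanically ventilated patients. The preprocessing pipeline
# is fixed (strip punctuation/symbols -> lowercase -> tokenize on
# whitespace -> drop stop words -> Porter stem) so that vectorisation is
# deterministic across runs and platforms.

.prompt_template <- paste(
  "Answer this question in %d words:",
  "How does %s impact the ICU mortality rates of mechanically ventilated patients?"
)

#' Render the description prompt for one clinical feature
#'
#' Produces the exact prompt used to elicit a feature's mortality-impact
#' description, with the word-count and feature slots substituted verbatim
#' (no grammatical fix-up for `word_count = 1`).
#'
#' @param feature_name nonempty feature name, e.g. `"Lactate"`.
#' @param word_count positive integer target word count.
#' @return a single string.
#' @examples
#' render_prompt("Lactate", 150)
#' @export
render_prompt <- function(feature_name, word_count) {
  if (!is.character(feature_name) || length(feature_name) != 1L ||
      !nzchar(feature_name)) {
    stop("feature_name must be a nonempty string", call. = FALSE)
  }
  word_count <- as.integer(word_count)
  if (is.na(word_count) || word_count <= 0L) {
    stop("word_count must be a positive integer", call. = FALSE)
  }
  sprintf(.prompt_template, word_count, feature_name)
}

#' Read a description corpus from JSON or CSV
#'
#' The on-disk format is a JSON array of objects (or a CSV with the same
#' columns) with fields `feature`, `prompt` (optional) and `body`.
#'
#' @param path file path; format inferred from the extension.
#' @return list of documents, each a list with `feature`, `prompt`, `body`.
#' @export
read_corpus <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    raw <- read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("feature", "body") %in% names(raw)))
  lapply(seq_len(nrow(raw)), function(i) {
    list(feature = raw$feature[i],
         prompt = if ("prompt" %in% names(raw)) raw$prompt[i] else NA_character_,
         body = raw$body[i])
  })
}

#' Write a corpus to JSON
#'
#' @param corpus list of documents as returned by [read_corpus()] or
#'   [simulate_corpus()].
#' @param path output path.
#' @export
write_corpus <- function(corpus, path) {
  df <- data.frame(
    feature = vapply(corpus, function(d) d$feature, character(1)),
    prompt = vapply(corpus, function(d) as.character(d$prompt %||% NA), character(1)),
    body = vapply(corpus, function(d) d$body, character(1)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(df, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate a corpus against the feature vocabulary
#'
#' Report-only check for missing features, duplicate documents, empty
#' bodies, and word counts outside +/-50% of the target.
#'
#' @param corpus list of documents.
#' @param feature_names character vector of expected feature names.
#' @param word_count_target optional positive integer; when given, documents
#'   whose body word count falls outside `[0.5, 1.5] * target` are flagged.
#' @return a list with components `missing`, `duplicated`, `empty_bodies`,
#'   `word_count_outliers` and a logical `ok`.
#' @export
validate_corpus <- function(corpus, feature_names, word_count_target = NULL) {
  feats <- vapply(corpus, function(d) d$feature, character(1))
  bodies <- vapply(corpus, function(d) d$body %||% "", character(1))
  wc <- vapply(strsplit(trimws(bodies), "\\s+"), function(x) sum(nzchar(x)), integer(1))
  out <- list(
    missing = setdiff(feature_names, feats),
    duplicated = unique(feats[duplicated(feats)]),
    empty_bodies = feats[!nzchar(trimws(bodies))],
    word_count_outliers = character(0)
  )
  if (!is.null(word_count_target)) {
    bad <- wc < 0.5 * word_count_target | wc > 1.5 * word_count_target
    out$word_count_outliers <- feats[bad]
  }
  out$ok <- all(lengths(out[c("missing", "duplicated", "empty_bodies",
                              "word_count_outliers")]) == 0L)
  out
}

#' Default English stop-word list
#'
#' A fixed list shipped with the package (not fetched at runtime) so that
#' vectorisation is bit-stable. Contractions are represented by their
#' punctuation-stripped fragments because punctuation is removed before
#' stop-word filtering.
#'
#' @return character vector of stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "icuhybrid")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "stopwords_en.txt")
  readLines(path, warn = FALSE)
}

#' Tokenize and normalise one text
#'
#' Fixed pipeline: non-alphabetic characters (punctuation, symbols, digits)
#' become separators, text is lowercased, split on whitespace into maximal
#' alphabetic runs, stop words are removed, and remaining tokens are Porter
#' stemmed. Deterministic for a fixed configuration. The cleaning,
#' tokenization and stop-word stages are idempotent; the pipeline is
#' applied exactly once per document because Porter stems are not
#' universally fixed points of the stemmer.
#'
#' @param text a single string.
#' @param stopwords character vector of stop words; compared after
#'   lowercasing, before stemming.
#' @param stem apply the Porter stemmer (default `TRUE`).
#' @return character vector of tokens (possibly empty).
#' @export
preprocess_text <- function(text, stopwords = default_stopwords(), stem = TRUE) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- gsub("[^A-Za-z]+", " ", text)
  x <- tolower(trimws(x))
  if (!nzchar(x)) return(character(0))
  toks <- strsplit(x, "\\s+")[[1]]
  toks <- toks[!(toks %in% stopwords)]
  if (stem) toks <- porter_stems(toks)
  toks
}

#' Preprocess a whole corpus
#'
#' @param corpus list of documents with `feature` and `body`.
#' @inheritParams preprocess_text
#' @return list of tokenized documents, each a list with `feature` and
#'   `tokens`. Documents whose body reduces to zero tokens are kept (with
#'   empty token vectors) and flagged downstream by [build_tfidf()] /
#'   [fit_semantic_clusters()].
#' @export
preprocess_corpus <- function(corpus, stopwords = default_stopwords(),
                              stem = TRUE) {
  lapply(corpus, function(d) {
    list(feature = d$feature,
         tokens = preprocess_text(d$body, stopwords = stopwords, stem = stem))
  })
}
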