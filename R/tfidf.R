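# TF-IDF vectorisation of the tokenized description corpus.
#
# Variant (fixed for reproducibility): tf = raw term count in the document,
# idf = ln((1 + N) / (1 + df)) + 1, rows L2-normalized. The smoothed,
# strictly positive idf down-weights ubiquitous terms without removing them
# entirely.

#' Build a TF-IDF matrix from tokenized documents
#'
#' @param tokenized_docs list of documents, each with `feature` and `tokens`
#'   (as from [preprocess_corpus()]).
#' @return an object of class `tfidf_matrix`: list with `weights` (N x V
#'   numeric matrix, rows = features, L2-normalized), `vocabulary` (ordered
#'   term list), `df` (per-term document frequencies), `n_docs`, and
#'   `empty_docs` (features whose token list was empty; their rows are all
#'   zero).
#' @export
build_tfidf <- function(tokenized_docs) {
  if (length(tokenized_docs) < 2L) stop("need at least 2 documents", call. = FALSE)
  feats <- vapply(tokenized_docs, function(d) d$feature, character(1))
  if (anyDuplicated(feats)) stop("duplicate feature documents", call. = FALSE)
  toks <- lapply(tokenized_docs, function(d) as.character(d$tokens))
  if (all(lengths(toks) == 0L)) stop("all documents are empty", call. = FALSE)

  vocab <- sort(unique(unlist(toks)))
  n <- length(toks)
  tf <- matrix(0, nrow = n, ncol = length(vocab),
               dimnames = list(feats, vocab))
  for (i in seq_len(n)) {
    if (length(toks[[i]]) == 0L) next
    tab <- table(toks[[i]])
    tf[i, names(tab)] <- as.numeric(tab)
  }
  df <- colSums(tf > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  w <- sweep(tf, 2L, idf, `*`)
  norms <- sqrt(rowSums(w^2))
  nz <- norms > 0
  w[nz, ] <- w[nz, , drop = FALSE] / norms[nz]

  structure(
    list(weights = w, vocabulary = vocab, df = df, idf = idf, n_docs = n,
         empty_docs = feats[!nz]),
    class = "tfidf_matrix"
  )
}

#' @export
print.tfidf_matrix <- function(x, ...) {
  cat(sprintf("TF-IDF matrix: %d documents x %d terms (%d empty documents)\n",
              x$n_docs, length(x$vocabulary), length(x$empty_docs)))
  invisible(x)
}
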