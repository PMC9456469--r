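#' Shipped English stopword list
#'
#' A fixed, versioned stopword list shipped with the package so that token
#' cleaning is reproducible.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords_en.txt", package = "tfgo",
                        mustWork = TRUE))
}

#' Clean an ontology label into word tokens
#'
#' Lowercases the text, replaces punctuation (every character that is not a
#' letter, digit or internal hyphen) with spaces, splits on whitespace,
#' keeps hyphenated compounds whole (e.g. "phosphate-containing"), drops
#' stopwords and empty tokens, and (by default) collapses duplicate tokens
#' within one label to a single occurrence. Cleaning is idempotent.
#'
#' @param label character string.
#' @param stopwords character vector (default: [default_stopwords()]).
#' @param dedupe collapse within-label duplicates (default `TRUE`).
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' clean_tokens("Regulation of Myeloid Cell Differentiation")
clean_tokens <- function(label, stopwords = default_stopwords(),
                         dedupe = TRUE) {
  x <- tolower(label)
  x <- gsub("[^a-z0-9-]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  if (length(toks) == 0L || identical(toks, "")) return(character(0))
  toks <- gsub("^-+|-+$", "", toks)   # hyphens only survive word-internally
  toks <- toks[nzchar(toks)]
  toks <- toks[!toks %in% stopwords]
  if (dedupe) toks <- unique(toks)
  toks
}

#' Order-weighted term-document matrix
#'
#' Builds the binary word-by-term incidence matrix from the cleaned labels
#' of a ranked enrichment result and scores every word by its significance:
#' the sum of the reciprocals of the orders (1-based p-value ranks) of the
#' terms whose label contains the word. Words are sorted by decreasing
#' significance, ties broken by ascending word.
#'
#' @param results an `enrichment_result` from [run_classic_gsea()] (or any
#'   data.frame with columns `term`, `label`, `order`); rows without an
#'   order (untestable terms) are ignored.
#' @param stopwords passed to [clean_tokens()].
#' @param dedupe passed to [clean_tokens()].
#' @return A list of class `term_document_matrix`: `words` (sorted),
#'   `significance` (named numeric), `incidence` (binary words x documents
#'   matrix), `documents` (data.frame `term`, `order`).
#' @export
build_tdm <- function(results, stopwords = default_stopwords(),
                      dedupe = TRUE) {
  stopifnot(is.data.frame(results),
            all(c("term", "label", "order") %in% names(results)))
  docs <- results[!is.na(results$order), , drop = FALSE]
  docs <- docs[order(docs$order), , drop = FALSE]
  token_sets <- lapply(docs$label, clean_tokens, stopwords = stopwords,
                       dedupe = dedupe)
  words <- sort(unique(unlist(token_sets)))
  if (length(words) == 0L || nrow(docs) == 0L) {
    return(structure(list(words = character(0),
                          significance = stats::setNames(numeric(0), character(0)),
                          incidence = matrix(0, 0, 0),
                          documents = docs[, c("term", "order")]),
                     class = "term_document_matrix"))
  }
  inc <- matrix(0L, nrow = length(words), ncol = nrow(docs),
                dimnames = list(words, docs$term))
  for (j in seq_len(nrow(docs)))
    inc[unique(token_sets[[j]]), j] <- 1L
  sig <- as.numeric(inc %*% (1 / docs$order))
  names(sig) <- words
  ord <- order(-sig, words)
  structure(list(words = words[ord], significance = sig[ord],
                 incidence = inc[ord, , drop = FALSE],
                 documents = data.frame(term = docs$term, order = docs$order,
                                        stringsAsFactors = FALSE)),
            class = "term_document_matrix")
}

#' @export
print.term_document_matrix <- function(x, ...) {
  cat(sprintf("term_document_matrix: %d words x %d documents\n",
              length(x$words), nrow(x$documents)))
  if (length(x$words))
    cat("top words:", paste(utils::head(x$words, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Top-n weighted word list
#'
#' The word-cloud export: the first `n` words by significance with their
#' weights and document counts.
#'
#' @param tdm a `term_document_matrix`.
#' @param n number of words (default 100).
#' @return A data.frame with columns `word`, `significance`, `n_documents`.
#' @export
top_words <- function(tdm, n = 100L) {
  stopifnot(inherits(tdm, "term_document_matrix"))
  k <- min(n, length(tdm$words))
  idx <- seq_len(k)
  data.frame(word = tdm$words[idx],
             significance = unname(tdm$significance[idx]),
             n_documents = if (k) unname(rowSums(tdm$incidence[idx, ,
                                                 drop = FALSE])) else numeric(0),
             stringsAsFactors = FALSE)
}

#' Word association analysis for the top-k words
#'
#' For each of the `k` most significant words (the anchors), computes the
#' Pearson correlation between its binary incidence vector and every other
#' word's vector across the ranked documents, and keeps associations with
#' correlation at least `cor_min`. Words with zero-variance incidence yield
#' no associations. When two anchors are mutually associated, both ordered
#' pairs are reported.
#'
#' @param tdm a `term_document_matrix` with at least 2 documents.
#' @param k number of anchor words (default 10).
#' @param cor_min minimum correlation to report (default 0.3).
#' @return A data.frame with columns `anchor`, `word`, `correlation`,
#'   `anchor_significance`.
#' @export
word_correlations <- function(tdm, k = 10L, cor_min = 0.3) {
  stopifnot(inherits(tdm, "term_document_matrix"))
  if (nrow(tdm$documents) < 2L)
    stop2("word correlations need at least 2 documents")
  anchors <- utils::head(tdm$words, k)
  sds <- apply(tdm$incidence, 1L, stats::sd)
  rows <- list()
  for (a in anchors) {
    if (sds[[a]] == 0) next
    for (w in tdm$words) {
      if (w == a || sds[[w]] == 0) next
      r <- stats::cor(tdm$incidence[a, ], tdm$incidence[w, ])
      if (r >= cor_min) {
        rows[[length(rows) + 1L]] <- data.frame(
          anchor = a, word = w, correlation = r,
          anchor_significance = unname(tdm$significance[a]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(anchor = character(0), word = character(0),
                      correlation = numeric(0),
                      anchor_significance = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
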