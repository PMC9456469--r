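#' Enrichment score transform
#'
#' Maps an enrichment p-value to the plotting scale
#' `log1p(-log10(p))` (natural-log `log1p`). Strictly decreasing in `p` on
#' (0, 1], equal to 0 at `p = 1`. `p = 0` returns `Inf` with a warning;
#' `p > 1` is an error.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Non-negative scores (possibly `Inf`).
#' @export
#' @examples
#' enrichment_score(c(1, 0.1, 0.001))  # 0, log(2), log(4)
enrichment_score <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop2("p-values must be in [0, 1]")
  if (any(p == 0)) warn2("p = 0 mapped to Inf enrichment score")
  log1p(-log10(p))
}

#' Default curated keyword set
#'
#' The keyword vocabulary shipped as a configuration file; expert curation
#' is an explicit, user-overridable configuration step.
#'
#' @return Character vector of keywords.
#' @export
default_keywords <- function() {
  readLines(system.file("extdata", "default_keywords.txt", package = "tfgo",
                        mustWork = TRUE))
}

#' Keyword-driven term selection
#'
#' Selects the enrichment results whose cleaned label tokens intersect the
#' keyword list (case-insensitive whole-token matching: keyword "cell" does
#' not match a label containing only "cellular"). Each selected term carries
#' its matching keywords and its enrichment score.
#'
#' @param results an `enrichment_result` (or any data.frame with `term`,
#'   `label`, `p`, `order`).
#' @param keywords character vector (default: [default_keywords()]); an
#'   empty vector yields an empty selection with a warning.
#' @param stopwords passed to [clean_tokens()].
#' @return A data.frame of class `curation_selection` with columns `term`,
#'   `label`, `p`, `order`, `enrichment_score`, `keywords`
#'   (semicolon-joined matches).
#' @export
select_by_keywords <- function(results, keywords = default_keywords(),
                               stopwords = default_stopwords()) {
  stopifnot(is.data.frame(results),
            all(c("term", "label", "p", "order") %in% names(results)))
  keywords <- tolower(keywords)
  if (length(keywords) == 0L)
    warn2("empty keyword list: empty selection")
  token_sets <- lapply(results$label, clean_tokens, stopwords = stopwords)
  matches <- lapply(token_sets, intersect, x = keywords)
  keep <- lengths(matches) > 0L
  out <- results[keep, c("term", "label", "p", "order"), drop = FALSE]
  es <- rep(NA_real_, nrow(out))
  ok <- !is.na(out$p)
  es[ok] <- enrichment_score(out$p[ok])
  out$enrichment_score <- es
  out$keywords <- vapply(matches[keep], paste, character(1), collapse = ";")
  rownames(out) <- NULL
  class(out) <- c("curation_selection", "data.frame")
  out
}

#' Keyword-grouped view of a selection
#'
#' Reproduces the keyword -> term-id grouping layout of the curated tables.
#'
#' @param sel a `curation_selection`.
#' @return A data.frame with columns `keyword`, `terms` (semicolon-joined).
#' @export
keyword_groups <- function(sel) {
  stopifnot(inherits(sel, "curation_selection"))
  kw <- strsplit(sel$keywords, ";", fixed = TRUE)
  pairs <- data.frame(keyword = unlist(kw),
                      term = rep(sel$term, lengths(kw)),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs))
    return(data.frame(keyword = character(0), terms = character(0),
                      stringsAsFactors = FALSE))
  agg <- lapply(split(pairs$term, pairs$keyword), function(t)
    paste(sort(unique(t)), collapse = ";"))
  data.frame(keyword = names(agg), terms = unlist(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' TF-to-term bubble table for a curated selection
#'
#' One row per (transcription-factor DEG, selected term) pair where the gene
#' belongs to the term's universe-restricted annotated set, with the term's
#' enrichment score.
#'
#' @param sel a `curation_selection` built from the same run.
#' @param run the `method_run` the selection came from.
#' @return A data.frame with columns `tf_deg`, `term`, `enrichment_score`.
#' @export
map_selection_to_genes <- function(sel, run) {
  stopifnot(inherits(sel, "curation_selection"), inherits(run, "method_run"))
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    genes <- run$tf_map[[sel$term[i]]]
    if (is.null(genes) || !length(genes)) return(NULL)
    data.frame(tf_deg = genes, term = sel$term[i],
               enrichment_score = sel$enrichment_score[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf_deg = character(0), term = character(0),
                      enrichment_score = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

run_sig_sets <- function(run) {
  sig <- run$results$term[run$results$significant]
  list(terms = sig,
       tf_degs = sort(unique(unlist(run$tf_map[sig]))))
}

#' Compare the two methods stream by stream
#'
#' For each stream, compares the significant GO-term sets and the associated
#' TF-DEG sets of Method 1 and Method 2: intersections, differences, Jaccard
#' indices, and whether Method 2's sets are contained in Method 1's (with a
#' `vacuous` flag when Method 2 is empty).
#'
#' @param runs the four-run list from [run_both_methods()].
#' @return A nested list of class `method_comparison` keyed by stream.
#' @export
compare_methods <- function(runs) {
  stopifnot(all(c("method1_up", "method1_down", "method2_up",
                  "method2_down") %in% names(runs)))
  cmp_sets <- function(a, b) {
    list(intersection = sort(intersect(a, b)),
         only_method1 = sort(setdiff(a, b)),
         only_method2 = sort(setdiff(b, a)),
         jaccard = jaccard(a, b),
         method2_contained = length(setdiff(b, a)) == 0L,
         vacuous = length(b) == 0L)
  }
  out <- lapply(c(up = "up", down = "down"), function(stream) {
    s1 <- run_sig_sets(runs[[paste0("method1_", stream)]])
    s2 <- run_sig_sets(runs[[paste0("method2_", stream)]])
    list(terms = cmp_sets(s1$terms, s2$terms),
         tf_degs = cmp_sets(s1$tf_degs, s2$tf_degs),
         method1 = s1, method2 = s2)
  })
  structure(out, class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  for (stream in names(x)) {
    cat(sprintf("%s stream: term Jaccard %.3f, TF-DEG Jaccard %.3f, method-2 TF-DEGs contained: %s%s\n",
                stream, x[[stream]]$terms$jaccard, x[[stream]]$tf_degs$jaccard,
                x[[stream]]$tf_degs$method2_contained,
                if (x[[stream]]$tf_degs$vacuous) " (vacuous)" else ""))
  }
  invisible(x)
}
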