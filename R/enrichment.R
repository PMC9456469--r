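#' One-sided two-sample Kolmogorov-Smirnov enrichment test
#'
#' Tests whether the gene scores annotated to a term are stochastically
#' smaller (smaller adjusted p-values = more enriched) than the scores of the
#' complement. The statistic is `D+ = max_t [ECDF_term(t) - ECDF_comp(t)]`
#' evaluated at the pooled sorted unique score values (which handles ties).
#'
#' The p-value is exact by complete enumeration of all `choose(m+n, m)`
#' assignments of the pooled scores to the term when that count is at most
#' `exact_limit`; otherwise the one-sided asymptotic bound
#' `exp(-2 * D+^2 * m * n / (m + n))` is used. The exact p-value is the
#' permutation frequency `P(D+_perm >= D+_obs)`.
#'
#' @param term_scores,complement_scores numeric score vectors (both nonempty).
#' @param exact_limit maximum number of assignments enumerated exactly
#'   (default 1e5); set to 0 to force the asymptotic branch.
#' @param alternative `"greater"` (term scores smaller: enrichment, default)
#'   or `"two.sided"` (uses `D = max |ECDF diff|` with the corresponding
#'   permutation/asymptotic tail).
#' @return A list with `ks_stat`, `p`, and `exact` (logical).
#' @export
#' @examples
#' ks_term_test(c(0.01, 0.02), c(0.5, 0.6, 0.7))  # D+ = 1, exact p = 0.1
ks_term_test <- function(term_scores, complement_scores, exact_limit = 1e5,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(term_scores)
  y <- as.numeric(complement_scores)
  if (length(x) == 0L || length(y) == 0L)
    stop2("both the term and its complement must be nonempty")
  if (anyNA(x) || anyNA(y)) stop2("scores must not contain NA")
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  thresholds <- sort(unique(pooled))
  tot <- vapply(thresholds, function(t) sum(pooled <= t), numeric(1))
  # ECDF differences are compared on the integer scale m*n*(cx/m - cy/n)
  # = cx*n - cy*m, so permutation ties are counted exactly (no floating
  # point rounding of fractions like 1/3).
  d_int_from_counts <- function(cnt) {
    d <- cnt * n - (tot - cnt) * m
    if (alternative == "greater") max(0, d) else max(abs(d))
  }
  cx <- vapply(thresholds, function(t) sum(x <= t), numeric(1))
  d_obs_int <- d_int_from_counts(cx)
  d_obs <- d_obs_int / (m * n)

  n_comb <- choose(m + n, m)
  if (n_comb <= exact_limit) {
    # ECDF counts for every assignment via one matrix product:
    # A[l, t] = 1 if pooled[l] <= threshold t; S = membership of each
    # assignment; counts_x = t(S) %*% A.
    A <- outer(pooled, thresholds, "<=") * 1
    idx <- utils::combn(m + n, m)
    S <- matrix(0, nrow = m + n, ncol = ncol(idx))
    S[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = m))] <- 1
    counts_x <- crossprod(S, A)                    # n_comb x T
    tot_mat <- matrix(tot, nrow = nrow(counts_x), ncol = length(tot),
                      byrow = TRUE)
    diffs_int <- counts_x * n - (tot_mat - counts_x) * m
    d_perm_int <- if (alternative == "greater") {
      pmax(0, apply(diffs_int, 1L, max))
    } else {
      apply(abs(diffs_int), 1L, max)
    }
    p <- sum(d_perm_int >= d_obs_int) / n_comb
    exact <- TRUE
  } else {
    scale <- m * n / (m + n)
    p <- if (alternative == "greater") {
      min(1, exp(-2 * d_obs^2 * scale))
    } else {
      min(1, 2 * exp(-2 * d_obs^2 * scale))
    }
    exact <- FALSE
  }
  list(ks_stat = d_obs, p = p, exact = exact)
}

#' Classic score-based GO enrichment
#'
#' Scores every term of the DAG independently of its neighbours ("classic"
#' algorithm: no parent-child elimination) with the one-sided KS test of
#' [ks_term_test()], comparing the scores of the genes annotated to the term
#' (after true-path propagation and restriction to the score list's
#' universe) with the scores of the rest of the universe. Terms covering the
#' whole universe have an empty complement and are reported untestable
#' (`testable = FALSE`, `p = NA`). Results are sorted by ascending p-value
#' with ties broken by ascending term id, and the 1-based rank of each
#' testable term is recorded as its `order`.
#'
#' @param scores named numeric vector: gene -> score (adjusted p-values from
#'   the differential expression step). The names define the gene universe.
#' @param dag a [go_dag()].
#' @param ann a `go_annotation` from [propagate()] (restricted internally).
#' @param min_size minimum annotated-gene count in the universe for a term
#'   to be evaluated (default 1).
#' @param exact_limit passed to [ks_term_test()].
#' @return A data.frame of class `enrichment_result` with columns `term`,
#'   `label`, `annotated_in_universe`, `ks_stat`, `p`, `order`, `testable`.
#' @export
run_classic_gsea <- function(scores, dag, ann, min_size = 1L,
                             exact_limit = 1e5) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (anyDuplicated(names(scores))) stop2("duplicate genes in score list")
  universe <- names(scores)
  if (length(universe) < 2L)
    stop2("gene universe must contain at least 2 genes")
  ann_u <- restrict_to_universe(ann, universe, min_size = min_size)
  term_ids <- names(ann_u$propagated)
  labels <- stats::setNames(dag$terms$name, dag$terms$id)
  rows <- lapply(term_ids, function(t) {
    genes <- ann_u$propagated[[t]]
    comp <- setdiff(universe, genes)
    if (length(comp) == 0L) {
      return(data.frame(term = t, label = unname(labels[t]),
                        annotated_in_universe = length(genes),
                        ks_stat = NA_real_, p = NA_real_, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    ks <- ks_term_test(scores[genes], scores[comp], exact_limit = exact_limit)
    data.frame(term = t, label = unname(labels[t]),
               annotated_in_universe = length(genes),
               ks_stat = ks$ks_stat, p = ks$p, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(term = character(0), label = character(0),
                      annotated_in_universe = integer(0),
                      ks_stat = numeric(0), p = numeric(0),
                      testable = logical(0), stringsAsFactors = FALSE)
  testable <- res[res$testable, , drop = FALSE]
  untestable <- res[!res$testable, , drop = FALSE]
  if (nrow(testable)) {
    testable <- testable[order(testable$p, testable$term), , drop = FALSE]
    testable$order <- seq_len(nrow(testable))
  } else testable$order <- integer(0)
  untestable$order <- rep(NA_integer_, nrow(untestable))
  out <- rbind(testable, untestable)
  rownames(out) <- NULL
  out <- out[, c("term", "label", "annotated_in_universe", "ks_stat", "p",
                 "order", "testable")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Run one analysis method on both streams
#'
#' Orchestrates the two orderings of enrichment and transcription-factor
#' selection, each on separate up- and down-regulated streams:
#' \describe{
#'   \item{Method 1}{the gene universe of a stream is all DEGs of that
#'     stream (scores = their adjusted p-values); enrichment first, then the
#'     transcription factors among each term's genes are recorded.}
#'   \item{Method 2}{the universe is restricted upfront to the TF-DEGs of
#'     the stream, and enrichment runs on that smaller universe.}
#' }
#' Note that the Method-1 universe is the DEG list itself, not all expressed
#' genes; this mirrors the study design this package implements and differs
#' from common GSEA practice where the whole array is scored.
#'
#' @param method 1 or 2.
#' @param stats a classified `gene_stats` data.frame (from [run_dea()]).
#' @param catalog transcription-factor catalog (character vector).
#' @param dag a [go_dag()].
#' @param ann a `go_annotation` from [propagate()].
#' @param streams which streams to run (default both).
#' @param p_cut significance cut for "significant GO terms" (raw enrichment
#'   p, default 0.05; no term-level multiplicity correction by default).
#' @param min_size,exact_limit passed to [run_classic_gsea()].
#' @return A named list of `method_run` objects (`up`, `down`), each a list
#'   with `method`, `stream`, `universe`, `results` (an `enrichment_result`
#'   with a `significant` column) and `tf_map` (term -> TF-DEGs of the
#'   stream annotated to it). Empty streams yield empty runs with a warning.
#' @export
run_method <- function(method, stats, catalog, dag, ann,
                       streams = c("up", "down"), p_cut = 0.05,
                       min_size = 1L, exact_limit = 1e5) {
  stopifnot(method %in% c(1L, 2L), is.data.frame(stats),
            !is.null(stats$status))
  out <- list()
  for (stream in streams) {
    degs <- stats$gene[stats$status == stream]
    tf_degs <- intersect(degs, catalog)
    universe <- if (method == 1L) degs else tf_degs
    if (length(universe) < 2L) {
      warn2(sprintf("method %d, stream %s: universe has %d gene(s); empty run",
                    method, stream, length(universe)))
      res <- data.frame(term = character(0), label = character(0),
                        annotated_in_universe = integer(0),
                        ks_stat = numeric(0), p = numeric(0),
                        order = integer(0), testable = logical(0),
                        significant = logical(0), stringsAsFactors = FALSE)
      out[[stream]] <- structure(
        list(method = method, stream = stream, universe = character(0),
             results = res, tf_map = list()),
        class = "method_run")
      next
    }
    scores <- stats$adj_p[match(universe, stats$gene)]
    names(scores) <- universe
    res <- run_classic_gsea(scores, dag, ann, min_size = min_size,
                            exact_limit = exact_limit)
    res$significant <- !is.na(res$p) & res$p < p_cut
    ann_u <- restrict_to_universe(ann, universe, min_size = 1L)
    tf_map <- lapply(res$term, function(t)
      intersect(ann_u$propagated[[t]], tf_degs))
    names(tf_map) <- res$term
    out[[stream]] <- structure(
      list(method = method, stream = stream, universe = universe,
           results = res, tf_map = tf_map),
      class = "method_run")
  }
  out
}

#' @export
print.method_run <- function(x, ...) {
  cat(sprintf("method_run: Method %d, %s stream, %d genes in universe, %d terms (%d significant)\n",
              x$method, x$stream, length(x$universe), nrow(x$results),
              sum(x$results$significant)))
  invisible(x)
}

#' Run both methods on both streams
#'
#' Convenience wrapper returning the full four-run structure
#' (`method1_up`, `method1_down`, `method2_up`, `method2_down`).
#'
#' @inheritParams run_method
#' @return Named list of four `method_run` objects.
#' @export
run_both_methods <- function(stats, catalog, dag, ann, p_cut = 0.05,
                             min_size = 1L, exact_limit = 1e5) {
  m1 <- run_method(1L, stats, catalog, dag, ann, p_cut = p_cut,
                   min_size = min_size, exact_limit = exact_limit)
  m2 <- run_method(2L, stats, catalog, dag, ann, p_cut = p_cut,
                   min_size = min_size, exact_limit = exact_limit)
  list(method1_up = m1$up, method1_down = m1$down,
       method2_up = m2$up, method2_down = m2$down)
}

#' Export a method run as a results table
#'
#' @param run a `method_run`.
#' @return A data.frame with the enrichment columns plus the associated
#'   TF-DEGs semicolon-joined.
#' @export
method_run_table <- function(run) {
  stopifnot(inherits(run, "method_run"))
  res <- run$results
  res$tf_degs <- vapply(res$term, function(t)
    paste(run$tf_map[[t]], collapse = ";"), character(1))
  res
}
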