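# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms / code paths than R/.

# Benjamini-Hochberg by the literal step-up definition:
# adj_p[i] = min over j with rank(j) >= rank(i) of (n / rank(j)) * p[j].
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    js <- which(r >= r[i])
    min(1, min(n / r[js] * p[js]))
  }, numeric(1))
}

# One-sided two-sample KS by naive enumeration of all assignments, ECDFs
# evaluated with stats::ecdf at the pooled unique values.
oracle_ks_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  thr <- sort(unique(pooled))
  dplus <- function(a, b) max(0, stats::ecdf(a)(thr) - stats::ecdf(b)(thr))
  d_obs <- dplus(x, y)
  idx <- utils::combn(m + n, m)
  hits <- 0L
  for (j in seq_len(ncol(idx))) {
    s <- idx[, j]
    if (dplus(pooled[s], pooled[-s]) >= d_obs - 1e-9) hits <- hits + 1L
  }
  list(ks_stat = d_obs, p = hits / ncol(idx))
}

# Classical pooled two-sample t-test (no moderation), gene by gene.
oracle_classical_t <- function(v1, v2) {
  n1 <- ncol(v1); n2 <- ncol(v2)
  m1 <- rowMeans(v1); m2 <- rowMeans(v2)
  df <- n1 + n2 - 2
  s2 <- (rowSums((v1 - m1)^2) + rowSums((v2 - m2)^2)) / df
  t <- (m2 - m1) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df = df), s2 = s2, df = df)
}

# Ancestor closure by walking parents from each term (memoized), then
# per-gene union over its direct terms' closures.
oracle_propagate <- function(dag, direct) {
  memo <- new.env(parent = emptyenv())
  ancestors <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    out <- t
    for (p in dag$parents[[t]]) out <- union(out, ancestors(p))
    memo[[t]] <- out
    out
  }
  prop <- lapply(stats::setNames(dag$terms$id, dag$terms$id),
                 function(i) character(0))
  for (g in names(direct)) {
    terms_g <- unique(unlist(lapply(direct[[g]], ancestors)))
    for (t in terms_g) prop[[t]] <- c(prop[[t]], g)
  }
  lapply(prop, function(g) sort(unique(g)))
}

# Word significance by the literal double loop over (word, document) pairs.
oracle_word_significance <- function(labels, orders, stopwords) {
  token_sets <- lapply(labels, clean_tokens, stopwords = stopwords)
  words <- sort(unique(unlist(token_sets)))
  sig <- stats::setNames(numeric(length(words)), words)
  for (w in words) {
    for (d in seq_along(labels)) {
      if (w %in% token_sets[[d]]) sig[[w]] <- sig[[w]] + 1 / orders[d]
    }
  }
  sig
}

# Random rooted DAG for propagation tests: node i draws 1-2 parents among
# earlier nodes (guaranteed acyclic, single root).
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- ids
  parents[[1L]] <- character(0)
  if (n_terms > 1L) {
    for (i in 2:n_terms) {
      np <- sample(1:2, 1)
      parents[[i]] <- ids[sample.int(i - 1L, min(np, i - 1L))]
    }
  }
  go_dag(data.frame(id = ids, name = paste("term", ids),
                    namespace = "biological_process",
                    stringsAsFactors = FALSE),
         parents)
}

random_direct <- function(dag, n_genes, seed) {
  set.seed(seed)
  ids <- dag$terms$id
  genes <- sprintf("g%03d", seq_len(n_genes))
  stats::setNames(lapply(genes, function(g)
    ids[sample.int(length(ids), sample(1:3, 1))]), genes)
}
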