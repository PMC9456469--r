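# Small in-code fixtures shared by the unit tests.

# Log2-scale 4-vs-2 matrix from explicit per-gene rows.
toy_log2_matrix <- function(rows, normalized = TRUE) {
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  colnames(mat) <- c(paste0("c", 1:4), paste0("t", 1:2))[seq_len(ncol(mat))]
  groups <- stats::setNames(
    rep(c("control", "treatment"), c(4, ncol(mat) - 4))[seq_len(ncol(mat))],
    colnames(mat))
  m <- expression_matrix(mat, groups, scale = "linear")
  m$scale <- "log2"
  m$normalized <- normalized
  m
}

toy_contrast <- function() contrast_spec("treatment", "control")

# Three-term chain R <- A <- B as an OBO document.
chain_obo <- function() {
  paste(c("format-version: 1.2", "",
          "[Term]", "id: GO:R", "name: root process",
          "namespace: biological_process", "",
          "[Term]", "id: GO:A", "name: middle process",
          "namespace: biological_process", "is_a: GO:R ! root process", "",
          "[Term]", "id: GO:B", "name: leaf process",
          "namespace: biological_process", "is_a: GO:A", ""),
        collapse = "\n")
}

# Small simulation config for fast unit tests (not the acceptance world).
quick_sim <- function(seed = 1L, ...) {
  sim_config(n_probes = 400L, n_go_terms = 15L, seed = seed, ...)
}

# Enrichment-result data.frame from parallel vectors.
toy_results <- function(labels, orders = seq_along(labels),
                        p = seq_along(labels) / (2 * length(labels))) {
  n <- length(labels)
  data.frame(term = sprintf("GO:%04d", seq_len(n)),
             label = labels, p = p, order = orders,
             ks_stat = rep(0.5, n), annotated_in_universe = rep(2L, n),
             testable = rep(TRUE, n),
             stringsAsFactors = FALSE)
}
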