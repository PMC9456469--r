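#' Simulation configuration
#'
#' Parameters of the synthetic microarray world. The defaults reproduce the
#' study design this package emulates: a 4-replicate untreated control group
#' (pooling an empty-vector and a catalytically dead sub-condition) against
#' 2 treatment replicates, ~2k probes (one probe per gene), 5% differentially
#' expressed genes at |log2FC| = 1, and gene variances drawn from a scaled
#' inverse-chi-square prior with `d0 = 4`, `s0_sq = 0.05`.
#'
#' @param n_probes number of probes (= genes; one probe per gene).
#' @param n_control,n_treatment replicates per group (default 4 and 2).
#' @param de_fraction fraction of genes differentially expressed.
#' @param effect_size_log2 |log2 fold change| of planted DE genes.
#' @param baseline_mean,baseline_sd mean/sd of baseline log2 expression.
#' @param d0,s0_sq degrees of freedom and scale of the scaled
#'   inverse-chi-square variance prior.
#' @param tf_fraction fraction of genes that are transcription factors.
#' @param n_go_terms number of ontology terms (including the single root).
#' @param planted_term_count number of terms with planted enrichment
#'   (streams alternate up, down, up, ...).
#' @param flag_absent_rate per-cell probability of an Absent detection flag.
#' @param seed integer RNG seed. All generators use R's Mersenne-Twister
#'   with inversion normals, recorded in the run manifest.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000L, n_control = 4L, n_treatment = 2L,
                       de_fraction = 0.05, effect_size_log2 = 1.0,
                       baseline_mean = 8, baseline_sd = 1.5,
                       d0 = 4, s0_sq = 0.05, tf_fraction = 0.1,
                       n_go_terms = 50L, planted_term_count = 2L,
                       flag_absent_rate = 0.05, seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_control = as.integer(n_control),
              n_treatment = as.integer(n_treatment), de_fraction = de_fraction,
              effect_size_log2 = effect_size_log2, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, d0 = d0, s0_sq = s0_sq,
              tf_fraction = tf_fraction, n_go_terms = as.integer(n_go_terms),
              planted_term_count = as.integer(planted_term_count),
              flag_absent_rate = flag_absent_rate, seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), character(0))])
  if (anyNA(num) || any(!is.finite(num)))
    stop2("sim_config values must be finite")
  if (!is_count(cfg$n_probes)) stop2("n_probes must be a positive integer")
  if (!is_count(cfg$n_control) || !is_count(cfg$n_treatment))
    stop2("replicate counts must be positive integers")
  if (cfg$n_control + cfg$n_treatment < 3L)
    stop2("need at least 3 samples in total")
  for (f in c("de_fraction", "tf_fraction", "flag_absent_rate"))
    if (!is_prop(cfg[[f]])) stop2(f, " must be a proportion in [0, 1]")
  for (f in c("effect_size_log2", "baseline_sd", "d0", "s0_sq"))
    if (!is_pos(cfg[[f]])) stop2(f, " must be a positive real")
  if (!is_count(cfg$n_go_terms)) stop2("n_go_terms must be a positive integer")
  if (cfg$planted_term_count < 0L)
    stop2("planted_term_count must be non-negative")
  if (cfg$planted_term_count > cfg$n_go_terms)
    stop2("planted_term_count must not exceed n_go_terms")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (f in names(x)) cat(sprintf("  %s = %s\n", f, format(x[[f]])))
  invisible(x)
}

sim_seed <- function(cfg, offset) {
  as.integer((cfg$seed %% 1000000000L) + offset)
}

#' Simulate a two-group expression matrix with planted structure
#'
#' Generates linear-scale intensities `2^(mu_g + delta_g * I[treatment] +
#' eps_gi)` with `eps_gi ~ N(0, sigma_g)` and `sigma_g^2 ~ d0 * s0_sq /
#' chisq(d0)` (scaled inverse-chi-square). `round(de_fraction * n_probes)`
#' genes carry `delta = +-effect_size_log2` (half up, half down; on odd
#' counts the up half is rounded down). Detection flags are drawn per cell:
#' Absent with probability `flag_absent_rate`, otherwise Present (90%) or
#' Marginal (10%). Transcription factors are a uniform random subset of
#' `round(tf_fraction * n_probes)` genes. Deterministic for a fixed seed.
#'
#' Control sample names record the two pooled sub-conditions (empty vector
#' and inactive mutant) for realism; statistically the control group is
#' homogeneous.
#'
#' @param config a [sim_config()].
#' @return A list with `matrix` (an [expression_matrix()], linear scale) and
#'   `truth` (a `truth_table`: list with `genes` data.frame; the `terms`
#'   slot is filled by [simulate_ontology()]).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_probes
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  genes <- sprintf("G%06d", seq_len(n))
  mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  sigma2 <- config$d0 * config$s0_sq / stats::rchisq(n, df = config$d0)
  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0L) sample.int(n, n_de) else integer(0)
  n_up <- floor(n_de / 2)
  up_idx <- de_idx[seq_len(n_up)]
  down_idx <- setdiff(de_idx, up_idx)
  delta <- numeric(n)
  delta[up_idx] <- config$effect_size_log2
  delta[down_idx] <- -config$effect_size_log2
  n_tf <- round(config$tf_fraction * n)
  tf_idx <- if (n_tf > 0L) sample.int(n, n_tf) else integer(0)

  n1 <- config$n_control; n2 <- config$n_treatment
  n_ev <- ceiling(n1 / 2)
  sample_ids <- c(sprintf("ctrl_ev_%d", seq_len(n_ev)),
                  sprintf("ctrl_d1028a_%d", seq_len(n1 - n_ev)),
                  sprintf("trt_ptprg_%d", seq_len(n2)))
  groups <- stats::setNames(rep(c("control", "treatment"), c(n1, n2)),
                            sample_ids)
  eps <- matrix(stats::rnorm(n * (n1 + n2), sd = sqrt(sigma2)),
                nrow = n, ncol = n1 + n2)
  log2_vals <- mu + outer(delta, c(rep(0, n1), rep(1, n2))) + eps
  values <- 2 ^ log2_vals
  dimnames(values) <- list(genes, sample_ids)
  r <- config$flag_absent_rate
  flags <- matrix(sample(c("A", "P", "M"), n * (n1 + n2), replace = TRUE,
                         prob = c(r, (1 - r) * 0.9, (1 - r) * 0.1)),
                  nrow = n, dimnames = dimnames(values))
  direction <- rep("none", n)
  direction[up_idx] <- "up"
  direction[down_idx] <- "down"
  truth_genes <- data.frame(
    gene = genes,
    is_de = direction != "none",
    direction = direction,
    true_log2fc = delta,
    is_tf = seq_len(n) %in% tf_idx,
    sigma2 = sigma2,
    stringsAsFactors = FALSE)
  truth <- structure(list(genes = truth_genes, terms = NULL,
                          config = config),
                     class = "truth_table")
  m <- expression_matrix(values, groups, flags = flags, scale = "linear")
  list(matrix = m, truth = truth)
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table: %d genes (%d DE: %d up / %d down; %d TFs)\n",
              nrow(x$genes), sum(x$genes$is_de),
              sum(x$genes$direction == "up"),
              sum(x$genes$direction == "down"), sum(x$genes$is_tf)))
  if (!is.null(x$terms))
    cat(sprintf("  %d terms, %d planted\n", nrow(x$terms),
                sum(x$terms$is_planted)))
  invisible(x)
}

#' Simulate a rooted ontology and gene annotations with planted enrichment
#'
#' Builds a single-rooted acyclic `is_a` graph of `n_go_terms` nodes: term
#' `i` (in topological order) draws one parent (80%) or two parents (20%)
#' uniformly among earlier terms. Labels are 3-word phrases drawn from the
#' fixed shipped vocabulary (so the text-mining steps see realistic tokens
#' such as "myeloid" or "differentiation"); planted terms get fixed
#' stream-flavoured labels. Every gene is directly annotated to 1-3 random
#' non-root terms; each planted term's annotation set is additionally
#' enriched with all differentially expressed transcription-factor genes of
#' its planted stream. The output serializes deterministically
#' ([write_obo()] is byte-identical for a fixed seed).
#'
#' @param config a [sim_config()].
#' @param truth the `truth_table` from [simulate_expression()].
#' @return A list with `dag` (a [go_dag()]), `direct` (gene -> term ids) and
#'   `truth` (the truth table with its per-term slot filled: columns `term`,
#'   `is_planted`, `planted_stream`).
#' @export
simulate_ontology <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  k <- config$n_go_terms
  if (config$planted_term_count > k)
    stop2("planted_term_count must not exceed n_go_terms")
  set.seed(sim_seed(config, 101L), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  vocab <- readLines(system.file("extdata", "label_vocabulary.txt",
                                 package = "tfgo", mustWork = TRUE))
  ids <- sprintf("GO:%07d", seq_len(k))
  parents <- vector("list", k)
  names(parents) <- ids
  parents[[1L]] <- character(0)
  if (k > 1L) {
    for (i in 2:k) {
      np <- if (i == 2L) 1L else sample(c(1L, 2L), 1L, prob = c(0.8, 0.2))
      parents[[i]] <- ids[sample.int(i - 1L, min(np, i - 1L))]
    }
  }
  labels <- c("biological_process",
              vapply(seq_len(max(k - 1L, 0L)), function(i)
                paste(sample(vocab, 3L), collapse = " "), character(1)))
  # planted terms: the last indices, streams alternating up, down, up, ...
  n_pl <- config$planted_term_count
  planted_idx <- if (n_pl > 0L) seq.int(k, by = -1L, length.out = n_pl) else integer(0)
  planted_stream_all <- rep("none", k)
  planted_labels <- c(up = "regulation of myeloid cell differentiation",
                      down = "negative regulation of leukocyte differentiation")
  for (j in seq_along(planted_idx)) {
    stream <- c("up", "down")[(j - 1L) %% 2L + 1L]
    i <- planted_idx[j]
    planted_stream_all[i] <- stream
    if (i > 1L) labels[i] <- planted_labels[[stream]]
  }
  dag <- go_dag(data.frame(id = ids, name = labels,
                           namespace = "biological_process",
                           stringsAsFactors = FALSE),
                parents)
  genes <- truth$genes$gene
  non_root <- if (k > 1L) ids[-1L] else ids
  direct <- vector("list", length(genes))
  names(direct) <- genes
  n_terms_per_gene <- sample(1:3, length(genes), replace = TRUE)
  for (g in seq_along(genes)) {
    direct[[g]] <- non_root[sample.int(length(non_root),
                                       min(n_terms_per_gene[g], length(non_root)))]
  }
  for (i in planted_idx) {
    stream <- planted_stream_all[i]
    tf_de <- genes[truth$genes$is_tf & truth$genes$direction == stream]
    for (g in tf_de) direct[[g]] <- unique(c(direct[[g]], ids[i]))
  }
  truth$terms <- data.frame(term = ids,
                            is_planted = planted_stream_all != "none",
                            planted_stream = planted_stream_all,
                            stringsAsFactors = FALSE)
  list(dag = dag, direct = direct, truth = truth)
}

#' Derive the transcription-factor catalog from the simulation truth
#'
#' @param truth a `truth_table`.
#' @param config the matching [sim_config()] (used for a consistency check).
#' @return Character vector of `round(tf_fraction * n_probes)` TF symbols,
#'   in agreement with `truth$genes$is_tf`.
#' @export
simulate_tf_catalog <- function(truth, config) {
  stopifnot(inherits(truth, "truth_table"))
  catalog <- truth$genes$gene[truth$genes$is_tf]
  if (!missing(config)) {
    stopifnot(inherits(config, "sim_config"))
    expected <- round(config$tf_fraction * config$n_probes)
    if (length(catalog) != expected)
      stop2("truth table and config disagree on the TF count")
  }
  catalog
}

#' Write a full synthetic input bundle to disk
#'
#' Writes the expression/flags/design TSV triplet, the OBO ontology, the
#' direct annotation TSV, the TF catalog and the truth tables, all in
#' deterministic plain-text formats.
#'
#' @param sim result of [simulate_expression()] after [simulate_ontology()]
#'   (see [simulate_all()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(sim$matrix, file.path(dir, "sim"))
  write_obo(sim$dag, file.path(dir, "ontology.obo"))
  write_annotation_tsv(sim$direct, file.path(dir, "annotation.tsv"))
  write_tf_catalog(sim$catalog, file.path(dir, "tf_catalog.txt"))
  write_tsv_det(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv_det(sim$truth$terms, file.path(dir, "truth_terms.tsv"))
  invisible(dir)
}

#' One-call synthetic world
#'
#' Runs [simulate_expression()], [simulate_ontology()] and
#' [simulate_tf_catalog()] and returns the combined bundle.
#'
#' @param config a [sim_config()].
#' @return A list with `matrix`, `truth`, `dag`, `direct`, `catalog`.
#' @export
simulate_all <- function(config = sim_config()) {
  sim <- simulate_expression(config)
  ont <- simulate_ontology(config, sim$truth)
  catalog <- simulate_tf_catalog(ont$truth, config)
  list(matrix = sim$matrix, truth = ont$truth, dag = ont$dag,
       direct = ont$direct, catalog = catalog)
}
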