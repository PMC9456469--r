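#' Full-run configuration
#'
#' Bundles the simulation parameters with every tunable analysis setting of
#' the pipeline. All defaults mirror the study design: DEG thresholds
#' `adj_p < 0.05` and `|log2FC| > 0.1` (strict), term-level significance at
#' raw `p < 0.05`, noise filter at within-group SD `< 0.3` and group-mean
#' distance `> 0.5` (off for the main contrast by default).
#'
#' @param sim a [sim_config()].
#' @param alpha,lfc_threshold DEG thresholds (see [classify_degs()]).
#' @param shrinkage enable empirical-Bayes variance moderation.
#' @param p_cut term-level significance cut (raw enrichment p).
#' @param term_bh apply BH across terms instead of the raw-p cut (off by
#'   default; the raw cut mirrors the study).
#' @param apply_noise_filter run [noise_filter()] before the DEA.
#' @param noise_sd_max,noise_dist_min noise-filter thresholds.
#' @param keywords curated keyword set.
#' @param top_n word-cloud size.
#' @param cor_k,cor_min word-association anchors and correlation cut.
#' @param min_size,exact_limit enrichment settings (see [run_classic_gsea()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), alpha = 0.05, lfc_threshold = 0.1,
                       shrinkage = TRUE, p_cut = 0.05, term_bh = FALSE,
                       apply_noise_filter = FALSE, noise_sd_max = 0.3,
                       noise_dist_min = 0.5, keywords = default_keywords(),
                       top_n = 100L, cor_k = 10L, cor_min = 0.3,
                       min_size = 1L, exact_limit = 1e5) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, alpha = alpha, lfc_threshold = lfc_threshold,
                 shrinkage = shrinkage, p_cut = p_cut, term_bh = term_bh,
                 apply_noise_filter = apply_noise_filter,
                 noise_sd_max = noise_sd_max, noise_dist_min = noise_dist_min,
                 keywords = keywords, top_n = as.integer(top_n),
                 cor_k = as.integer(cor_k), cor_min = cor_min,
                 min_size = as.integer(min_size), exact_limit = exact_limit),
            class = "run_config")
}

#' Standard preprocessing chain
#'
#' Clamp non-positive values to 1, normalize each sample to its 75th
#' percentile, keep probes Present/Marginal in at least one sample, and
#' log2-transform. The order is fixed; each step guards its own
#' preconditions.
#'
#' @param m a linear-scale [expression_matrix()].
#' @return A log2-scale, normalized, filtered [expression_matrix()].
#' @export
preprocess <- function(m) {
  m <- clamp_negatives(m)
  m <- normalize_p75(m)
  if (!is.null(m$flags)) m <- filter_expressed(m)
  log2_transform(m)
}

#' Run the complete pipeline on a synthetic world
#'
#' Executes simulate -> preprocess -> DEA -> both methods x both streams ->
#' word mining -> keyword curation -> method comparison, writing every
#' result table as TSV plus `comparison.json` and a machine-readable
#' `manifest.json` (package version, seed, config hash, RNG and quantile
#' conventions). The run is idempotent: a fixed seed produces byte-identical
#' outputs. Any stage error aborts with the stage name and removes files
#' written so far.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if missing).
#' @param seed optional integer overriding `config$sim$seed`.
#' @return Invisibly, a list with the in-memory objects (`sim`, `stats`,
#'   `runs`, `tdms`, `selections`, `comparison`, `manifest`).
#' @export
run_all <- function(config = run_config(), outdir, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }
  current_stage <- "setup"
  res <- tryCatch({
    current_stage <- "simulate"
    sim <- simulate_all(config$sim)
    dir.create(file.path(outdir, "inputs"), showWarnings = FALSE)
    write_sim_inputs(sim, file.path(outdir, "inputs"))
    note(file.path(outdir, "inputs"))

    current_stage <- "preprocess"
    m <- preprocess(sim$matrix)

    current_stage <- "dea"
    contrast <- contrast_spec("treatment", "control")
    noise_probes <- if (config$apply_noise_filter)
      noise_filter(m, contrast, config$noise_sd_max, config$noise_dist_min)
    else NULL
    stats <- run_dea(m, contrast, alpha = config$alpha,
                     lfc_threshold = config$lfc_threshold,
                     shrinkage = config$shrinkage,
                     noise_probes = noise_probes)
    stats_out <- stats
    stats_out$is_tf <- stats_out$gene %in% sim$catalog
    write_tsv_det(stats_out, note(file.path(outdir, "dea_results.tsv")))
    write_tsv_det(volcano_table(stats, sim$catalog),
                  note(file.path(outdir, "volcano.tsv")))

    current_stage <- "gsea"
    ann <- propagate(sim$dag, sim$direct)
    runs <- run_both_methods(stats, sim$catalog, sim$dag, ann,
                             p_cut = config$p_cut,
                             min_size = config$min_size,
                             exact_limit = config$exact_limit)
    if (config$term_bh) {
      for (key in names(runs)) {
        ok <- !is.na(runs[[key]]$results$p)
        adj <- runs[[key]]$results$p
        adj[ok] <- bh_adjust(adj[ok])
        runs[[key]]$results$significant <- ok & adj < config$p_cut
      }
    }
    for (key in names(runs))
      write_tsv_det(method_run_table(runs[[key]]),
                    note(file.path(outdir, paste0(key, "_enrichment.tsv"))))

    current_stage <- "semantics"
    tdms <- lapply(runs, function(r) build_tdm(r$results))
    for (key in names(tdms)) {
      write_tsv_det(top_words(tdms[[key]], config$top_n),
                    note(file.path(outdir, paste0(key, "_words.tsv"))))
      assoc <- if (nrow(tdms[[key]]$documents) >= 2L)
        word_correlations(tdms[[key]], k = config$cor_k,
                          cor_min = config$cor_min)
      else data.frame(anchor = character(0), word = character(0),
                      correlation = numeric(0),
                      anchor_significance = numeric(0))
      write_tsv_det(assoc, note(file.path(outdir, paste0(key, "_associations.tsv"))))
    }

    current_stage <- "curate"
    selections <- lapply(runs, function(r)
      select_by_keywords(r$results, keywords = config$keywords))
    for (key in names(selections)) {
      write_tsv_det(as.data.frame(selections[[key]]),
                    note(file.path(outdir, paste0(key, "_selection.tsv"))))
      write_tsv_det(map_selection_to_genes(selections[[key]], runs[[key]]),
                    note(file.path(outdir, paste0(key, "_bubble.tsv"))))
    }

    current_stage <- "compare"
    comparison <- compare_methods(runs)
    jsonlite::write_json(unclass(comparison),
                         note(file.path(outdir, "comparison.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    current_stage <- "manifest"
    manifest <- run_manifest(config)
    jsonlite::write_json(manifest, note(file.path(outdir, "manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(sim = sim, stats = stats, runs = runs, tdms = tdms,
         selections = selections, comparison = comparison,
         manifest = manifest)
  }, error = function(e) {
    unlink(written, recursive = TRUE)
    stop2(sprintf("pipeline stage '%s' failed: %s", current_stage,
                  conditionMessage(e)))
  })
  invisible(res)
}

run_manifest <- function(config) {
  cfg <- rapply(unclass(config), function(x)
    if (inherits(x, "sim_config")) unclass(x) else x, how = "replace")
  cfg$sim <- unclass(cfg$sim)
  json_cfg <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  list(package = "tfgo",
       package_version = as.character(utils::packageVersion("tfgo")),
       rng = list(kind = "Mersenne-Twister", normal_kind = "Inversion",
                  sample_kind = "Rejection"),
       quantile_convention = "type 7: linear interpolation at 1 + (n - 1) * q",
       seed = config$sim$seed,
       config = cfg,
       config_hash = fnv1a_hash(as.character(json_cfg)))
}
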