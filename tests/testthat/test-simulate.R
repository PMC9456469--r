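test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(de_fraction = 1.2), "proportion")
  expect_error(sim_config(n_control = 1, n_treatment = 1), "at least 3")
  expect_error(sim_config(planted_term_count = 99, n_go_terms = 5),
               "planted_term_count")
  expect_error(sim_config(effect_size_log2 = Inf), "finite")
  expect_error(sim_config(s0_sq = 0), "positive")
})

test_that("simulate_expression plants the configured counts", {
  cfg <- sim_config(n_probes = 2000, de_fraction = 0.05, seed = 7)
  sim <- simulate_expression(cfg)
  expect_equal(dim(sim$matrix$values), c(2000L, 6L))
  expect_equal(sum(sim$truth$genes$is_de), 100L)
  # half up / half down, up rounded down on odd counts
  expect_equal(sum(sim$truth$genes$direction == "up"), 50L)
  cfg_odd <- sim_config(n_probes = 1000, de_fraction = 0.005, seed = 7)
  t_odd <- simulate_expression(cfg_odd)$truth$genes
  expect_equal(sum(t_odd$direction == "up"), 2L)
  expect_equal(sum(t_odd$direction == "down"), 3L)
  # truth-table invariants
  tr <- sim$truth$genes
  expect_identical(tr$is_de, tr$direction != "none")
  expect_true(all(abs(tr$true_log2fc[tr$is_de]) == 1.0))
  expect_true(all(tr$true_log2fc[!tr$is_de] == 0))
  expect_false(anyDuplicated(tr$gene) > 0)
  expect_identical(dim(sim$matrix$flags), dim(sim$matrix$values))
  # null config
  sim0 <- simulate_expression(sim_config(n_probes = 500, de_fraction = 0,
                                         seed = 1))
  expect_equal(sum(sim0$truth$genes$is_de), 0L)
})

test_that("fixed seed reproduces the world bit-for-bit", {
  cfg <- quick_sim(seed = 42)
  a <- simulate_all(cfg)
  b <- simulate_all(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$matrix$flags, b$matrix$flags)
  expect_identical(a$truth, b$truth)
  expect_identical(a$direct, b$direct)
  # OBO serialization byte-identical
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_obo(a$dag, p1); write_obo(b$dag, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted mean group difference is unbiased", {
  cfg <- sim_config(n_probes = 1000, seed = 5)
  sim <- simulate_expression(cfg)
  m <- log2_transform(clamp_negatives(sim$matrix))
  tr <- sim$truth$genes
  up <- tr$direction == "up"
  diff_up <- rowMeans(m$values[up, 5:6]) - rowMeans(m$values[up, 1:4])
  se <- sd(diff_up) / sqrt(sum(up))
  expect_lt(abs(mean(diff_up) - cfg$effect_size_log2), 3 * se)
})

test_that("simulated variances recover the inverse-chi-square prior", {
  cfg <- sim_config(n_probes = 5000, d0 = 4, s0_sq = 0.05, seed = 3)
  sim <- simulate_expression(cfg)
  m <- sim$matrix; m$scale <- "log2"; m$values <- log2(m$values)
  st <- fit_contrast(m, contrast_spec("treatment", "control"))
  h <- estimate_hyper(st$s2, st$df_residual[1])
  expect_lt(abs(h$d0 - 4) / 4, 0.15)
  expect_lt(abs(h$s0_sq - 0.05) / 0.05, 0.15)
})

test_that("simulate_ontology builds a rooted annotated DAG with planted terms", {
  # enough DE TFs that the planted-enrichment contrast is observable
  cfg <- sim_config(n_probes = 600, n_go_terms = 15, tf_fraction = 0.2,
                    de_fraction = 0.1, seed = 8)
  sim <- simulate_expression(cfg)
  ont <- simulate_ontology(cfg, sim$truth)
  expect_length(dag_roots(ont$dag), 1L)
  expect_equal(nrow(ont$dag$terms), cfg$n_go_terms)
  # every gene annotated somewhere
  expect_setequal(names(ont$direct), sim$truth$genes$gene)
  expect_true(all(lengths(ont$direct) >= 1))
  # go_dag() construction already guarantees acyclicity; root reachability:
  ann <- propagate(ont$dag, ont$direct)
  expect_setequal(ann$propagated[[dag_roots(ont$dag)]],
                  sim$truth$genes$gene)
  # planted term is enriched for DE-TF genes of its stream
  tr <- sim$truth$genes
  up_tf <- tr$gene[tr$is_tf & tr$direction == "up"]
  planted_up <- ont$truth$terms$term[ont$truth$terms$planted_stream == "up"]
  direct_by_term <- split(
    rep(names(ont$direct), lengths(ont$direct)),
    unlist(ont$direct))
  frac_planted <- mean(up_tf %in% direct_by_term[[planted_up]])
  expect_equal(frac_planted, 1)  # construction: all up DE-TFs annotated
  random_terms <- setdiff(ont$dag$terms$id,
                          c(planted_up, dag_roots(ont$dag)))
  frac_random <- mean(vapply(random_terms, function(t)
    mean(up_tf %in% direct_by_term[[t]]), numeric(1)), na.rm = TRUE)
  expect_gt(frac_planted, frac_random)
  # degenerate single-term ontology: all genes on the root
  cfg1 <- sim_config(n_probes = 50, n_go_terms = 1, planted_term_count = 1,
                     seed = 2)
  sim1 <- simulate_expression(cfg1)
  ont1 <- simulate_ontology(cfg1, sim1$truth)
  expect_equal(nrow(ont1$dag$terms), 1L)
  expect_true(all(vapply(ont1$direct, identical, logical(1),
                         ont1$dag$terms$id)))
})

test_that("simulate_tf_catalog agrees with the truth table", {
  cfg <- sim_config(n_probes = 2000, tf_fraction = 0.1, seed = 9)
  sim <- simulate_expression(cfg)
  catalog <- simulate_tf_catalog(sim$truth, cfg)
  expect_length(catalog, 200L)
  expect_setequal(catalog, sim$truth$genes$gene[sim$truth$genes$is_tf])
  # catalog ∩ DE genes = TF-DEG truth set
  tr <- sim$truth$genes
  expect_setequal(intersect(catalog, tr$gene[tr$is_de]),
                  tr$gene[tr$is_de & tr$is_tf])
  # empty catalog case
  cfg0 <- sim_config(n_probes = 100, tf_fraction = 0, seed = 9)
  sim0 <- simulate_expression(cfg0)
  expect_length(simulate_tf_catalog(sim0$truth, cfg0), 0L)
})

test_that("raising the effect size never loses true positives (same seed)", {
  tp_count <- function(effect) {
    cfg <- sim_config(n_probes = 800, effect_size_log2 = effect, seed = 13)
    sim <- simulate_expression(cfg)
    st <- run_dea(preprocess(sim$matrix), contrast_spec("treatment", "control"))
    tr <- sim$truth$genes
    sum(st$status != "ns" &
          st$status == tr$direction[match(st$gene, tr$gene)])
  }
  tps <- vapply(c(0.5, 1.0, 2.0), tp_count, numeric(1))
  expect_true(all(diff(tps) >= 0))
})
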