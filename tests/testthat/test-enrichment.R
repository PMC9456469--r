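test_that("ks_term_test worked example: 2-vs-3 separation", {
  out <- ks_term_test(c(0.01, 0.02), c(0.5, 0.6, 0.7))
  expect_equal(out$ks_stat, 1.0)
  expect_equal(out$p, 1 / 10)   # all C(5,2) = 10 assignments enumerated
  expect_true(out$exact)
})

test_that("ks_term_test null cases", {
  # same multiset split evenly -> D+ = 0, p = 1
  out <- ks_term_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(out$ks_stat, 0)
  expect_equal(out$p, 1)
  # identical constant scores
  out2 <- ks_term_test(c(0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(out2$ks_stat, 0)
  expect_equal(out2$p, 1)
  expect_error(ks_term_test(numeric(0), 1), "nonempty")
})

test_that("exact p equals the brute-force permutation frequency", {
  set.seed(21)
  for (i in 1:25) {
    m <- sample(1:5, 1); n <- sample(1:6, 1)
    # mix continuous and tied scores
    x <- sample(c(runif(m), round(runif(m), 1)), m)
    y <- sample(c(runif(n), round(runif(n), 1)), n)
    mine <- ks_term_test(x, y)
    orc <- oracle_ks_exact(x, y)
    expect_equal(mine$ks_stat, orc$ks_stat, tolerance = 1e-12)
    expect_equal(mine$p, orc$p)
  }
})

test_that("asymptotic branch applies the one-sided exponential bound", {
  x <- runif(30); y <- runif(40)
  out <- ks_term_test(x, y, exact_limit = 0)
  expect_false(out$exact)
  expect_equal(out$p,
               min(1, exp(-2 * out$ks_stat^2 * 30 * 40 / 70)),
               tolerance = 1e-15)
})

gsea_fixture <- function() {
  dag <- go_dag(
    data.frame(id = c("R", "T1", "T2", "T3"),
               name = c("root", "planted process", "other process", "spare"),
               namespace = "biological_process", stringsAsFactors = FALSE),
    list(R = character(0), T1 = "R", T2 = "R", T3 = "R"))
  genes <- sprintf("g%02d", 1:10)
  direct <- stats::setNames(as.list(c(rep("T1", 3), rep("T2", 4),
                                      rep("T3", 3))), genes)
  list(dag = dag, ann = propagate(dag, direct), genes = genes)
}

test_that("run_classic_gsea ranks a strongly enriched term first", {
  fx <- gsea_fixture()
  scores <- stats::setNames(c(0.001, 0.002, 0.003, runif(7, 0.4, 1)),
                            fx$genes)
  res <- run_classic_gsea(scores, fx$dag, fx$ann)
  expect_identical(res$term[which(res$order == 1)], "T1")
  # root covers the whole universe -> untestable but reported
  expect_false(res$testable[res$term == "R"])
  expect_true(is.na(res$p[res$term == "R"]))
  # orders are a permutation of 1..N over testable terms
  expect_setequal(res$order[res$testable], seq_len(sum(res$testable)))
  # p non-decreasing along order
  ord <- res[res$testable, ]
  expect_true(all(diff(ord$p[order(ord$order)]) >= 0))
  # annotated_in_universe cross-check against the ontology module
  ann_u <- restrict_to_universe(fx$ann, names(scores))
  expect_equal(res$annotated_in_universe,
               unname(lengths(ann_u$propagated[res$term])))
})

test_that("equal p-values break ties by ascending term id, deterministically", {
  dag <- go_dag(
    data.frame(id = c("R", "TA", "TB"), name = c("r", "a", "b"),
               namespace = "biological_process", stringsAsFactors = FALSE),
    list(R = character(0), TA = "R", TB = "R"))
  # symmetric construction: TA and TB get mirror-image score sets
  direct <- list(g1 = "TA", g2 = "TA", g3 = "TB", g4 = "TB")
  ann <- propagate(dag, direct)
  scores <- c(g1 = 0.1, g2 = 0.9, g3 = 0.1, g4 = 0.9)
  r1 <- run_classic_gsea(scores, dag, ann)
  r2 <- run_classic_gsea(scores, dag, ann)
  expect_identical(r1, r2)
  tied <- r1[r1$term %in% c("TA", "TB"), ]
  expect_equal(tied$p[1], tied$p[2])
  expect_identical(tied$term[order(tied$order)], c("TA", "TB"))
})

test_that("classic scoring is independent of the rest of the DAG", {
  fx <- gsea_fixture()
  set.seed(9)
  scores <- stats::setNames(runif(10), fx$genes)
  full <- run_classic_gsea(scores, fx$dag, fx$ann)
  # drop term T3 from the DAG and annotation entirely
  dag2 <- go_dag(fx$dag$terms[fx$dag$terms$id != "T3", ],
                 fx$dag$parents[setdiff(names(fx$dag$parents), "T3")])
  direct2 <- lapply(fx$ann$direct, setdiff, y = "T3")
  direct2 <- direct2[lengths(direct2) > 0]
  res2 <- run_classic_gsea(scores, dag2, propagate(dag2, direct2))
  for (t in c("T1", "T2")) {
    expect_equal(res2$p[res2$term == t], full$p[full$term == t])
    expect_equal(res2$ks_stat[res2$term == t], full$ks_stat[full$term == t])
  }
  expect_error(run_classic_gsea(scores[1], fx$dag, fx$ann), "at least 2")
})

test_that("run_method builds the right universes and TF maps", {
  fx <- gsea_fixture()
  st <- data.frame(gene = fx$genes,
                   log2fc = c(rep(1, 5), rep(-1, 5)),
                   adj_p = c(0.001, 0.002, 0.003, 0.004, 0.005,
                             0.001, 0.002, 0.3, 0.4, 0.5))
  st <- classify_degs(st)
  catalog <- c("g01", "g02", "g06")
  # method 2's down stream has one TF-DEG -> warns about the empty run
  runs <- suppressWarnings(run_both_methods(st, catalog, fx$dag, fx$ann))
  # method 1 up universe = all up DEGs; method 2 = TF-DEGs only
  expect_setequal(runs$method1_up$universe, sprintf("g%02d", 1:5))
  expect_setequal(runs$method2_up$universe, c("g01", "g02"))
  expect_lt(length(runs$method2_up$universe),
            length(runs$method1_up$universe))
  expect_true(all(runs$method2_up$universe %in% catalog))
  # TF map: T1 contains g01..g03, of which g01, g02 are TF-DEGs up
  expect_setequal(runs$method1_up$tf_map[["T1"]], c("g01", "g02"))
  # down stream has a single TF-DEG -> method 2 down is an empty run
  expect_identical(nrow(runs$method2_down$results), 0L)
  # catalog covering every gene makes the methods coincide
  runs_all <- suppressWarnings(
    run_both_methods(st, fx$genes, fx$dag, fx$ann))
  expect_identical(runs_all$method1_up$results, runs_all$method2_up$results)
  # no TFs at all: method 2 empty with one warning per stream
  w <- capture_warnings(m2 <- run_method(2L, st, character(0), fx$dag, fx$ann))
  expect_length(w, 2L)
  expect_match(w, "empty run", all = TRUE)
  expect_identical(nrow(m2$up$results), 0L)
  m1 <- run_method(1L, st, character(0), fx$dag, fx$ann)
  expect_true(all(lengths(m1$up$tf_map) == 0))
})
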