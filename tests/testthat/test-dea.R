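test_that("fit_contrast computes means, log2fc and pooled variance", {
  m <- toy_log2_matrix(list(g1 = c(0.9, 1.1, 1.0, 1.0, 2.0, 2.2),
                            g2 = c(1, 1, 1, 1, 1, 1),
                            g3 = c(2, 2, 2, 2, 5, 5)))
  st <- fit_contrast(m, toy_contrast())
  expect_equal(st$log2fc[1], 1.1, tolerance = 1e-12)
  expect_equal(st$s2[1], 0.01, tolerance = 1e-12)
  expect_equal(st$df_residual[1], 4L)
  expect_equal(st$log2fc[2], 0)          # identical groups
  expect_equal(st$s2[3], 0)              # both groups constant
  # group-size guard
  m1 <- m; m1$groups[] <- c("control", "control", "control", "control",
                            "control", "treatment")
  expect_error(fit_contrast(m1, toy_contrast()), "at least 2 samples")
  # scale guard
  m2 <- m; m2$scale <- "linear"
  expect_error(fit_contrast(m2, toy_contrast()), "log2")
})

test_that("estimate_hyper matches the moment equations", {
  # identical variances -> no spread -> infinitely strong prior
  h <- estimate_hyper(rep(0.02, 10), df = 4)
  expect_identical(h$d0, Inf)
  expect_equal(h$s0_sq, exp(mean(log(rep(0.02, 10))) - digamma(2) + log(2)),
               tolerance = 1e-12)
  # two genes whose log-variance spread exceeds trigamma(df/2): the fitted
  # d0 must solve the trigamma equation; check the root against a dense
  # grid search
  s2 <- c(0.01, 0.5); df <- 4
  h2 <- estimate_hyper(s2, df)
  target <- var(log(s2)) - trigamma(df / 2)
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 200001))
  best <- grid[which.min(abs(trigamma(grid) - target))]
  expect_equal(h2$d0, 2 * best, tolerance = 1e-3)
  expect_equal(trigamma(h2$d0 / 2), target, tolerance = 1e-9)
  # spread below trigamma(df/2) (e.g. s2 = 0.01, 0.02 at df = 4) cannot
  # support a finite d0 under the moment equations: complete shrinkage
  expect_identical(estimate_hyper(c(0.01, 0.02), 4)$d0, Inf)
  # errors
  expect_error(estimate_hyper(c(0, 0, 0), 4), "zero")
})

test_that("moderated_t implements the posterior-variance formula", {
  m <- toy_log2_matrix(list(g1 = c(0.9, 1.1, 1.0, 1.0, 2.0, 2.2)))
  st <- fit_contrast(m, toy_contrast())   # s2 = 0.01, df = 4
  out <- moderated_t(st, list(d0 = 4, s0_sq = 0.05))
  expect_equal(out$s2_post, (0.2 + 0.04) / 8, tolerance = 1e-12)  # 0.03
  expect_equal(out$t_mod, 1.1 / sqrt(0.03 * (1 / 4 + 1 / 2)),
               tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(out$t_mod), df = 8), tolerance = 1e-15)
  # |t| = 2.776 at 4 total df gives p = 0.0500 two-sided
  st2 <- st; st2$log2fc <- 2.776 * sqrt(st2$s2 * 0.75)
  out2 <- moderated_t(st2, list(d0 = 0, s0_sq = 1))
  expect_equal(out2$p, 0.05, tolerance = 1e-3)
  # d0 = Inf uses the normal tail
  outI <- moderated_t(st, list(d0 = Inf, s0_sq = 0.05))
  expect_equal(outI$s2_post, 0.05)
  expect_equal(outI$p, 2 * pnorm(-abs(outI$t_mod)), tolerance = 1e-15)
})

test_that("d0 = 0 reproduces the classical pooled t-test exactly", {
  set.seed(11)
  vals <- matrix(rnorm(200 * 6, 8, 1), nrow = 200)
  m <- toy_log2_matrix(stats::setNames(
    lapply(seq_len(200), function(i) vals[i, ]), sprintf("G%03d", 1:200)))
  st <- moderated_t(fit_contrast(m, toy_contrast()), list(d0 = 0, s0_sq = 1))
  orc <- oracle_classical_t(vals[, 1:4, drop = FALSE], vals[, 5:6, drop = FALSE])
  expect_equal(st$t_mod, unname(orc$t), tolerance = 1e-10)
  expect_equal(st$p, unname(orc$p), tolerance = 1e-10)
})

test_that("zero posterior variance yields p = 0 with a flag, not an error", {
  m <- toy_log2_matrix(list(g1 = c(2, 2, 2, 2, 5, 5),
                            g2 = c(1, 1, 1, 1, 1, 1)))
  st <- fit_contrast(m, toy_contrast())
  expect_warning(out <- moderated_t(st, list(d0 = 0, s0_sq = 1)), "degenerate")
  expect_equal(out$p[1], 0)
  expect_true(out$degenerate_variance[1])
  expect_equal(out$p[2], 2 * pt(0, 4))   # log2fc = 0, s2 = 0 -> t = 0, p = 1
})

test_that("bh_adjust matches the step-up definition and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1.0), 1.0)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-15)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("classify_degs uses strict inequalities on both thresholds", {
  st <- data.frame(gene = letters[1:5],
                   log2fc = c(0.2, 0.05, 2.0, -0.3, -0.1),
                   adj_p = c(0.04, 0.04, 0.05, 0.01, 0.01))
  out <- classify_degs(st)
  expect_identical(out$status, c("up", "ns", "ns", "down", "ns"))
})

test_that("select_tf_degs intersects DEGs with the catalog", {
  st <- data.frame(gene = c("A", "B", "C", "E"),
                   status = c("up", "down", "up", "ns"))
  out <- select_tf_degs(st, c("B", "C", "D"))
  expect_identical(out$gene, c("B", "C"))
  expect_identical(out$status, c("down", "up"))
  expect_identical(select_tf_degs(st, c("A", "B", "C", "E"))$gene,
                   c("A", "B", "C"))
  expect_identical(nrow(select_tf_degs(st, "Z")), 0L)
  expect_warning(out0 <- select_tf_degs(st, character(0)), "empty")
  expect_identical(nrow(out0), 0L)
})

test_that("intersect_contrasts keeps direction-consistent common DEGs", {
  a <- data.frame(gene = c("x", "y"), status = c("up", "down"))
  b <- data.frame(gene = c("x", "y"), status = c("up", "up"))
  out <- intersect_contrasts(a, b, catalog = "x")
  expect_identical(out$common_up, "x")
  expect_identical(out$common_down, character(0))
  expect_identical(out$tf_flags, c(x = TRUE))
  # idempotence and disjointness
  expect_identical(intersect_contrasts(a, a)$common_down, "y")
  d <- data.frame(gene = "z", status = "up")
  both <- intersect_contrasts(a, d)
  expect_length(both$common_up, 0)
  expect_length(both$common_down, 0)
})

test_that("run_dea refuses unnormalized input", {
  m <- toy_log2_matrix(list(g1 = c(1, 1, 1, 1, 2, 2)), normalized = FALSE)
  expect_error(run_dea(m, toy_contrast()), "normalized")
})
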