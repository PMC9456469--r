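#' Two-group contrast specification
#'
#' @param treatment_group,control_group group labels present in the design.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(treatment_group, control_group) {
  structure(list(treatment_group = treatment_group,
                 control_group = control_group),
            class = "contrast_spec")
}

contrast_columns <- function(m, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  ctl <- which(m$groups == contrast$control_group)
  trt <- which(m$groups == contrast$treatment_group)
  if (length(ctl) < 2L || length(trt) < 2L)
    stop2("both contrast groups need at least 2 samples (found ",
          length(ctl), " control, ", length(trt), " treatment)")
  list(control = ctl, treatment = trt)
}

#' Per-gene contrast fit
#'
#' Computes, for every probe/gene, the two group means on the log2 scale, the
#' log2 fold change (treatment minus control), the pooled within-group
#' residual variance `s2 = SS_within / (n1 + n2 - 2)` and its degrees of
#' freedom. Statistical moderation is applied afterwards by [moderated_t()].
#'
#' @param m an [expression_matrix()] on the log2 scale.
#' @param contrast a [contrast_spec()]; both groups need >= 2 samples.
#' @return A `gene_stats` data.frame with columns `gene`, `mean_control`,
#'   `mean_treatment`, `log2fc`, `s2`, `df_residual`.
#' @export
fit_contrast <- function(m, contrast) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2")
    stop2("fit_contrast() expects log2-scale data; run the preprocessing ",
          "chain (clamp -> normalize -> filter -> log2) first")
  idx <- contrast_columns(m, contrast)
  v1 <- m$values[, idx$control, drop = FALSE]   # control
  v2 <- m$values[, idx$treatment, drop = FALSE] # treatment
  n1 <- ncol(v1); n2 <- ncol(v2)
  m1 <- rowMeans(v1); m2 <- rowMeans(v2)
  ss <- rowSums((v1 - m1)^2) + rowSums((v2 - m2)^2)
  df <- n1 + n2 - 2L
  out <- data.frame(
    gene = rownames(m$values),
    mean_control = unname(m1),
    mean_treatment = unname(m2),
    log2fc = unname(m2 - m1),
    s2 = unname(ss / df),
    df_residual = df,
    stringsAsFactors = FALSE)
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Inverse of the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by monotone root bracketing.
#' `trigamma` is strictly decreasing on (0, Inf) with range (0, Inf), so the
#' root is unique. Used by the empirical-Bayes hyperparameter estimator.
#'
#' @param y positive target value.
#' @return The unique positive `x` with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  stopifnot(is.numeric(y), length(y) == 1L, is.finite(y))
  if (y <= 0) stop2("trigamma_inverse() needs a positive target")
  lower <- 1e-8
  upper <- 1e8
  # trigamma(1e-8) ~ 1e16, trigamma(1e8) ~ 1e-8: bracket covers practical y
  if (y >= trigamma(lower)) return(lower)
  if (y <= trigamma(upper)) return(upper)
  stats::uniroot(function(x) trigamma(x) - y, lower = lower, upper = upper,
                 tol = 1e-12, maxiter = 1000L)$root
}

#' Empirical-Bayes variance-prior estimation
#'
#' Estimates the scaled inverse-chi-square prior on gene variances
#' (degrees of freedom `d0`, scale `s0_sq`) by moment matching on
#' `e_g = log(s2_g)`. Under the model, `var(e) = trigamma(df/2) +
#' trigamma(d0/2)`, so `d0` solves `trigamma(d0/2) = var(e) - trigamma(df/2)`
#' and `s0_sq = exp(mean(e) - digamma(df/2) + log(df/2) + digamma(d0/2) -
#' log(d0/2))`. When the observed spread is no larger than expected under a
#' single common variance, `d0 = Inf` is returned (complete shrinkage).
#'
#' @param s2 numeric vector of residual variances (>= 2 finite positive
#'   values required; zeros are excluded from the fit).
#' @param df residual degrees of freedom shared by all genes.
#' @return A list of class `ebayes_hyper` with elements `d0` and `s0_sq`.
#' @export
estimate_hyper <- function(s2, df) {
  stopifnot(is.numeric(s2), is_count(df))
  s2 <- s2[is.finite(s2)]
  if (all(s2 <= 0)) stop2("all residual variances are zero")
  pos <- s2[s2 > 0]
  if (length(pos) < 2L)
    stop2("need at least 2 positive residual variances")
  e <- log(pos)
  evar <- stats::var(e)
  target <- evar - trigamma(df / 2)
  if (target <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s0_sq <- exp(mean(e) - digamma(df / 2) + log(df / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_hyper")
}

#' @export
print.ebayes_hyper <- function(x, ...) {
  cat(sprintf("empirical-Bayes variance prior: d0 = %s, s0^2 = %.6g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated t-statistics
#'
#' Shrinks each gene's residual variance toward the empirical-Bayes prior,
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`, forms
#' `t = log2fc / sqrt(s2_post * (1/n1 + 1/n2))`, and computes two-sided
#' p-values from a Student t distribution with `d0 + df` degrees of freedom
#' (standard normal when `d0 = Inf`; with `d0 = 0` the statistic reduces to
#' the classical pooled two-sample t). Genes whose posterior variance is zero
#' get `p = 0` and are flagged `degenerate_variance` rather than producing a
#' division error.
#'
#' @param stats a `gene_stats` data.frame from [fit_contrast()].
#' @param hyper an `ebayes_hyper` list (or `list(d0=, s0_sq=)`).
#' @return `stats` with columns `s2_post`, `t_mod`, `p`,
#'   `degenerate_variance` added.
#' @export
moderated_t <- function(stats, hyper) {
  stopifnot(inherits(stats, "gene_stats"))
  d0 <- hyper$d0; s0_sq <- hyper$s0_sq
  stopifnot(is.numeric(d0), d0 >= 0)
  n1 <- attr(stats, "n1"); n2 <- attr(stats, "n2")
  df <- stats$df_residual
  s2_post <- if (is.infinite(d0)) rep(s0_sq, nrow(stats)) else
    (d0 * s0_sq + df * stats$s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  degenerate <- s2_post <= 0
  t_mod <- ifelse(degenerate, ifelse(stats$log2fc == 0, 0, Inf * sign(stats$log2fc)),
                  stats$log2fc / se)
  df_total <- d0 + df
  p <- ifelse(degenerate & stats$log2fc != 0, 0,
              2 * stats::pt(-abs(t_mod), df = df_total))
  if (any(degenerate))
    warn2(sum(degenerate), " gene(s) with zero posterior variance flagged ",
          "degenerate_variance (p set to 0 where log2fc != 0)")
  stats$s2_post <- s2_post
  stats$t_mod <- t_mod
  stats$p <- p
  stats$degenerate_variance <- degenerate
  attr(stats, "hyper") <- list(d0 = d0, s0_sq = s0_sq)
  stats
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `adj_p[i] = min over j with rank(j) >= rank(i) of
#' (n / rank(j)) * p[j]`, capped at 1. Input order is preserved. Implemented
#' directly (not via [stats::p.adjust()]) so the test suite can cross-check
#' it against an independent brute-force oracle.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)) ||
      any(p < 0) || any(p > 1))
    stop2("p-values must be finite numbers in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

#' Classify differentially expressed genes
#'
#' A gene is `up` iff `adj_p < alpha` and `log2fc > lfc_threshold`, `down`
#' iff `adj_p < alpha` and `log2fc < -lfc_threshold`, otherwise `ns`. All
#' inequalities are strict, so boundary values (e.g. `adj_p == alpha`) are
#' not significant.
#'
#' @param stats a `gene_stats` data.frame with `adj_p` filled.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_threshold absolute log2-fold-change cutoff (default 0.1).
#' @return `stats` with a `status` column (`up`/`down`/`ns`).
#' @export
classify_degs <- function(stats, alpha = 0.05, lfc_threshold = 0.1) {
  stopifnot(is.data.frame(stats), !is.null(stats$adj_p))
  status <- rep("ns", nrow(stats))
  status[stats$adj_p < alpha & stats$log2fc > lfc_threshold] <- "up"
  status[stats$adj_p < alpha & stats$log2fc < -lfc_threshold] <- "down"
  stats$status <- status
  attr(stats, "alpha") <- alpha
  attr(stats, "lfc_threshold") <- lfc_threshold
  stats
}

#' Full differential expression analysis
#'
#' Runs the fixed analysis chain on preprocessed data: contrast fit,
#' empirical-Bayes hyperparameter estimation, moderated t, BH adjustment and
#' DEG classification. The input must be log2-scale and 75th-percentile
#' normalized; running on unnormalized data is an error.
#'
#' @inheritParams fit_contrast
#' @inheritParams classify_degs
#' @param shrinkage logical; `FALSE` disables variance moderation (`d0 = 0`),
#'   giving the classical pooled t-test.
#' @param noise_probes optional character vector from [noise_filter()]; when
#'   given, the analysis is restricted to these probes.
#' @return A `gene_stats` data.frame with all columns through `status`.
#' @export
run_dea <- function(m, contrast, alpha = 0.05, lfc_threshold = 0.1,
                    shrinkage = TRUE, noise_probes = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!isTRUE(m$normalized))
    stop2("run_dea() requires 75th-percentile normalized data")
  if (!is.null(noise_probes))
    m <- subset_probes(m, rownames(m$values) %in% noise_probes)
  stats <- fit_contrast(m, contrast)
  hyper <- if (shrinkage) estimate_hyper(stats$s2, stats$df_residual[1L])
           else list(d0 = 0, s0_sq = 1)
  stats <- moderated_t(stats, hyper)
  stats$adj_p <- bh_adjust(stats$p)
  classify_degs(stats, alpha = alpha, lfc_threshold = lfc_threshold)
}

#' Select transcription-factor DEGs
#'
#' Intersects the differentially expressed genes (status not `ns`) with a
#' transcription-factor catalog, preserving status and direction.
#'
#' @param stats a classified `gene_stats` data.frame.
#' @param catalog character vector of transcription-factor symbols.
#' @return The subset of `stats` rows that are TF-DEGs.
#' @export
select_tf_degs <- function(stats, catalog) {
  stopifnot(is.data.frame(stats), !is.null(stats$status))
  if (length(catalog) == 0L) {
    warn2("empty transcription-factor catalog: no TF-DEGs")
    return(stats[0L, , drop = FALSE])
  }
  stats[stats$status != "ns" & stats$gene %in% catalog, , drop = FALSE]
}

#' Intersect the DEG calls of two contrasts
#'
#' @param degsA,degsB classified `gene_stats` data.frames from two contrasts.
#' @param catalog optional TF catalog used to flag the common genes.
#' @return A list with `common_up`, `common_down` (character vectors of genes
#'   significant in the same direction in both contrasts) and `tf_flags`, a
#'   named logical vector over the union of common genes.
#' @export
intersect_contrasts <- function(degsA, degsB, catalog = character(0)) {
  up <- intersect(degsA$gene[degsA$status == "up"],
                  degsB$gene[degsB$status == "up"])
  down <- intersect(degsA$gene[degsA$status == "down"],
                    degsB$gene[degsB$status == "down"])
  genes <- c(up, down)
  list(common_up = up, common_down = down,
       tf_flags = stats::setNames(genes %in% catalog, genes))
}

#' Volcano-plot export table
#'
#' Plot-ready table with the log2 fold change on the x-axis and
#' `log1p(-log10 adj_p)` on the y-axis, plus status and TF flags.
#'
#' @param stats a classified `gene_stats` data.frame.
#' @param catalog TF catalog for the `is_tf` column.
#' @return A data.frame with columns `gene`, `log2fc`, `enrichment_y`,
#'   `status`, `is_tf`.
#' @export
volcano_table <- function(stats, catalog = character(0)) {
  data.frame(gene = stats$gene,
             log2fc = stats$log2fc,
             enrichment_y = log1p(-log10(pmax(stats$adj_p, .Machine$double.xmin))),
             status = stats$status,
             is_tf = stats$gene %in% catalog,
             stringsAsFactors = FALSE)
}
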