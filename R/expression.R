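#' Probe-by-sample expression container
#'
#' A lightweight S3 container for one-colour microarray intensities: a numeric
#' probe x sample matrix, an optional companion matrix of detection flags
#' (`"P"`resent / `"M"`arginal / `"A"`bsent), a sample-to-group design, and a
#' scale marker recording whether values are linear intensities or log2
#' intensities. Preprocessing functions update the marker and refuse to run
#' out of order (e.g. [log2_transform()] on already-logged data errors).
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param groups named character vector mapping sample id to group label;
#'   names must cover all columns of `values`.
#' @param flags optional character matrix of the same dimension as `values`
#'   with entries in `P`, `M`, `A`.
#' @param scale `"linear"` or `"log2"`.
#' @param normalized logical; set by [normalize_p75()].
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, groups, flags = NULL,
                              scale = c("linear", "log2"),
                              normalized = FALSE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop2("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop2("`values` must have unique rownames (probe ids); ",
          "duplicate probe/gene symbols are rejected")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop2("`values` must have unique colnames (sample ids)")
  if (!all(colnames(values) %in% names(groups)))
    stop2("every sample id must appear in `groups`")
  if (!is.null(flags)) {
    if (!identical(dim(flags), dim(values)))
      stop2("`flags` must have the same dimensions as `values`")
    if (!all(flags %in% c("P", "M", "A")))
      stop2("flags must be one of 'P', 'M', 'A'")
    dimnames(flags) <- dimnames(values)
  }
  structure(
    list(values = values, flags = flags,
         groups = groups[colnames(values)],
         scale = scale, normalized = normalized),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples [%s%s]\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (x$normalized) ", p75-normalized" else ""))
  cat("groups:", paste(sprintf("%s=%s", names(x$groups), x$groups),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

subset_probes <- function(m, keep) {
  m$values <- m$values[keep, , drop = FALSE]
  if (!is.null(m$flags)) m$flags <- m$flags[keep, , drop = FALSE]
  m
}

#' Clamp non-positive raw intensities to 1.0
#'
#' Replaces every raw intensity at or below zero by 1.0 on the linear scale.
#' Zeroes are clamped together with negatives so that the later log2
#' transform is always defined.
#'
#' @param m an [expression_matrix()] on the linear scale.
#' @return The matrix with all values positive.
#' @export
clamp_negatives <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "linear")
    stop2("clamp_negatives() expects linear-scale intensities")
  m$values[m$values <= 0] <- 1.0
  m
}

#' 75th-percentile normalization
#'
#' Divides each sample's column by that sample's 75th percentile, so that
#' afterwards every sample's 75th percentile equals 1.0. The percentile uses
#' linear interpolation between order statistics at position `1 + (n-1)q`
#' (R's default quantile type 7); the convention is recorded in run
#' manifests because it is required for bit-reproducibility.
#'
#' @param m an [expression_matrix()] on the linear scale with positive values.
#' @return The normalized matrix (`normalized` marker set).
#' @export
normalize_p75 <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "linear")
    stop2("normalize_p75() expects linear-scale intensities")
  p75 <- apply(m$values, 2L, stats::quantile, probs = 0.75, names = FALSE,
               type = 7)
  if (any(p75 <= 0))
    stop2("75th percentile is not positive for sample(s): ",
          paste(colnames(m$values)[p75 <= 0], collapse = ", "),
          " (clamp first)")
  m$values <- sweep(m$values, 2L, p75, "/")
  m$normalized <- TRUE
  m
}

#' Keep probes detected in at least one sample
#'
#' Retains exactly the probes whose detection flag is Present or Marginal in
#' at least one sample; probes Absent everywhere are removed. Probe order is
#' preserved.
#'
#' @param m an [expression_matrix()] with a flags matrix.
#' @return The filtered matrix.
#' @export
filter_expressed <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$flags))
    stop2("filter_expressed() requires detection flags")
  keep <- rowSums(m$flags == "P" | m$flags == "M") >= 1L
  if (!any(keep)) warn2("no probe is flagged Present or Marginal in any sample")
  subset_probes(m, keep)
}

#' Log2-transform linear intensities
#'
#' @param m an [expression_matrix()] on the linear scale with positive values.
#' @return The matrix on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "linear")
    stop2("data are already log2-transformed")
  if (any(m$values <= 0))
    stop2("non-positive values present; run clamp_negatives() first")
  m$values <- log2(m$values)
  m$scale <- "log2"
  m
}

#' Low-noise probe filter for a contrast
#'
#' Keeps the probes whose expression is tight within each group and clearly
#' separated between groups: both groups must have a sample standard
#' deviation strictly below `sd_max` and the absolute difference of the group
#' means must strictly exceed `dist_min`. Intended to precede differential
#' expression in noisy secondary contrasts.
#'
#' @param m an [expression_matrix()] on the log2 scale.
#' @param contrast a [contrast_spec()].
#' @param sd_max maximum within-group standard deviation (log2 units).
#' @param dist_min minimum distance between group means (log2 units).
#' @return Character vector of retained probe ids.
#' @export
noise_filter <- function(m, contrast, sd_max = 0.3, dist_min = 0.5) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop2("noise_filter() expects log2-scale data")
  idx <- contrast_columns(m, contrast)
  v1 <- m$values[, idx$control, drop = FALSE]
  v2 <- m$values[, idx$treatment, drop = FALSE]
  sd1 <- apply(v1, 1L, stats::sd)
  sd2 <- apply(v2, 1L, stats::sd)
  dist <- abs(rowMeans(v2) - rowMeans(v1))
  rownames(m$values)[sd1 < sd_max & sd2 < sd_max & dist > dist_min]
}

#' Write / read the expression TSV triplet
#'
#' The on-disk format is three TSV files: intensities (first column `probe`,
#' header = sample ids), detection flags with values in `P`/`M`/`A`, and a
#' two-column design mapping `sample` to `group`.
#'
#' @param m an [expression_matrix()].
#' @param prefix path prefix; writes `<prefix>_expression.tsv`,
#'   `<prefix>_flags.tsv`, `<prefix>_design.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_expression_tsv <- function(m, prefix) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(probe = rownames(m$values), m$values, check.names = FALSE)
  write_tsv_det(df, paste0(prefix, "_expression.tsv"))
  if (!is.null(m$flags)) {
    df <- data.frame(probe = rownames(m$flags), m$flags, check.names = FALSE)
    write_tsv_det(df, paste0(prefix, "_flags.tsv"))
  }
  des <- data.frame(sample = names(m$groups), group = unname(m$groups))
  write_tsv_det(des, paste0(prefix, "_design.tsv"))
  invisible(prefix)
}

#' @rdname write_expression_tsv
#' @param scale scale of the stored values (files written by
#'   [write_expression_tsv()] before any transform are linear).
#' @export
read_expression_tsv <- function(prefix, scale = "linear") {
  vals <- read_tsv_simple(paste0(prefix, "_expression.tsv"))
  mat <- as.matrix(vals[, -1L, drop = FALSE])
  rownames(mat) <- vals[[1L]]
  flags_path <- paste0(prefix, "_flags.tsv")
  flags <- NULL
  if (file.exists(flags_path)) {
    fd <- read_tsv_simple(flags_path)
    flags <- as.matrix(fd[, -1L, drop = FALSE])
    rownames(flags) <- fd[[1L]]
    flags <- flags[rownames(mat), colnames(mat), drop = FALSE]
  }
  des <- read_tsv_simple(paste0(prefix, "_design.tsv"))
  groups <- stats::setNames(des$group, des$sample)
  expression_matrix(mat, groups, flags = flags, scale = scale)
}
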