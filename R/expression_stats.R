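# Gene-expression stage: RPKM -> log2 -> sample-level quantile
# normalization -> per-gene t-test -> BH, plus PCA and hierarchical
# clustering applied to expression or PSI matrices.

#' Remove genes with low read depth across the cohort
#'
#' Keeps genes whose mean count across samples is at least `min_mean`
#' (boundary inclusive).
#'
#' @param counts Gene x sample integer matrix (rownames = gene ids).
#' @param min_mean Minimum mean count (default 1).
#' @return The filtered matrix.
#' @export
filter_low_depth_genes <- function(counts, min_mean = 1) {
  counts <- as.matrix(counts)
  counts[rowMeans(counts) >= min_mean, , drop = FALSE]
}

#' Reads-per-kilobase-per-million normalization
#'
#' `RPKM = count / (gene length / 1e3) / (library size / 1e6)`.
#'
#' @param counts Gene x sample matrix.
#' @param gene_lengths Named vector of gene lengths in bp (>= 1), covering
#'   all rows.
#' @param library_sizes Optional named per-sample totals (> 0); defaults to
#'   the column sums of `counts`.
#' @return Matrix of RPKM values.
#' @export
counts_to_rpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  gl <- gene_lengths[rownames(counts)]
  if (anyNA(gl)) stop("missing gene length for some rows")
  if (any(gl <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  ls <- library_sizes[colnames(counts)]
  if (anyNA(ls)) ls <- library_sizes  # unnamed vector in column order
  sweep(counts / (gl / 1e3), 2L, as.numeric(ls) / 1e6, "/")
}

#' Log2 transformation with pseudocount
#'
#' @param m Numeric matrix (non-negative).
#' @param pseudocount Added before taking log2 (default 1).
#' @return `log2(m + pseudocount)`.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  log2(as.matrix(m) + pseudocount)
}

#' Sample-level quantile normalization
#'
#' Classic quantile normalization across samples (columns): each column's
#' ranks are mapped onto the row means of the sorted columns, so that
#' afterwards every sample is a permutation of one shared reference
#' vector. Ties are broken by position order rather than averaged; this
#' keeps the defining property exact (identical sorted columns) and makes
#' the transformation idempotent, which tie-averaging does not.
#'
#' @param m Numeric matrix (genes x samples).
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  out <- limma::normalizeQuantiles(m, ties = FALSE)
  dimnames(out) <- dimnames(m)
  out
}

#' Differential expression by per-gene t-test
#'
#' Two-sided t-test on the normalized scale per gene (Student's pooled
#' variance by default), BH-adjusted across genes.
#'
#' @param norm Normalized gene x sample matrix.
#' @param groups Named character vector: sample -> group.
#' @param group_a,group_b Group labels (`diff` is a - b).
#' @param var_equal Pooled-variance Student test (default TRUE); set FALSE
#'   for Welch.
#' @return data.table: `gene`, `mean_a`, `mean_b`, `diff`, `p`, `q`,
#'   `significant` (q < 0.05).
#' @export
differential_expression <- function(norm, groups, group_a, group_b,
                                    var_equal = TRUE) {
  m <- as.matrix(norm)
  sa <- intersect(names(groups)[groups == group_a], colnames(m))
  sb <- intersect(names(groups)[groups == group_b], colnames(m))
  if (length(sa) < 2L || length(sb) < 2L) {
    stop("need at least two samples per group")
  }
  res <- data.table::data.table(
    gene = rownames(m),
    mean_a = rowMeans(m[, sa, drop = FALSE]),
    mean_b = rowMeans(m[, sb, drop = FALSE]))
  res[, diff := mean_a - mean_b]
  res[, p := vapply(seq_len(nrow(m)), function(i) {
    welch_p(m[i, sa], m[i, sb], var_equal = var_equal)$p
  }, numeric(1))]
  res[, q := bh_adjust(p)]
  res[, significant := q < 0.05]
  res[]
}

#' Principal components analysis of a feature x sample matrix
#'
#' Samples (columns) are the observations; features are centred but not
#' scaled; components come from the singular value decomposition
#' ([stats::prcomp()]).
#'
#' @param m Feature x sample matrix.
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `loadings`, `var_frac`.
#' @export
pca_samples <- function(m) {
  m <- as.matrix(m)
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, loadings = pr$rotation, var_frac = var_frac),
            class = "pca_result")
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the columns with Euclidean distance
#' (complete linkage by default).
#'
#' @param m Feature x sample matrix.
#' @param linkage One of `"complete"`, `"average"`, `"ward.D2"`.
#' @return List with the `hclust` object and `leaf_order` (column labels in
#'   dendrogram order).
#' @export
hierarchical_cluster <- function(m, linkage = c("complete", "average",
                                                "ward.D2")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(m)
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                      method = linkage)
  list(hclust = hc, leaf_order = hc$labels[hc$order])
}
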