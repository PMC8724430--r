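#' Marker-correlation quality control for cell-type signatures
#'
#' A cell type's marker set is usable for scoring only when its markers
#' co-vary across samples, i.e. when the minimum pairwise Pearson correlation
#' of their log2 expression is at least `r_min` (default 0.6, inclusive).
#' Single-marker types pass by definition (R undefined). Markers missing from
#' the retained matrix are dropped with a warning; a type with all markers
#' missing is reported below detection and fails.
#'
#' @param norm a `normalized_matrix` or a log2 genes x samples matrix.
#' @param signatures signature `data.frame` (see [read_signatures()]) or a
#'   named list of marker vectors.
#' @param r_min minimum acceptable pairwise correlation (default 0.6).
#' @return `data.frame`: per cell type, `n_markers` (present), `r_min`
#'   (minimum pairwise correlation, `NA` for <2 markers), `pass`,
#'   `below_detection`.
#' @export
marker_qc <- function(norm, signatures, r_min = 0.6) {
  lmat <- if (inherits(norm, "normalized_matrix")) norm$log2 else as.matrix(norm)
  if (ncol(lmat) < 4) stopf("marker_qc needs at least 4 samples")
  sets <- if (is.data.frame(signatures)) signature_gene_lists(signatures, "cell")
          else signatures
  out <- lapply(names(sets), function(ct) {
    markers <- sets[[ct]]
    present <- intersect(markers, rownames(lmat))
    missing <- setdiff(markers, present)
    if (length(missing) && length(present))
      warnf("cell type %s: dropping %d marker(s) not in the retained matrix: %s",
            ct, length(missing), paste(missing, collapse = ", "))
    if (!length(present))
      return(data.frame(cell_type = ct, n_markers = 0L, r_min = NA_real_,
                        pass = FALSE, below_detection = TRUE))
    rmin <- NA_real_
    if (length(present) >= 2L) {
      cm <- stats::cor(t(lmat[present, , drop = FALSE]))
      rmin <- min(cm[upper.tri(cm)])
    }
    data.frame(cell_type = ct, n_markers = length(present), r_min = rmin,
               pass = is.na(rmin) || rmin >= r_min, below_detection = FALSE)
  })
  do.call(rbind, out)
}

#' Cell-type score for one marker set
#'
#' The score of sample s is the arithmetic mean of the log2 expression of the
#' cell type's marker genes in s: a relative abundance proxy comparable
#' across samples (not across cell types).
#'
#' @param norm a `normalized_matrix` or log2 matrix.
#' @param markers marker gene names; those present in the matrix are used.
#' @return Named numeric vector, one score per sample (log2 units).
#' @export
cell_score <- function(norm, markers) {
  lmat <- if (inherits(norm, "normalized_matrix")) norm$log2 else as.matrix(norm)
  present <- intersect(markers, rownames(lmat))
  if (!length(present)) stopf("no marker genes present in the matrix")
  colMeans(lmat[present, , drop = FALSE])
}

#' Score all cell types of a signature set
#'
#' @inheritParams marker_qc
#' @return List with `scores` (samples x cell types matrix) and `qc` (the
#'   [marker_qc()] table). Below-detection types get `NA` scores.
#' @export
cell_scores <- function(norm, signatures, r_min = 0.6) {
  lmat <- if (inherits(norm, "normalized_matrix")) norm$log2 else as.matrix(norm)
  sets <- if (is.data.frame(signatures)) signature_gene_lists(signatures, "cell")
          else signatures
  qc <- suppressWarnings(marker_qc(lmat, sets, r_min))
  scores <- matrix(NA_real_, ncol(lmat), length(sets),
                   dimnames = list(colnames(lmat), names(sets)))
  for (ct in names(sets)) {
    if (qc$below_detection[qc$cell_type == ct]) next
    scores[, ct] <- cell_score(lmat, sets[[ct]])
  }
  list(scores = scores, qc = qc)
}

#' Pathway global significance score
#'
#' For one contrast, the global significance of a pathway is the square root
#' of the mean squared per-gene t-like statistic over the pathway's genes.
#' Genes without a test statistic are excluded from the mean.
#'
#' @param t_stats named numeric vector of per-gene statistics (e.g.
#'   `log2fc / se` from a `de_result`).
#' @param genes pathway gene names.
#' @return List: `score` (>= 0), `n_genes` (used), `n_missing`.
#' @export
pathway_global_score <- function(t_stats, genes) {
  t_g <- t_stats[intersect(genes, names(t_stats))]
  t_g <- t_g[is.finite(t_g)]
  if (!length(t_g)) stopf("no testable gene in pathway")
  list(score = sqrt(mean(t_g^2)), n_genes = length(t_g),
       n_missing = length(genes) - length(t_g))
}

#' Per-sample pathway score
#'
#' First principal component of the per-gene z-scored log2 expression
#' restricted to the pathway genes; scores are centered at zero across the
#' cohort. Orientation is fixed so the score correlates positively with the
#' mean pathway expression (exact ties broken toward a positive loading of
#' the lexicographically first gene).
#'
#' @param norm a `normalized_matrix` or log2 matrix.
#' @param genes pathway gene names (at least 2 present).
#' @return Named numeric vector, one centered score per sample.
#' @export
pathway_sample_score <- function(norm, genes) {
  lmat <- if (inherits(norm, "normalized_matrix")) norm$log2 else as.matrix(norm)
  present <- sort(intersect(genes, rownames(lmat)))
  if (length(present) < 2L) stopf("pathway sample score needs >= 2 present genes")
  if (ncol(lmat) < 3L) stopf("pathway sample score needs >= 3 samples")
  sub <- lmat[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (all(sds == 0)) stopf("constant expression matrix; principal component undefined")
  z <- (sub - rowMeans(sub)) / ifelse(sds == 0, 1, sds)
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  score <- pc$x[, 1L]
  anchor <- stats::cor(score, colMeans(z))
  if (is.na(anchor) || anchor == 0) anchor <- pc$rotation[1L, 1L]
  if (anchor < 0) score <- -score
  score - mean(score)
}

#' Ward hierarchical clustering of a gene-expression block
#'
#' Rows (or columns) are z-scored per gene ("scaled to the gene average"),
#' then clustered with Ward linkage on Euclidean distances. Zero-variance
#' items z-score to zero vectors (allowed; they merge at height 0).
#'
#' @param mat numeric matrix, genes x samples, log2 scale.
#' @param axis `"genes"` (cluster rows) or `"samples"` (cluster columns;
#'   z-scoring is still per gene).
#' @return List of class `ward_cluster`: `order` (leaf order, labels),
#'   `heights` (linkage heights), `hclust` (the `stats::hclust` object).
#' @export
ward_cluster <- function(mat, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  mat <- as.matrix(mat)
  sds <- apply(mat, 1, stats::sd)
  z <- (mat - rowMeans(mat)) / ifelse(sds == 0, 1, sds)
  items <- if (axis == "genes") z else t(z)
  if (nrow(items) < 2L) stopf("ward_cluster needs at least 2 items")
  hc <- stats::hclust(stats::dist(items), method = "ward.D2")
  structure(list(order = rownames(items)[hc$order],
                 heights = hc$height, hclust = hc),
            class = "ward_cluster")
}

#' @export
print.ward_cluster <- function(x, ...) {
  cat(sprintf("ward_cluster: %d items, top merge height %.3f\n",
              length(x$order), max(x$heights)))
  invisible(x)
}
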