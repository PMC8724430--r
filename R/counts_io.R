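#' Construct a count matrix with probe-class annotation
#'
#' The central container for raw nCounter-style panel data: an integer
#' gene-by-sample count matrix in which every gene (probe) carries one of the
#' four panel probe classes: `endogenous` (the genes of interest),
#' `housekeeping` (candidate reference genes), `positive` and `negative`
#' (spike-in control probes).
#'
#' @param counts numeric matrix, genes x samples, non-negative integers, with
#'   unique rownames (genes) and colnames (samples).
#' @param probe_class character vector, one class per gene, in row order or
#'   named by gene.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `probe_class` (named character vector).
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' count_matrix(m, c("endogenous", "housekeeping", "negative"))
#' @export
count_matrix <- function(counts, probe_class) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene identifier: %s",
          rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample identifier: %s",
          colnames(counts)[duplicated(colnames(counts))][1L])
  if (any(is.na(counts)) || !is.numeric(counts))
    stopf("counts must be numeric with no missing values")
  if (any(counts < 0)) stopf("negative count at gene %s",
                             rownames(counts)[which(rowSums(counts < 0) > 0)[1L]])
  if (any(counts != round(counts))) stopf("counts must be integer-valued")
  if (!is.null(names(probe_class))) probe_class <- probe_class[rownames(counts)]
  probe_class <- as.character(probe_class)
  if (length(probe_class) != nrow(counts))
    stopf("probe_class length (%d) != number of genes (%d)",
          length(probe_class), nrow(counts))
  bad <- setdiff(unique(probe_class), PROBE_CLASSES)
  if (length(bad))
    stopf("unknown probe class '%s'; allowed classes: %s", bad[1L],
          paste(PROBE_CLASSES, collapse = ", "))
  names(probe_class) <- rownames(counts)
  storage.mode(counts) <- "double"
  structure(list(counts = counts, probe_class = probe_class),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(factor(x$probe_class, levels = PROBE_CLASSES))
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  probe classes: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# genes of one or more probe classes, in matrix order
genes_of_class <- function(x, classes) {
  names(x$probe_class)[x$probe_class %in% classes]
}

read_table_checked <- function(path, sep = "\t", required = character()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  miss <- setdiff(required, colnames(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  df
}

#' Read a count matrix from a delimited text file
#'
#' Expected layout: one row per gene; columns `gene`, `probe_class`, then one
#' column per sample holding non-negative integer counts. Row and column order
#' are preserved.
#'
#' @param path path to a TSV (or CSV, with `sep = ","`) file.
#' @param sep field separator, tab by default.
#' @return A [count_matrix].
#' @seealso [write_count_matrix()]
#' @export
read_count_matrix <- function(path, sep = "\t") {
  df <- read_table_checked(path, sep, required = c("gene", "probe_class"))
  samples <- setdiff(colnames(df), c("gene", "probe_class"))
  if (!length(samples)) stopf("%s: no sample columns", path)
  cnt <- as.matrix(df[, samples, drop = FALSE])
  if (!is.numeric(cnt)) {
    bad <- which(is.na(suppressWarnings(apply(cnt, 2, as.numeric))), arr.ind = TRUE)
    stopf("non-numeric count at row %d, column '%s'",
          bad[1L, 1L], samples[bad[1L, 2L]])
  }
  rownames(cnt) <- df$gene
  count_matrix(cnt, df$probe_class)
}

#' Write a count matrix to a delimited text file
#' @param x a [count_matrix].
#' @param path output path.
#' @param sep field separator.
#' @export
write_count_matrix <- function(x, path, sep = "\t") {
  df <- data.frame(gene = rownames(x$counts),
                   probe_class = unname(x$probe_class),
                   x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample annotations
#'
#' Columns `sample` and `group` are required; any further columns (for example
#' `binding_density`, clinical covariates) are carried along unchanged. The
#' canonical study groups are `healthy`, `eoPE` (early-onset preeclampsia) and
#' `loPE` (late-onset), but arbitrary labels are accepted.
#'
#' @param path path to a delimited text file.
#' @param sep field separator.
#' @return A `data.frame` with one row per sample, input order preserved.
#' @export
read_annotations <- function(path, sep = "\t") {
  df <- read_table_checked(path, sep, required = c("sample", "group"))
  validate_annotations(df)
}

validate_annotations <- function(df) {
  if (anyDuplicated(df$sample))
    stopf("duplicate sample identifier: %s", df$sample[duplicated(df$sample)][1L])
  grp <- as.character(df$group)
  if (any(is.na(grp) | !nzchar(trimws(grp))))
    stopf("missing group value for sample %s",
          df$sample[which(is.na(grp) | !nzchar(trimws(grp)))[1L]])
  df$group <- grp
  df
}

#' @rdname read_annotations
#' @param ann annotation `data.frame`.
#' @export
write_annotations <- function(ann, path, sep = "\t") {
  utils::write.table(ann, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read signature definitions (cell-type markers and pathway gene sets)
#'
#' Long format with columns `signature_type` (`cell` or `pathway`),
#' `signature_name` and `gene`. The package ships a default cell-marker table
#' (M2 macrophages: CD163, MRC1, C1QA, C1QB; M1: CD86, MSR1; mast cells:
#' TPSAB1; B cells: CD19) in `inst/extdata/default_signatures.tsv`.
#'
#' @param path path to a delimited text file.
#' @param sep field separator.
#' @return A `data.frame` with the three columns above.
#' @export
read_signatures <- function(path, sep = "\t") {
  df <- read_table_checked(path, sep,
                           required = c("signature_type", "signature_name", "gene"))
  validate_signatures(df)
}

validate_signatures <- function(df) {
  bad <- setdiff(unique(df$signature_type), c("cell", "pathway"))
  if (length(bad)) stopf("unknown signature_type '%s' (allowed: cell, pathway)", bad[1L])
  dup <- duplicated(df[, c("signature_type", "signature_name", "gene")])
  if (any(dup))
    stopf("duplicate gene '%s' within signature '%s'",
          df$gene[dup][1L], df$signature_name[dup][1L])
  if (any(!nzchar(df$gene))) stopf("empty gene name in signature table")
  df
}

#' @rdname read_signatures
#' @param sig signature `data.frame`.
#' @export
write_signatures <- function(sig, path, sep = "\t") {
  utils::write.table(sig, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a signature table into named gene lists
#' @param sig signature `data.frame` as returned by [read_signatures()].
#' @param type `"cell"` or `"pathway"`.
#' @return Named list of character vectors.
#' @export
signature_gene_lists <- function(sig, type = c("cell", "pathway")) {
  type <- match.arg(type)
  sub <- sig[sig$signature_type == type, , drop = FALSE]
  split(sub$gene, factor(sub$signature_name, levels = unique(sub$signature_name)))
}

#' Read an immunohistochemistry field-count table
#'
#' One row per counted field: columns `slide`, `group`, `region` (`villi` or
#' `decidua`), `field`, `category` (stain category, e.g. `CD68+CD163+` for M2
#' macrophages, `CD68+CD163-` for M1, `tryptase+` for mast cells), `count` and
#' `area_mm2`. Villous fields are conventionally 1 mm^2; decidual field areas
#' vary with decidual thickness.
#'
#' @param path path to a delimited text file.
#' @param sep field separator.
#' @return A validated `data.frame`.
#' @export
read_ihc <- function(path, sep = "\t") {
  df <- read_table_checked(path, sep,
      required = c("slide", "group", "region", "field", "category", "count", "area_mm2"))
  validate_ihc(df)
}

validate_ihc <- function(df) {
  bad <- setdiff(unique(df$region), c("villi", "decidua"))
  if (length(bad)) stopf("unknown region '%s' (allowed: villi, decidua)", bad[1L])
  if (any(df$count < 0)) stopf("negative cell count in IHC table")
  if (any(df$area_mm2 <= 0)) stopf("non-positive area in IHC table")
  df
}

#' @rdname read_ihc
#' @param ihc IHC `data.frame`.
#' @export
write_ihc <- function(ihc, path, sep = "\t") {
  utils::write.table(ihc, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a count matrix and an annotation table on their shared samples
#'
#' Restricts both to the intersection of their sample identifiers, in the
#' matrix's column order, and reports identifiers dropped on either side.
#'
#' @param counts a [count_matrix].
#' @param ann annotation `data.frame` with a `sample` column.
#' @return A list with `counts`, `ann`, `dropped_counts`, `dropped_ann`.
#' @export
align_samples <- function(counts, ann) {
  shared <- intersect(colnames(counts$counts), ann$sample)
  if (!length(shared))
    stopf("no samples shared between count matrix and annotations")
  keep <- colnames(counts$counts)[colnames(counts$counts) %in% shared]
  out_counts <- count_matrix(counts$counts[, keep, drop = FALSE], counts$probe_class)
  out_ann <- ann[match(keep, ann$sample), , drop = FALSE]
  rownames(out_ann) <- NULL
  list(counts = out_counts,
       ann = out_ann,
       dropped_counts = setdiff(colnames(counts$counts), shared),
       dropped_ann = setdiff(ann$sample, shared))
}
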