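#' Sample-level quality control
#'
#' Flags samples by three rules: lane binding density below a minimum (only
#' when a `binding_density` annotation column is present; failed lanes in the
#' motivating study sat below 0.2 versus above 0.7 for good lanes), and
#' positive-control geometric mean or housekeeping-count sum below a multiple
#' of the cohort median (failed lanes show depressed control counts).
#'
#' @param counts a [count_matrix].
#' @param ann optional annotation `data.frame`; its `binding_density` column,
#'   if present, drives the binding-density rule.
#' @param binding_density_min minimum acceptable binding density (default 0.2).
#' @param control_frac control-count rule multiplier: a sample fails when its
#'   positive-control geometric mean (or housekeeping sum) is below
#'   `control_frac` times the cohort median of that statistic (default 0.25).
#' @return A `data.frame` of class `qc_report`: per sample, the three QC
#'   statistics, `pass`, and a semicolon-joined `reasons` string (empty when
#'   passing). Sample order is preserved.
#' @export
sample_qc <- function(counts, ann = NULL, binding_density_min = 0.2,
                      control_frac = 0.25) {
  stopifnot(binding_density_min > 0, control_frac > 0)
  cnt <- counts$counts
  samples <- colnames(cnt)
  pos <- genes_of_class(counts, "positive")
  hk <- genes_of_class(counts, "housekeeping")
  if (!length(pos)) stopf("sample_qc requires positive-control probes")
  if (!length(hk)) stopf("sample_qc requires housekeeping probes")

  pos_gm <- apply(cnt[pos, , drop = FALSE], 2, function(x) geomean(pmax(x, 0.5)))
  hk_sum <- colSums(cnt[hk, , drop = FALSE])
  bd <- rep(NA_real_, length(samples))
  if (!is.null(ann) && "binding_density" %in% colnames(ann))
    bd <- as.numeric(ann$binding_density[match(samples, ann$sample)])

  reasons <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    r <- character()
    if (!is.na(bd[i]) && bd[i] < binding_density_min) r <- c(r, "binding_density")
    if (pos_gm[i] < control_frac * stats::median(pos_gm)) r <- c(r, "positive_controls")
    if (hk_sum[i] < control_frac * stats::median(hk_sum)) r <- c(r, "housekeeping_counts")
    reasons[[i]] <- r
  }
  pass <- lengths(reasons) == 0L
  if (!any(pass)) stopf("all samples fail QC; empty cohort")
  structure(data.frame(sample = samples,
                       binding_density = bd,
                       positive_geomean = unname(pos_gm),
                       housekeeping_sum = unname(hk_sum),
                       pass = pass,
                       reasons = vapply(reasons, paste, "", collapse = ";"),
                       stringsAsFactors = FALSE),
            class = c("qc_report", "data.frame"))
}

#' geNorm expression-stability measure M
#'
#' For each candidate reference gene j, `M_j` is the mean over the other
#' candidates k of the sample standard deviation (n-1 denominator) of the
#' per-sample log2 ratios `log2 x_j - log2 x_k`. Low M means the gene moves
#' in lockstep with the other candidates, the geNorm notion of stability.
#' M is invariant to per-sample multiplicative scaling of the raw counts
#' because such scaling cancels in every log-ratio.
#'
#' @param log2_hk numeric matrix of log2 expression, candidate genes x samples.
#' @return Named numeric vector of M values.
#' @export
genorm_stability <- function(log2_hk) {
  if (!is.matrix(log2_hk)) log2_hk <- as.matrix(log2_hk)
  if (nrow(log2_hk) < 3) stopf("genorm_stability needs at least 3 candidate genes")
  if (ncol(log2_hk) < 2) stopf("genorm_stability needs at least 2 samples")
  if (any(!is.finite(log2_hk))) stopf("non-finite log2 values")
  n <- nrow(log2_hk)
  M <- numeric(n)
  for (j in seq_len(n)) {
    sds <- vapply(setdiff(seq_len(n), j),
                  function(k) stats::sd(log2_hk[j, ] - log2_hk[k, ]), 0)
    M[j] <- mean(sds)
  }
  names(M) <- rownames(log2_hk)
  M
}

#' Iterative geNorm reference-gene selection
#'
#' Repeatedly removes the candidate with the highest stability measure M
#' (recomputed each round) until a stop rule holds: either a target number of
#' genes (`target_n`) or all remaining M at or below `max_M` (default 0.5,
#' the conventional geNorm cutoff for heterogeneous tissue). Ties on M are
#' broken by removing the gene with the higher variance of log2 values, then
#' lexicographically. Selection never drops below 3 genes; if the stop rule
#' would, selection stops at 3 with `floor_reached = TRUE`.
#'
#' @param counts a [count_matrix].
#' @param candidates candidate gene names; default all housekeeping-class
#'   genes.
#' @param target_n stop when this many genes remain (overrides `max_M`).
#' @param max_M stability cutoff used when `target_n` is `NULL`.
#' @return A list of class `genorm_result`: `selected`, `eliminated` (in
#'   elimination order), `M` (final M of selected genes), `M_initial` (M of
#'   all candidates at the first round), `pairwise_variation` (V_k trace,
#'   NULL when fewer than 3 elimination rounds), `floor_reached`.
#' @export
select_housekeepers <- function(counts, candidates = NULL, target_n = NULL,
                                max_M = 0.5) {
  hk <- genes_of_class(counts, "housekeeping")
  candidates <- candidates %||% hk
  bad <- setdiff(candidates, hk)
  if (length(bad)) stopf("candidate '%s' is not a housekeeping-class gene", bad[1L])
  if (length(candidates) < 3) stopf("need at least 3 candidate genes")
  if (!is.null(target_n) && target_n > length(candidates))
    target_n <- length(candidates)

  lmat <- log2_floor(counts$counts[candidates, , drop = FALSE])
  current <- candidates
  eliminated <- character()
  M_initial <- genorm_stability(lmat)
  floor_reached <- FALSE
  nf_trace <- list(stats::setNames(apply(lmat, 2, mean), colnames(lmat)))

  repeat {
    M <- genorm_stability(lmat[current, , drop = FALSE])
    done <- if (!is.null(target_n)) length(current) <= target_n
            else all(M <= max_M)
    if (done) break
    if (length(current) <= 3L) { floor_reached <- TRUE; break }
    worst <- which(M == max(M))
    if (length(worst) > 1L) {
      v <- apply(lmat[current[worst], , drop = FALSE], 1, stats::var)
      worst <- worst[order(-v, current[worst])][1L]
    }
    eliminated <- c(eliminated, current[worst])
    current <- current[-worst]
    nf_trace[[length(nf_trace) + 1L]] <-
      stats::setNames(apply(lmat[current, , drop = FALSE], 2, mean), colnames(lmat))
  }
  if (floor_reached)
    warnf("geNorm stop rule would select fewer than 3 genes; stopped at 3")

  # pairwise variation V_k between successive reference sets (most stable
  # k vs k+1 genes), computed from the elimination order
  pv <- NULL
  order_by_stability <- c(current[order(genorm_stability(
    lmat[current, , drop = FALSE]))], rev(eliminated))
  if (length(order_by_stability) >= 3) {
    ks <- 2:(length(order_by_stability) - 1L)
    pv <- vapply(ks, function(k) {
      nf_k <- apply(lmat[order_by_stability[1:k], , drop = FALSE], 2, mean)
      nf_k1 <- apply(lmat[order_by_stability[1:(k + 1)], , drop = FALSE], 2, mean)
      stats::sd(nf_k - nf_k1)
    }, 0)
    names(pv) <- sprintf("V%d/%d", ks, ks + 1L)
  }

  structure(list(selected = current,
                 eliminated = eliminated,
                 M = genorm_stability(lmat[current, , drop = FALSE]),
                 M_initial = M_initial,
                 pairwise_variation = pv,
                 floor_reached = floor_reached),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat(sprintf("geNorm selection: %d reference genes (max M = %.3f), %d eliminated\n",
              length(x$selected), max(x$M), length(x$eliminated)))
  invisible(x)
}

#' Per-sample background expression thresholds
#'
#' The detection threshold of sample s is twice the arithmetic mean of that
#' sample's negative-control counts.
#'
#' @param counts a [count_matrix] with at least one negative-control probe.
#' @return Named numeric vector `b_s`, one threshold per sample.
#' @export
background_thresholds <- function(counts) {
  neg <- genes_of_class(counts, "negative")
  if (!length(neg)) stopf("no negative-control probes; background threshold undefined")
  2 * colMeans(counts$counts[neg, , drop = FALSE])
}

#' Filter genes below the background threshold
#'
#' A gene is excluded when its count is below the per-sample threshold in
#' strictly more than `excl_frac` of samples (default 0.8, i.e. the >80
#' percent rule: below-threshold in 5 of 6 samples excludes, in 4 of 5 does
#' not). Control probes are never filtered. Order of retained genes follows
#' the input matrix.
#'
#' @param counts a [count_matrix].
#' @param b per-sample thresholds from [background_thresholds()].
#' @param excl_frac exclusion fraction (strict inequality).
#' @return Character vector of retained endogenous and housekeeping genes.
#' @export
filter_low_expressed <- function(counts, b, excl_frac = 0.8) {
  samples <- colnames(counts$counts)
  if (!all(samples %in% names(b))) stopf("thresholds b must cover all samples")
  b <- b[samples]
  core <- genes_of_class(counts, c("endogenous", "housekeeping"))
  below <- sweep(counts$counts[core, , drop = FALSE], 2, b, `<`)
  frac_below <- rowMeans(below)
  core[!(frac_below > excl_frac)]
}

#' Housekeeping (content) normalization to a log2 expression matrix
#'
#' Each sample is scaled by `f_s = geomean_over_samples(g) / g_s`, where `g_s`
#' is the geometric mean of the selected reference genes' counts in sample s
#' (counts floored at 0.5). By construction the geometric mean of the factors
#' is 1. Normalized counts are `raw * f_s`; reported expression is
#' `log2(normalized + pseudocount)`.
#'
#' @param counts a [count_matrix].
#' @param housekeepers selected reference gene names (e.g.
#'   `select_housekeepers(...)$selected`).
#' @param retained genes to keep in the output matrix (default: all
#'   endogenous + housekeeping genes); see [filter_low_expressed()].
#' @param b optional per-sample background thresholds, stored for reporting.
#' @param pseudocount added before the log2 transform (default 0.5).
#' @return An object of class `normalized_matrix`: list with `log2` (retained
#'   genes x samples), `factors` (named, geometric mean 1), `retained`,
#'   `housekeepers`, `background`, `pseudocount`.
#' @export
normalize_counts <- function(counts, housekeepers, retained = NULL, b = NULL,
                             pseudocount = 0.5) {
  cnt <- counts$counts
  miss <- setdiff(housekeepers, rownames(cnt))
  if (length(miss)) stopf("housekeeper '%s' absent from count matrix", miss[1L])
  retained <- retained %||% genes_of_class(counts, c("endogenous", "housekeeping"))
  if (!all(housekeepers %in% retained))
    stopf("all selected housekeepers must be retained")

  g_s <- apply(pmax(cnt[housekeepers, , drop = FALSE], 0.5), 2, geomean)
  if (any(g_s <= 0)) stopf("zero housekeeping geometric mean; cannot normalize")
  f <- geomean(g_s) / g_s
  norm <- sweep(cnt[retained, , drop = FALSE], 2, f, `*`)
  structure(list(log2 = log2(norm + pseudocount),
                 factors = f,
                 retained = retained,
                 housekeepers = housekeepers,
                 background = b,
                 pseudocount = pseudocount),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples (log2 scale)\n",
              nrow(x$log2), ncol(x$log2)))
  cat(sprintf("  normalization factors in [%.3f, %.3f], %d reference genes\n",
              min(x$factors), max(x$factors), length(x$housekeepers)))
  invisible(x)
}

#' Run the full QC + normalization stage
#'
#' Convenience wrapper: sample QC, geNorm reference selection, background
#' thresholding, low-expression filtering, and content normalization, in that
#' order, on the QC-passing samples.
#'
#' @param counts a [count_matrix].
#' @param ann optional annotation `data.frame` (binding density rule).
#' @param target_n_hk,max_M geNorm stop rule (see [select_housekeepers()]).
#' @param excl_frac background exclusion fraction.
#' @param ... passed to [sample_qc()].
#' @return A `normalized_matrix` with extra elements `qc` (the
#'   [sample_qc()] report) and `genorm` (the [select_housekeepers()] result).
#' @export
qc_normalize <- function(counts, ann = NULL, target_n_hk = NULL, max_M = 0.5,
                         excl_frac = 0.8, ...) {
  qc <- sample_qc(counts, ann, ...)
  keep <- qc$sample[qc$pass]
  counts_qc <- count_matrix(counts$counts[, keep, drop = FALSE], counts$probe_class)
  gn <- select_housekeepers(counts_qc, target_n = target_n_hk, max_M = max_M)
  b <- background_thresholds(counts_qc)
  retained <- filter_low_expressed(counts_qc, b, excl_frac)
  retained <- union(retained, gn$selected)  # references kept for normalization
  norm <- normalize_counts(counts_qc, gn$selected, retained, b)
  norm$qc <- qc
  norm$genorm <- gn
  norm
}
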