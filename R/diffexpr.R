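#' Per-gene negative-binomial group fit
#'
#' NB regression with log link on raw counts: linear predictor
#' `intercept + beta * I[test group] + offset`. The dispersion is estimated
#' per gene by maximum likelihood. The group effect is tested with a Wald
#' test against a t reference with `n - 2` degrees of freedom (the normal
#' reference is anti-conservative at cohort sizes of a dozen samples per
#' group) and reported in log2 units (natural-log coefficient divided by
#' ln 2).
#'
#' @param y per-sample raw counts for one gene.
#' @param group logical or 0/1 indicator of the test group.
#' @param offset_log per-sample log (natural) offset, e.g. `-log(f_s)` for
#'   normalization factors `f_s` (so the model sees lane-scaled means).
#' @param maxit iteration cap (default 100).
#' @param epsilon relative convergence tolerance on deviance (default 1e-8).
#' @return List: `beta` (log2), `se` (log2), `p`, `converged`, `theta`
#'   (NB size; `1/theta` is the dispersion). On fit failure `beta`, `se`, `p`
#'   are `NA` and `converged` is `FALSE`, signalling the log-linear fallback.
#' @export
fit_gene_nb <- function(y, group, offset_log = 0, maxit = 100L, epsilon = 1e-8) {
  group <- as.numeric(group)
  if (length(unique(group)) != 2L) stopf("group must have exactly two levels")
  if (min(table(group)) < 2L) stopf("both groups need at least 2 samples")
  if (length(offset_log) == 1L) offset_log <- rep(offset_log, length(y))
  if (all(y[group == 0] == 0) || all(y[group == 1] == 0))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE, theta = NA_real_))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(
      y ~ group + offset(offset_log),
      control = stats::glm.control(maxit = maxit, epsilon = epsilon))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$theta) || anyNA(coef(fit)))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE, theta = NA_real_))
  cf <- stats::coef(summary(fit))["group", ]
  list(beta = unname(cf["Estimate"]) / log(2),
       se = unname(cf["Std. Error"]) / log(2),
       p = 2 * stats::pt(-abs(cf["Estimate"] / cf["Std. Error"]),
                         df = length(y) - 2L),
       converged = isTRUE(fit$converged),
       theta = fit$theta)
}

#' Per-gene log-linear (two-sample) fit on log2 expression
#'
#' Pooled-variance two-sample comparison of log2 normalized values; the
#' effect is the difference of group means (test minus reference) in log2
#' units, tested with a pooled t-test. Used as the fallback model when the NB
#' fit does not converge.
#'
#' @param log2_vals per-sample log2 normalized expression for one gene.
#' @param group logical or 0/1 indicator of the test group.
#' @return List: `beta`, `se`, `p`.
#' @export
fit_gene_loglinear <- function(log2_vals, group) {
  group <- as.numeric(group)
  if (min(table(group)) < 2L) stopf("both groups need at least 2 samples")
  x1 <- log2_vals[group == 1]; x0 <- log2_vals[group == 0]
  n1 <- length(x1); n0 <- length(x0)
  beta <- mean(x1) - mean(x0)
  s2 <- (sum((x1 - mean(x1))^2) + sum((x0 - mean(x0))^2)) / (n1 + n0 - 2)
  se <- sqrt(s2 * (1 / n1 + 1 / n0))
  if (se == 0) {
    p <- if (beta == 0) 1 else .Machine$double.xmin
  } else {
    p <- 2 * stats::pt(-abs(beta / se), df = n1 + n0 - 2)
  }
  list(beta = beta, se = se, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `adj_(i) = min_(j>=i) (p_(j) * m / j)` capped at 1, mapped back to the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression for one contrast
#'
#' For every retained endogenous gene: NB fit on raw counts with the
#' normalization offset; on non-convergence, log-linear fallback on the
#' normalized log2 values (the model used is recorded per gene). P-values are
#' BH-adjusted across all tested genes of the contrast. The linear fold of
#' change (FOC) is signed: `sign(beta) * 2^|beta|`, so FOC = +1 at beta = 0
#' and negative FOC encodes down-regulation.
#'
#' @param norm a `normalized_matrix` (see [normalize_counts()]).
#' @param counts the raw [count_matrix] (same samples).
#' @param ann annotation `data.frame`.
#' @param contrast length-2 character: `c(test, reference)` group labels,
#'   e.g. `c("eoPE", "healthy")`.
#' @return A `data.frame` of class `de_result` with columns `gene`, `log2fc`,
#'   `foc`, `se`, `p`, `adj_p`, `model`, `converged`, plus attributes
#'   `contrast` and `n_samples`.
#' @export
run_de <- function(norm, counts, ann, contrast) {
  stopifnot(length(contrast) == 2L, contrast[1] != contrast[2])
  miss <- setdiff(contrast, ann$group)
  if (length(miss)) stopf("contrast group '%s' absent from annotations", miss[1L])
  samples <- colnames(norm$log2)
  grp_all <- ann$group[match(samples, ann$sample)]
  use <- samples[grp_all %in% contrast]
  grp <- as.numeric(grp_all[grp_all %in% contrast] == contrast[1])
  if (min(table(grp)) < 2L) stopf("both contrast groups need at least 2 samples")

  genes <- intersect(norm$retained, genes_of_class(counts, "endogenous"))
  off <- -log(norm$factors[use])
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    y <- counts$counts[g, use]
    nb <- fit_gene_nb(y, grp, off)
    if (nb$converged) {
      row <- data.frame(gene = g, log2fc = nb$beta, se = nb$se, p = nb$p,
                        model = "nb", converged = TRUE)
    } else {
      ll <- fit_gene_loglinear(norm$log2[g, use], grp)
      row <- data.frame(gene = g, log2fc = ll$beta, se = ll$se, p = ll$p,
                        model = "loglinear", converged = FALSE)
    }
    res[[i]] <- row
  }
  de <- do.call(rbind, res)
  de$adj_p <- adjust_bh(de$p)
  de$foc <- foc_from_log2fc(de$log2fc)
  de <- de[, c("gene", "log2fc", "foc", "se", "p", "adj_p", "model", "converged")]
  rownames(de) <- NULL
  attr(de, "contrast") <- contrast
  attr(de, "n_samples") <- table(factor(grp, 0:1, labels = rev(contrast)))
  class(de) <- c("de_result", "data.frame")
  de
}

# signed linear fold of change: +-2^|log2fc|, +1 at 0
foc_from_log2fc <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  if (is.null(ct)) {  # subset without attributes: plain table
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat(sprintf("de_result: %s vs %s, %d genes tested (%d by NB, %d log-linear fallback)\n",
              ct[1], ct[2], nrow(x), sum(x$model == "nb"),
              sum(x$model == "loglinear")))
  calls <- call_degs(x)
  cat(sprintf("  DEGs at adj-p < 0.05 & |FOC| > 1.5: %d down, %d up\n",
              length(calls$down), length(calls$up)))
  invisible(x)
}

#' Call differentially expressed genes
#'
#' A gene is called when its BH-adjusted p-value is strictly below `alpha`
#' and its signed linear fold change is strictly beyond `foc_min` in either
#' direction (`foc > foc_min` up, `foc < -foc_min` down). Lists are sorted by
#' adjusted p, then by decreasing |FOC|.
#'
#' @param de a `de_result` from [run_de()] (or any data.frame with `gene`,
#'   `foc`, `adj_p`).
#' @param alpha significance cutoff on the adjusted p (default 0.05).
#' @param foc_min linear fold-change cutoff (default 1.5).
#' @return List with character vectors `down` and `up`.
#' @export
call_degs <- function(de, alpha = 0.05, foc_min = 1.5) {
  ord <- order(de$adj_p, -abs(de$foc))
  de <- de[ord, , drop = FALSE]
  list(down = de$gene[de$adj_p < alpha & de$foc < -foc_min],
       up = de$gene[de$adj_p < alpha & de$foc > foc_min])
}
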