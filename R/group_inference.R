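#' Cell densities from an IHC field-count table
#'
#' Per slide, region and stain category, the density is the sum of field
#' counts divided by the sum of field areas (cells/mm^2). Decidual rows are
#' simply absent for slides without decidua. For the villous CD68/CD163
#' duplex stain, double-positive cells (CD68+CD163+) are by definition M2
#' macrophages and CD68+CD163- cells M1 macrophages.
#'
#' @param ihc IHC `data.frame` (see [read_ihc()]).
#' @return `data.frame` with columns `slide`, `group`, `region`, `category`,
#'   `density`.
#' @export
ihc_density <- function(ihc) {
  ihc <- validate_ihc(ihc)
  key <- interaction(ihc$slide, ihc$region, ihc$category, drop = TRUE)
  agg <- lapply(split(ihc, key), function(d) {
    if (sum(d$area_mm2) <= 0) stopf("zero total area for slide %s", d$slide[1L])
    data.frame(slide = d$slide[1L], group = d$group[1L], region = d$region[1L],
               category = d$category[1L],
               density = sum(d$count) / sum(d$area_mm2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$slide, out$region, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on k-1 degrees
#' of freedom. The degenerate all-identical case returns H = 0, p = 1.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) == 0L)) stopf("empty group")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Rank-based pairwise post-hoc tests after Kruskal-Wallis
#'
#' Dunn's test: pairwise z statistics on the pooled-rank means with tie
#' correction, Bonferroni-adjusted over the pairs. Nemenyi: the same rank
#' statistics referred to the studentized-range distribution (the rank
#' analogue of Tukey's multiple comparisons).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @param method `"dunn"` (Bonferroni) or `"nemenyi"` (studentized range).
#' @return `data.frame`: `group1`, `group2`, `z`, `p`, `adj_p`.
#' @export
posthoc_pairwise <- function(values, groups, method = c("dunn", "nemenyi")) {
  method <- match.arg(method)
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stopf("need at least 2 groups")
  n_i <- table(groups)
  if (any(n_i == 0L)) stopf("empty group")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(s2 * (1 / n_i[[i]] + 1 / n_i[[j]]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    p <- if (method == "dunn") 2 * stats::pnorm(-abs(z))
         else stats::ptukey(abs(z) * sqrt(2), nmeans = k, df = Inf,
                            lower.tail = FALSE)
    data.frame(group1 = i, group2 = j, z = z, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- if (method == "dunn") pmin(1, out$p * nrow(out)) else out$p
  rownames(out) <- NULL
  out
}

#' Omnibus + post-hoc group comparison of one variable
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param posthoc post-hoc method, see [posthoc_pairwise()].
#' @return List of class `group_test`: `kw` (see [kruskal_wallis()]),
#'   `pairwise` (see [posthoc_pairwise()]), `posthoc` (method name).
#' @export
group_test <- function(values, groups, posthoc = c("dunn", "nemenyi")) {
  posthoc <- match.arg(posthoc)
  structure(list(kw = kruskal_wallis(values, groups),
                 pairwise = posthoc_pairwise(values, groups, posthoc),
                 posthoc = posthoc),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g (post-hoc: %s)\n",
              x$kw$H, x$kw$df, x$kw$p, x$posthoc))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Contingency-table test for categorical clinical variables
#'
#' Pearson chi-square without continuity correction for r x c tables. A 2 x 2
#' table with any expected count below 5 switches to Fisher's exact test (the
#' switch is recorded in `method`).
#'
#' @param tab matrix of non-negative counts, at least 2 x 2.
#' @return List: `statistic` (X^2, `NA` for Fisher), `df`, `p`, `method`.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stopf("table must be at least 2 x 2")
  if (any(tab < 0)) stopf("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("zero row or column margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == 2L) && any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, df = NA_integer_, p = ft$p.value,
                method = "fisher"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, method = "chisq")
}
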