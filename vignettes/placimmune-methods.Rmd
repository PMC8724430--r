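---
title: "Methods: models, parameters and design choices in placimmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in placimmune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placimmune)
```

`placimmune` analyses targeted immune expression panels measured on
barcode-counting platforms (NanoString nCounter), built around the placental
preeclampsia use case: small cohorts (order 10–15 placentas per group), a
fixed panel of ~730 immune genes plus ~40 candidate housekeeping genes and
spike-in control probes, and three kinds of downstream readout —
differentially expressed genes, marker-based immune cell-type scores, and
pathway scores — compared across clinical groups with nonparametric tests.
This vignette documents the statistical model behind each stage, the
parameters a user may want to move, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## Quality control and normalization

**Sample QC.** A lane is excluded when (i) its binding density, if supplied
as an annotation column, falls below `binding_density_min` (default 0.2 —
failed lanes in practice sit far below the ~0.7+ of good lanes, so the
exact value is uncritical); or (ii) its positive-control geometric mean or
housekeeping-count sum falls below `control_frac` (default 0.25) times the
cohort median of that statistic. The control-count rule has no canonical
constant; 0.25× the cohort median separates catastrophic lanes from ordinary
lane-to-lane scatter (which is well within 2×) while staying insensitive to
cohort composition. Both constants are arguments of `sample_qc()` and every
failure records its reasons.

**geNorm.** Reference genes are selected by expression stability:
`genorm_stability()` computes, for candidate $j$,
$M_j = \frac{1}{n-1}\sum_{k \neq j} \mathrm{SD}_s(\log_2 x_{js} - \log_2 x_{ks})$
with the $n-1$ SD denominator. Because only log-ratios enter, $M$ is exactly
invariant to per-sample scaling — the property that makes it usable before
normalization. `select_housekeepers()` iteratively removes the highest-$M$
gene, recomputing $M$ each round, until either `target_n` genes remain or
all $M \le$ `max_M` (default 0.5, the conventional geNorm cutoff for
heterogeneous tissue such as placenta). Ties on $M$ are broken by removing
the higher-variance gene, then lexicographically; selection never goes below
3 genes ($M$ is not meaningful there), flagging `floor_reached` instead. The
pairwise-variation trace $V_{k/k+1}$ (SD of the change in the log-scale
normalization signal when the $(k{+}1)$-th most stable gene is added) is
reported for diagnostics but does not drive the stop rule.

**Background and filtering.** The detection threshold of sample $s$ is
$b_s = 2 \times \mathrm{mean}$(negative-control counts in $s$) — per sample,
not global, since background tracks the lane. A gene is excluded when its
count is below $b_s$ in strictly more than `excl_frac` (default 0.8) of
samples: below threshold in 5 of 6 samples (0.833) excludes, in 4 of 5
(0.80) does not. Control probes are never filtered, and selected reference
genes are always kept so normalization stays defined.

**Normalization.** With $g_s$ the geometric mean of the selected reference
genes in sample $s$ (counts floored at 0.5 so zeros cannot annihilate the
product), the factor is $f_s = \mathrm{geomean}_s(g)/g_s$, which makes
$\mathrm{geomean}(f_s) = 1$ by construction; normalized counts are
$x f_s$ and reported expression is $\log_2(x f_s + 0.5)$. The 0.5
pseudocount keeps values finite and is half the smallest nonzero count, the
usual convention for count data. Re-normalizing already normalized counts
returns factors of 1. Positive-control (spike-in curve) normalization is
deliberately not a separate scaling step: the content factors absorb lane
scale, and stacking both would double-correct.

## Differential expression

Counts for gene $g$ are modelled as negative binomial with
$\mathrm{Var} = \mu + \phi\mu^2$ ($\phi \to 0$ recovers Poisson), log link,
linear predictor $\beta_0 + \beta\,\mathbb{1}[\text{test group}] +
\log(1/f_s)$. Fitting raw counts with the normalization offset (rather than
normalized counts directly) keeps the count likelihood honest; $\phi$ is
estimated per gene by maximum likelihood. The group effect is reported in
log₂ units ($\hat\beta/\ln 2$) and tested by a Wald test referred to a $t$
distribution with $n-2$ degrees of freedom: with a dozen samples per group
and a per-gene estimated dispersion, the normal reference is visibly
anti-conservative in the far tail that Benjamini–Hochberg acts on, and the
$t$ reference restores type-I control (the package's null-simulation tests
check exactly this). Non-convergence — degenerate counts, infinite
dispersion paths, or hitting the iteration cap (100 iterations, relative
deviance tolerance 1e-8) — triggers a recorded fallback to a pooled-variance
two-sample comparison of the log₂ normalized values (`fit_gene_loglinear()`),
whose estimate is the difference of group means in log₂ units. A mixture-NB
middle rung is not implemented: its specification in the originating
software is unpublished, and a convergence-based two-rung ladder with the
model recorded per gene preserves the intent.

P-values are BH-adjusted per contrast. DEG calls use strict cutoffs:
adjusted $p <$ `alpha` (0.05) and signed linear fold of change
$\mathrm{FOC} = \mathrm{sign}(\hat\beta)\,2^{|\hat\beta|}$ beyond ±`foc_min`
(1.5); FOC is +1 at $\hat\beta = 0$ and negative values encode
down-regulation.

## Cell-type and pathway scores

A cell-type score is the arithmetic mean of the marker genes' log₂
expression per sample — a *relative* abundance proxy, comparable across
samples but not across cell types (no per-gene centering, so highly
expressed markers weigh in at their natural scale). The method presumes the
markers move together because they come from the same cell population;
`marker_qc()` checks this directly, requiring the minimum pairwise Pearson
correlation of log₂ expression to reach `r_min` (default 0.6, inclusive).
Single-marker types (e.g. TPSAB1 for mast cells) pass by definition. Types
whose markers were all background-filtered are reported below detection
rather than scored.

Two pathway quantities exist because they answer different questions. The
per-contrast *global significance* score, $\sqrt{\mathrm{mean}_g(t_g^2)}$
over the pathway's tested genes, measures how much differential signal a
pathway carries regardless of direction. The *per-sample* score — PC1 of the
per-gene z-scored log₂ expression restricted to the pathway, centered at 0,
oriented so it rises with mean pathway expression (ties broken toward a
positive loading of the lexicographically first gene) — supports group
comparisons of individual samples, which a t-based formula cannot. Both are
exported and labelled; conflating them is a common source of confusion with
this platform's tooling.

Heatmap ordering uses Ward linkage (`ward.D2`) on Euclidean distances of
per-gene z-scored values ("scaled to the gene average"); zero-variance genes
z-score to zero vectors and merge at height 0.

## Group inference

Scores and IHC densities are compared with the tie-corrected Kruskal–Wallis
test (all-identical input returns $H=0$, $p=1$ rather than NaN). The
post-hoc is rank-based: Dunn's z statistics on pooled rank means with tie
correction, Bonferroni-adjusted (default), or Nemenyi's studentized-range
reference — the rank analogue of Tukey's multiple comparisons, included
because clinical software dialogs often label the rank post-hoc "Tukey".
Both are selectable; the choice is recorded in the result. Categorical
clinical tables use Pearson's chi-square without continuity correction, with
Fisher's exact test substituted (and recorded) for 2×2 tables with any
expected count below 5.

IHC densities are computed per slide, region and stain category as total
cells over total field area (cells/mm²); villous fields are 1 mm² by
convention, decidual field areas vary with decidual thickness, and slides
without decidua simply contribute no decidual rows (dropped pairwise per
region). The CD68/CD163 duplex convention is double-positive = M2,
CD68-single-positive = M1.

## The synthetic-data generator

`generate_counts()` draws
$y_{gs} \sim \mathrm{NB}\!\left(s_s\,\mu_g\,2^{\beta_g \mathbb{1}[\text{group}]}\,
2^{\lambda_{c(g),s}},\ \phi_g\right)$: per-gene baselines
$\log_2\mu_g \sim U(4,10)$ and dispersions $\phi_g \sim U(0.05, 0.3)$
(typical bulk-tissue biological variation); lane scale factors
$s_s = 2^{N(0,\,0.4)}$ (lane-to-lane scatter of roughly ±30 %); spiked group
effects $\beta_g$ from the config; and latent per-sample cell abundances
$\lambda_{c,s} \sim N(\text{group shift},\ 0.5)$ added on the log₂ scale to
all markers of cell type $c$ — the simplest mechanism that induces the
pairwise marker correlations the scoring method assumes. Marker genes use
their own baseline (log₂ mean 8 ± 0.5) and a small residual dispersion
(0.02): marker-based scoring presumes abundance dominates marker variance,
so the non-abundance residual must be modest — with these defaults the
implied marker-marker correlation is ~0.8, matching what usable signatures
show in practice. Housekeeping genes carry the lane factor but no group or
latent term ($\phi = 0.005$); by default 7/40 of them receive extra
independent log₂-normal noise (SD 0.6) to emulate unstable reference
candidates for geNorm to find. Negative controls are Poisson with mean 4;
positive controls follow a 6-step 4-fold geometric ladder scaled by the lane
factor with 1 % log-normal noise. Default cohort sizes are 13/13/6
(healthy/eoPE/loPE). One integer seed drives everything through
deterministically derived per-component sub-streams, so output is
bit-for-bit reproducible and stable under unrelated config edits.
`generate_ihc()` draws field counts as NB(density × area) with three 1-mm²
villous and three variable-area decidual fields per slide, and a
configurable number of slides per group lacking decidua.

What the generator does *not* emulate: probe cross-hybridization, RCC lane
metadata beyond a binding-density column, batch/hybridization-date effects,
count saturation, compositional coupling between cell types, and any claim
about the real effect-size distribution of preeclampsia genes (spike sizes
are config choices). Passing parameter-recovery tests therefore demonstrates
the pipeline's correctness under its own model assumptions, not performance
on real placental data.

## Problem sizes used by the test suite

The parameter-recovery tests use 100 replicates of 200-gene cohorts
(20 genes spiked at |log₂FC| = 1.5, 13 vs 13 samples, $\phi = 0.2$), 100
replicates of small marker-structure cohorts (32 samples), 30 null 100-gene
cohorts for DEG-call calibration, and 1 000 Kruskal–Wallis null replicates
at the 13/13/6 group sizes — sizes chosen so each Monte-Carlo bound is
tested at 3 standard errors while the full suite completes in a couple of
minutes. `scripts/acceptance.R` runs one full-size cohort (730 endogenous /
40 housekeeping genes, 35 lanes of which 3 fail QC, 48 spiked genes, a
49-slide IHC cohort) and reports every headline quantity it computes.

## Known limitations

* The NB dispersion is estimated per gene with no information sharing;
  with very small groups the log-linear fallback may engage more often.
  Empirical-Bayes shrinkage is deliberately out of scope.
* geNorm's stop rule in the originating software is undocumented; both
  `max_M` and `target_n` are exposed, and fixed-size selections should use
  `target_n`.
* Cell scores are relative; they cannot be compared across cell types or
  interpreted as fractions.
* Binary RCC parsing, GEO retrieval, and web-service enrichment (DAVID) are
  out of scope; inputs are plain TSV.
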