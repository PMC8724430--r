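#' Simulation configuration for synthetic panel data
#'
#' Defines a synthetic cohort with the statistical structure a targeted-panel
#' immune analysis assumes: negative-binomially distributed endogenous counts
#' with gene-specific mean and dispersion, low-variance housekeeping genes (a
#' configurable subset destabilized by extra independent noise), a
#' near-deterministic positive-control ladder, Poisson negative-control
#' background, multiplicative per-sample lane scale factors, spiked group
#' log2 fold changes, and latent per-sample cell-type abundances that induce
#' correlated marker genes.
#'
#' The NB parameterization is mean `mu` and dispersion `phi` with variance
#' `mu + phi * mu^2`; `phi = 0` recovers the Poisson.
#'
#' @param n_endogenous,n_housekeeping,n_positive,n_negative probe counts per
#'   class. Defaults mirror a PanCancer-immune-style panel: 730 endogenous
#'   genes, 40 candidate housekeepers, 6 positive and 8 negative controls.
#' @param samples_per_group named integer vector, samples per group. Default
#'   `c(healthy = 13, eoPE = 13, loPE = 6)`, the study cohort sizes.
#' @param log2_mean_range range of baseline log2 mean counts for endogenous
#'   genes (uniform draw per gene).
#' @param dispersion_range range of NB dispersion `phi` for endogenous genes.
#' @param hk_log2_mean_range baseline log2 mean range for housekeeping genes.
#' @param hk_dispersion NB dispersion of stable housekeeping genes.
#' @param n_destabilized_hk number of housekeeping candidates given extra
#'   independent per-sample log2-normal noise (mimics unstable reference
#'   genes; the study retained 33 of 40 candidates). The default, `NULL`,
#'   destabilizes the same proportion as that panel (7 of 40), leaving at
#'   least three stable candidates.
#' @param hk_destab_sd log2 SD of that extra noise.
#' @param scale_log2_sd SD of per-sample lane scale factors on the log2 scale.
#' @param neg_mean Poisson mean of negative-control background counts.
#' @param pos_ladder positive-control geometric ladder (top count and 4-fold
#'   steps, 1 percent log-normal noise).
#' @param de_spikes `NULL` or a `data.frame` with columns `gene`, `group`,
#'   `log2fc`: gene `gene` has its mean multiplied by `2^log2fc` in samples of
#'   `group`. Spiked genes must be endogenous.
#' @param cell_types `NULL` or a named list; each element is a list with
#'   `markers` (character), `log2_sd` (SD of the latent abundance on log2
#'   scale) and optional `shift` (named vector of group-wise mean abundance
#'   shifts in log2 units). See [default_cell_types()].
#' @param marker_log2_mean,marker_dispersion baseline log2 mean and residual
#'   NB dispersion for marker genes. The residual dispersion is deliberately
#'   small: marker-score methods presume the latent cell abundance dominates
#'   marker-gene variance.
#' @param seed integer seed; fixes the full output bit-for-bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_endogenous = 730L, n_housekeeping = 40L,
                       n_positive = 6L, n_negative = 8L,
                       samples_per_group = c(healthy = 13L, eoPE = 13L, loPE = 6L),
                       log2_mean_range = c(4, 10),
                       dispersion_range = c(0.05, 0.3),
                       hk_log2_mean_range = c(6, 10),
                       hk_dispersion = 0.005,
                       n_destabilized_hk = NULL,
                       hk_destab_sd = 0.6,
                       scale_log2_sd = 0.4,
                       neg_mean = 4,
                       pos_ladder = 32768 / 4^(0:5),
                       de_spikes = NULL,
                       cell_types = NULL,
                       marker_log2_mean = 8,
                       marker_dispersion = 0.02,
                       seed = 1L) {
  cfg <- list(n_endogenous = as.integer(n_endogenous),
              n_housekeeping = as.integer(n_housekeeping),
              n_positive = as.integer(n_positive),
              n_negative = as.integer(n_negative),
              samples_per_group = samples_per_group,
              log2_mean_range = log2_mean_range,
              dispersion_range = dispersion_range,
              hk_log2_mean_range = hk_log2_mean_range,
              hk_dispersion = hk_dispersion,
              n_destabilized_hk = as.integer(
                n_destabilized_hk %||%
                  min(round(7 / 40 * as.integer(n_housekeeping)),
                      max(0L, as.integer(n_housekeeping) - 3L))),
              hk_destab_sd = hk_destab_sd,
              scale_log2_sd = scale_log2_sd,
              neg_mean = neg_mean,
              pos_ladder = pos_ladder,
              de_spikes = de_spikes,
              cell_types = cell_types,
              marker_log2_mean = marker_log2_mean,
              marker_dispersion = marker_dispersion,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_endogenous >= 0, cfg$n_housekeeping >= 0,
            cfg$n_positive >= 0, cfg$n_negative >= 0)
  if (is.null(names(cfg$samples_per_group)) ||
      any(!nzchar(names(cfg$samples_per_group))))
    stopf("samples_per_group must be a named vector of group sizes")
  if (any(cfg$samples_per_group < 0)) stopf("negative group size")
  if (any(cfg$dispersion_range < 0) || cfg$hk_dispersion < 0 ||
      cfg$marker_dispersion < 0)
    stopf("dispersions must be non-negative")
  if (cfg$n_destabilized_hk > cfg$n_housekeeping)
    stopf("n_destabilized_hk exceeds n_housekeeping")
  if (!is.null(cfg$de_spikes)) {
    need <- c("gene", "group", "log2fc")
    if (!all(need %in% colnames(cfg$de_spikes)))
      stopf("de_spikes needs columns gene, group, log2fc")
    bad <- setdiff(cfg$de_spikes$group, names(cfg$samples_per_group))
    if (length(bad)) stopf("de_spikes group '%s' not in samples_per_group", bad[1L])
  }
  cfg
}

#' Default latent cell-type structure mirroring the study's headline findings
#'
#' M2 macrophages (Hofbauer cells) and mast cells shifted down in eoPE, M1
#' macrophages unshifted, B cells up in loPE.
#'
#' @param log2_sd latent abundance SD (log2) shared by all four types.
#' @return Named list suitable for the `cell_types` argument of [sim_config()].
#' @export
default_cell_types <- function(log2_sd = 0.5) {
  list(
    M2   = list(markers = c("CD163", "MRC1", "C1QA", "C1QB"),
                log2_sd = log2_sd, shift = c(eoPE = -1)),
    M1   = list(markers = c("CD86", "MSR1"), log2_sd = log2_sd),
    mast = list(markers = "TPSAB1", log2_sd = log2_sd, shift = c(eoPE = -1)),
    B    = list(markers = "CD19", log2_sd = log2_sd, shift = c(loPE = 0.5))
  )
}

# NB draw in the (mu, phi) parameterization; phi = 0 -> Poisson
rnb <- function(n, mu, phi) {
  if (length(phi) == 1L) phi <- rep(phi, length(mu))
  out <- numeric(length(mu))
  pois <- phi <= 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                               size = 1 / phi[!pois])
  out
}

#' Generate a synthetic count matrix with annotations and ground truth
#'
#' Endogenous counts are drawn as
#' `NB(mean = s_s * mu_g * 2^(beta_g I\[group\]) * 2^(lambda_cs I\[marker\]),
#' dispersion phi_g)` where `s_s` is the lane scale factor, `beta_g` the
#' spiked group log2 fold change and `lambda_cs` the latent abundance of the
#' cell type the marker belongs to. Housekeeping genes carry no group effect
#' and no latent term; negative controls are Poisson background (no lane
#' effect); positive controls follow the configured geometric ladder scaled
#' by the lane factor with 1 percent log-normal noise.
#'
#' @param cfg a [sim_config()].
#' @return List with `counts` (a [count_matrix]), `ann` (annotation
#'   `data.frame`) and `truth` (list: `de` data.frame of spiked genes,
#'   `scale_factors` named per-sample lane factors, `abundances` sample x
#'   cell-type latent log2 abundance matrix).
#' @export
generate_counts <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  seeds <- derive_seeds(cfg$seed, c("genes", "samples", "latent", "counts"))

  marker_genes <- character()
  if (!is.null(cfg$cell_types)) {
    marker_genes <- unique(unlist(lapply(cfg$cell_types, `[[`, "markers")))
    if (length(marker_genes) > cfg$n_endogenous)
      stopf("more marker genes than endogenous genes")
  }
  n_plain <- cfg$n_endogenous - length(marker_genes)
  endo <- c(marker_genes,
            sprintf("GENE%04d", seq_len(n_plain)))
  hk  <- sprintf("HK%02d",  seq_len(cfg$n_housekeeping))
  pos <- sprintf("POS%d", seq_len(cfg$n_positive))
  neg <- sprintf("NEG%d", seq_len(cfg$n_negative))
  genes <- c(endo, hk, pos, neg)
  probe_class <- rep(PROBE_CLASSES, c(length(endo), length(hk),
                                      length(pos), length(neg)))
  names(probe_class) <- genes

  if (!is.null(cfg$de_spikes)) {
    orphan <- setdiff(cfg$de_spikes$gene, endo)
    if (length(orphan)) stopf("spiked gene '%s' is not an endogenous gene", orphan[1L])
  }
  if (!is.null(cfg$cell_types)) {
    orphan <- setdiff(marker_genes, endo)
    if (length(orphan)) stopf("marker gene '%s' absent from gene list", orphan[1L])
  }

  # per-gene baselines
  set.seed(seeds[["genes"]])
  mu <- numeric(length(genes)); names(mu) <- genes
  phi <- numeric(length(genes)); names(phi) <- genes
  mu[endo]  <- 2^stats::runif(length(endo), cfg$log2_mean_range[1], cfg$log2_mean_range[2])
  phi[endo] <- stats::runif(length(endo), cfg$dispersion_range[1], cfg$dispersion_range[2])
  if (length(marker_genes)) {
    mu[marker_genes] <- 2^stats::runif(length(marker_genes),
                                       cfg$marker_log2_mean - 0.5,
                                       cfg$marker_log2_mean + 0.5)
    phi[marker_genes] <- cfg$marker_dispersion
  }
  if (length(hk)) {
    mu[hk]  <- 2^stats::runif(length(hk), cfg$hk_log2_mean_range[1], cfg$hk_log2_mean_range[2])
    phi[hk] <- cfg$hk_dispersion
  }
  destab <- if (cfg$n_destabilized_hk > 0) hk[seq_len(cfg$n_destabilized_hk)] else character()

  # samples and lane scale factors
  set.seed(seeds[["samples"]])
  groups <- rep(names(cfg$samples_per_group), cfg$samples_per_group)
  samples <- sprintf("S%02d", seq_along(groups))
  ann <- data.frame(sample = samples, group = groups, stringsAsFactors = FALSE)
  s <- 2^stats::rnorm(length(samples), 0, cfg$scale_log2_sd)
  names(s) <- samples

  # latent cell abundances (log2), per sample x cell type
  set.seed(seeds[["latent"]])
  abund <- NULL
  if (!is.null(cfg$cell_types)) {
    abund <- matrix(0, length(samples), length(cfg$cell_types),
                    dimnames = list(samples, names(cfg$cell_types)))
    for (ct in names(cfg$cell_types)) {
      spec <- cfg$cell_types[[ct]]
      shift <- rep(0, length(samples))
      if (!is.null(spec$shift)) {
        for (g in names(spec$shift)) shift[groups == g] <- spec$shift[[g]]
      }
      abund[, ct] <- stats::rnorm(length(samples), shift, spec$log2_sd %||% 0.5)
    }
  }

  # spike matrix of log2 effects (genes x samples)
  beta <- matrix(0, length(genes), length(samples), dimnames = list(genes, samples))
  if (!is.null(cfg$de_spikes)) {
    for (i in seq_len(nrow(cfg$de_spikes))) {
      sp <- cfg$de_spikes[i, ]
      beta[sp$gene, groups == sp$group] <- beta[sp$gene, groups == sp$group] + sp$log2fc
    }
  }
  if (!is.null(abund)) {
    for (ct in names(cfg$cell_types)) {
      mk <- cfg$cell_types[[ct]]$markers
      beta[mk, ] <- beta[mk, , drop = FALSE] +
        matrix(abund[, ct], length(mk), length(samples), byrow = TRUE)
    }
  }
  if (length(destab)) {
    beta[destab, ] <- beta[destab, , drop = FALSE] +
      matrix(stats::rnorm(length(destab) * length(samples), 0, cfg$hk_destab_sd),
             length(destab), length(samples))
  }

  set.seed(seeds[["counts"]])
  cnt <- matrix(0, length(genes), length(samples), dimnames = list(genes, samples))
  core <- c(endo, hk)
  mean_mat <- outer(mu[core], s) * 2^beta[core, , drop = FALSE]
  for (j in seq_along(samples))
    cnt[core, j] <- rnb(length(core), mean_mat[, j], phi[core])
  if (length(pos)) {
    for (j in seq_along(samples))
      cnt[pos, j] <- round(cfg$pos_ladder[seq_along(pos)] * s[j] *
                             2^stats::rnorm(length(pos), 0, 0.0144))  # ~1% CV
  }
  if (length(neg)) {
    for (j in seq_along(samples))
      cnt[neg, j] <- stats::rpois(length(neg), cfg$neg_mean)
  }

  de_truth <- cfg$de_spikes %||%
    data.frame(gene = character(), group = character(), log2fc = numeric())
  list(counts = count_matrix(cnt, probe_class),
       ann = ann,
       truth = list(de = de_truth,
                    scale_factors = s,
                    abundances = abund,
                    destabilized_hk = destab))
}

#' Generate a synthetic immunohistochemistry field-count table
#'
#' Per slide: three villous fields of 1 mm^2 and three decidual fields with
#' variable area; per field and stain category, counts are NB with mean
#' `density * area`.
#'
#' @param n_slides named integer vector, slides per group (default the study's
#'   IHC cohort: 20 healthy, 19 eoPE, 10 loPE).
#' @param densities `data.frame` with columns `region`, `category`, `group`,
#'   `density` (cells/mm^2); missing group rows default to 0.
#' @param overdispersion NB dispersion of field counts (0 = Poisson).
#' @param decidua_area_range range of decidual field areas (mm^2).
#' @param missing_decidua named integer vector: number of slides per group
#'   without decidua (their decidual rows are absent, as in FFPE practice).
#' @param seed integer seed.
#' @return A validated IHC `data.frame` (see [read_ihc()]).
#' @export
generate_ihc <- function(n_slides = c(healthy = 20L, eoPE = 19L, loPE = 10L),
                         densities,
                         overdispersion = 0.2,
                         decidua_area_range = c(0.4, 1),
                         missing_decidua = c(healthy = 5L, eoPE = 9L, loPE = 5L),
                         seed = 1L) {
  if (any(densities$density < 0)) stopf("densities must be non-negative")
  set.seed(seed)
  rows <- list()
  for (g in names(n_slides)) {
    n_miss <- missing_decidua[[g]] %||% 0L
    for (i in seq_len(n_slides[[g]])) {
      slide <- sprintf("%s_%02d", g, i)
      has_dec <- i > n_miss
      for (region in c("villi", if (has_dec) "decidua")) {
        areas <- if (region == "villi") rep(1, 3) else
          stats::runif(3, decidua_area_range[1], decidua_area_range[2])
        cats <- unique(densities$category[densities$region == region])
        for (f in 1:3) {
          for (cat in cats) {
            d <- densities$density[densities$region == region &
                                   densities$category == cat &
                                   densities$group == g]
            d <- if (length(d)) d[1L] else 0
            cnt <- rnb(1L, d * areas[f], overdispersion)
            rows[[length(rows) + 1L]] <- data.frame(
              slide = slide, group = g, region = region, field = f,
              category = cat, count = cnt, area_mm2 = areas[f],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  validate_ihc(do.call(rbind, rows))
}

#' Default IHC densities mirroring the study's qualitative findings
#'
#' Villous M2 macrophages (CD68+CD163+) and mast cells (tryptase+) reduced in
#' eoPE; M1 macrophages (CD68+CD163-) unchanged.
#'
#' @return `data.frame` usable as the `densities` argument of [generate_ihc()].
#' @export
default_ihc_densities <- function() {
  expand <- function(region, category, healthy, eoPE, loPE)
    data.frame(region = region, category = category,
               group = c("healthy", "eoPE", "loPE"),
               density = c(healthy, eoPE, loPE), stringsAsFactors = FALSE)
  rbind(expand("villi",   "CD68+CD163+", 12, 6, 11),
        expand("villi",   "CD68+CD163-", 3, 3, 3),
        expand("villi",   "tryptase+",   2.5, 1, 2.2),
        expand("decidua", "CD68+CD163+", 25, 20, 24),
        expand("decidua", "CD68+CD163-", 8, 8, 8),
        expand("decidua", "tryptase+",   6, 5, 6))
}
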