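#' End-to-end pipeline run
#'
#' Orchestrates a full analysis from a single configuration: load (or
#' simulate) the inputs, sample QC + normalization, differential expression
#' per contrast, cell-type and pathway scores, group inference on the scores,
#' and (when an IHC table is supplied) IHC densities with group tests. Every
#' intermediate table is written to `out_dir` and a manifest summarizing the
#' run (config hash, seed, per-stage counts, QC exclusions, DEG counts, file
#' digests) is returned and written as `manifest.yaml`.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   * `counts`, `annotations`: input TSV paths, or `simulate`: a list of
#'     [sim_config()] arguments (one of the two is required);
#'   * `signatures`: signature TSV path (default: the packaged marker table);
#'   * `ihc`: optional IHC TSV path;
#'   * `contrasts`: list of `c(test, reference)` pairs (default
#'     `list(c("eoPE","healthy"), c("loPE","healthy"), c("loPE","eoPE"))`);
#'   * thresholds `alpha` (0.05), `foc_min` (1.5), `excl_frac` (0.8),
#'     `r_min` (0.6), `target_n_hk` (NULL), `max_M` (0.5),
#'     `posthoc` ("dunn");
#'   * `seed`: integer (default 1), the only entropy source of the run.
#' @param out_dir output directory, created if missing.
#' @return The manifest, invisibly, as a list of class `run_manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg_hash <- substr(digest_string(serialize_config(config)), 1, 12)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    if (!is.null(sim_args$cell_types) && identical(sim_args$cell_types, "default"))
      sim_args$cell_types <- default_cell_types()
    if (!is.null(sim_args$de_spikes))
      sim_args$de_spikes <- as.data.frame(sim_args$de_spikes)
    sim <- stage("simulate", generate_counts(do.call(sim_config, sim_args)))
    counts <- sim$counts; ann <- sim$ann
    write_count_matrix(counts, file.path(out_dir, "counts.tsv"))
    write_annotations(ann, file.path(out_dir, "annotations.tsv"))
    truth_df <- sim$truth$de
    utils::write.table(truth_df, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(config$counts) || is.null(config$annotations))
      stopf("config needs either 'simulate' or 'counts' + 'annotations'")
    counts <- stage("load_counts", read_count_matrix(config$counts))
    ann <- stage("load_annotations", read_annotations(config$annotations))
  }
  al <- stage("align", align_samples(counts, ann))
  counts <- al$counts; ann <- al$ann

  sig_path <- config$signatures %||%
    system.file("extdata", "default_signatures.tsv", package = "placimmune")
  sig <- stage("load_signatures", read_signatures(sig_path))

  # --- QC + normalization -------------------------------------------------
  norm <- stage("qc_normalize",
                qc_normalize(counts, ann,
                             target_n_hk = config$target_n_hk,
                             max_M = config$max_M %||% 0.5,
                             excl_frac = config$excl_frac %||% 0.8))
  ann_pass <- ann[ann$sample %in% colnames(norm$log2), , drop = FALSE]
  utils::write.table(norm$qc, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(norm$factors),
                                factor = unname(norm$factors)),
                     file.path(out_dir, "factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(norm$log2), norm$log2,
                                check.names = FALSE),
                     file.path(out_dir, "normalized.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(norm$genorm$M_initial),
                                M = unname(norm$genorm$M_initial),
                                selected = names(norm$genorm$M_initial) %in%
                                  norm$genorm$selected),
                     file.path(out_dir, "genorm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- differential expression --------------------------------------------
  contrasts <- config$contrasts %||%
    list(c("eoPE", "healthy"), c("loPE", "healthy"), c("loPE", "eoPE"))
  alpha <- config$alpha %||% 0.05
  foc_min <- config$foc_min %||% 1.5
  de_results <- list()
  deg_counts <- list()
  for (ct in contrasts) {
    miss <- setdiff(ct, ann_pass$group)
    if (length(miss)) stopf("contrast group '%s' absent", miss[1L])
    nm <- paste(ct, collapse = "_vs_")
    de <- stage(paste0("de_", nm), run_de(norm, counts, ann_pass, ct))
    calls <- call_degs(de, alpha, foc_min)
    de$call <- ifelse(de$gene %in% calls$up, "up",
                      ifelse(de$gene %in% calls$down, "down", "ns"))
    utils::write.table(de, file.path(out_dir, sprintf("de_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de_results[[nm]] <- de
    deg_counts[[nm]] <- list(down = length(calls$down), up = length(calls$up))
  }

  # --- signatures ---------------------------------------------------------
  cs <- stage("cell_scores", cell_scores(norm, sig, config$r_min %||% 0.6))
  utils::write.table(data.frame(sample = rownames(cs$scores), cs$scores,
                                check.names = FALSE),
                     file.path(out_dir, "cell_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cs$qc, file.path(out_dir, "cell_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pathways <- signature_gene_lists(sig, "pathway")
  if (length(pathways) && length(de_results)) {
    glob <- list()
    for (nm in names(de_results)) {
      de <- de_results[[nm]]
      t_stats <- stats::setNames(de$log2fc / de$se, de$gene)
      for (pw in names(pathways)) {
        sc <- tryCatch(pathway_global_score(t_stats, pathways[[pw]]),
                       error = function(e) NULL)
        if (!is.null(sc))
          glob[[length(glob) + 1L]] <- data.frame(
            contrast = nm, pathway = pw, score = sc$score,
            n_genes = sc$n_genes, stringsAsFactors = FALSE)
      }
    }
    if (length(glob))
      utils::write.table(do.call(rbind, glob),
                         file.path(out_dir, "pathway_global.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- group inference on scores ------------------------------------------
  grp <- ann_pass$group[match(rownames(cs$scores), ann_pass$sample)]
  posthoc <- config$posthoc %||% "dunn"
  score_tests <- list()
  if (length(unique(grp)) >= 2L) {
    for (ctype in colnames(cs$scores)) {
      v <- cs$scores[, ctype]
      if (anyNA(v)) next
      gt <- group_test(v, grp, posthoc)
      score_tests[[ctype]] <- data.frame(variable = ctype, H = gt$kw$H,
                                         df = gt$kw$df, p = gt$kw$p)
    }
    if (length(score_tests))
      utils::write.table(do.call(rbind, score_tests),
                         file.path(out_dir, "score_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- IHC ----------------------------------------------------------------
  ihc_summary <- NULL
  if (!is.null(config$ihc)) {
    ihc <- stage("load_ihc", read_ihc(config$ihc))
    dens <- stage("ihc_density", ihc_density(ihc))
    utils::write.table(dens, file.path(out_dir, "ihc_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ihc_summary <- nrow(dens)
  }

  # --- manifest -----------------------------------------------------------
  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("placimmune")),
    config_hash = cfg_hash,
    seed = seed,
    n_samples_in = nrow(ann),
    n_samples_pass_qc = sum(norm$qc$pass),
    qc_exclusions = norm$qc$reasons[!norm$qc$pass],
    n_housekeepers_selected = length(norm$genorm$selected),
    n_genes_retained = length(norm$retained),
    deg_counts = deg_counts,
    ihc_density_rows = ihc_summary,
    output_digests = as.list(tools::md5sum(files))
  )
  names(manifest$output_digests) <- basename(files)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("pipeline run (config %s, seed %d): %d/%d samples passed QC, %d genes retained\n",
              x$config_hash, x$seed, x$n_samples_pass_qc, x$n_samples_in,
              x$n_genes_retained))
  for (nm in names(x$deg_counts))
    cat(sprintf("  %s: %d down / %d up DEGs\n", nm,
                x$deg_counts[[nm]]$down, x$deg_counts[[nm]]$up))
  invisible(x)
}

serialize_config <- function(config) {
  paste(utils::capture.output(utils::str(config, list.len = 1e6,
                                         vec.len = 1e6, digits.d = 15)),
        collapse = "\n")
}

# tiny dependency-free polynomial string hash (config identity only)
digest_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
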