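# in-code fixtures shared across test files

toy_count_matrix <- function() {
  m <- matrix(c(10, 20,
                30, 40,
                2, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "NEGX"), c("s1", "s2")))
  count_matrix(m, c("endogenous", "housekeeping", "negative"))
}

# random small count matrix with all four probe classes
random_count_matrix <- function(n_endo = 6, n_hk = 4, n_samples = 5, seed = 1) {
  set.seed(seed)
  genes <- c(sprintf("G%02d", seq_len(n_endo)), sprintf("H%02d", seq_len(n_hk)),
             "POS1", "POS2", "NEG1", "NEG2")
  cls <- rep(c("endogenous", "housekeeping", "positive", "negative"),
             c(n_endo, n_hk, 2, 2))
  m <- matrix(rpois(length(genes) * n_samples, 50), length(genes), n_samples,
              dimnames = list(genes, sprintf("s%d", seq_len(n_samples))))
  count_matrix(m, cls)
}

toy_annotations <- function(samples = c("s1", "s2"),
                            groups = c("healthy", "eoPE")) {
  data.frame(sample = samples, group = groups, stringsAsFactors = FALSE)
}

# a cohort-sized simulation small enough for repeated fitting in tests
small_sim_cfg <- function(seed = 1, ...) {
  sim_config(n_endogenous = 40, n_housekeeping = 10, n_positive = 6,
             n_negative = 8,
             samples_per_group = c(healthy = 13, eoPE = 13),
             seed = seed, ...)
}

# write a data.frame (or count matrix) to a temp TSV and return the path
tmp_tsv <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}
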