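test_that("sample QC flags binding density and depressed control counts", {
  x <- random_count_matrix(n_samples = 6, seed = 2)
  ann <- data.frame(sample = colnames(x$counts), group = "healthy",
                    binding_density = c(0.15, rep(0.8, 5)))
  qc <- sample_qc(x, ann)
  expect_false(qc$pass[1])
  expect_match(qc$reasons[1], "binding_density")
  expect_true(all(qc$pass[-1]))

  # all samples identical -> all pass
  m <- matrix(50, 6, 4, dimnames = list(
    c("G1", "G2", "H1", "H2", "P1", "N1"), sprintf("s%d", 1:4)))
  x2 <- count_matrix(m, c("endogenous", "endogenous", "housekeeping",
                          "housekeeping", "positive", "negative"))
  expect_true(all(sample_qc(x2)$pass))

  # one sample with all control counts at 1% of the cohort: both rules fire
  m3 <- m; m3[, 4] <- c(50, 50, 0, 1, 1, 50)
  x3 <- count_matrix(m3, x2$probe_class)
  qc3 <- sample_qc(x3)
  expect_false(qc3$pass[4])
  expect_match(qc3$reasons[4], "positive_controls")
  expect_match(qc3$reasons[4], "housekeeping_counts")

  # an empty cohort is an error
  ann_bad <- data.frame(sample = sprintf("s%d", 1:4), group = "healthy",
                        binding_density = 0.05)
  expect_error(sample_qc(x2, ann_bad), "all samples fail")
})

test_that("geNorm M is zero for exactly proportional genes and matches a brute-force oracle", {
  # scalar multiples: all log-ratios constant across samples -> M = 0
  base <- c(10, 20, 40, 80, 160)
  lmat <- rbind(g1 = log2(base), g2 = log2(2 * base), g3 = log2(5 * base))
  expect_equal(unname(genorm_stability(lmat)), c(0, 0, 0))

  # brute-force double loop on a random 4 x 5 fixture
  set.seed(7)
  lmat2 <- matrix(rnorm(20, 8, 1), 4, 5,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  M <- genorm_stability(lmat2)
  M_brute <- numeric(4)
  for (j in 1:4) {
    acc <- c()
    for (k in 1:4) if (k != j) acc <- c(acc, sd(lmat2[j, ] - lmat2[k, ]))
    M_brute[j] <- mean(acc)
  }
  expect_equal(unname(M), M_brute)

  # per-sample shifts (multiplicative scaling of raw counts) cancel
  shift <- rnorm(5)
  expect_equal(genorm_stability(sweep(lmat2, 2, shift, `+`)), M)

  expect_error(genorm_stability(lmat2[1:2, ]), "3 candidate")
})

test_that("geNorm selection eliminates destabilized genes first", {
  set.seed(10)
  n_s <- 12
  lane <- rnorm(n_s, 0, 0.5)
  mk <- function(noise_sd) 2^(8 + lane + rnorm(n_s, 0, noise_sd))
  m <- rbind(HKA = mk(0.02), HKB = mk(0.02), HKC = mk(0.02), HKD = mk(0.02),
             HKE = mk(1.0))  # HKE destabilized
  m <- round(rbind(m, NEG1 = rpois(n_s, 4)))
  colnames(m) <- sprintf("s%02d", 1:n_s)
  x <- count_matrix(m, c(rep("housekeeping", 5), "negative"))
  res <- select_housekeepers(x, target_n = 4)
  expect_identical(res$eliminated, "HKE")
  expect_setequal(res$selected, c("HKA", "HKB", "HKC", "HKD"))

  # target_n = all candidates: nothing eliminated
  res2 <- select_housekeepers(x, target_n = 5)
  expect_length(res2$eliminated, 0)
  expect_setequal(res2$selected, c("HKA", "HKB", "HKC", "HKD", "HKE"))

  # elimination order is a permutation of the eliminated set; never below 3
  expect_warning(res3 <- select_housekeepers(x, target_n = 2), "3")
  expect_length(res3$selected, 3)
  expect_true(res3$floor_reached)
})

test_that("33-of-40 selection is recovered when 7 candidates are destabilized", {
  sim <- generate_counts(sim_config(n_endogenous = 5, n_housekeeping = 40,
                                    n_destabilized_hk = 7,
                                    samples_per_group = c(healthy = 13,
                                                          eoPE = 13, loPE = 6),
                                    seed = 4))
  res <- select_housekeepers(sim$counts, target_n = 33)
  expect_length(res$selected, 33)
  expect_setequal(res$eliminated, sim$truth$destabilized_hk)
})

test_that("background thresholds are twice the negative-control mean", {
  m <- rbind(G1 = c(5, 5), N1 = c(4, 0), N2 = c(6, 0), N3 = c(8, 0))
  colnames(m) <- c("s1", "s2")
  x <- count_matrix(m, c("endogenous", "negative", "negative", "negative"))
  b <- background_thresholds(x)
  expect_equal(unname(b), c(12, 0))

  # single negative probe value v -> 2v
  m2 <- rbind(G1 = c(5, 5), N1 = c(7, 3))
  colnames(m2) <- c("s1", "s2")
  b2 <- background_thresholds(count_matrix(m2, c("endogenous", "negative")))
  expect_equal(unname(b2), c(14, 6))

  expect_error(background_thresholds(
    count_matrix(m2[1, , drop = FALSE], "endogenous")), "negative-control")
})

test_that("the >80% exclusion rule is strict and matches brute force", {
  # gene below threshold in 5/6 samples (0.833 > 0.8): excluded
  m <- rbind(LOW = c(1, 1, 1, 1, 1, 50), HIGH = rep(50, 6), NEG = rep(5, 6))
  colnames(m) <- sprintf("s%d", 1:6)
  x <- count_matrix(m, c("endogenous", "endogenous", "negative"))
  b <- background_thresholds(x)  # 10 everywhere
  expect_identical(filter_low_expressed(x, b), "HIGH")

  # below threshold in 4/5 samples (0.8, not > 0.8): retained
  m2 <- rbind(EDGE = c(1, 1, 1, 1, 50), NEG = rep(5, 5))
  colnames(m2) <- sprintf("s%d", 1:5)
  x2 <- count_matrix(m2, c("endogenous", "negative"))
  expect_identical(filter_low_expressed(x2, background_thresholds(x2)), "EDGE")

  # random toy matrix vs brute-force counting
  set.seed(3)
  x3 <- random_count_matrix(n_endo = 10, n_hk = 3, n_samples = 7, seed = 3)
  x3$counts[1:5, 1:6] <- rpois(30, 3)  # push some genes to background
  b3 <- background_thresholds(x3)
  got <- filter_low_expressed(x3, b3, excl_frac = 0.5)
  core <- names(x3$probe_class)[x3$probe_class %in% c("endogenous", "housekeeping")]
  want <- core[vapply(core, function(g)
    !(sum(x3$counts[g, ] < b3) / 7 > 0.5), TRUE)]
  expect_identical(got, want)
})

test_that("normalization factors follow the geometric-mean definition", {
  m <- rbind(G1 = c(10, 20), H1 = c(40, 80), H2 = c(90, 180), NEG = c(4, 4))
  colnames(m) <- c("A", "B")
  x <- count_matrix(m, c("endogenous", "housekeeping", "housekeeping", "negative"))
  norm <- normalize_counts(x, c("H1", "H2"))
  # sample B = 2 x sample A: f = (sqrt(2), 1/sqrt(2)), normalized identical
  expect_equal(unname(norm$factors), c(sqrt(2), 1 / sqrt(2)))
  nrm <- sweep(x$counts[norm$retained, ], 2, norm$factors, `*`)
  expect_equal(nrm[, 1], nrm[, 2])
  expect_equal(geomean <- exp(mean(log(norm$factors))), 1, tolerance = 1e-9)

  # identical samples -> unit factors
  m2 <- m; m2[, 2] <- m2[, 1]; colnames(m2) <- c("A", "B")
  x2 <- count_matrix(m2, x$probe_class)
  expect_equal(unname(normalize_counts(x2, c("H1", "H2"))$factors), c(1, 1))

  # permutation equivariance
  x_perm <- count_matrix(x$counts[, c("B", "A")], x$probe_class)
  norm_perm <- normalize_counts(x_perm, c("H1", "H2"))
  expect_equal(norm_perm$factors[c("A", "B")], norm$factors[c("A", "B")])
})

test_that("renormalizing normalized counts yields unit factors", {
  x <- random_count_matrix(n_samples = 8, seed = 6)
  hk <- names(x$probe_class)[x$probe_class == "housekeeping"]
  norm <- normalize_counts(x, hk)
  renorm <- sweep(x$counts, 2, norm$factors, `*`)
  g_s <- apply(pmax(renorm[hk, ], 0.5), 2, function(v) exp(mean(log(v))))
  f2 <- exp(mean(log(g_s))) / g_s
  expect_equal(unname(f2), rep(1, 8), tolerance = 1e-9)
})

test_that("normalization recovers simulated lane scale factors", {
  sim <- generate_counts(sim_config(n_endogenous = 30, n_housekeeping = 12,
                                    samples_per_group = c(healthy = 8, eoPE = 8),
                                    seed = 8))
  norm <- qc_normalize(sim$counts, sim$ann)
  expect_gt(cor(log(norm$factors), -log(sim$truth$scale_factors)), 0.95)
})

test_that("qc_normalize keeps only passing samples and finite log2 values", {
  sim <- generate_counts(small_sim_cfg(seed = 12))
  ann <- sim$ann
  ann$binding_density <- c(0.1, rep(0.8, nrow(ann) - 1))  # fail first sample
  norm <- qc_normalize(sim$counts, ann)
  expect_false(ann$sample[1] %in% colnames(norm$log2))
  expect_equal(ncol(norm$log2), nrow(ann) - 1L)
  expect_true(all(is.finite(norm$log2)))
  expect_equal(exp(mean(log(norm$factors))), 1, tolerance = 1e-9)
})
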