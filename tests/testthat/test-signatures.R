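test_that("marker QC gates on the minimum pairwise correlation", {
  s <- seq_len(8)
  lmat <- rbind(A = s, B = s, C = rev(s))  # B identical to A, C anti-correlated
  colnames(lmat) <- paste0("x", s)
  qc <- marker_qc(lmat, list(good = c("A", "B"), bad = c("A", "C")))
  expect_true(qc$pass[qc$cell_type == "good"])
  expect_equal(qc$r_min[qc$cell_type == "good"], 1)
  expect_false(qc$pass[qc$cell_type == "bad"])
  expect_equal(qc$r_min[qc$cell_type == "bad"], -1)

  # single-marker types pass by definition
  qc1 <- marker_qc(lmat, list(mast = "A"))
  expect_true(qc1$pass)
  expect_true(is.na(qc1$r_min))

  # missing markers are dropped with a warning; all-missing fails
  expect_warning(qc2 <- marker_qc(lmat, list(m = c("A", "B", "ZZ"))), "ZZ")
  expect_equal(qc2$n_markers, 2L)
  qc3 <- suppressWarnings(marker_qc(lmat, list(gone = c("Y", "Z"))))
  expect_false(qc3$pass)
  expect_true(qc3$below_detection)

  # pass/fail invariant to per-sample shifts of the whole matrix
  shifted <- sweep(lmat, 2, rnorm(8), `+`)
  expect_equal(marker_qc(shifted, list(good = c("A", "B")))$r_min, 1)
})

test_that("cell scores are marker means of log2 expression", {
  lmat <- rbind(TPSAB1 = c(3.5, 4.0, 2.0), M_A = c(4, 4, 4), M_B = c(6, 8, 2))
  colnames(lmat) <- paste0("s", 1:3)
  # single-marker type: the score is that gene's value
  expect_equal(unname(cell_score(lmat, "TPSAB1")), c(3.5, 4.0, 2.0))
  # two markers (4, 6) -> 5
  expect_equal(unname(cell_score(lmat, c("M_A", "M_B"))), c(5, 6, 3))
  expect_error(cell_score(lmat, "ABSENT"), "no marker")

  # random fixture vs brute-force mean
  set.seed(9)
  lm2 <- matrix(rnorm(40, 8), 5, 8,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  markers <- c("g2", "g4", "g5")
  brute <- apply(lm2[markers, ], 2, mean)
  expect_equal(cell_score(lm2, markers), brute)

  # adding a constant to all markers shifts the score by that constant
  expect_equal(cell_score(lm2 + 1.7, markers), brute + 1.7)
})

test_that("simulated correlated signatures pass marker QC and independent ones fail", {
  pass_corr <- logical(40); fail_indep <- logical(40)
  for (r in 1:40) {
    cfg <- sim_config(
      n_endogenous = 8, n_housekeeping = 3, n_positive = 2, n_negative = 2,
      samples_per_group = c(healthy = 16, eoPE = 16),
      cell_types = list(M2 = list(markers = c("CD163", "MRC1", "C1QA", "C1QB"),
                                  log2_sd = 0.5)),
      seed = 1000 + r)
    sim <- generate_counts(cfg)
    lmat <- log2(sim$counts$counts + 0.5)
    qc <- marker_qc(lmat, list(
      M2 = c("CD163", "MRC1", "C1QA", "C1QB"),
      DC = c("GENE0001", "GENE0002", "GENE0003")))  # independent genes
    pass_corr[r] <- qc$pass[qc$cell_type == "M2"]
    fail_indep[r] <- !qc$pass[qc$cell_type == "DC"]
  }
  expect_gte(mean(pass_corr), 0.95)
  expect_gte(mean(fail_indep), 0.95)
})

test_that("pathway global score follows the root-mean-square-t formula", {
  t_stats <- c(a = -3, b = 4, c = 0)
  expect_equal(pathway_global_score(t_stats, "a")$score, 3)
  expect_equal(pathway_global_score(t_stats, c("a", "b"))$score, sqrt(12.5))
  expect_equal(pathway_global_score(t_stats, "c")$score, 0)
  # invariant to gene order and sign flips
  expect_equal(pathway_global_score(t_stats, c("b", "a"))$score,
               pathway_global_score(-t_stats, c("a", "b"))$score)
  # untested genes are excluded and counted
  res <- pathway_global_score(t_stats, c("a", "b", "zz"))
  expect_equal(res$n_genes, 2L)
  expect_equal(res$n_missing, 1L)
  expect_error(pathway_global_score(t_stats, "zz"), "no testable")
})

test_that("per-sample pathway score is a centered, orientation-fixed PC1", {
  set.seed(4)
  shared <- rnorm(10)
  lmat <- rbind(P1 = 8 + shared, P2 = 6 + 2 * shared, Q = rnorm(10))
  colnames(lmat) <- paste0("s", 1:10)
  sc <- pathway_sample_score(lmat, c("P1", "P2"))
  expect_equal(mean(sc), 0, tolerance = 1e-9)
  # rank-1 case: score proportional to the shared z-profile
  expect_gt(abs(cor(sc, shared)), 0.999)
  # orientation: score rises with pathway expression
  expect_gt(cor(sc, colMeans(lmat[c("P1", "P2"), ])), 0)

  # raising every pathway gene in one sample raises that sample's score
  lmat2 <- lmat; lmat2[c("P1", "P2"), 3] <- lmat2[c("P1", "P2"), 3] + 2
  sc2 <- pathway_sample_score(lmat2, c("P1", "P2"))
  expect_gt(sc2[3] - mean(sc2[-3]), sc[3] - mean(sc[-3]))

  # invariant to gene ordering
  expect_equal(pathway_sample_score(lmat[c(2, 1, 3), ], c("P2", "P1")), sc,
               tolerance = 1e-9)

  expect_error(pathway_sample_score(
    matrix(5, 2, 4, dimnames = list(c("P1", "P2"), paste0("s", 1:4))),
    c("P1", "P2")), "constant")
})

test_that("Ward clustering matches a Lance-Williams oracle and handles ties", {
  # two identical items merge at height zero
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  wc <- ward_cluster(m, axis = "genes")
  expect_equal(min(wc$heights), 0)
  first <- wc$hclust$merge[1, ]
  expect_setequal(rownames(m)[-first], c("a", "b"))

  # 6-item fixture: heights equal a hand-rolled Ward (D2) Lance-Williams update
  set.seed(12)
  z6 <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  # z-score per gene as ward_cluster does
  z6s <- (z6 - rowMeans(z6)) / apply(z6, 1, sd)
  lw_ward <- function(items) {
    n <- nrow(items)
    d2 <- as.matrix(dist(items))^2
    size <- rep(1, n)
    active <- seq_len(n)
    heights <- numeric(n - 1)
    for (step in seq_len(n - 1)) {
      best <- c(NA, NA); bestv <- Inf
      for (ii in seq_along(active)) for (jj in seq_along(active)) {
        if (ii < jj) {
          v <- d2[active[ii], active[jj]]
          if (v < bestv - 1e-12) { bestv <- v; best <- c(active[ii], active[jj]) }
        }
      }
      i <- best[1]; j <- best[2]
      heights[step] <- sqrt(bestv)
      for (k in setdiff(active, c(i, j))) {
        ni <- size[i]; nj <- size[j]; nk <- size[k]
        d2[i, k] <- d2[k, i] <-
          ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
          (ni + nj + nk)
      }
      size[i] <- size[i] + size[j]
      active <- setdiff(active, j)
    }
    heights
  }
  wc6 <- ward_cluster(z6, axis = "genes")
  expect_equal(sort(wc6$heights), sort(lw_ward(z6s)), tolerance = 1e-8)

  # leaf order is a permutation of the inputs; zero-variance rows allowed
  expect_setequal(wc6$order, rownames(z6))
  mzv <- rbind(z6, flat = rep(3, 4))
  expect_silent(ward_cluster(mzv, axis = "genes"))
})
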