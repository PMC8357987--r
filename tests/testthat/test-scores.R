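test_that("threshold selection is strict and order-preserving", {
  st <- data.frame(cpg_id = c("a", "b", "c"), effect = 1:3,
                   p = c(0.5, 1e-6, 1e-8))
  expect_equal(select_markers(st, 1e-5)$cpg_id, c("b", "c"))
  expect_equal(select_markers(st, 1e-7)$cpg_id, "c")
  expect_equal(nrow(select_markers(st, 1.0)), 3)
  expect_error(select_markers(st, 0))
})

test_that("greedy pruning follows the forced examples", {
  # A most significant; B correlated with A above the cut-off; C below it
  set.seed(1)
  n <- 2000
  a <- rnorm(n)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  c <- 0.02 * a + rnorm(n)
  m <- stats::plogis(0.5 * cbind(A = a, B = b, C = c))
  rownames(m) <- sprintf("S%04d", seq_len(n))
  beta <- omics_matrix(m, "beta")
  st <- data.frame(cpg_id = c("A", "B", "C"), effect = 1,
                   p = c(1e-9, 1e-8, 1e-7))
  kept <- prune_markers(st, beta, r_cutoff = 0.1)
  expect_equal(kept$cpg_id, c("A", "C"))

  # r_cutoff = 1 is a no-op when all |r| < 1
  expect_setequal(prune_markers(st, beta, r_cutoff = 1)$cpg_id,
                  c("A", "B", "C"))

  # zero-variance marker excluded up front with a warning
  m2 <- cbind(m, D = rep(0.5, n))
  st2 <- rbind(st, data.frame(cpg_id = "D", effect = 1, p = 1e-10))
  expect_warning(kept2 <- prune_markers(st2, omics_matrix(m2, "beta"), 0.1),
                 "zero-variance")
  expect_false("D" %in% kept2$cpg_id)
})

test_that("pruning matches the exhaustive greedy reference on random instances", {
  set.seed(42)
  for (i in seq_len(60)) {
    inst <- random_prune_instance(sample(3:15, 1))
    cutoff <- sample(c(0.1, 0.3, 0.6), 1)
    mine <- prune_markers(inst$stats, inst$beta, r_cutoff = cutoff)
    ref <- prune_reference(inst$stats, inst$beta, r_cutoff = cutoff)
    expect_identical(mine$cpg_id, ref$cpg_id)
    # kept set is independent at the cut-off
    if (nrow(mine) > 1) {
      cm <- abs(stats::cor(unclass(inst$beta)[, mine$cpg_id]))
      expect_true(all(cm[upper.tri(cm)] < cutoff))
    }
  }
})

test_that("methylation scores equal the per-sample accumulation oracle", {
  # forced cancellation and single-marker examples
  m <- matrix(c(0.5, 0.5), nrow = 1,
              dimnames = list("S1", c("cg1", "cg2")))
  st <- data.frame(cpg_id = c("cg1", "cg2"), effect = c(1, -1), p = c(0.01, 0.01))
  expect_equal(unname(build_ms(st, omics_matrix(m, "beta"))$values), 0)

  m1 <- matrix(0.25, 1, 1, dimnames = list("S1", "cg1"))
  st1 <- data.frame(cpg_id = "cg1", effect = 2, p = 0.01)
  expect_equal(unname(build_ms(st1, omics_matrix(m1, "beta"))$values), 0.5)

  # random instance against the loop oracle
  set.seed(7)
  n_cpg <- 50; n_s <- 20
  mv <- matrix(runif(n_s * n_cpg), n_s, n_cpg,
               dimnames = list(sprintf("S%02d", 1:n_s), sprintf("cg%02d", 1:n_cpg)))
  beta <- omics_matrix(mv, "beta")
  st2 <- data.frame(cpg_id = colnames(mv), effect = rnorm(n_cpg),
                    p = runif(n_cpg, 0, 0.5))
  ms <- build_ms(st2, beta, p_threshold = 1)
  ref <- weighted_sum_reference(st2$effect, st2$cpg_id, beta)
  expect_equal(ms$values, ref, tolerance = 1e-12)
})

test_that("coverage accounting: absent markers warned and excluded, never renormalized", {
  m <- matrix(runif(6), 2, 3,
              dimnames = list(c("S1", "S2"), c("cg1", "cg2", "cg3")))
  beta <- omics_matrix(m, "beta")
  st <- data.frame(cpg_id = c("cg1", "cg2", "cg3", "cg4", "cg5"),
                   effect = rep(1, 5), p = rep(0.01, 5))
  expect_warning(ms <- build_ms(st, beta), "2 of 5")
  expect_equal(ms$n_markers_used, 3)
  expect_equal(ms$coverage, 3 / 5)
  expect_equal(unname(ms$values), unname(rowSums(m)))  # weights untouched

  st_none <- data.frame(cpg_id = c("cgX", "cgY"), effect = 1, p = 0.01)
  expect_error(suppressWarnings(build_ms(st_none, beta)), "overlap")
})

test_that("fixed marker-list mode bypasses the threshold grid", {
  co <- tiny_cohort()
  st <- simulate_discovery_stats(co)$ewas
  keep <- st$cpg_id[1:5]
  ms <- build_ms(st, co$beta, marker_list = keep)
  expect_equal(ms$n_markers_used, 5)
  expect_true(is.na(ms$p_threshold))
})

test_that("polygenic scores align alleles and match the pre-flip oracle", {
  d1 <- matrix(2, 1, 1, dimnames = list("S1", "rs1"))
  dos <- omics_matrix(d1, "dosage")
  al <- data.frame(snp_id = "rs1", counted_allele = "A", other_allele = "G")
  st <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "G",
                   effect = 0.3, p = 0.01)
  expect_equal(unname(build_pgs(st, dos, al)$values), 0.6)

  # cohort counts the other allele: dosage flips to 2 - d
  st_fl <- transform(st, effect_allele = "G", other_allele = "A")
  expect_equal(unname(build_pgs(st_fl, dos, al)$values), 0)

  # mismatching alleles dropped with warning -> here no variant remains
  st_mm <- transform(st, effect_allele = "C", other_allele = "T")
  expect_error(suppressWarnings(build_pgs(st_mm, dos, al)))

  # random flips against an oracle that pre-flips dosages then sums
  set.seed(21)
  n_snp <- 100; n_s <- 30
  dv <- matrix(sample(0:2, n_s * n_snp, TRUE), n_s, n_snp,
               dimnames = list(sprintf("S%02d", 1:n_s), sprintf("rs%03d", 1:n_snp)))
  dos2 <- omics_matrix(dv, "dosage")
  al2 <- data.frame(snp_id = colnames(dv),
                    counted_allele = sample(c("A", "T"), n_snp, TRUE),
                    other_allele = "C", stringsAsFactors = FALSE)
  al2$other_allele[al2$counted_allele == "T"] <- "G"
  flip <- as.logical(rbinom(n_snp, 1, 0.5))
  st2 <- data.frame(snp_id = al2$snp_id,
                    effect_allele = ifelse(flip, al2$other_allele, al2$counted_allele),
                    other_allele = ifelse(flip, al2$counted_allele, al2$other_allele),
                    effect = rnorm(n_snp), p = runif(n_snp, 0, 0.5),
                    stringsAsFactors = FALSE)
  pgs <- build_pgs(st2, dos2, al2)
  dv_aligned <- dv
  dv_aligned[, flip] <- 2 - dv_aligned[, flip]
  ref <- weighted_sum_reference(st2$effect, st2$snp_id,
                                omics_matrix(dv_aligned, "dosage"))
  expect_equal(pgs$values, ref, tolerance = 1e-12)

  # invariance: relabelling the cohort's counted allele AND replacing d by
  # 2-d leaves the score unchanged
  pgs_relabel <- build_pgs(
    st2, omics_matrix(2 - dv, "dosage"),
    transform(al2, counted_allele = al2$other_allele,
              other_allele = al2$counted_allele))
  expect_equal(pgs_relabel$values, pgs$values, tolerance = 1e-12)
})

test_that("z-scoring has mean 0, sample SD 1, and is idempotent", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 5, 3)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(stats::sd(z), 1)
  expect_equal(zscore(z), z, tolerance = 1e-10)
  expect_error(zscore(rep(1, 10)), "zero-variance")
})

test_that("methylation score is linear in the beta matrix", {
  set.seed(3)
  m1 <- matrix(runif(40), 4, 10, dimnames = list(paste0("S", 1:4), paste0("cg", 1:10)))
  m2 <- matrix(runif(40), 4, 10, dimnames = dimnames(m1))
  st <- data.frame(cpg_id = colnames(m1), effect = rnorm(10), p = 0.01)
  a <- 0.3
  mix <- build_ms(st, omics_matrix(a * m1 + (1 - a) * m2, "beta"))$values
  s1 <- build_ms(st, omics_matrix(m1, "beta"))$values
  s2 <- build_ms(st, omics_matrix(m2, "beta"))$values
  expect_equal(mix, a * s1 + (1 - a) * s2, tolerance = 1e-12)
})

test_that("noisy-weight scores converge toward the true-weight score with discovery size", {
  co <- simulate_cohort(sim_config(n_pairs = 400, r2_ms_true = 0.3, seed = 13))
  w <- co$truth$cpg_effects
  ms_true <- zscore(drop(unclass(co$beta)[, names(w)] %*% w))
  cors <- vapply(c(1e2, 1e3, 1e4, 1e6), function(nd) {
    cfg <- co$config; cfg$n_discovery <- nd
    st <- simulate_discovery_stats(co, cfg)$ewas
    ms <- build_ms(st, co$beta, p_threshold = 1)
    stats::cor(ms_true, zscore(unname(ms$values)))
  }, numeric(1))
  expect_true(all(diff(abs(cors)) > 0))
  expect_gt(abs(cors[4]), 0.99)
})
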