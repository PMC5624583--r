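test_that("rpkm matches hand arithmetic and its invariances", {
  m <- matrix(c(1, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  len <- c(g1 = 1000, g2 = 500)
  expect_equal(rpkm(m, len, librarySizes = 1e6)["g1", "s1"], 1.0)
  expect_equal(rpkm(m, len, librarySizes = 2e6)["g2", "s1"], 10.0)
  # joint rescaling of counts and library size leaves RPKM unchanged
  expect_equal(rpkm(m, len, librarySizes = 1e6),
               rpkm(2 * m, len, librarySizes = 2e6))
  # linear in counts at fixed library size
  expect_equal(rpkm(3 * m, len, librarySizes = 1e6),
               3 * rpkm(m, len, librarySizes = 1e6))
  expect_error(rpkm(m, len, librarySizes = 0), "library size")
})

test_that("fold difference reproduces the published day-3 ratio and flags", {
  expect_equal(round(foldDifference(19.94, 4.76), 1), 4.2)
  expect_equal(foldDifference(7, 7), 1.0)
  expect_identical(foldDifference(7.86, 0), Inf)
  expect_true(is.nan(foldDifference(0, 0)))
  expect_error(foldDifference(-1, 2), "non-negative")
})

test_that("dispersion estimator recovers the simulated regimes", {
  # constant replicate counts: zero variance, zero dispersion
  const <- matrix(7, 5, 6, dimnames = list(paste0("g", 1:5), NULL))
  phi <- estimateTagwiseDispersion(const, rep(c("a", "b"), each = 3))
  expect_equal(unname(phi), rep(0, 5), ignore_attr = TRUE)

  # Poisson counts: dispersions concentrate near zero
  set.seed(1)
  pois <- t(sapply(stats::rlnorm(1000, log(50), 1),
                   function(m) stats::rpois(12, m)))
  rownames(pois) <- paste0("g", 1:1000)
  phi_p <- estimateTagwiseDispersion(pois, rep(c("a", "b"), each = 6),
                                     priorWeight = 0)
  expect_lt(median(phi_p), 0.02)

  # NB at dispersion 0.1, 6 per group, 2000 genes: median in [0.05, 0.2]
  set.seed(2)
  nb <- t(sapply(stats::rlnorm(2000, log(50), 1),
                 function(m) stats::rnbinom(12, mu = m, size = 10)))
  rownames(nb) <- paste0("g", 1:2000)
  phi_nb <- estimateTagwiseDispersion(nb, rep(c("a", "b"), each = 6))
  expect_gt(median(phi_nb), 0.05)
  expect_lt(median(phi_nb), 0.2)

  # all-zero genes are flagged with dispersion 0
  zero <- rbind(nb[1:3, ], g0 = 0L)
  phi_z <- estimateTagwiseDispersion(zero, rep(c("a", "b"), each = 6))
  expect_equal(unname(phi_z["g0"]), 0)
  expect_true(attr(phi_z, "allZero")["g0"])
})

test_that("exact test: identical group sums give p = 1", {
  expect_equal(nbExactTest(c(5, 5, 5), c(5, 5, 5), 0.1), 1)
  expect_equal(nbExactTest(c(0, 0), c(0, 0), 0.5), 1)
})

test_that("Poisson-limit exact test equals binomial-conditional enumeration", {
  for (s in c(1, 5, 12, 20)) for (xa in c(0, floor(s / 3), s)) {
    a <- c(xa, 0, 0); b <- c(s - xa, 0)
    probs <- dbinom(0:s, s, 3 / 5)
    expected <- sum(probs[probs <= probs[xa + 1] * (1 + 1e-10)])
    expect_equal(nbExactTest(a, b, 0), expected)
  }
})

test_that("exact test matches the per-sample convolution oracle", {
  # spot grid here; the exhaustive totals <= 30 sweep runs in the
  # acceptance suite
  for (phi in c(0, 0.1, 1)) for (s in c(4, 11, 25)) for (xa in 0:s) {
    p1 <- nbExactTest(c(xa, 0, 0), c(s - xa, 0, 0), phi)
    p2 <- convolution_exact_p(c(xa, 0, 0), c(s - xa, 0, 0), phi)
    expect_equal(p1, p2, tolerance = 1e-8)
  }
})

test_that("exact test agrees with an independent reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  for (phi in c(0.05, 0.3, 1)) for (i in 1:10) {
    a <- stats::rnbinom(3, mu = 40, size = 1 / phi)
    b <- stats::rnbinom(2, mu = 25, size = 1 / phi)
    ref <- edgeR::exactTestBySmallP(matrix(a, 1), matrix(b, 1),
                                    dispersion = phi)
    expect_equal(nbExactTest(a, b, phi), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up worked example", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(0.03, 5)), rep(0.03, 5))
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the directional filter keeps the published late-induced gene rows", {
  rec <- dhn1_records()
  kept <- degFilter(rec)
  expect_equal(nrow(kept), 4)
  expect_true(all(kept$induced_phenotype == "responsive"))
  expect_true(all(kept$fold_difference >= 4.1))
})

test_that("filter drops sub-threshold folds and keeps nonresponsive induction", {
  rec <- data.frame(gene = c("a", "b", "c"), day = 3,
                    rpkm_responsive = c(15, 4, 30),
                    rpkm_nonresponsive = c(10, 10, 1),
                    fold_difference = c(1.5, 0.4, 30),
                    p_value = c(0.001, 0.01, 0.5),
                    fdr = c(0.001, 0.01, 0.5))
  kept <- degFilter(rec)
  expect_equal(kept$gene, "b")
  expect_equal(kept$induced_phenotype, "nonresponsive")
})

test_that("filter counts are monotone in both thresholds", {
  set.seed(4)
  rec <- data.frame(gene = paste0("g", 1:300), day = 3,
                    rpkm_responsive = runif(300, 0, 50),
                    rpkm_nonresponsive = runif(300, 0, 50))
  rec$fold_difference <- foldDifference(rec$rpkm_responsive,
                                        rec$rpkm_nonresponsive)
  rec$p_value <- runif(300)
  rec$fdr <- bhFdr(rec$p_value)
  n_at <- function(p, f) nrow(degFilter(rec, pThreshold = p,
                                        foldThreshold = f))
  for (f in c(1.5, 2, 4))
    expect_true(all(diff(sapply(c(0.2, 0.1, 0.05, 0.01),
                                n_at, f = f)) <= 0))
  for (p in c(0.25, 0.05))
    expect_true(all(diff(sapply(c(1.2, 2, 3, 6),
                                function(f) n_at(p, f))) <= 0))
})

test_that("planted responsive-induced genes are recovered end to end", {
  cfg <- rnaseqSimConfig(nGenes = 2000, deFraction = 0.005,
                         foldRange = c(4, 4), days = 3, nReplicates = 3,
                         dispersion = 0.1, seed = 11)
  sim <- simulateCountData(cfg)
  rec <- degAnalysis(sim$se)
  kept <- degFilter(rec)
  planted <- names(which(sim$truth$deGenes))
  hits <- kept$gene[kept$induced_phenotype == "responsive"]
  # regression floor: at fold 4 with 3 replicates per group, recover at
  # least 8 of the 10 planted genes
  expect_length(planted, 10)
  expect_gte(sum(planted %in% hits), 8)
  smry <- degSummary(kept)
  expect_gte(smry$n_deg[smry$induced_phenotype == "responsive"], 8)
})

test_that("deg summary handles empty cells and singletons", {
  empty <- degFilter(dhn1_records(), pThreshold = 1e-30)
  smry <- degSummary(empty, days = c(3, 7))
  expect_equal(smry$n_deg, rep(0L, 4))
  expect_true(all(is.na(smry$avg_rpkm)))

  one <- dhn1_records()[1, ]
  one$induced_phenotype <- "responsive"
  s1 <- degSummary(one)
  expect_equal(s1$avg_rpkm[s1$induced_phenotype == "responsive"], 19.94)
})

test_that("degAnalysis validates the per-day design", {
  sim <- simulateCountData(rnaseqSimConfig(nGenes = 50, days = 3,
                                           nReplicates = 1, seed = 1))
  expect_error(degAnalysis(sim$se), ">= 2")
})
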