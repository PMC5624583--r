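test_that("series reference means are per-series arithmetic means", {
  qt <- QuantityTable(data.frame(
    sample_id = c("s1", "s2"), series = "G6", day = c(0, 3),
    gene = "refA", role = "reference", quantity = c(100, 300)))
  m <- seriesReferenceMeans(qt)
  expect_equal(m$mean_quantity, 200)

  # constant quantities give back the constant
  qt2 <- QuantityTable(data.frame(
    sample_id = paste0("s", 1:4), series = rep(c("A", "B"), each = 2),
    day = c(0, 3, 0, 3), gene = "refA", role = "reference", quantity = 42))
  expect_true(all(seriesReferenceMeans(qt2)$mean_quantity == 42))
})

test_that("a sample lacking a reference measurement is an error naming it", {
  d <- as.data.frame(worked_example_table())
  d <- d[!(d$sample_id == "s2" & d$gene == "refB"), ]
  expect_error(seriesReferenceMeans(QuantityTable(d)), "refB.*s2")
})

test_that("a series with a single sample is rejected", {
  d <- as.data.frame(worked_example_table())
  d$series[d$sample_id == "s2"] <- "G2"
  # now both series have one sample each
  expect_error(normalizationFactors(QuantityTable(d)), "series")
})

test_that("normalization factors follow the fraction-averaging construction", {
  nf <- normalizationFactors(worked_example_table())
  expect_equal(normFactors(nf), c(s1 = 0.75, s2 = 1.25))
  fr <- refFractions(nf)
  expect_equal(fr$fraction[fr$gene == "refA"], c(0.5, 1.5))
  expect_equal(fr$fraction[fr$gene == "refB"], c(1, 1))
})

test_that("references at their series mean give unit factors", {
  qt <- QuantityTable(data.frame(
    sample_id = rep(c("s1", "s2"), each = 2), series = "G6",
    day = rep(c(0, 3), each = 2), gene = rep(c("refA", "refB"), 2),
    role = "reference", quantity = c(100, 250, 100, 250)))
  expect_equal(unname(normFactors(normalizationFactors(qt))), c(1, 1))
})

test_that("a single reference gene yields its fractions as factors", {
  qt <- QuantityTable(data.frame(
    sample_id = c("s1", "s2"), series = "G6", day = c(0, 3),
    gene = "refA", role = "reference", quantity = c(100, 300)))
  expect_equal(normFactors(normalizationFactors(qt)),
               c(s1 = 0.5, s2 = 1.5))
})

test_that("per-series factor means equal 1 for arbitrary valid input", {
  for (seed in 1:10) {
    qt <- random_quantity_table(seed)
    nf <- normalizationFactors(qt)
    f <- normFactors(nf)
    by_series <- tapply(f, nf@series[names(f)], mean)
    expect_equal(as.numeric(by_series), rep(1, length(by_series)),
                 tolerance = 1e-9)
  }
})

test_that("normalization divides every quantity by its sample factor", {
  qt <- worked_example_table()
  nf <- normalizationFactors(qt)
  out <- as.data.frame(applyNormalization(qt, nf))
  expect_equal(out$quantity[out$gene == "TGT"], c(100, 100))
  # schema preserved
  expect_identical(names(out), names(as.data.frame(qt)))
})

test_that("unit factors leave the table unchanged", {
  qt <- random_quantity_table(3)
  f <- rep(1, length(sampleIds(qt)))
  names(f) <- sampleIds(qt)
  ser <- setNames(as.data.frame(qt)$series, as.data.frame(qt)$sample_id)
  nf <- new("NormalizationFactors", factors = f,
            fractions = data.frame(), series = ser[names(f)])
  expect_equal(as.data.frame(applyNormalization(qt, nf)),
               as.data.frame(qt))
})

test_that("single-reference normalization maps references to series means", {
  for (seed in 1:5) {
    qt <- random_quantity_table(seed, n_refs = 1)
    nf <- normalizationFactors(qt)
    norm <- as.data.frame(applyNormalization(qt, nf))
    ref <- norm[norm$role == "reference", ]
    m <- seriesReferenceMeans(qt)
    for (i in seq_len(nrow(ref))) {
      expected <- m$mean_quantity[m$series == ref$series[i] &
                                  m$gene == ref$gene[i]]
      expect_equal(ref$quantity[i], expected)
    }
  }
})

test_that("recomputing factors on a single-reference normalized table gives 1", {
  qt <- random_quantity_table(9, n_refs = 1)
  norm <- applyNormalization(qt, normalizationFactors(qt))
  f2 <- normFactors(normalizationFactors(norm))
  expect_equal(unname(f2), rep(1, length(f2)))
})

test_that("scaling one sample scales its factor as brute-force recomputation predicts", {
  qt <- random_quantity_table(11, n_refs = 1)
  d <- as.data.frame(qt)
  target_sample <- sampleIds(qt)[1]
  for (c_mult in c(0.5, 2, 3.7)) {
    d2 <- d
    d2$quantity[d2$sample_id == target_sample] <-
      d2$quantity[d2$sample_id == target_sample] * c_mult
    f2 <- normFactors(normalizationFactors(QuantityTable(d2)))
    # brute-force from definition: fraction = quantity / series mean
    ref <- d2[d2$role == "reference", ]
    for (s in unique(ref$sample_id)) {
      ser <- ref$series[ref$sample_id == s][1]
      expected <- ref$quantity[ref$sample_id == s] /
        mean(ref$quantity[ref$series == ser])
      expect_equal(unname(f2[s]), expected)
    }
  }
})

test_that("sample without a factor is reported by name", {
  qt <- worked_example_table()
  nf <- normalizationFactors(qt)
  extra <- as.data.frame(qt)
  extra <- rbind(extra, data.frame(sample_id = "s3", series = "G6", day = 7,
                                   gene = "TGT", role = "target",
                                   quantity = 10))
  expect_error(applyNormalization(QuantityTable(extra), nf), "s3")
})

test_that("divergence summary reports min/max percent and half-range", {
  expect_equal(divergenceSummary(c(0.67, 1.0, 1.35)),
               list(min_percent = 67, max_percent = 135,
                    half_range_percent = 34))
  expect_equal(divergenceSummary(c(1, 1, 1)),
               list(min_percent = 100, max_percent = 100,
                    half_range_percent = 0))
  expect_equal(divergenceSummary(c(0.8, 1.0, 1.2)),
               list(min_percent = 80, max_percent = 120,
                    half_range_percent = 20))
  expect_error(divergenceSummary(numeric(0)), "no factors")
})

test_that("geometric combination is available and differs from arithmetic", {
  qt <- worked_example_table()
  fa <- normFactors(normalizationFactors(qt, method = "arithmetic"))
  fg <- normFactors(normalizationFactors(qt, method = "geometric"))
  expect_equal(unname(fg), c(sqrt(0.5), sqrt(1.5)))
  expect_false(isTRUE(all.equal(fa, fg)))
})

test_that("QuantityTable validity rejects malformed input", {
  base <- as.data.frame(worked_example_table())
  neg <- base; neg$quantity[1] <- -1
  expect_error(QuantityTable(neg), "non-negative")
  dup <- rbind(base, base[1, ])
  expect_error(QuantityTable(dup), "duplicated")
  twoseries <- base; twoseries$series[1] <- "G2"
  expect_error(QuantityTable(twoseries), "more than one series")
})
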