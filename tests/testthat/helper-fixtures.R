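# Shared in-code fixtures

# Two-sample, two-reference worked example: refA fractions {0.5, 1.5},
# refB fractions {1, 1}, so factors are {0.75, 1.25}; target {75, 125}
# normalizes to {100, 100}.
worked_example_table <- function() {
  QuantityTable(data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    series = "G6",
    day = rep(c(0, 3), each = 3),
    gene = rep(c("refA", "refB", "TGT"), 2),
    role = rep(c("reference", "reference", "target"), 2),
    quantity = c(100, 200, 75, 300, 200, 125)))
}

# Published per-day expression of the top late-induced dehydrin: phenotype
# mean RPKM and exact-test p-values at the four collection days.
dhn1_records <- function() {
  rec <- data.frame(
    gene = "DHN1", day = c(3, 7, 15, 21),
    rpkm_responsive = c(19.94, 17.88, 19.36, 40.39),
    rpkm_nonresponsive = c(4.76, 3.49, 2.87, 2.02),
    p_value = c(6.13e-8, 6.42e-6, 7.03e-10, 8.94e-20))
  rec$fold_difference <- foldDifference(rec$rpkm_responsive,
                                        rec$rpkm_nonresponsive)
  rec$fdr <- rec$p_value  # already far below any threshold
  rec
}

# Random valid quantity table for property-style tests
random_quantity_table <- function(seed, n_series = 3, n_days = 4,
                                  n_refs = 2, n_targets = 2) {
  set.seed(seed)
  series <- paste0("S", seq_len(n_series))
  days <- sort(sample(0:30, n_days))
  genes <- c(paste0("ref", seq_len(n_refs)), paste0("tgt", seq_len(n_targets)))
  roles <- rep(c("reference", "target"), c(n_refs, n_targets))
  grid <- expand.grid(series = series, day = days, stringsAsFactors = FALSE)
  grid$sample_id <- paste0(grid$series, "_d", grid$day)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(sample_id = grid$sample_id[i], series = grid$series[i],
               day = grid$day[i], gene = genes, role = roles,
               quantity = runif(length(genes), 10, 5000))))
  QuantityTable(rows)
}

# Brute-force oracle for the conditional two-group exact test: numeric
# convolution of per-sample NB (or Poisson) pmfs, then condition on the
# grand total. Independent of the closed-form conditional distribution
# used by nbExactTest.
convolution_exact_p <- function(countsA, countsB, dispersion, mu = 2.3) {
  s <- sum(countsA) + sum(countsB)
  if (s == 0) return(1)
  supp <- 0:s
  pmf1 <- if (dispersion == 0) dpois(supp, mu)
          else dnbinom(supp, mu = mu, size = 1 / dispersion)
  conv_n <- function(n) {
    out <- pmf1
    if (n > 1) for (i in 2:n) {
      new <- numeric(s + 1)
      for (k in supp) new[k + 1] <- sum(out[0:k + 1] * pmf1[k - (0:k) + 1])
      out <- new
    }
    out
  }
  joint <- conv_n(length(countsA)) * rev(conv_n(length(countsB)))
  joint <- joint / sum(joint)
  pobs <- joint[sum(countsA) + 1]
  sum(joint[joint <= pobs * (1 + 1e-10)])
}
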