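#' Assemble an RNA-seq count container
#'
#' Bundles a gene x sample integer count matrix, per-gene lengths and the
#' sample sheet (phenotype, day, replicate) into a
#' [SummarizedExperiment::SummarizedExperiment], the input of
#' [degAnalysis()].
#'
#' @param counts integer matrix, genes x samples, non-negative, with row and
#'   column names.
#' @param lengths named numeric, gene -> length in bases (> 0); order/names
#'   must cover `rownames(counts)`.
#' @param sampleInfo data.frame with columns `phenotype`
#'   (`"responsive"`/`"nonresponsive"`), `day` and `replicate`; rows match
#'   `colnames(counts)`.
#' @return SummarizedExperiment with assay `counts`, rowData `length` and
#'   the sample sheet as colData.
#' @export
makeCountSE <- function(counts, lengths, sampleInfo) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  lack <- setdiff(rownames(counts), names(lengths))
  if (length(lack) > 0)
    stop("no length for gene(s): ", paste(utils::head(lack, 5), collapse = ", "))
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  sampleInfo <- as.data.frame(sampleInfo)
  need <- c("phenotype", "day", "replicate")
  miss <- setdiff(need, names(sampleInfo))
  if (length(miss) > 0)
    stop("sampleInfo missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(sampleInfo) != ncol(counts))
    stop("sampleInfo rows must match count matrix columns")
  if (!all(sampleInfo$phenotype %in% c("responsive", "nonresponsive")))
    stop("phenotype must be 'responsive' or 'nonresponsive'")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length = unname(lengths[rownames(counts)]),
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(sampleInfo, row.names = colnames(counts)))
}

#' Reads per kilobase per million mapped reads (RPKM)
#'
#' `rpkm = count / (gene length in kb x library size in millions)`. The
#' library size defaults to the column sum of the count matrix; an external
#' vector of total mapped reads can be supplied instead.
#'
#' @param counts gene x sample count matrix, or a SummarizedExperiment from
#'   [makeCountSE()].
#' @param lengths named numeric gene lengths in bases; taken from rowData
#'   when `counts` is a SummarizedExperiment.
#' @param librarySizes per-sample totals of mapped reads (> 0); default
#'   `colSums(counts)`.
#' @return matrix of RPKM values, same dimensions as the counts.
#' @examples
#' m <- matrix(1, 1, 1, dimnames = list("g", "s"))
#' rpkm(m, c(g = 1000), librarySizes = 1e6)  # 1.0
#' @export
rpkm <- function(counts, lengths = NULL, librarySizes = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(lengths))
      lengths <- setNames(SummarizedExperiment::rowData(counts)$length,
                          rownames(counts))
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (is.null(lengths)) stop("gene lengths are required")
  len <- if (is.null(names(lengths))) lengths else lengths[rownames(counts)]
  if (any(is.na(len)) || any(len <= 0)) stop("gene lengths must be > 0")
  if (is.null(librarySizes)) librarySizes <- colSums(counts)
  if (any(librarySizes <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[librarySizes <= 0], collapse = ", "))
  sweep(counts / (len / 1000), 2, librarySizes / 1e6, "/")
}

#' Fold difference between phenotype means
#'
#' Ratio of responsive to nonresponsive mean expression. A zero denominator
#' with a nonzero numerator is flagged infinite (`Inf`); 0/0 is undefined
#' (`NaN`). Vectorized.
#'
#' @param meanResp,meanNonresp non-negative mean expression values (RPKM).
#' @return numeric ratio(s); `Inf` and `NaN` flag the degenerate cases.
#' @examples
#' round(foldDifference(19.94, 4.76), 1)  # 4.2
#' @export
foldDifference <- function(meanResp, meanNonresp) {
  if (any(meanResp < 0, na.rm = TRUE) || any(meanNonresp < 0, na.rm = TRUE))
    stop("mean expression values must be non-negative")
  r <- meanResp / meanNonresp
  r[meanNonresp == 0 & meanResp > 0] <- Inf
  r[meanNonresp == 0 & meanResp == 0] <- NaN
  r
}

#' Tagwise negative-binomial dispersion (method of moments, shrunk)
#'
#' Per-gene NB dispersion estimated within groups by the method of moments,
#' `(variance - mean) / mean^2`, pooled across groups with degrees-of-freedom
#' weights, floored at 0, then shrunk toward the all-gene median with weight
#' `priorWeight`. Genes with zero counts throughout get dispersion 0 and are
#' flagged in the `"allZero"` attribute.
#'
#' @param counts gene x sample count matrix.
#' @param groups group label per column; at least one group needs >= 2
#'   samples.
#' @param priorWeight weight in `[0, 1]` of the common (median) dispersion
#'   in the shrunk estimate; default 0.5, an even compromise between the
#'   noisy per-gene moment estimate at typical replicate numbers and the
#'   stable common value.
#' @return named numeric vector of dispersions (>= 0) with attributes
#'   `common` (the median before shrinkage) and `allZero`.
#' @export
estimateTagwiseDispersion <- function(counts, groups, priorWeight = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("one group label per sample column is required")
  if (priorWeight < 0 || priorWeight > 1) stop("priorWeight must be in [0, 1]")
  sizes <- table(groups)
  use <- names(sizes)[sizes >= 2]
  if (length(use) == 0) stop("need >= 2 samples in at least one group")
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (g in use) {
    sub <- counts[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    df <- ncol(sub) - 1
    phi_g <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    ok <- !is.na(phi_g)
    num[ok] <- num[ok] + df * phi_g[ok]
    den[ok] <- den[ok] + df
  }
  phi <- ifelse(den > 0, pmax(0, num / den), 0)
  all_zero <- rowSums(counts) == 0
  phi[all_zero] <- 0
  common <- median(phi[!all_zero])
  if (!is.finite(common)) common <- 0
  out <- (1 - priorWeight) * phi + priorWeight * common
  out[all_zero] <- 0
  names(out) <- rownames(counts)
  attr(out, "common") <- common
  attr(out, "allZero") <- all_zero
  out
}

#' Conditional two-group negative-binomial exact test
#'
#' Exact test for a difference in mean count between two groups of samples,
#' conditioned on the grand total. Under equal group means, with each sample
#' count NB-distributed at dispersion `dispersion`, the group totals are NB
#' with sizes `nA/dispersion` and `nB/dispersion` and the conditional
#' distribution of the group-A total given the grand total is free of the
#' mean parameter (negative hypergeometric; binomial when `dispersion = 0`,
#' the Poisson limit). The two-sided p-value sums the probabilities of all
#' splits at most as probable as the observed one (ties included).
#'
#' Counts must be comparable across samples: adjust each library to a common
#' size first (done by [degAnalysis()], which scales to the geometric mean
#' library size and rounds to integer pseudo-counts).
#'
#' @param countsA,countsB non-negative integer counts for the gene, one per
#'   sample in each group.
#' @param dispersion NB dispersion (>= 0); 0 selects the Poisson limit.
#' @return p-value in (0, 1].
#' @examples
#' nbExactTest(c(10, 12, 11), c(11, 10, 12), dispersion = 0.1)  # near 1
#' @export
nbExactTest <- function(countsA, countsB, dispersion) {
  if (any(countsA < 0) || any(countsB < 0)) stop("counts must be non-negative")
  if (length(dispersion) != 1 || !is.finite(dispersion) || dispersion < 0)
    stop("dispersion must be a single value >= 0")
  nA <- length(countsA); nB <- length(countsB)
  if (nA == 0 || nB == 0) stop("both groups need at least one sample")
  s <- sum(countsA) + sum(countsB)
  if (s == 0) return(1)
  xobs <- sum(countsA)
  x <- 0:s
  if (dispersion == 0) {
    lp <- dbinom(x, s, nA / (nA + nB), log = TRUE)
  } else {
    r1 <- nA / dispersion; r2 <- nB / dispersion
    lp <- lgamma(x + r1) - lgamma(x + 1) - lgamma(r1) +
          lgamma(s - x + r2) - lgamma(s - x + 1) - lgamma(r2)
  }
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  pobs <- p[xobs + 1]
  min(1, sum(p[p <= pobs * (1 + 1e-10)]))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with the usual monotonicity enforcement
#' (delegates to `stats::p.adjust(method = "BH")` after validating the
#' input range).
#'
#' @param p p-values in `[0, 1]`; `NA`s are propagated.
#' @return adjusted values in `[0, 1]`, same order as the input.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-day two-group differential expression analysis
#'
#' For each collection day, compares responsive vs nonresponsive samples
#' gene by gene: RPKM phenotype means (computed on the full library sizes),
#' responsive/nonresponsive fold difference, tagwise dispersion
#' ([estimateTagwiseDispersion()]) on library-size-adjusted pseudo-counts,
#' the conditional NB exact test ([nbExactTest()]) and per-day BH FDR.
#' Library-size adjustment scales each sample's counts to the geometric
#' mean library size of the day's samples and rounds to the nearest
#' integer, so that conditioning on the total is meaningful.
#'
#' @param se SummarizedExperiment from [makeCountSE()] (assay `counts`,
#'   rowData `length`, colData `phenotype` and `day`).
#' @param days which days to analyze; default all days present.
#' @param priorWeight passed to [estimateTagwiseDispersion()].
#' @param librarySizes optional named per-sample totals of mapped reads;
#'   default column sums.
#' @return data.frame with one row per gene x day: `gene`, `day`,
#'   `rpkm_responsive`, `rpkm_nonresponsive`, `fold_difference`,
#'   `dispersion`, `p_value`, `fdr`.
#' @export
degAnalysis <- function(se, days = NULL, priorWeight = 0.5,
                        librarySizes = NULL) {
  counts <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  lengths <- setNames(SummarizedExperiment::rowData(se)$length, rownames(se))
  if (is.null(librarySizes)) librarySizes <- colSums(counts)
  rk <- rpkm(counts, lengths, librarySizes)
  if (is.null(days)) days <- sort(unique(cd$day))
  out <- list()
  for (d in days) {
    sel <- cd$day == d
    if (!any(sel)) stop("no samples collected at day ", d)
    ph <- cd$phenotype[sel]
    for (lv in c("responsive", "nonresponsive"))
      if (sum(ph == lv) < 2)
        stop(sprintf("day %s: need >= 2 '%s' samples for testing", d, lv))
    sub <- counts[, sel, drop = FALSE]
    ls_sub <- librarySizes[sel]
    # equal-library pseudo-counts for the conditional test
    common_ls <- exp(mean(log(ls_sub)))
    pseudo <- round(sweep(sub, 2, common_ls / ls_sub, "*"))
    phi <- estimateTagwiseDispersion(pseudo, ph, priorWeight = priorWeight)
    ia <- which(ph == "responsive"); ib <- which(ph == "nonresponsive")
    pv <- vapply(seq_len(nrow(pseudo)), function(i)
      nbExactTest(pseudo[i, ia], pseudo[i, ib], phi[i]), numeric(1))
    mr <- rowMeans(rk[, sel, drop = FALSE][, ia, drop = FALSE])
    mn <- rowMeans(rk[, sel, drop = FALSE][, ib, drop = FALSE])
    out[[as.character(d)]] <- data.frame(
      gene = rownames(counts), day = d,
      rpkm_responsive = unname(mr), rpkm_nonresponsive = unname(mn),
      fold_difference = unname(foldDifference(mr, mn)),
      dispersion = unname(phi), p_value = pv, fdr = bhFdr(pv),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Directional fold-change filter for DEG records
#'
#' Keeps genes significant at `pThreshold` and induced at least
#' `foldThreshold`-fold in one phenotype: fold >= `foldThreshold` calls the
#' responsive phenotype induced, fold <= `1/foldThreshold` the
#' nonresponsive phenotype (i.e. >= 2-fold induction within each respective
#' phenotype at the defaults). Significance is judged on the FDR-adjusted
#' value by default; set `useRawP = TRUE` to filter on the raw p-value.
#'
#' @param records output of [degAnalysis()] (columns `fold_difference` and
#'   `p_value`/`fdr` required).
#' @param pThreshold significance cutoff, strict (`p < pThreshold`);
#'   default 0.05.
#' @param foldThreshold minimum induction fold; default 2.0.
#' @param useRawP filter on `p_value` instead of `fdr`.
#' @return the retained records with an added `induced_phenotype` column
#'   (`"responsive"` or `"nonresponsive"`); an infinite fold counts as
#'   responsive-induced, an undefined (0/0) fold is dropped.
#' @export
degFilter <- function(records, pThreshold = 0.05, foldThreshold = 2.0,
                      useRawP = FALSE) {
  p <- if (useRawP) records$p_value else records$fdr
  fold <- records$fold_difference
  sig <- !is.na(p) & p < pThreshold
  up <- !is.nan(fold) & fold >= foldThreshold
  down <- !is.nan(fold) & fold <= 1 / foldThreshold
  keep <- sig & (up | down)
  out <- records[keep, , drop = FALSE]
  out$induced_phenotype <- ifelse(up[keep], "responsive", "nonresponsive")
  rownames(out) <- NULL
  out
}

#' Per-day DEG counts and average expression
#'
#' Tabulates, for each (day, induced phenotype) cell, the number of genes
#' retained by [degFilter()] and the mean RPKM of those genes in their
#' induced phenotype. Empty cells report a count of 0 and an undefined
#' (`NA`) average.
#'
#' @param filtered output of [degFilter()].
#' @param days days to tabulate; default those present in `filtered` (pass
#'   the full design's days to force zero rows for empty days).
#' @return data.frame with columns `day`, `induced_phenotype`, `n_deg`,
#'   `avg_rpkm`.
#' @export
degSummary <- function(filtered, days = NULL) {
  if (is.null(days)) days <- sort(unique(filtered$day))
  grid <- expand.grid(day = days,
                      induced_phenotype = c("responsive", "nonresponsive"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$day, rev(grid$induced_phenotype)), , drop = FALSE]
  rownames(grid) <- NULL
  grid$n_deg <- 0L
  grid$avg_rpkm <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- filtered$day == grid$day[i] &
      filtered$induced_phenotype == grid$induced_phenotype[i]
    grid$n_deg[i] <- sum(sel)
    if (any(sel)) {
      col <- if (grid$induced_phenotype[i] == "responsive")
        "rpkm_responsive" else "rpkm_nonresponsive"
      grid$avg_rpkm[i] <- mean(filtered[[col]][sel])
    }
  }
  grid
}
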