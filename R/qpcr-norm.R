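#' Per-series reference-gene means
#'
#' Averages each reference gene's absolute quantity across all samples of
#' each explant series. These series means are the denominators of the
#' fractional values from which sample-specific normalization factors are
#' built.
#'
#' @param table a [QuantityTable-class]. Every sample of every series must
#'   carry a measurement for every reference gene.
#' @return data.frame with columns `series`, `gene`, `mean_quantity`
#'   (one row per series x reference gene).
#' @examples
#' qt <- QuantityTable(data.frame(
#'   sample_id = c("s1", "s2"), series = "G6", day = c(0, 3),
#'   gene = "EF1a", role = "reference", quantity = c(100, 300)))
#' seriesReferenceMeans(qt)  # mean 200
#' @export
seriesReferenceMeans <- function(table) {
  stopifnot(is(table, "QuantityTable"))
  d <- as.data.frame(table)
  refs <- referenceGenes(table)
  if (length(refs) == 0)
    stop("QuantityTable contains no reference genes")
  samples <- unique(d[, c("sample_id", "series")])
  ref_rows <- d[d$gene %in% refs & d$role == "reference", , drop = FALSE]
  # every sample must measure every reference gene
  for (g in refs) {
    have <- ref_rows$sample_id[ref_rows$gene == g]
    lack <- setdiff(samples$sample_id, have)
    if (length(lack) > 0)
      stop(sprintf("reference gene '%s' missing in sample(s): %s",
                   g, paste(lack, collapse = ", ")))
  }
  n_per_series <- table(samples$series)
  if (any(n_per_series < 2))
    stop("every series needs >= 2 samples; offending series: ",
         paste(names(n_per_series)[n_per_series < 2], collapse = ", "))
  m <- aggregate(quantity ~ series + gene, data = ref_rows, FUN = mean)
  names(m)[names(m) == "quantity"] <- "mean_quantity"
  if (any(m$mean_quantity == 0))
    stop("zero series mean for reference gene(s): ",
         paste(unique(m$gene[m$mean_quantity == 0]), collapse = ", "),
         " (division impossible)")
  m <- m[order(m$series, m$gene), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Sample-specific normalization factors
#'
#' Computes one dimensionless normalization factor per sample from the
#' reference-gene quantities: each reference quantity is first converted to
#' a fractional value relative to its series average
#' (see [seriesReferenceMeans()]); the fractions of the reference genes are
#' then averaged within each sample. The factor captures the combined
#' technical divergence of the sample (RNA extraction, quantification,
#' reverse transcription) relative to its series, so dividing by it removes
#' sample-preparation scaling while preserving absolute units. Within each
#' series the factors average to exactly 1 when the default arithmetic
#' combination is used.
#'
#' @param table a [QuantityTable-class].
#' @param method how fractions are combined across reference genes:
#'   `"arithmetic"` mean (default) or `"geometric"` mean. Only the
#'   arithmetic mean guarantees a per-series factor mean of exactly 1.
#' @return a [NormalizationFactors-class] object.
#' @examples
#' qt <- QuantityTable(data.frame(
#'   sample_id = rep(c("s1", "s2"), each = 2), series = "G6",
#'   day = rep(c(0, 3), each = 2), gene = rep(c("refA", "refB"), 2),
#'   role = "reference", quantity = c(100, 200, 300, 200)))
#' normFactors(normalizationFactors(qt))  # 0.75, 1.25
#' @export
normalizationFactors <- function(table, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  means <- seriesReferenceMeans(table)
  d <- as.data.frame(table)
  refs <- referenceGenes(table)
  ref_rows <- d[d$gene %in% refs & d$role == "reference", , drop = FALSE]
  key <- paste(ref_rows$series, ref_rows$gene)
  mean_lookup <- setNames(means$mean_quantity, paste(means$series, means$gene))
  frac <- data.frame(sample_id = ref_rows$sample_id,
                     series = ref_rows$series,
                     gene = ref_rows$gene,
                     fraction = ref_rows$quantity / mean_lookup[key],
                     stringsAsFactors = FALSE)
  if (method == "arithmetic") {
    f <- tapply(frac$fraction, frac$sample_id, mean)
  } else {
    if (any(frac$fraction == 0))
      stop("geometric combination undefined with a zero reference fraction")
    f <- tapply(frac$fraction, frac$sample_id, function(v) exp(mean(log(v))))
  }
  if (any(f <= 0))
    stop("zero reference quantity makes the factor undefined in sample(s): ",
         paste(names(f)[f <= 0], collapse = ", "))
  samp <- unique(d[, c("sample_id", "series")])
  series_map <- setNames(samp$series, samp$sample_id)
  new("NormalizationFactors",
      factors = setNames(as.numeric(f), names(f)),
      fractions = frac[order(frac$sample_id, frac$gene), , drop = FALSE],
      series = series_map[names(f)])
}

#' Apply sample-specific normalization
#'
#' Divides every quantity in the table -- targets and the reference genes
#' themselves -- by its sample's normalization factor. Units are preserved
#' (molecules per 10 ng RNA): the procedure removes per-sample technical
#' scaling without collapsing the data to relative fold changes.
#'
#' @param table a [QuantityTable-class].
#' @param factors a [NormalizationFactors-class] covering every sample of
#'   `table` (typically from [normalizationFactors()] on the same table).
#' @return a [QuantityTable-class] with the same schema and normalized
#'   quantities.
#' @examples
#' qt <- QuantityTable(data.frame(
#'   sample_id = rep(c("s1", "s2"), each = 2), series = "G6",
#'   day = rep(c(0, 3), each = 2), gene = rep(c("refA", "TGT"), 2),
#'   role = rep(c("reference", "target"), 2), quantity = c(100, 75, 300, 125)))
#' nf <- normalizationFactors(qt)
#' as.data.frame(applyNormalization(qt, nf))
#' @export
applyNormalization <- function(table, factors) {
  stopifnot(is(table, "QuantityTable"), is(factors, "NormalizationFactors"))
  d <- as.data.frame(table)
  f <- normFactors(factors)
  lack <- setdiff(unique(d$sample_id), names(f))
  if (length(lack) > 0)
    stop("no normalization factor for sample(s): ",
         paste(lack, collapse = ", "))
  d$quantity <- d$quantity / f[d$sample_id]
  QuantityTable(d)
}

#' Reference-gene divergence summary
#'
#' Summarizes the spread of the sample-specific normalization factors as
#' percentages: the minimum and maximum factor x 100 and the half-range
#' `(max - min) / 2`, a conservative "roughly +/- x%" statement of the
#' technical variance the normalization removes.
#'
#' @param factors a [NormalizationFactors-class] (or a bare numeric vector
#'   of factors).
#' @return list with `min_percent`, `max_percent`, `half_range_percent`.
#' @examples
#' divergenceSummary(c(0.67, 1.0, 1.35))  # 67, 135, +/- 34
#' @export
divergenceSummary <- function(factors) {
  f <- if (is(factors, "NormalizationFactors")) normFactors(factors)
       else as.numeric(factors)
  if (length(f) == 0) stop("no factors to summarize")
  if (any(!is.finite(f)) || any(f <= 0)) stop("factors must be finite and > 0")
  lo <- min(f) * 100
  hi <- max(f) * 100
  list(min_percent = lo, max_percent = hi,
       half_range_percent = (hi - lo) / 2)
}
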