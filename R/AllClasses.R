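#' QuantityTable: absolute transcript quantities per sample and gene
#'
#' Long-format container for absolute qPCR quantities (molecules per 10 ng
#' total RNA). Each row is one (sample, gene) measurement; samples carry a
#' series label (the explant series they belong to) and an induction day.
#' Genes are flagged as `reference` or `target`: reference genes drive the
#' sample-specific normalization, targets are only normalized.
#'
#' @slot data data.frame with columns `sample_id`, `series`, `day`,
#'   `gene`, `role` (`"reference"` or `"target"`) and `quantity`
#'   (non-negative, molecules per 10 ng RNA).
#'
#' @seealso [normalizationFactors()], [applyNormalization()],
#'   [readQuantityTable()]
#' @export
setClass("QuantityTable", representation(data = "data.frame"))

.qt_columns <- c("sample_id", "series", "day", "gene", "role", "quantity")

setValidity("QuantityTable", function(object) {
  d <- object@data
  missing_cols <- setdiff(.qt_columns, names(d))
  if (length(missing_cols) > 0)
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (!is.numeric(d$quantity))
    return("quantity must be numeric")
  if (any(!is.finite(d$quantity)) || any(d$quantity < 0))
    return("quantities must be finite and non-negative")
  if (!all(d$role %in% c("reference", "target")))
    return("role must be 'reference' or 'target'")
  if (anyDuplicated(d[, c("sample_id", "gene")]) > 0)
    return("duplicated (sample_id, gene) measurement")
  n_series <- tapply(d$series, d$sample_id, function(s) length(unique(s)))
  if (any(n_series > 1))
    return(paste("sample in more than one series:",
                 paste(names(n_series)[n_series > 1], collapse = ", ")))
  TRUE
})

#' Construct a QuantityTable
#'
#' @param data data.frame with columns `sample_id`, `series`, `day`, `gene`,
#'   `role`, `quantity`. Character-like columns are coerced to character.
#' @return A [QuantityTable-class] object.
#' @examples
#' qt <- QuantityTable(data.frame(
#'   sample_id = c("s1", "s2"), series = "G6", day = c(0, 3),
#'   gene = "EF1a", role = "reference", quantity = c(100, 300)))
#' @export
QuantityTable <- function(data) {
  data <- as.data.frame(data)
  for (col in c("sample_id", "series", "gene", "role"))
    if (col %in% names(data)) data[[col]] <- as.character(data[[col]])
  if ("day" %in% names(data)) data$day <- as.numeric(data$day)
  rownames(data) <- NULL
  new("QuantityTable", data = data[, .qt_columns, drop = FALSE])
}

#' @describeIn QuantityTable underlying data.frame
#' @param x,object a QuantityTable
#' @param ... unused
#' @export
setMethod("as.data.frame", "QuantityTable", function(x, ...) x@data)

#' @describeIn QuantityTable number of measurements
#' @export
setMethod("length", "QuantityTable", function(x) nrow(x@data))

setMethod("show", "QuantityTable", function(object) {
  d <- object@data
  cat("QuantityTable:", nrow(d), "measurements;",
      length(unique(d$sample_id)), "samples in",
      length(unique(d$series)), "series;",
      sum(tapply(d$role, d$gene, `[`, 1) == "reference"), "reference and",
      sum(tapply(d$role, d$gene, `[`, 1) == "target"), "target genes\n")
  cat("  units: molecules per 10 ng total RNA\n")
})

#' Sample and gene accessors for QuantityTable
#'
#' @param x a [QuantityTable-class]
#' @return `sampleIds`: character vector of sample identifiers;
#'   `referenceGenes`: character vector of genes with role `"reference"`.
#' @export
sampleIds <- function(x) unique(x@data$sample_id)

#' @rdname sampleIds
#' @export
referenceGenes <- function(x) unique(x@data$gene[x@data$role == "reference"])

#' NormalizationFactors: per-sample normalization factors
#'
#' One dimensionless factor per sample, computed from reference-gene
#' fractional divergence relative to the sample series average
#' (see [normalizationFactors()]). The per-sample, per-reference fractional
#' values are retained for diagnostics. By construction the factors of each
#' series average to exactly 1.
#'
#' @slot factors named numeric, sample_id -> factor (> 0).
#' @slot fractions data.frame with columns `sample_id`, `series`, `gene`,
#'   `fraction`: each reference gene's quantity divided by its series mean.
#' @slot series named character, sample_id -> series label.
#' @export
setClass("NormalizationFactors",
         representation(factors = "numeric", fractions = "data.frame",
                        series = "character"))

setValidity("NormalizationFactors", function(object) {
  if (is.null(names(object@factors)) || anyDuplicated(names(object@factors)))
    return("factors must be uniquely named by sample_id")
  if (any(!is.finite(object@factors)) || any(object@factors <= 0))
    return("all factors must be finite and > 0")
  if (!identical(sort(names(object@factors)), sort(names(object@series))))
    return("factors and series must cover the same samples")
  TRUE
})

#' @describeIn NormalizationFactors named numeric vector of factors
#' @param x,object a NormalizationFactors object
#' @export
normFactors <- function(x) x@factors

#' @describeIn NormalizationFactors per-sample per-reference fractions
#' @export
refFractions <- function(x) x@fractions

setMethod("show", "NormalizationFactors", function(object) {
  f <- object@factors
  cat("NormalizationFactors:", length(f), "samples in",
      length(unique(object@series)), "series\n")
  cat(sprintf("  range %.3f - %.3f (per-series mean = 1 by construction)\n",
              min(f), max(f)))
})

#' TrimPolicy: positional read-trimming rules
#'
#' The cleaning rules applied to mapped-library reads after adapter removal:
#' the first `headTrim` bases are removed (low-quality 5' ends), reads are
#' capped at `maxLength` bases, and any read left shorter than `minLength`
#' is discarded.
#'
#' @slot minLength integer, minimum retained read length in bases (default 20).
#' @slot headTrim integer, bases removed from the 5' end (default 15).
#' @slot maxLength integer, maximum retained length in bases; batch-dependent
#'   (205 for one sequencing batch, 170 for another).
#' @seealso [trimReads()]
#' @export
setClass("TrimPolicy",
         representation(minLength = "integer", headTrim = "integer",
                        maxLength = "integer"))

setValidity("TrimPolicy", function(object) {
  if (length(object@minLength) != 1 || object@minLength < 1)
    return("minLength must be a single integer >= 1")
  if (length(object@headTrim) != 1 || object@headTrim < 0)
    return("headTrim must be a single integer >= 0")
  if (length(object@maxLength) != 1 || object@maxLength <= object@minLength)
    return("maxLength must be a single integer > minLength")
  TRUE
})

#' @rdname TrimPolicy-class
#' @param minLength,headTrim,maxLength see slots
#' @export
trimPolicy <- function(minLength = 20, headTrim = 15, maxLength = 205) {
  new("TrimPolicy", minLength = as.integer(minLength),
      headTrim = as.integer(headTrim), maxLength = as.integer(maxLength))
}

setMethod("show", "TrimPolicy", function(object) {
  cat(sprintf(
    "TrimPolicy: drop 5' %d bases, cap at %d bases, discard reads < %d bases\n",
    object@headTrim, object@maxLength, object@minLength))
})
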