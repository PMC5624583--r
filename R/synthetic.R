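#' Configuration for the synthetic absolute-qPCR generator
#'
#' Describes an induction-series qPCR experiment with known ground truth:
#' explant series sampled at fixed induction days, stable reference genes, a
#' set of target genes with parameterized true profiles, per-sample
#' multiplicative technical scaling (what sample-specific normalization is
#' meant to remove) and multiplicative measurement error.
#'
#' Target profile shapes:
#' \describe{
#'   \item{flat}{constant at `baseline` over all days.}
#'   \item{late_induced}{geometric ramp from `baseline` on the first day to
#'     `baseline * peakFold` on the last day (dehydrin-like late induction).}
#'   \item{early_transient}{zero at day 0, `baseline * peakFold` at the
#'     first positive day, halving at each subsequent sampled day, and zero
#'     from day 15 onward (expressed during the first two weeks only, like
#'     the most strongly early-induced de novo transcript).}
#' }
#'
#' The optional `assoc` column plants series structure: `"responsiveness"`
#' multiplies the first series label (the responsive series) by `assocFold`;
#' `"genotype"` multiplies the first two labels (the two series of the
#' responsive genotype) by `assocFold`; `"none"` leaves all series equal.
#' `seriesLabels` order is therefore (responsive, its nonresponsive
#' same-genotype sibling, other genotypes...).
#'
#' @slot seriesLabels explant series names; default
#'   `c("G6", "G6NR", "G2", "G12")`.
#' @slot days strictly increasing induction days; default `c(0, 3, 7, 15, 21)`.
#' @slot nReferenceGenes number of stable reference genes (>= 1, default 2).
#' @slot targetProfiles data.frame with columns `gene`, `shape`, `baseline`
#'   (molecules per 10 ng RNA, > 0), `peakFold` (>= 1), `assoc`, `assocFold`.
#' @slot techScaleSigma sd of the log technical scale factor; the default
#'   0.16 makes factors over twenty samples typically span about 0.67-1.35.
#' @slot measurementCV fractional multiplicative measurement error
#'   (default 0.25, the accuracy of the absolute quantification method).
#' @slot seed integer RNG seed.
#' @export
setClass("QpcrSimConfig",
         representation(seriesLabels = "character", days = "numeric",
                        nReferenceGenes = "integer",
                        targetProfiles = "data.frame",
                        techScaleSigma = "numeric", measurementCV = "numeric",
                        seed = "integer"))

setValidity("QpcrSimConfig", function(object) {
  if (length(object@days) < 2 || any(diff(object@days) <= 0))
    return("days: must be strictly increasing (>= 2 days)")
  if (object@nReferenceGenes < 1)
    return("nReferenceGenes: must be >= 1")
  tp <- object@targetProfiles
  need <- c("gene", "shape", "baseline", "peakFold", "assoc", "assocFold")
  if (!all(need %in% names(tp)))
    return(paste("targetProfiles: missing column(s)",
                 paste(setdiff(need, names(tp)), collapse = ", ")))
  if (!all(tp$shape %in% c("flat", "late_induced", "early_transient")))
    return("targetProfiles$shape: must be flat, late_induced or early_transient")
  if (any(tp$baseline <= 0))
    return("targetProfiles$baseline: must be > 0")
  if (any(tp$peakFold < 1) || any(tp$assocFold < 1))
    return("targetProfiles: peakFold and assocFold must be >= 1")
  if (!all(tp$assoc %in% c("none", "responsiveness", "genotype")))
    return("targetProfiles$assoc: must be none, responsiveness or genotype")
  if (object@techScaleSigma < 0)
    return("techScaleSigma: must be >= 0")
  if (object@measurementCV < 0)
    return("measurementCV: must be >= 0")
  TRUE
})

.default_targets <- function() {
  data.frame(
    gene = c("TGT_flat", "TGT_late", "TGT_early"),
    shape = c("flat", "late_induced", "early_transient"),
    baseline = c(500, 200, 36),
    peakFold = c(1, 10, 10),
    assoc = "none", assocFold = 1,
    stringsAsFactors = FALSE)
}

#' @rdname QpcrSimConfig-class
#' @param seriesLabels,days,nReferenceGenes,targetProfiles,techScaleSigma,measurementCV,seed
#'   see slots; `targetProfiles = NULL` uses one flat, one late-induced and
#'   one early-transient target at defaults.
#' @export
qpcrSimConfig <- function(seriesLabels = c("G6", "G6NR", "G2", "G12"),
                          days = c(0, 3, 7, 15, 21),
                          nReferenceGenes = 2,
                          targetProfiles = NULL,
                          techScaleSigma = 0.16,
                          measurementCV = 0.25,
                          seed = 1L) {
  if (is.null(targetProfiles)) targetProfiles <- .default_targets()
  targetProfiles <- as.data.frame(targetProfiles)
  if (!"assoc" %in% names(targetProfiles)) targetProfiles$assoc <- "none"
  if (!"assocFold" %in% names(targetProfiles)) targetProfiles$assocFold <- 1
  new("QpcrSimConfig", seriesLabels = as.character(seriesLabels),
      days = as.numeric(days), nReferenceGenes = as.integer(nReferenceGenes),
      targetProfiles = targetProfiles,
      techScaleSigma = as.numeric(techScaleSigma),
      measurementCV = as.numeric(measurementCV), seed = as.integer(seed))
}

setMethod("show", "QpcrSimConfig", function(object) {
  cat("QpcrSimConfig:", length(object@seriesLabels), "series x",
      length(object@days), "days;", object@nReferenceGenes,
      "reference genes,", nrow(object@targetProfiles), "targets;",
      sprintf("tech sigma %.3g, measurement CV %.3g, seed %d\n",
              object@techScaleSigma, object@measurementCV, object@seed))
})

# true noise-free quantity of one target gene at one day
.profile_value <- function(shape, baseline, peakFold, day, days) {
  switch(shape,
    flat = baseline,
    late_induced = baseline *
      peakFold^((day - days[1]) / (max(days) - days[1])),
    early_transient = {
      window <- days[days > 0 & days < 15]
      if (!(day %in% window)) 0
      else baseline * peakFold * 0.5^(match(day, window) - 1)
    },
    stop("unknown profile shape: ", shape))
}

.assoc_multiplier <- function(assoc, assocFold, series, seriesLabels) {
  induced <- switch(assoc,
    none = character(0),
    responsiveness = seriesLabels[1],
    genotype = seriesLabels[1:2])
  ifelse(series %in% induced, assocFold, 1)
}

# multiplicative lognormal noise with unit mean and fractional sd = cv
.mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic absolute-qPCR quantity table with ground truth
#'
#' Builds one sample per series x day. Reference genes are flat (stable) at
#' fixed baselines; targets follow the configured profile shapes and series
#' associations. The observed quantity is
#' `true profile x sample technical scale x measurement noise`, with the
#' technical scale log-normal and mean-centered in log space (multiplicative
#' sample-preparation error) and the measurement noise multiplicative
#' log-normal at the configured CV with unit mean. Fully deterministic given
#' the config seed.
#'
#' @param config a [QpcrSimConfig-class] from [qpcrSimConfig()].
#' @return list with elements `table` (a [QuantityTable-class]) and `truth`
#'   (list: `techScale` named per-sample factor, `trueQuantities` noise-free
#'   long table, `config`).
#' @examples
#' sim <- simulateQpcrData(qpcrSimConfig(seed = 7))
#' sim$table
#' @export
simulateQpcrData <- function(config) {
  stopifnot(is(config, "QpcrSimConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)

  grid <- expand.grid(series = config@seriesLabels, day = config@days,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$series, config@seriesLabels), grid$day), ]
  grid$sample_id <- sprintf("%s_d%g", grid$series, grid$day)
  n_samp <- nrow(grid)
  tech <- setNames(exp(rnorm(n_samp, 0, config@techScaleSigma)),
                   grid$sample_id)

  refs <- data.frame(gene = sprintf("REF%d", seq_len(config@nReferenceGenes)),
                     role = "reference",
                     baseline = 10000 * 0.7^(seq_len(config@nReferenceGenes) - 1),
                     stringsAsFactors = FALSE)
  tp <- config@targetProfiles

  rows <- list()
  for (i in seq_len(n_samp)) {
    s <- grid$series[i]; d <- grid$day[i]; id <- grid$sample_id[i]
    tq_ref <- refs$baseline
    tq_tgt <- vapply(seq_len(nrow(tp)), function(j)
      .profile_value(tp$shape[j], tp$baseline[j], tp$peakFold[j], d,
                     config@days) *
      .assoc_multiplier(tp$assoc[j], tp$assocFold[j], s, config@seriesLabels),
      numeric(1))
    rows[[i]] <- data.frame(
      sample_id = id, series = s, day = d,
      gene = c(refs$gene, tp$gene),
      role = c(refs$role, rep("target", nrow(tp))),
      true_quantity = c(tq_ref, tq_tgt),
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  noise <- .mult_noise(nrow(long), config@measurementCV)
  long$quantity <- long$true_quantity * tech[long$sample_id] * noise

  table <- QuantityTable(long[, c("sample_id", "series", "day", "gene",
                                  "role", "quantity")])
  truth <- list(
    techScale = tech,
    trueQuantities = long[, c("sample_id", "series", "day", "gene", "role",
                              "true_quantity")],
    config = config)
  list(table = table, truth = truth)
}

#' Configuration for the synthetic RNA-seq count generator
#'
#' Describes a two-phenotype induction-series RNA-seq design (responsive vs
#' nonresponsive explants, several collection days, biological replicates)
#' with negative-binomial counts and a planted set of differentially
#' expressed genes.
#'
#' @slot nGenes number of genes.
#' @slot lengthRange gene length bounds in bases (> 0).
#' @slot groups the two phenotype labels; default
#'   `c("responsive", "nonresponsive")`.
#' @slot nReplicates biological replicates per phenotype x day (default 3).
#' @slot days collection days; default `c(3, 7, 15, 21)`.
#' @slot librarySizeRange bounds on total mapped reads per sample.
#' @slot deFraction fraction of genes truly DE, in `[0, 1]`.
#' @slot foldRange true fold-change bounds for DE genes (>= 1; the study's
#'   filter convention makes >= 2 the interesting region).
#' @slot dispersion NB dispersion (default 0.1); 0 requests Poisson
#'   sampling, flagged in the truth metadata.
#' @slot seed integer RNG seed.
#' @export
setClass("RnaseqSimConfig",
         representation(nGenes = "integer", lengthRange = "numeric",
                        groups = "character", nReplicates = "integer",
                        days = "numeric", librarySizeRange = "numeric",
                        deFraction = "numeric", foldRange = "numeric",
                        dispersion = "numeric", seed = "integer"))

setValidity("RnaseqSimConfig", function(object) {
  if (object@nGenes < 1) return("nGenes: must be >= 1")
  if (length(object@lengthRange) != 2 || any(object@lengthRange <= 0) ||
      object@lengthRange[1] > object@lengthRange[2])
    return("lengthRange: need positive bounds lo <= hi")
  if (length(object@groups) != 2) return("groups: exactly two labels")
  if (object@nReplicates < 1) return("nReplicates: must be >= 1")
  if (object@deFraction < 0 || object@deFraction > 1)
    return("deFraction: must be in [0, 1]")
  if (length(object@foldRange) != 2 || any(object@foldRange < 1) ||
      object@foldRange[1] > object@foldRange[2])
    return("foldRange: need bounds 1 <= lo <= hi")
  if (object@dispersion < 0) return("dispersion: must be >= 0")
  if (length(object@librarySizeRange) != 2 ||
      any(object@librarySizeRange <= 0) ||
      object@librarySizeRange[1] > object@librarySizeRange[2])
    return("librarySizeRange: need positive bounds lo <= hi")
  TRUE
})

#' @rdname RnaseqSimConfig-class
#' @param nGenes,lengthRange,groups,nReplicates,days,librarySizeRange,deFraction,foldRange,dispersion,seed
#'   see slots.
#' @export
rnaseqSimConfig <- function(nGenes = 2000, lengthRange = c(300, 3000),
                            groups = c("responsive", "nonresponsive"),
                            nReplicates = 3, days = c(3, 7, 15, 21),
                            librarySizeRange = c(8e5, 1.2e6),
                            deFraction = 0.1, foldRange = c(2, 8),
                            dispersion = 0.1, seed = 1L) {
  new("RnaseqSimConfig", nGenes = as.integer(nGenes),
      lengthRange = as.numeric(lengthRange), groups = as.character(groups),
      nReplicates = as.integer(nReplicates), days = as.numeric(days),
      librarySizeRange = as.numeric(librarySizeRange),
      deFraction = as.numeric(deFraction), foldRange = as.numeric(foldRange),
      dispersion = as.numeric(dispersion), seed = as.integer(seed))
}

setMethod("show", "RnaseqSimConfig", function(object) {
  cat("RnaseqSimConfig:", object@nGenes, "genes;",
      paste(object@groups, collapse = " vs "), "x",
      length(object@days), "days x", object@nReplicates, "replicates;",
      sprintf("DE fraction %.3g in folds [%.3g, %.3g], dispersion %.3g, seed %d\n",
              object@deFraction, object@foldRange[1], object@foldRange[2],
              object@dispersion, object@seed))
})

#' Sample manifest for an RNA-seq simulation design
#'
#' Expands the design into one row per sample: phenotype x day x replicate
#' (e.g. 2 phenotypes x 4 days x 3 replicates = 24 samples at defaults).
#'
#' @param config a [RnaseqSimConfig-class].
#' @return data.frame with columns `sample_id`, `phenotype`, `day`,
#'   `replicate`.
#' @export
sampleManifest <- function(config) {
  stopifnot(is(config, "RnaseqSimConfig"))
  grid <- expand.grid(replicate = seq_len(config@nReplicates),
                      day = config@days, phenotype = config@groups,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("phenotype", "day", "replicate")]
  grid$sample_id <- sprintf("%s_d%g_r%d", substr(grid$phenotype, 1, 4),
                            grid$day, grid$replicate)
  grid[, c("sample_id", "phenotype", "day", "replicate")]
}

#' Generate a synthetic RNA-seq count matrix with ground truth
#'
#' Draws per-gene relative expression levels (log-normal, normalized to sum
#' to 1 at baseline), plants `deFraction` of the genes as differentially
#' expressed with true folds uniform in `foldRange` (elevated in the
#' responsive phenotype at every day), and samples counts NB with mean
#' `library size x relative expression x fold` at the configured
#' dispersion. Non-DE genes therefore have exactly equal means in the two
#' phenotypes; the induced phenotype's expected total exceeds its nominal
#' library size by the planted excess, as in real libraries.
#' `dispersion = 0` substitutes Poisson sampling, flagged as
#' `truth$poisson`. Deterministic given the seed.
#'
#' @param config a [RnaseqSimConfig-class] from [rnaseqSimConfig()].
#' @return list with `se` (SummarizedExperiment from [makeCountSE()]:
#'   assay `counts`, rowData `length`, colData the [sampleManifest()]) and
#'   `truth` (list: `deGenes` named logical, `foldChange` named numeric
#'   (1 for non-DE), `inducedPhenotype`, `librarySizes`, `poisson`,
#'   `config`).
#' @export
simulateCountData <- function(config) {
  stopifnot(is(config, "RnaseqSimConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)

  genes <- sprintf("gene_%05d", seq_len(config@nGenes))
  lengths <- setNames(
    round(runif(config@nGenes, config@lengthRange[1], config@lengthRange[2])),
    genes)
  manifest <- sampleManifest(config)
  lib <- setNames(round(runif(nrow(manifest), config@librarySizeRange[1],
                              config@librarySizeRange[2])),
                  manifest$sample_id)

  rel <- rlnorm(config@nGenes, meanlog = 0, sdlog = 1.2)
  rel <- rel / sum(rel)
  n_de <- round(config@deFraction * config@nGenes)
  de <- setNames(rep(FALSE, config@nGenes), genes)
  if (n_de > 0) de[sample.int(config@nGenes, n_de)] <- TRUE
  fold <- setNames(rep(1, config@nGenes), genes)
  fold[de] <- runif(n_de, config@foldRange[1], config@foldRange[2])
  induced <- config@groups[1]  # responsive phenotype carries the induction

  counts <- matrix(0L, config@nGenes, nrow(manifest),
                   dimnames = list(genes, manifest$sample_id))
  poisson <- config@dispersion == 0
  for (j in seq_len(nrow(manifest))) {
    f <- if (manifest$phenotype[j] == induced) fold else rep(1, config@nGenes)
    mu <- lib[j] * rel * f
    counts[, j] <- if (poisson) rpois(config@nGenes, mu)
                   else rnbinom(config@nGenes, mu = mu,
                                size = 1 / config@dispersion)
  }
  se <- makeCountSE(counts, lengths,
                    manifest[, c("phenotype", "day", "replicate")])
  truth <- list(deGenes = de, foldChange = fold, inducedPhenotype = induced,
                librarySizes = lib, poisson = poisson, config = config)
  list(se = se, truth = truth)
}

#' Generate random FASTQ reads
#'
#' Random-base reads with a constant quality string (Phred+33 "I", Q40),
#' lengths uniform over `lengthRange`. Intended as a seeded fixture source
#' for [trimReads()].
#'
#' @param nReads number of reads (0 gives an empty set).
#' @param lengthRange integer length bounds in bases (positive).
#' @param seed integer RNG seed.
#' @return a [Biostrings::QualityScaledDNAStringSet] named `read_1`, ...
#' @export
simulateReads <- function(nReads, lengthRange = c(20, 250), seed = 1L) {
  if (length(lengthRange) != 2 || any(lengthRange < 1) ||
      lengthRange[1] > lengthRange[2])
    stop("lengthRange: need positive bounds lo <= hi")
  if (nReads < 0) stop("nReads must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  lens <- if (nReads == 0) integer(0)
          else round(runif(nReads, lengthRange[1], lengthRange[2]))
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  quals <- vapply(lens, function(L) strrep("I", L), character(1))
  nm <- if (nReads == 0) character(0) else sprintf("read_%d", seq_len(nReads))
  Biostrings::QualityScaledDNAStringSet(
    setNames(Biostrings::DNAStringSet(seqs), nm),
    Biostrings::PhredQuality(setNames(Biostrings::BStringSet(quals), nm)))
}
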