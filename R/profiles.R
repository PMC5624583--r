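#' Build normalized time-course expression profiles
#'
#' Produces one expression profile per (gene, series): the normalized
#' quantity trajectory over the induction days. When several samples share a
#' (series, day) -- replicates -- their normalized quantities are averaged
#' before profile construction.
#'
#' @param table a [QuantityTable-class].
#' @param factors optional [NormalizationFactors-class]; when supplied the
#'   table is normalized with [applyNormalization()] first. Pass `NULL` to
#'   profile raw quantities.
#' @return data.frame with columns `gene`, `series`, `day`, `quantity`,
#'   ordered by gene, series and day.
#' @export
buildProfiles <- function(table, factors = NULL) {
  stopifnot(is(table, "QuantityTable"))
  if (!is.null(factors)) table <- applyNormalization(table, factors)
  d <- as.data.frame(table)
  # every gene must be measured in every sample
  genes <- unique(d$gene)
  samples <- unique(d$sample_id)
  have <- table(factor(d$gene, genes), factor(d$sample_id, samples))
  if (any(have == 0)) {
    gaps <- which(have == 0, arr.ind = TRUE)
    msg <- paste(sprintf("(%s, %s)", genes[gaps[, 1]], samples[gaps[, 2]]),
                 collapse = ", ")
    stop("missing (gene, sample) measurements: ", msg)
  }
  prof <- aggregate(quantity ~ gene + series + day, data = d, FUN = mean)
  prof <- prof[order(prof$gene, prof$series, prof$day), , drop = FALSE]
  rownames(prof) <- NULL
  prof[, c("gene", "series", "day", "quantity")]
}

.profile_vector <- function(p) {
  # accept a buildProfiles() subset or a (day, quantity) data.frame
  stopifnot(all(c("day", "quantity") %in% names(p)))
  p <- p[order(p$day), , drop = FALSE]
  setNames(p$quantity, p$day)
}

#' Distance between two expression profiles
#'
#' Mean absolute log2 ratio across the shared day grid:
#' `mean(|log2((qa + eps) / (qb + eps))|)`. The pseudocount `eps` keeps the
#' ratio defined when a transcript is undetectable (zero molecules) at some
#' day. The distance is a pseudometric on profiles over the same day grid:
#' non-negative, symmetric, zero iff the profiles are identical, and
#' satisfying the triangle inequality.
#'
#' @param a,b data.frames with columns `day` and `quantity` (e.g. subsets of
#'   [buildProfiles()] output for one gene and one series each). Day grids
#'   must match exactly.
#' @param pseudocount added to both quantities before the ratio; default 1
#'   molecule per 10 ng RNA.
#' @return non-negative scalar in log2 units (1 = average 2-fold separation).
#' @export
profileDistance <- function(a, b, pseudocount = 1) {
  va <- .profile_vector(a)
  vb <- .profile_vector(b)
  if (length(va) != length(vb) ||
      !isTRUE(all.equal(as.numeric(names(va)), as.numeric(names(vb)))))
    stop("profiles are on different day grids")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(va + pseudocount <= 0) || any(vb + pseudocount <= 0))
    stop("all quantities must be positive after pseudocount handling")
  mean(abs(log2((va + pseudocount) / (vb + pseudocount))))
}

#' Classify a gene as responsiveness- or genotype-associated
#'
#' Formalizes the comparison of responsive vs nonresponsive explant series.
#' Two clonal series of the same genotype that differ in induction
#' responsiveness (e.g. G6 vs G6NR) isolate responsiveness from genotype:
#' a gene whose profiles separate between them is responsiveness-associated.
#' Otherwise, if the responsive series separates from the nonresponsive
#' *genotypes* (e.g. G6 vs G2 and G6 vs G12 on average), differential
#' expression is attributed to genotype-specific factors. Profiles that stay
#' within the threshold everywhere are called `"none"`.
#'
#' @param profiles [buildProfiles()] output (or any data.frame with columns
#'   `gene`, `series`, `day`, `quantity`).
#' @param gene gene to classify; must be profiled in all four series.
#' @param responsive,responsiveNR the responsive series and its
#'   nonresponsive same-genotype sibling (defaults `"G6"`, `"G6NR"`).
#' @param otherGenotypes the nonresponsive genotype series
#'   (default `c("G2", "G12")`).
#' @param threshold decision threshold in log2 units; the default 1.0
#'   (2-fold) follows the convention that expression differences should
#'   exceed one fold to be considered biologically meaningful.
#' @param pseudocount passed to [profileDistance()].
#' @return list with `gene`, `call` (`"responsiveness_associated"`,
#'   `"genotype_associated"` or `"none"`), `within_genotype_distance`
#'   (responsive vs sibling), `between_genotype_distance` (mean of
#'   responsive vs each nonresponsive genotype) and `threshold`.
#' @export
classifyAssociation <- function(profiles, gene,
                                responsive = "G6", responsiveNR = "G6NR",
                                otherGenotypes = c("G2", "G12"),
                                threshold = 1.0, pseudocount = 1) {
  need <- c(responsive, responsiveNR, otherGenotypes)
  p <- profiles[profiles$gene == gene, , drop = FALSE]
  lack <- setdiff(need, unique(p$series))
  if (length(lack) > 0)
    stop(sprintf("gene '%s' has no profile for series: %s",
                 gene, paste(lack, collapse = ", ")))
  grab <- function(s) p[p$series == s, , drop = FALSE]
  within <- profileDistance(grab(responsive), grab(responsiveNR), pseudocount)
  between <- mean(vapply(otherGenotypes, function(s)
    profileDistance(grab(responsive), grab(s), pseudocount), numeric(1)))
  call <- if (within > threshold) "responsiveness_associated"
          else if (between > threshold) "genotype_associated"
          else "none"
  list(gene = gene, call = call,
       within_genotype_distance = unname(within),
       between_genotype_distance = unname(between),
       threshold = threshold)
}
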