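#' Read and write absolute-quantity tables
#'
#' TSV with header columns `sample_id`, `series`, `day`, `gene`, `role`,
#' `quantity` (tab-separated, UTF-8, `.` decimal separator).
#'
#' @param path file path.
#' @return `readQuantityTable`: a [QuantityTable-class].
#' @export
readQuantityTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.qt_columns, names(d))
  if (length(miss) > 0)
    stop("quantity table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  QuantityTable(d)
}

#' @rdname readQuantityTable
#' @param table a [QuantityTable-class]
#' @export
writeQuantityTable <- function(table, path) {
  stopifnot(is(table, "QuantityTable"))
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read RNA-seq count data from TSV files
#'
#' Assembles a SummarizedExperiment from three tab-separated files:
#' a gene x sample count matrix (first column `gene`), a gene annotation
#' (`gene`, `length` in bases), and a sample sheet (`sample_id`,
#' `phenotype`, `day`, `replicate`).
#'
#' @param countsPath,annotationPath,samplesPath file paths.
#' @return SummarizedExperiment, as from [makeCountSE()].
#' @export
readCountData <- function(countsPath, annotationPath, samplesPath) {
  ct <- read.delim(countsPath, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(ct)[1] != "gene")
    stop("counts file ", countsPath, ": first column must be 'gene'")
  m <- as.matrix(ct[, -1, drop = FALSE])
  rownames(m) <- ct$gene
  ann <- read.delim(annotationPath, stringsAsFactors = FALSE)
  if (!all(c("gene", "length") %in% names(ann)))
    stop("annotation file needs columns gene, length")
  ss <- read.delim(samplesPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phenotype", "day", "replicate") %in% names(ss)))
    stop("sample sheet needs columns sample_id, phenotype, day, replicate")
  if (!setequal(ss$sample_id, colnames(m)))
    stop("sample sheet and count matrix name different samples")
  ss <- ss[match(colnames(m), ss$sample_id), , drop = FALSE]
  makeCountSE(m, setNames(ann$length, ann$gene),
              ss[, c("phenotype", "day", "replicate")])
}

#' Positional FASTQ read trimming
#'
#' Applies the fixed cleaning rules to each read, in this order: remove the
#' first `headTrim` bases from the 5' end, truncate to `maxLength` bases,
#' then discard the read if fewer than `minLength` bases remain. Quality
#' strings are trimmed identically, so sequence and quality lengths always
#' stay equal and the output has at most as many records as the input.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (e.g. from
#'   [readFastq()] or [simulateReads()]).
#' @param policy a [TrimPolicy-class]; default `trimPolicy()`
#'   (drop < 20 bases, remove first 15 bases, cap at 205 bases).
#' @return the trimmed reads, same class as the input.
#' @examples
#' r <- simulateReads(5, c(10, 250), seed = 1)
#' trimReads(r, trimPolicy(20, 15, 205))
#' @export
trimReads <- function(reads, policy = trimPolicy()) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"), is(policy, "TrimPolicy"))
  if (length(reads) == 0) return(reads)
  w <- Biostrings::width(reads)
  start <- pmin(policy@headTrim + 1L, w + 1L)
  end <- pmin(w, policy@headTrim + policy@maxLength)
  end <- pmax(end, start - 1L)  # allow empty (fully trimmed) reads
  trimmed <- IRanges::narrow(reads, start = start, end = end)
  trimmed[Biostrings::width(trimmed) >= policy@minLength]
}

#' Read and write FASTQ
#'
#' Thin wrappers over Biostrings' quality-aware FASTQ support; qualities are
#' interpreted as Phred+33.
#'
#' @param path file path.
#' @return `readFastq`: a [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on this path
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' @rdname readFastq
#' @param reads a [Biostrings::QualityScaledDNAStringSet]
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Genomic DNA contamination check
#'
#' RNA preparations are accepted only when the measured genomic copy number
#' is strictly below the threshold (default: fewer than 5 genomes per 10 ng
#' total RNA).
#'
#' @param genomesPer10ng measured genome copies per 10 ng RNA (>= 0).
#' @param threshold acceptance threshold; strict (`<`).
#' @return list with `genomes_per_10ng`, `threshold`, `pass`.
#' @examples
#' gdnaCheck(4)$pass   # TRUE
#' gdnaCheck(5)$pass   # FALSE
#' @export
gdnaCheck <- function(genomesPer10ng, threshold = 5) {
  if (length(genomesPer10ng) != 1 || !is.finite(genomesPer10ng) ||
      genomesPer10ng < 0)
    stop("genomesPer10ng must be a single value >= 0")
  list(genomes_per_10ng = genomesPer10ng, threshold = threshold,
       pass = genomesPer10ng < threshold)
}

#' Filter assembly contigs by minimum length
#'
#' Retains contigs at least `minLength` bases long (inclusive), preserving
#' input order. Accepts an in-memory set or a FASTA path.
#'
#' @param contigs a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param minLength minimum retained contig length in bases (default 500).
#' @return a [Biostrings::DNAStringSet] of the retained contigs.
#' @export
filterContigs <- function(contigs, minLength = 500) {
  if (is.character(contigs)) contigs <- Biostrings::readDNAStringSet(contigs)
  stopifnot(is(contigs, "DNAStringSet"))
  contigs[Biostrings::width(contigs) >= minLength]
}
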