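#' MethylationExperiment: per-CpG bisulfite call container
#'
#' An S4 container for targeted bisulfite sequencing calls, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are CpG
#' dinucleotides (width-2 `GRanges` on the plus strand), columns are samples.
#' Two integer assays hold the methylated (`meth`) and total (`total`) read
#' counts; the beta value (methylated fraction) is derived on demand and is
#' `NA` wherever no reads were observed, never 0.
#'
#' Missing data are explicit throughout: after [coverageFilter()] a cell
#' that fails the depth cutoff carries `NA` counts, so that downstream
#' "measurable" logic (group signatures, promoter records) can distinguish
#' unmethylated from unmeasured.
#'
#' @slot .. inherits all slots from `RangedSummarizedExperiment`.
#'
#' @seealso [MethylationExperiment()] for construction, [betaValues()],
#'   [coverageFilter()], [testCpGs()].
#' @export
setClass("MethylationExperiment",
         contains = "RangedSummarizedExperiment")

.validMethylationExperiment <- function(object) {
  msg <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("meth", "total") %in% a))
    msg <- c(msg, "assays 'meth' and 'total' are required")
  else {
    m <- SummarizedExperiment::assay(object, "meth")
    n <- SummarizedExperiment::assay(object, "total")
    bad <- which(!is.na(m) & !is.na(n) & m > n)
    if (length(bad))
      msg <- c(msg, sprintf("%d cell(s) with meth > total (first at index %d)",
                            length(bad), bad[1]))
    if (any(m[!is.na(m)] < 0) || any(n[!is.na(n)] < 0))
      msg <- c(msg, "read counts must be non-negative")
    if (xor(anyNA(m), anyNA(n)) ||
        (anyNA(m) && !identical(is.na(m), is.na(n))))
      msg <- c(msg, "'meth' and 'total' must share the same missing cells")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    if (!all(BiocGenerics::width(rr) == 2L))
      msg <- c(msg, "CpG sites must have width 2 (the CG dinucleotide)")
    ord <- order(GenomicRanges::seqnames(rr), BiocGenerics::start(rr))
    if (!identical(ord, seq_along(rr)))
      msg <- c(msg, "CpG sites must be sorted by position")
    if (anyDuplicated(paste(GenomicRanges::seqnames(rr),
                            BiocGenerics::start(rr))))
      msg <- c(msg, "CpG site positions must be strictly increasing")
  }
  if (!"cohort" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'cohort' column")
  if (length(msg)) msg else TRUE
}

setValidity("MethylationExperiment", .validMethylationExperiment)

#' Construct a MethylationExperiment
#'
#' @param meth,total Integer matrices (CpG sites x samples) of methylated and
#'   total read counts. `NA` marks an unmeasured cell; `meth` and `total`
#'   must be `NA` together.
#' @param sites A `GRanges` of CpG dinucleotides (width 2, sorted, plus
#'   strand convention: the first base is the C of a plus-strand CG). A
#'   numeric vector of 0-based C positions together with `chrom` is also
#'   accepted.
#' @param sampleInfo A `data.frame` with one row per sample carrying at
#'   least a `cohort` column and optionally a `group` column (insulinoma
#'   sub-group label); row order matches the columns of `meth`.
#' @param chrom Chromosome name used when `sites` is a position vector.
#'
#' @return A [MethylationExperiment-class] object.
#' @examples
#' sites <- GenomicRanges::GRanges("chr11", IRanges::IRanges(c(101, 201), width = 2))
#' me <- MethylationExperiment(
#'   meth  = matrix(c(3L, 5L, 0L, 8L), 2),
#'   total = matrix(c(10L, 10L, 4L, 8L), 2),
#'   sites = sites,
#'   sampleInfo = data.frame(cohort = c("beta", "insulinoma"))
#' )
#' betaValues(me)
#' @export
MethylationExperiment <- function(meth, total, sites, sampleInfo,
                                  chrom = "chr11") {
  if (is.numeric(sites) && !methods::is(sites, "GRanges"))
    sites <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = sites + 1L, width = 2L))
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  storage.mode(meth) <- "integer"
  storage.mode(total) <- "integer"
  if (is.null(sampleInfo$sample))
    sampleInfo$sample <- if (!is.null(colnames(meth))) colnames(meth) else
      sprintf("S%02d", seq_len(ncol(meth)))
  ord <- order(GenomicRanges::seqnames(sites), BiocGenerics::start(sites))
  if (!identical(ord, seq_along(sites))) {
    sites <- sites[ord]
    meth <- meth[ord, , drop = FALSE]
    total <- total[ord, , drop = FALSE]
  }
  if (is.null(S4Vectors::mcols(sites)$site_id))
    S4Vectors::mcols(sites)$site_id <- seq_along(sites)
  colnames(meth) <- colnames(total) <- sampleInfo$sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, total = total),
    rowRanges = sites,
    colData = S4Vectors::DataFrame(sampleInfo, row.names = sampleInfo$sample))
  methods::new("MethylationExperiment", se)
}

#' @describeIn MethylationExperiment Methylated read counts (sites x samples).
#' @param x A `MethylationExperiment`.
#' @export
methReads <- function(x) SummarizedExperiment::assay(x, "meth")

#' @describeIn MethylationExperiment Total read counts (sites x samples).
#' @export
totalReads <- function(x) SummarizedExperiment::assay(x, "total")

#' @describeIn MethylationExperiment Beta values (methylated fraction);
#'   `NA` where no reads were observed.
#' @export
betaValues <- function(x) {
  m <- methReads(x)
  n <- totalReads(x)
  b <- m / n
  b[!is.na(n) & n == 0L] <- NA_real_
  b
}

#' @describeIn MethylationExperiment Cohort label per sample.
#' @export
cohorts <- function(x) as.character(SummarizedExperiment::colData(x)$cohort)

#' @describeIn MethylationExperiment Sub-group label per sample (`NA` when
#'   none was assigned).
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% colnames(cd)) as.character(cd$group)
  else rep(NA_character_, ncol(x))
}

#' @describeIn MethylationExperiment CpG sites as a width-2 `GRanges`.
#' @export
cpgSites <- function(x) SummarizedExperiment::rowRanges(x)

#' Apply the minimum sequencing depth filter
#'
#' Cells with fewer than `minDepth` total reads are set to missing (`NA`),
#' never to zero, so that they are excluded from every downstream mean,
#' test and "measurable" check. The default of 5x is the conventional
#' depth floor for targeted bisulfite calls.
#'
#' @param x A [MethylationExperiment-class].
#' @param minDepth Minimum total reads per cell (default 5).
#' @return A filtered `MethylationExperiment` of identical dimensions.
#' @seealso [measurableSites()] for the per-cohort measurability flags.
#' @export
coverageFilter <- function(x, minDepth = 5L) {
  .assertScalarNum(minDepth, "minDepth", lo = 1)
  m <- methReads(x)
  n <- totalReads(x)
  drop <- is.na(n) | n < minDepth
  m[drop] <- NA_integer_
  n[drop] <- NA_integer_
  SummarizedExperiment::assay(x, "meth") <- m
  SummarizedExperiment::assay(x, "total") <- n
  S4Vectors::metadata(x)$minDepth <- minDepth
  x
}

#' Per-cohort measurability of each CpG
#'
#' A site is measurable in a cohort when at least one of that cohort's
#' samples retains reads after [coverageFilter()]. Sites missing in all
#' samples of a cohort are "not measurable" there and are excluded from
#' cohort summaries rather than treated as zero.
#'
#' @param x A [MethylationExperiment-class].
#' @return A logical matrix, sites x cohorts.
#' @export
measurableSites <- function(x) {
  b <- betaValues(x)
  ch <- cohorts(x)
  sapply(unique(ch), function(cc)
    rowSums(!is.na(b[, ch == cc, drop = FALSE])) > 0L)
}

setMethod("show", "MethylationExperiment", function(object) {
  cat(sprintf("MethylationExperiment: %d CpG sites x %d samples\n",
              nrow(object), ncol(object)))
  ch <- table(cohorts(object))
  cat("  cohorts:", paste(sprintf("%s (%d)", names(ch), ch), collapse = ", "),
      "\n")
  md <- S4Vectors::metadata(object)$minDepth
  if (!is.null(md)) cat(sprintf("  coverage-filtered at %dx\n", md))
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr))
    cat(sprintf("  span: %s:%d-%d\n",
                as.character(GenomicRanges::seqnames(rr)[1]),
                min(BiocGenerics::start(rr)) - 1L,
                max(BiocGenerics::end(rr))))
  invisible(NULL)
})
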