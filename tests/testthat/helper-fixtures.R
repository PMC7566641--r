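## Shared fixtures and independent brute-force oracles.

## tiny MethylationExperiment built in code
toyExperiment <- function(meth, total, pos0 = NULL, cohort = NULL,
                          group = NULL, chrom = "chr11") {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  if (is.null(pos0)) pos0 <- seq(100, by = 50, length.out = nrow(meth))
  if (is.null(cohort))
    cohort <- rep(c("beta", "insulinoma"), length.out = ncol(meth))
  si <- data.frame(cohort = cohort)
  if (!is.null(group)) si$group <- group
  MethylationExperiment(meth, total, pos0, si, chrom = chrom)
}

## width-2 CpG sites from 0-based C positions
cpgAt <- function(pos0) GenomicRanges::GRanges(
  "chr11", IRanges::IRanges(pos0 + 1, width = 2))

## random GRanges for oracle comparisons
randomRanges <- function(n, span = 10000, maxLen = 300, chrom = "chrT") {
  s <- sample.int(span, n, replace = TRUE)
  w <- sample.int(maxLen, n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = s, width = w))
}

## O(n^2) all-pairs overlap oracle (half-open arithmetic on 0-based coords)
bruteIntersect <- function(a, b) {
  as <- BiocGenerics::start(a) - 1; ae <- BiocGenerics::end(a)
  bs <- BiocGenerics::start(b) - 1; be <- BiocGenerics::end(b)
  out <- NULL
  for (i in seq_along(a)) for (j in seq_along(b)) {
    ov <- min(ae[i], be[j]) - max(as[i], bs[j])
    if (ov > 0) out <- rbind(out, c(i, j, ov))
  }
  if (is.null(out)) data.frame(a_idx = integer(), b_idx = integer(),
                               overlap = integer())
  else data.frame(a_idx = out[, 1], b_idx = out[, 2], overlap = out[, 3])
}

## naive O(n) CG scan of a character sequence
bruteCgScan <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  which(ch[-length(ch)] == "C" & ch[-1] == "G")
}

## per-base membership oracle for covered length of sites within a class
bruteCoveredBp <- function(sites, classGr) {
  bp <- unique(unlist(lapply(seq_along(classGr), function(i)
    seq(BiocGenerics::start(classGr)[i], BiocGenerics::end(classGr)[i]))))
  sum(vapply(seq_along(sites), function(i)
    sum(seq(BiocGenerics::start(sites)[i],
            BiocGenerics::end(sites)[i]) %in% bp), numeric(1)))
}
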