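#' Merge significant CpGs into differentially methylated regions
#'
#' Chains significant CpGs whose successive positions lie within
#' `bandwidth` bp of each other; chains with at least `minCpgs`
#' constituents become DMRs spanning first to last constituent (+1 bp,
#' half-open). A DMR is retained only when the maximum FDR among its
#' constituents stays below `maxFdr`, so a DMR can never contain a
#' non-significant constituent.
#'
#' @param results Output of [testCpGs()].
#' @param bandwidth Maximum gap between chained CpGs in bp (default 1000,
#'   the kernel bandwidth conventionally used for smoothed DMR calling).
#' @param minCpgs Minimum constituent count (default 3).
#' @param maxFdr Retention cutoff on the maximum constituent FDR
#'   (default 0.005).
#' @return A `GRanges` of DMRs with `nCpgs`, `maxFdr`, `meanDelta`,
#'   `direction` (majority of constituent directions, mean-delta sign on
#'   ties) and `sites` (comma-separated constituent ids).
#' @export
callDMRs <- function(results, bandwidth = 1000, minCpgs = 3,
                     maxFdr = 0.005) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  if (!nrow(sig)) return(GenomicRanges::GRanges())
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  newChain <- c(TRUE, diff(sig$pos) > bandwidth |
                  sig$chrom[-1] != sig$chrom[-nrow(sig)])
  chain <- cumsum(newChain)
  keep <- which(tabulate(chain) >= minCpgs)
  out <- GenomicRanges::GRanges()
  for (k in keep) {
    rows <- sig[chain == k, , drop = FALSE]
    if (max(rows$fdr) >= maxFdr) next
    nHyper <- sum(rows$direction == "hyper")
    nHypo <- sum(rows$direction == "hypo")
    dir <- if (nHyper > nHypo) "hyper" else if (nHypo > nHyper) "hypo"
           else if (mean(rows$delta) >= 0) "hyper" else "hypo"
    gr <- GenomicRanges::GRanges(
      rows$chrom[1],
      ## 0-based [first, last + 1): 1-based inclusive first+1 .. last+1
      IRanges::IRanges(start = min(rows$pos) + 1L, end = max(rows$pos) + 1L))
    S4Vectors::mcols(gr)$nCpgs <- nrow(rows)
    S4Vectors::mcols(gr)$maxFdr <- max(rows$fdr)
    S4Vectors::mcols(gr)$meanDelta <- mean(rows$delta)
    S4Vectors::mcols(gr)$direction <- dir
    S4Vectors::mcols(gr)$sites <- paste(rows$site_id, collapse = ",")
    out <- c(out, gr)
  }
  out
}
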