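#' Count significant CpGs per window, split by direction
#'
#' Partitions the significant CpGs of a differential test across the
#' window grid (half-open rule: a CpG whose C position equals a window
#' start belongs to that window). The counts over all windows sum to the
#' total number of significant sites.
#'
#' @param results Output of [testCpGs()].
#' @param grid Window `GRanges` from [makeWindows()].
#' @return A `data.frame` with `window`, `start`, `end`, `nHypo`,
#'   `nHyper`.
#' @export
windowSigCounts <- function(results, grid) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  pts <- GenomicRanges::GRanges(sig$chrom,
                                IRanges::IRanges(sig$pos + 1L, width = 1L))
  w <- GenomicRanges::findOverlaps(pts, grid, select = "first")
  nW <- length(grid)
  data.frame(window = S4Vectors::mcols(grid)$window,
             start = BiocGenerics::start(grid) - 1L,
             end = BiocGenerics::end(grid),
             nHypo = tabulate(w[sig$direction == "hypo"], nW),
             nHyper = tabulate(w[sig$direction == "hyper"], nW))
}

#' Call contiguous hypo-/hypermethylated regions
#'
#' Seed windows carry a count of one direction above the `pct`th
#' percentile of that direction's distribution across all windows
#' (zero-count windows included) and at least `purity` of their
#' significant CpGs in that direction. Seeds of the same direction
#' separated by at most one sub-threshold window are merged. Region
#' coordinates are determined from the DMRs: boundaries snap to the
#' outermost endpoints of same-direction DMRs overlapping the merged
#' window span, and when a DMR set is supplied a candidate with no
#' overlapping same-direction DMR is dropped (isolated significant CpGs
#' cannot define region coordinates). When no DMR set is given, window
#' edges are used as a fallback.
#'
#' @param counts Output of [windowSigCounts()].
#' @param dmrs `GRanges` from [callDMRs()] (may be empty).
#' @param chrom Chromosome of the window grid.
#' @param pct Seed percentile (default 95).
#' @param purity Minimum direction fraction (default 0.75).
#' @return A `GRanges` of regions with `direction`, `windows`
#'   (comma-separated supporting window ids), `nHypo`, `nHyper`,
#'   `purity`.
#' @export
callRegions <- function(counts, dmrs = GenomicRanges::GRanges(),
                        chrom = "chr11", pct = 95, purity = 0.75) {
  out <- GenomicRanges::GRanges()
  for (dir in c("hypo", "hyper")) {
    own <- if (dir == "hypo") counts$nHypo else counts$nHyper
    other <- if (dir == "hypo") counts$nHyper else counts$nHypo
    thr <- .pctl(own, pct)
    frac <- ifelse(own + other > 0, own / (own + other), 0)
    seed <- which(own > thr & frac >= purity)
    if (!length(seed)) next
    ## merge seeds separated by at most one sub-threshold window
    grpBreak <- c(TRUE, diff(seed) > 2)
    grp <- cumsum(grpBreak)
    for (g in unique(grp)) {
      wins <- seed[grp == g]
      ws <- counts$start[min(wins)]
      we <- counts$end[max(wins)]
      span <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(ws + 1L, we))
      snap <- span
      if (length(dmrs)) {
        od <- dmrs[S4Vectors::mcols(dmrs)$direction == dir &
                     IRanges::overlapsAny(dmrs, span)]
        if (!length(od)) next  # no DMR support: no coordinates
        snap <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(min(BiocGenerics::start(od)),
                                  max(BiocGenerics::end(od))))
      }
      nh <- sum(counts$nHypo[wins])
      ny <- sum(counts$nHyper[wins])
      S4Vectors::mcols(snap)$direction <- dir
      S4Vectors::mcols(snap)$windows <- paste(counts$window[wins],
                                              collapse = ",")
      S4Vectors::mcols(snap)$nHypo <- nh
      S4Vectors::mcols(snap)$nHyper <- ny
      S4Vectors::mcols(snap)$purity <- max(nh, ny) / max(nh + ny, 1)
      out <- c(out, snap)
    }
  }
  BiocGenerics::sort(out)
}
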