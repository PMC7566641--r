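## Transcription-regulator binding-site enrichment.
##
## Each binding site is scored by the fraction of its nucleotides covered
## by CpG dinucleotides (each CpG covers 2 bp, clipped at site
## boundaries, unioned so adjacent CpGs never double count). Per-TR
## scores are summed over sites and ranked; comparing the ranking against
## all CpGs with the ranking against only the significant differentially
## methylated CpGs, normalized for list size, yields the enrichment rank
## change. Together with the per-TR cumulative differential methylation
## this places every TR on the rank-change x methylation plane, where the
## 5th/95th percentile corners single out the strongly over-/under-
## enriched, hypo-/hypermethylated regulators.

#' CpG coverage fraction of a binding site
#'
#' Covered bases are the union over constituent CpGs of their 2 bp
#' dinucleotide clipped to the site; the fraction is covered bp over
#' site length.
#'
#' @param sites `GRanges` of binding sites.
#' @param cpgs `GRanges` of CpG sites (width 2).
#' @return Numeric vector of coverage fractions, one per site.
#' @export
siteCpGCoverage <- function(sites, cpgs) {
  red <- GenomicRanges::reduce(GenomicRanges::granges(cpgs),
                               ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(sites, red, ignore.strand = TRUE)
  covered <- rep(0, length(sites))
  if (length(hits)) {
    w <- BiocGenerics::width(IRanges::pintersect(
      GenomicRanges::ranges(sites)[S4Vectors::queryHits(hits)],
      GenomicRanges::ranges(red)[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(agg))] <- agg
  }
  covered / BiocGenerics::width(sites)
}

#' Score and rank TRs by summed CpG coverage of their sites
#'
#' Per TR, the enrichment score is the sum over its binding sites of the
#' coverage fraction against the supplied CpG subset. TRs are ranked in
#' descending score order with average ranks on ties; TRs scoring 0 are
#' excluded from the ranked list (the list size is recorded).
#'
#' @param trSites `GRanges` with a `tr` metadata column.
#' @param cpgs CpG `GRanges` to score against (all CpGs for the
#'   baseline, significant CpGs for the differential list).
#' @param expressed Optional character vector restricting the TR
#'   universe to expressed regulators.
#' @return A `data.frame` with `tr`, `score`, `rank`, and attribute
#'   `N` (ranked-list size).
#' @export
trScores <- function(trSites, cpgs, expressed = NULL) {
  if (!is.null(expressed))
    trSites <- trSites[S4Vectors::mcols(trSites)$tr %in% expressed]
  if (!length(trSites)) stop("empty TR site set")
  cov <- siteCpGCoverage(trSites, cpgs)
  sc <- tapply(cov, S4Vectors::mcols(trSites)$tr, sum)
  sc <- sc[sc > 0]
  out <- data.frame(tr = names(sc), score = as.numeric(sc))
  out$rank <- rank(-out$score, ties.method = "average")
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- nrow(out)
  out
}

#' Normalized enrichment rank change between two TR rankings
#'
#' `deltaR = rank_baseline/N0 - rank_significant/N1`, the size-normalized
#' rank shift between scoring against all CpGs and scoring against the
#' significant set; positive values mean the TR rose in the significant
#' list (over-enrichment). TRs absent from the significant list get an
#' undefined `deltaR` and are flagged as under-enrichment candidates
#' only.
#'
#' @param baseline,significant Outputs of [trScores()] over the same TR
#'   universe.
#' @return A `data.frame` with `tr`, `score0`, `rank0`, `score1`,
#'   `rank1`, `deltaR`, `absentFromSignificant`.
#' @export
rankChange <- function(baseline, significant) {
  n0 <- attr(baseline, "N")
  n1 <- attr(significant, "N")
  m <- match(baseline$tr, significant$tr)
  data.frame(tr = baseline$tr,
             score0 = baseline$score, rank0 = baseline$rank,
             score1 = significant$score[m], rank1 = significant$rank[m],
             deltaR = baseline$rank / n0 - significant$rank[m] / n1,
             absentFromSignificant = is.na(m))
}

#' Per-TR cumulative differential methylation
#'
#' Each binding site's methylation change is the mean delta over its
#' significant constituent CpGs; the TR's cumulative methylation is the
#' mean over sites that have at least one significant constituent
#' (a mean of site means, not a pooled mean). TRs with no qualifying site
#' are undefined and stay unclassified.
#'
#' @param trSites `GRanges` with a `tr` column.
#' @param results Output of [testCpGs()].
#' @return A named numeric vector of per-TR mean deltas.
#' @export
trCumulativeMethylation <- function(trSites, results) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$pos + 1L, width = 2L))
  hits <- GenomicRanges::findOverlaps(trSites, gr, ignore.strand = TRUE)
  siteMean <- rep(NA_real_, length(trSites))
  if (length(hits)) {
    agg <- tapply(sig$delta[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
    siteMean[as.integer(names(agg))] <- agg
  }
  trs <- S4Vectors::mcols(trSites)$tr
  out <- tapply(siteMean, trs, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  stats::setNames(as.numeric(out), names(out))
}

#' Classify TRs on the rank-change x methylation plane
#'
#' Cutoffs are the 5th and 95th percentiles of `deltaR` and of `deltaM`
#' across records. A full class (`over-enriched+hyper`,
#' `over-enriched+hypo`, `under-enriched+hyper`, `under-enriched+hypo`)
#' requires both dimensions strictly beyond a cutoff; single-dimension
#' exceedances are labeled in `rankClass`/`methClass` for peak-category
#' maps; everything else is `unclassified`. Degenerate all-equal records
#' classify nothing.
#'
#' @param records Output of [rankChange()] with a `deltaM` column added
#'   (see [trEnrichmentAnalysis()]).
#' @param pctLo,pctHi Percentile cutoffs (defaults 5 and 95).
#' @return `records` with `rankClass`, `methClass` and `class` columns.
#' @export
classifyTRs <- function(records, pctLo = 5, pctHi = 95) {
  rLo <- .pctl(records$deltaR, pctLo)
  rHi <- .pctl(records$deltaR, pctHi)
  mLo <- .pctl(records$deltaM, pctLo)
  mHi <- .pctl(records$deltaM, pctHi)
  rankClass <- ifelse(is.na(records$deltaR), NA_character_,
                      ifelse(records$deltaR > rHi, "over-enriched",
                             ifelse(records$deltaR < rLo, "under-enriched",
                                    NA_character_)))
  methClass <- ifelse(is.na(records$deltaM), NA_character_,
                      ifelse(records$deltaM > mHi, "hyper",
                             ifelse(records$deltaM < mLo, "hypo",
                                    NA_character_)))
  records$rankClass <- rankClass
  records$methClass <- methClass
  records$class <- ifelse(!is.na(rankClass) & !is.na(methClass),
                          paste(rankClass, methClass, sep = "+"),
                          "unclassified")
  records
}

#' Full TR enrichment analysis
#'
#' Convenience wrapper: baseline and significant-set scoring, rank
#' change, cumulative methylation, and percentile classification.
#'
#' @param trSites `GRanges` with a `tr` column.
#' @param cpgs All CpG sites (`GRanges`).
#' @param results Output of [testCpGs()].
#' @param expressed Optional expressed-TR filter.
#' @param pctLo,pctHi Classification percentiles.
#' @return The classified records `data.frame` (one row per baseline TR).
#' @export
trEnrichmentAnalysis <- function(trSites, cpgs, results, expressed = NULL,
                                 pctLo = 5, pctHi = 95) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  sigGr <- GenomicRanges::GRanges(sig$chrom,
                                  IRanges::IRanges(sig$pos + 1L, width = 2L))
  base <- trScores(trSites, cpgs, expressed)
  sigScores <- trScores(trSites, sigGr, expressed)
  rec <- rankChange(base, sigScores)
  dm <- trCumulativeMethylation(trSites, results)
  rec$deltaM <- unname(dm[rec$tr])
  classifyTRs(rec, pctLo, pctHi)
}

#' Map differentially methylated TR sites onto targets
#'
#' Per TR and target interval (called regions or element-catalog
#' classes), counts binding sites overlapping the target split by the
#' site's methylation direction (the sign of its mean delta over
#' significant constituents), plus the per-TR fraction of sites that are
#' differentially methylated at all.
#'
#' @param trSites `GRanges` with a `tr` column.
#' @param results Output of [testCpGs()].
#' @param targets A `GRanges` of target intervals (a `name` or
#'   `direction` column is carried through as the target label).
#' @return A list with `perTarget` (tr x target counts) and `perTR`
#'   (`tr`, `nSites`, `nDiffSites`, `fracDiff`, `nHypoSites`,
#'   `nHyperSites`).
#' @export
mapTRSites <- function(trSites, results, targets) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$pos + 1L, width = 2L))
  hits <- GenomicRanges::findOverlaps(trSites, gr, ignore.strand = TRUE)
  siteMean <- rep(NA_real_, length(trSites))
  if (length(hits)) {
    agg <- tapply(sig$delta[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
    siteMean[as.integer(names(agg))] <- agg
  }
  dir <- ifelse(is.na(siteMean), NA_character_,
                ifelse(siteMean < 0, "hypo", "hyper"))
  trs <- S4Vectors::mcols(trSites)$tr
  labels <- S4Vectors::mcols(targets)$name
  if (is.null(labels)) labels <- S4Vectors::mcols(targets)$direction
  if (is.null(labels)) labels <- sprintf("target%d", seq_along(targets))
  labels <- make.unique(as.character(labels))
  perTarget <- do.call(rbind, lapply(seq_along(targets), function(i) {
    inT <- IRanges::overlapsAny(trSites, targets[i], ignore.strand = TRUE)
    do.call(rbind, lapply(unique(trs), function(tt) {
      sel <- inT & trs == tt
      data.frame(tr = tt, target = labels[i], nSites = sum(sel),
                 nHypoSites = sum(sel & dir %in% "hypo"),
                 nHyperSites = sum(sel & dir %in% "hyper"))
    }))
  }))
  perTR <- do.call(rbind, lapply(unique(trs), function(tt) {
    sel <- trs == tt
    nd <- sum(sel & !is.na(dir))
    data.frame(tr = tt, nSites = sum(sel), nDiffSites = nd,
               fracDiff = nd / sum(sel),
               nHypoSites = sum(sel & dir %in% "hypo"),
               nHyperSites = sum(sel & dir %in% "hyper"))
  }))
  list(perTarget = perTarget, perTR = perTR)
}

#' Overlay a 4C loop-score track on per-window TR-site counts
#'
#' Loop scores stay at their native coordinates (they are never
#' window-averaged or otherwise normalized); each in-region score is
#' annotated with the window it falls in and joined, read-only, against
#' the per-window counts. Scores outside the region are dropped with a
#' message.
#'
#' @param loopScores `GRanges` with a `score` column (positions within
#'   the region).
#' @param windowCounts Per-window `data.frame` (e.g. TR-site counts).
#' @param grid Window `GRanges`.
#' @param region Analysis region.
#' @return A list with `loops` (`pos`, `score`, `window`) and `windows`
#'   (the input counts, unchanged).
#' @export
overlayLoopScores <- function(loopScores, windowCounts, grid, region) {
  inR <- IRanges::overlapsAny(loopScores, region)
  if (any(!inR))
    message(sprintf("dropped %d loop score(s) outside the region",
                    sum(!inR)))
  ls <- loopScores[inR]
  w <- GenomicRanges::findOverlaps(ls, grid, select = "first")
  list(loops = data.frame(pos = BiocGenerics::start(ls) - 1L,
                          score = S4Vectors::mcols(ls)$score,
                          window = w),
       windows = windowCounts)
}
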