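#' Tile an analysis region into fixed-width windows
#'
#' Windows tile the region without gaps or overlaps; the final window is
#' truncated when the region length is not a multiple of `width`. Tiling
#' the 1.35 Mbp target span at the default 10 kbp yields 135 windows.
#'
#' @param region A `GRanges` of length 1 (see [regionInterval()]).
#' @param width Window width in bp (default 10,000).
#' @return A `GRanges` of windows with a `window` index column.
#' @examples
#' length(makeWindows(regionInterval("chr11", 1850000, 3200000)))  # 135
#' @export
makeWindows <- function(region, width = 10000) {
  .assertScalarNum(width, "width", lo = 1)
  rlen <- BiocGenerics::width(region)[1]
  if (width > rlen)
    warning("window width exceeds region length; returning a single window")
  starts <- seq(BiocGenerics::start(region)[1],
                BiocGenerics::end(region)[1], by = width)
  ends <- pmin(starts + width - 1, BiocGenerics::end(region)[1])
  gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(region))[1],
    IRanges::IRanges(starts, ends))
  S4Vectors::mcols(gr)$window <- seq_along(gr)
  gr
}

## window index of each CpG by its C position (half-open rule: a site whose
## C falls on a window start belongs to that window)
.siteWindow <- function(sites, grid) {
  pts <- GenomicRanges::resize(sites, width = 1, fix = "start")
  hits <- GenomicRanges::findOverlaps(pts, grid, select = "first")
  hits
}

#' Per-window cohort methylation with confidence intervals
#'
#' The per-window point estimate pools every measurable (sample, site)
#' beta value of the cohort's samples in the window (x100 to percent);
#' the 95% confidence interval is t-based across per-sample window means,
#' which is what the interval shading of a profile plot represents.
#' Windows with no measurable CpG are missing, not 0.
#'
#' @param me A [MethylationExperiment-class] (coverage-filtered).
#' @param grid Window `GRanges` from [makeWindows()].
#' @param cohort Cohort label to summarize.
#' @return A `data.frame` with `window`, `start`, `end`, `mean`, `ciLo`,
#'   `ciHi` (percent scale), `nCpG`.
#' @export
windowMethylation <- function(me, grid, cohort) {
  ch <- cohorts(me)
  if (!cohort %in% ch) stop(sprintf("no samples in cohort '%s'", cohort))
  b <- betaValues(me)[, ch == cohort, drop = FALSE]
  w <- .siteWindow(cpgSites(me), grid)
  out <- data.frame(window = S4Vectors::mcols(grid)$window,
                    start = BiocGenerics::start(grid) - 1L,
                    end = BiocGenerics::end(grid),
                    mean = NA_real_, ciLo = NA_real_, ciHi = NA_real_,
                    nCpG = 0L)
  for (i in seq_along(grid)) {
    rows <- which(w == i)
    if (!length(rows)) next
    cells <- b[rows, , drop = FALSE]
    vals <- cells[!is.na(cells)]
    out$nCpG[i] <- length(rows)
    if (!length(vals)) next
    out$mean[i] <- mean(vals) * 100
    perSample <- colMeans(cells, na.rm = TRUE)
    perSample <- perSample[is.finite(perSample)]
    if (length(perSample) >= 2) {
      se <- stats::sd(perSample) / sqrt(length(perSample))
      tq <- stats::qt(0.975, df = length(perSample) - 1)
      mu <- mean(perSample) * 100
      out$ciLo[i] <- mu - tq * se * 100
      out$ciHi[i] <- mu + tq * se * 100
    }
  }
  out
}

#' Per-window normalized ATAC score
#'
#' Per sample, each peak score is normalized to that sample's total
#' signal across the analysis region; per window the maximum normalized
#' score is taken (0 when the sample has no peak there) and averaged over
#' samples. Taking the maximum rather than the sum prevents dilution of
#' the signal by the many low-intensity peaks that surround a few strong
#' ones.
#'
#' @param peaks `GRanges` of peaks with `score` and `sample` columns.
#' @param grid Window `GRanges`.
#' @param region Analysis region; peaks outside are ignored and the
#'   per-sample totals are region-restricted.
#' @return A `data.frame` with `window` and `atac`.
#' @export
windowAtac <- function(peaks, grid, region) {
  peaks <- IRanges::subsetByOverlaps(peaks, region)
  ids <- unique(S4Vectors::mcols(peaks)$sample)
  if (!length(ids)) stop("no ATAC peaks within the region")
  mat <- matrix(0, nrow = length(grid), ncol = length(ids),
                dimnames = list(NULL, ids))
  for (s in ids) {
    p <- peaks[S4Vectors::mcols(peaks)$sample == s]
    tot <- sum(S4Vectors::mcols(p)$score)
    if (!is.finite(tot) || tot <= 0)
      stop(sprintf("all-zero ATAC signal for sample '%s'", s))
    norm <- S4Vectors::mcols(p)$score / tot
    hits <- GenomicRanges::findOverlaps(p, grid)
    for (h in seq_along(hits)) {
      wi <- S4Vectors::subjectHits(hits)[h]
      mat[wi, s] <- max(mat[wi, s], norm[S4Vectors::queryHits(hits)[h]])
    }
  }
  data.frame(window = S4Vectors::mcols(grid)$window,
             atac = rowMeans(mat))
}

#' Pearson correlation between two per-window profiles
#'
#' Pairwise-complete Pearson correlation; missing windows are dropped
#' from both profiles rather than imputed.
#'
#' @param x,y Numeric vectors of per-window values.
#' @return A list with `r`, `p` (two-sided) and `n` (windows used).
#' @export
profileCorrelation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  n <- sum(keep)
  if (n < 3) stop("need at least 3 paired non-missing windows")
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
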