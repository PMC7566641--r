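## Per-CpG differential methylation testing.
##
## The test is a beta-binomial likelihood-ratio test of a shared vs a
## cohort-specific methylation proportion with a common per-site
## dispersion. The dispersion is estimated by method of moments from the
## within-cohort scatter of the per-sample methylated fractions and then
## shrunk 50/50 toward the across-site median, which stabilizes the
## per-site estimate at small sample sizes the same way kernel-based
## differential methylation tools shrink their dispersions.

## beta-binomial log-likelihood per site, cells with n = 0 contribute 0
.bbLoglik <- function(y, n, p, rho) {
  th <- (1 - rho) / rho
  a <- p * th
  b <- (1 - p) * th
  ll <- lbeta(y + a, n - y + b) - lbeta(a, b)
  rowSums(ll)
}

#' Beta-binomial differential methylation test per CpG
#'
#' For every testable CpG (at least `minSamples` samples with reads in
#' each cohort), fits a shared and a cohort-specific beta-binomial
#' methylation proportion under a common method-of-moments dispersion
#' (shrunk 50/50 toward the across-site median) and reports the
#' likelihood-ratio statistic against a chi-squared null with one degree
#' of freedom, with Benjamini-Hochberg FDR across the tested sites.
#' Untestable sites are reported as untested, not as p = 1.
#'
#' The per-cohort mean beta is the read-pooled proportion (total
#' methylated over total reads), matching the proportion the likelihood
#' is maximized over; `delta` is case minus control in fraction units and
#' its sign defines the hypo/hyper direction of significant sites.
#'
#' @param me A coverage-filtered [MethylationExperiment-class].
#' @param control,case Cohort labels (defaults `"beta"`, `"insulinoma"`).
#' @param fdrThreshold Significance cutoff on BH FDR (default 0.005).
#' @param shrink Weight of the per-site dispersion against the across-site
#'   median (default 0.5).
#' @param minSamples Minimum informative samples per cohort for a site to
#'   be testable (default 2).
#' @return A `data.frame` with one row per CpG: `site_id`, `chrom`, `pos`
#'   (0-based C position), `meanControl`, `meanCase`, `delta`, `stat`,
#'   `p`, `fdr`, `significant`, `direction` (`"hypo"`/`"hyper"` for
#'   significant sites), `tested`.
#' @export
testCpGs <- function(me, control = "beta", case = "insulinoma",
                     fdrThreshold = 0.005, shrink = 0.5, minSamples = 2) {
  ch <- cohorts(me)
  if (!all(c(control, case) %in% ch))
    stop("both cohorts must be present in the data")
  y <- methReads(me)
  n <- totalReads(me)
  ## missing cells contribute nothing: y = n = 0 zeroes their likelihood
  y[is.na(y)] <- 0L
  n[is.na(n)] <- 0L
  gc1 <- ch == control
  gc2 <- ch == case
  inform1 <- rowSums(n[, gc1, drop = FALSE] > 0)
  inform2 <- rowSums(n[, gc2, drop = FALSE] > 0)
  tested <- inform1 >= minSamples & inform2 >= minSamples
  sumY1 <- rowSums(y[, gc1, drop = FALSE]); sumN1 <- rowSums(n[, gc1, drop = FALSE])
  sumY2 <- rowSums(y[, gc2, drop = FALSE]); sumN2 <- rowSums(n[, gc2, drop = FALSE])
  eps <- 1e-6
  p1 <- .clamp(sumY1 / pmax(sumN1, 1L), eps, 1 - eps)
  p2 <- .clamp(sumY2 / pmax(sumN2, 1L), eps, 1 - eps)
  p0 <- .clamp((sumY1 + sumY2) / pmax(sumN1 + sumN2, 1L), eps, 1 - eps)

  ## method-of-moments dispersion from within-cohort scatter of beta-hats
  rhoCohort <- function(idx, pc) {
    nn <- n[, idx, drop = FALSE]
    bb <- y[, idx, drop = FALSE] / nn          # NaN where n = 0
    bb[nn == 0] <- NA
    m <- rowSums(!is.na(bb))
    v <- rowSums((bb - pc)^2, na.rm = TRUE) / pmax(m - 1, 1)
    v[m < 2] <- NA
    invn <- rowMeans(ifelse(nn > 0, 1 / nn, NA), na.rm = TRUE)
    (v / (pc * (1 - pc)) - invn) / (1 - invn)
  }
  r1 <- rhoCohort(gc1, p1)
  r2 <- rhoCohort(gc2, p2)
  w1 <- pmax(inform1 - 1, 0)
  w2 <- pmax(inform2 - 1, 0)
  den <- w1 * as.numeric(!is.na(r1)) + w2 * as.numeric(!is.na(r2))
  rho <- (w1 * ifelse(is.na(r1), 0, r1) + w2 * ifelse(is.na(r2), 0, r2)) /
    pmax(den, 1)
  rho <- .clamp(rho, 1e-4, 0.5)
  med <- stats::median(rho[tested])
  rho <- .clamp(shrink * rho + (1 - shrink) * med, 1e-4, 0.5)

  ll0 <- .bbLoglik(y, n, p0, rho)
  llA <- .bbLoglik(y[, gc1, drop = FALSE], n[, gc1, drop = FALSE], p1, rho) +
         .bbLoglik(y[, gc2, drop = FALSE], n[, gc2, drop = FALSE], p2, rho)
  stat <- pmax(2 * (llA - ll0), 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[!tested] <- NA
  stat[!tested] <- NA
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  sig <- !is.na(fdr) & fdr < fdrThreshold
  delta <- p2 - p1
  rr <- cpgSites(me)
  out <- data.frame(
    site_id = S4Vectors::mcols(rr)$site_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr) - 1L,
    meanControl = ifelse(sumN1 > 0, sumY1 / pmax(sumN1, 1L), NA),
    meanCase = ifelse(sumN2 > 0, sumY2 / pmax(sumN2, 1L), NA),
    delta = delta, stat = stat, p = p, fdr = fdr,
    significant = sig,
    direction = ifelse(sig, ifelse(delta < 0, "hypo", "hyper"),
                       NA_character_),
    tested = tested)
  attr(out, "fdrThreshold") <- fdrThreshold
  out
}
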