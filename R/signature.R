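#' Multi-step group-signature extraction
#'
#' Implements the five-step procedure for extracting a cross-group
#' methylation signature from sub-grouped case samples against a
#' reference cohort:
#' \enumerate{
#'   \item within each group, compute the per-CpG standard deviation of
#'     the differential methylation (each sample's beta minus the
#'     reference-cohort mean beta) and discard CpGs above that group's
#'     95th percentile;
#'   \item keep CpGs measurable in all groups (and surviving step 1 in
#'     all groups);
#'   \item per group, compute the mean differential methylation;
#'   \item compute the across-group standard deviation of those means;
#'   \item CpGs above the 95th percentile of that SD form the signature.
#' }
#' Percentiles use the linear-interpolation convention, so the signature
#' is ~5\% of the eligible set by construction.
#'
#' @param me A coverage-filtered [MethylationExperiment-class].
#' @param betaCohort Reference cohort label (default `"beta"`).
#' @param groups Named assignment of case samples to groups, or `NULL` to
#'   use the `group` column of the sample metadata.
#' @param pct Percentile for both drop and selection steps (default 95).
#' @return A list of class `SignatureSet`: `perGroupRetained` (site ids
#'   surviving step 1 per group), `measurableIds` (step 2),
#'   `groupMeanDelta` (step 3 matrix), `crossGroupSd` (step 4, full-length
#'   vector, `NA` for ineligible sites), `signatureIds` (step 5) and
#'   `eligibleIds`.
#' @export
groupSignature <- function(me, betaCohort = "beta", groups = NULL,
                           pct = 95) {
  ch <- cohorts(me)
  b <- betaValues(me)
  if (is.null(groups)) {
    groups <- sampleGroups(me)
    names(groups) <- colnames(me)
  }
  caseIdx <- which(!is.na(groups) & ch != betaCohort)
  grp <- groups[caseIdx]
  gnames <- sort(unique(grp))
  if (length(gnames) < 2) stop("need at least 2 case groups")
  if (any(table(grp) < 2))
    stop("every group needs at least 2 samples for a standard deviation")
  refMean <- rowMeans(b[, ch == betaCohort, drop = FALSE], na.rm = TRUE)
  refMean[is.nan(refMean)] <- NA
  siteIds <- S4Vectors::mcols(cpgSites(me))$site_id
  diffs <- b[, caseIdx, drop = FALSE] - refMean

  ## step 1: per-group SD filter at the group's own 95th percentile
  perGroupRetained <- list()
  retainedAll <- rep(TRUE, nrow(b))
  for (g in gnames) {
    sdg <- .rowSds(diffs[, grp == g, drop = FALSE])
    thr <- .pctl(sdg, pct)
    keep <- !is.na(sdg) & sdg <= thr
    perGroupRetained[[g]] <- siteIds[keep]
    retainedAll <- retainedAll & keep
  }

  ## step 2: measurable in every group (>= 1 value), surviving step 1
  measurable <- rep(TRUE, nrow(b))
  for (g in gnames)
    measurable <- measurable &
      rowSums(!is.na(diffs[, grp == g, drop = FALSE])) > 0
  measurable <- measurable & !is.na(refMean)
  eligible <- retainedAll & measurable

  ## steps 3-4: across-group SD of the per-group mean differential
  gm <- sapply(gnames, function(g)
    rowMeans(diffs[, grp == g, drop = FALSE], na.rm = TRUE))
  sdAcross <- .rowSds(gm)
  sdAcross[!eligible] <- NA

  ## step 5: signature above the 95th percentile of the across-group SD
  thr <- .pctl(sdAcross[eligible], pct)
  sigIdx <- which(eligible & sdAcross > thr)

  structure(list(perGroupRetained = perGroupRetained,
                 measurableIds = siteIds[measurable],
                 eligibleIds = siteIds[eligible],
                 groupMeanDelta = gm,
                 crossGroupSd = sdAcross,
                 signatureIds = siteIds[sigIdx],
                 pct = pct),
            class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet: %d signature CpGs out of %d eligible (%dth pctile)\n",
              length(x$signatureIds), length(x$eligibleIds), x$pct))
  invisible(x)
}

#' Association between methylation direction and signature membership
#'
#' Cross-tabulates significant CpGs as hypo/hyper x in/out of the group
#' signature and tests independence with an uncorrected Pearson
#' chi-squared test (df = 1).
#'
#' @param results Output of [testCpGs()].
#' @param signatureIds Site ids in the signature (see [groupSignature()]).
#' @return A list with `statistic`, `df`, `p` and the 2x2 `table`.
#' @export
directionSignatureAssociation <- function(results, signatureIds) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  if (!nrow(sig)) stop("no significant CpGs")
  tab <- table(direction = factor(sig$direction, c("hypo", "hyper")),
               inSignature = factor(sig$site_id %in% signatureIds,
                                    c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared undefined: empty margin in the 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Hierarchical clustering of samples on methylation profiles
#'
#' Ward-linkage agglomeration on a 1 - Pearson correlation distance
#' between sample beta-value columns (pairwise-complete). Identical
#' samples are at distance 0 and merge first; merge heights are invariant
#' to sample order (ties are resolved by the deterministic order of the
#' distance matrix, i.e. lowest sample index first).
#'
#' @param me A [MethylationExperiment-class] with >= 3 samples.
#' @param k Optional number of flat clusters to cut.
#' @return The `hclust` object, with a `clusters` attribute when `k` is
#'   given.
#' @export
sampleDistanceCluster <- function(me, k = NULL) {
  if (ncol(me) < 3) stop("need at least 3 samples")
  b <- betaValues(me)
  cc <- stats::cor(b, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "ward.D2")
  if (!is.null(k)) attr(hc, "clusters") <- stats::cutree(hc, k = k)
  hc
}
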