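#' Methylation index (M-value)
#'
#' `M = log2(beta / (1 - beta))` with beta clamped to
#' `[eps, 1 - eps]`, putting methylation on the same log2 scale as
#' expression fold changes. The index is strictly increasing and
#' antisymmetric about beta = 0.5 (`M(b) = -M(1 - b)`).
#'
#' @param beta Methylated fraction(s) in \[0, 1\].
#' @param eps Clamp bound keeping the index finite at beta 0/1
#'   (default 0.01).
#' @return M-value(s).
#' @examples
#' methylationIndex(c(0.5, 0.8))  # 0, 2
#' @export
methylationIndex <- function(beta, eps = 0.01) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop("beta values must lie in [0, 1]")
  b <- .clamp(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' Promoter methylation-index log-fold change
#'
#' Per cohort, the promoter beta is the unweighted mean over constituent
#' CpGs of the cohort-mean beta (each CpG's cohort mean is the average of
#' its per-sample betas); the M log-fold change is
#' `M(case) - M(control)`. A promoter with no CpG measurable in both
#' cohorts is flagged methylation-data-absent rather than scored 0.
#'
#' @param me A coverage-filtered [MethylationExperiment-class].
#' @param promoter A `GRanges` of length 1.
#' @param control,case Cohort labels.
#' @param eps Clamp for [methylationIndex()].
#' @return A list with `mLfc`, `nCpG`, `available`.
#' @export
promoterMLFC <- function(me, promoter, control = "beta",
                         case = "insulinoma", eps = 0.01) {
  hit <- IRanges::overlapsAny(cpgSites(me), promoter, ignore.strand = TRUE)
  if (!any(hit)) return(list(mLfc = NA_real_, nCpG = 0L, available = FALSE))
  b <- betaValues(me)[hit, , drop = FALSE]
  ch <- cohorts(me)
  mCtl <- rowMeans(b[, ch == control, drop = FALSE], na.rm = TRUE)
  mCas <- rowMeans(b[, ch == case, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(mCtl) & is.finite(mCas)
  if (!any(ok)) return(list(mLfc = NA_real_, nCpG = 0L, available = FALSE))
  list(mLfc = methylationIndex(mean(mCas[ok]), eps) -
         methylationIndex(mean(mCtl[ok]), eps),
       nCpG = sum(ok), available = TRUE)
}

#' Select the promoter isoform best matching expression
#'
#' Picks the isoform whose ratio of methylation to expression log-fold
#' change approaches 1 most closely (argmin of `|mLfc/exprLfc - 1|` on
#' the signed ratio, which penalizes sign-discordant isoforms); ties go
#' to the lowest isoform ordinal. When the expression fold change is 0
#' the ratio is undefined and the isoform with the largest `|mLfc|` is
#' taken, flagged as a fallback.
#'
#' @param mLfcs Named numeric vector of per-isoform M log-fold changes.
#' @param exprLfc The gene's expression log2 fold change.
#' @return A list with `isoform`, `mLfc`, `fallback`.
#' @export
selectIsoform <- function(mLfcs, exprLfc) {
  ok <- which(is.finite(mLfcs))
  if (!length(ok)) return(list(isoform = NA_character_, mLfc = NA_real_,
                               fallback = FALSE))
  if (exprLfc == 0) {
    i <- ok[which.max(abs(mLfcs[ok]))]
    return(list(isoform = names(mLfcs)[i], mLfc = unname(mLfcs[i]),
                fallback = TRUE))
  }
  crit <- abs(mLfcs[ok] / exprLfc - 1)
  i <- ok[which.min(crit)]  # which.min takes the first on ties
  list(isoform = names(mLfcs)[i], mLfc = unname(mLfcs[i]),
       fallback = FALSE)
}

#' Classify a gene by methylation-expression concordance
#'
#' Categories follow the quadrant reading of a promoter-methylation vs
#' expression scatter: `significant-opposite` (opposite signs, expression
#' change significant), `opposite-nonsignificant`, `concordant` (same
#' sign, or either change exactly 0), and the one-sided
#' `expression-only` / `methylation-only` data-availability categories.
#'
#' @param mLfc Methylation-index log-fold change (or `NA`).
#' @param exprLfc Expression log2 fold change (or `NA`).
#' @param exprSignificant Logical significance flag for expression.
#' @param mAvailable,exprAvailable Data-availability flags.
#' @return The category as a character scalar (`NA` when no data at all).
#' @export
classifyGene <- function(mLfc, exprLfc, exprSignificant,
                         mAvailable = !is.na(mLfc),
                         exprAvailable = !is.na(exprLfc)) {
  if (!mAvailable && !exprAvailable) return(NA_character_)
  if (!mAvailable) return("expression-only")
  if (!exprAvailable) return("methylation-only")
  opposite <- sign(mLfc) * sign(exprLfc) < 0
  if (opposite && isTRUE(exprSignificant)) "significant-opposite"
  else if (opposite) "opposite-nonsignificant"
  else "concordant"
}

#' Promoter methylation vs expression, gene by gene
#'
#' For every gene: builds the per-isoform promoters, computes each
#' isoform's methylation-index log-fold change, selects the isoform best
#' matching the gene's expression fold change, and classifies the gene
#' into the concordance categories of [classifyGene()]. Genes absent
#' from the expression table but with promoter methylation are
#' `methylation-only`; expression-table genes without a promoter in the
#' region are `expression-only`.
#'
#' @param me A coverage-filtered [MethylationExperiment-class].
#' @param isoforms Isoform `GRanges` (strand, `gene`, `isoform`).
#' @param expression `data.frame` with `gene`, `log2fc`, `significant`.
#' @param region Optional clipping region for promoters.
#' @param up,down Promoter geometry.
#' @param eps M-value clamp.
#' @param control,case Cohort labels.
#' @return A `data.frame` with `gene`, `isoform`, `mLfc`, `exprLfc`,
#'   `exprSignificant`, `category`.
#' @export
analyzePromoterExpression <- function(me, isoforms, expression,
                                      region = NULL, up = 1500, down = 500,
                                      eps = 0.01, control = "beta",
                                      case = "insulinoma") {
  prom <- suppressWarnings(buildPromoters(isoforms, up, down, region))
  genes <- unique(c(S4Vectors::mcols(isoforms)$gene, expression$gene))
  rows <- lapply(genes, function(g) {
    pi <- prom[S4Vectors::mcols(prom)$gene == g]
    mlfcs <- if (length(pi)) {
      v <- vapply(seq_along(pi), function(i)
        promoterMLFC(me, pi[i], control, case, eps)$mLfc, numeric(1))
      stats::setNames(v, S4Vectors::mcols(pi)$isoform)
    } else numeric(0)
    er <- expression[expression$gene == g, , drop = FALSE]
    exprLfc <- if (nrow(er)) er$log2fc[1] else NA_real_
    exprSig <- if (nrow(er)) isTRUE(er$significant[1]) else NA
    sel <- selectIsoform(mlfcs, if (is.na(exprLfc)) 1 else exprLfc)
    data.frame(gene = g, isoform = sel$isoform, mLfc = sel$mLfc,
               exprLfc = exprLfc, exprSignificant = exprSig,
               category = classifyGene(sel$mLfc, exprLfc, exprSig))
  })
  do.call(rbind, rows)
}
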