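## Internal helpers shared across modules.

## All percentile rules in the package (signature step 1/5, region seeds,
## TR classification) use the linear-interpolation convention (stats::quantile
## type 7) so that every threshold is reproducible from the documentation.
.pctl <- function(x, p, na.rm = TRUE) {
  stats::quantile(x, probs = p / 100, na.rm = na.rm, type = 7, names = FALSE)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Row-wise SD with NA removal; rows with fewer than 2 values return NA.
.rowSds <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  v <- rowSums((m - mu)^2, na.rm = TRUE) / (n - 1)
  v[n < 2] <- NA_real_
  sqrt(v)
}

.assertScalarNum <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

#' Jaccard index between two interval sets
#'
#' Overlap-based similarity used to compare called DMRs or regions with a
#' reference set: intersection width over union width after reducing each
#' set to disjoint intervals.
#'
#' @param a,b `GRanges` objects.
#' @return A number in \[0, 1\], or `NA` when both sets are empty.
#' @export
intervalJaccard <- function(a, b) {
  a <- GenomicRanges::reduce(a)
  b <- GenomicRanges::reduce(b)
  inter <- sum(BiocGenerics::width(GenomicRanges::intersect(a, b)))
  uni <- sum(BiocGenerics::width(GenomicRanges::union(a, b)))
  if (uni == 0) return(NA_real_)
  inter / uni
}
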