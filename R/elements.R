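#' Strand-aware promoter construction
#'
#' Promoters span 1,500 bp upstream and 500 bp downstream of each
#' isoform's transcription start site (2,000 bp exactly), honoring
#' strand; promoters running past the analysis region are clipped with a
#' warning.
#'
#' @param isoforms `GRanges` of gene isoforms with strand and `gene`,
#'   `isoform` metadata.
#' @param up,down Bases upstream/downstream of the TSS (defaults
#'   1500/500).
#' @param region Optional `GRanges` to clip against.
#' @return A `GRanges` of promoters with the isoform metadata.
#' @export
buildPromoters <- function(isoforms, up = 1500, down = 500, region = NULL) {
  if (any(BiocGenerics::strand(isoforms) == "*"))
    stop("every isoform needs a strand to place its promoter")
  prom <- GenomicRanges::promoters(isoforms, upstream = up,
                                   downstream = down)
  if (!is.null(region)) {
    clipped <- IRanges::pintersect(
      prom, rep(region[1], length(prom)), ignore.strand = TRUE)
    nclip <- sum(BiocGenerics::width(clipped) < BiocGenerics::width(prom))
    if (nclip)
      warning(sprintf("clipped %d promoter(s) at the region boundary",
                      nclip))
    S4Vectors::mcols(clipped)$hit <- NULL
    prom <- clipped
  }
  prom
}

#' Maximum gene footprint across isoforms
#'
#' Per gene, the span from the outermost isoform start to the outermost
#' isoform end (the isoforms extending the farthest in both directions).
#'
#' @param isoforms `GRanges` with a `gene` metadata column.
#' @return A `GRanges` with one footprint per gene.
#' @export
geneFootprints <- function(isoforms) {
  sp <- S4Vectors::split(isoforms, S4Vectors::mcols(isoforms)$gene)
  fp <- unlist(range(sp, ignore.strand = TRUE))
  S4Vectors::mcols(fp)$gene <- names(fp)
  names(fp) <- NULL
  BiocGenerics::sort(fp)
}

#' Assemble the genomic-element catalog
#'
#' Builds the five element classes used for CpG attribution: promoters
#' (per isoform), gene bodies (maximum footprints), islet-specific
#' enhancers, generic enhancers, and the non-mapping remainder of the
#' region (the region minus the union of the other four). The first four
#' classes may overlap each other; non-mapping overlaps none.
#'
#' @param isoforms Isoform `GRanges` (strand, `gene`, `isoform`).
#' @param enhancers Enhancer `GRanges` with a `source` column
#'   (`"islet"`/`"generic"`).
#' @param region Analysis region `GRanges`.
#' @param up,down Promoter geometry (see [buildPromoters()]).
#' @return A list of class `ElementCatalog` with `promoters`,
#'   `gene_bodies`, `islet_enhancers`, `generic_enhancers`,
#'   `non_mapping`, `region`.
#' @export
elementCatalog <- function(isoforms, enhancers, region,
                           up = 1500, down = 500) {
  prom <- suppressWarnings(buildPromoters(isoforms, up, down, region))
  gb <- geneFootprints(isoforms)
  islet <- enhancers[S4Vectors::mcols(enhancers)$source == "islet"]
  generic <- enhancers[S4Vectors::mcols(enhancers)$source == "generic"]
  mapped <- GenomicRanges::reduce(c(
    GenomicRanges::granges(prom), GenomicRanges::granges(gb),
    GenomicRanges::granges(islet), GenomicRanges::granges(generic)),
    ignore.strand = TRUE)
  nonmap <- GenomicRanges::setdiff(region, mapped, ignore.strand = TRUE)
  structure(list(promoters = prom, gene_bodies = gb,
                 islet_enhancers = islet, generic_enhancers = generic,
                 non_mapping = nonmap, region = region),
            class = "ElementCatalog")
}

#' @export
print.ElementCatalog <- function(x, ...) {
  for (cl in c("promoters", "gene_bodies", "islet_enhancers",
               "generic_enhancers", "non_mapping"))
    cat(sprintf("  %-18s %4d interval(s), %7d bp\n", cl, length(x[[cl]]),
                sum(BiocGenerics::width(GenomicRanges::reduce(
                  x[[cl]], ignore.strand = TRUE)))))
  invisible(x)
}

.elementClasses <- c("promoters", "gene_bodies", "islet_enhancers",
                     "generic_enhancers", "non_mapping")

#' Count significant CpGs per genomic-element class
#'
#' A CpG (its 2 bp dinucleotide) counts once in every class it overlaps
#' — classes are non-exclusive, mirroring per-element bar charts with a
#' separate non-mapping bar — and the whole-region row recovers the
#' total significant count exactly.
#'
#' @param results Output of [testCpGs()].
#' @param catalog An [elementCatalog()].
#' @return A `data.frame` with `class`, `nHypo`, `nHyper`, `pctHypo`,
#'   `pctHyper`.
#' @export
countSigCpGsByElement <- function(results, catalog) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$pos + 1L, width = 2L))
  rows <- lapply(c(.elementClasses, "whole_region"), function(cl) {
    hit <- if (cl == "whole_region") rep(TRUE, length(gr))
    else IRanges::overlapsAny(gr, catalog[[cl]], ignore.strand = TRUE)
    nh <- sum(hit & sig$direction == "hypo")
    ny <- sum(hit & sig$direction == "hyper")
    data.frame(class = cl, nHypo = nh, nHyper = ny,
               pctHypo = if (nh + ny > 0) 100 * nh / (nh + ny) else NA,
               pctHyper = if (nh + ny > 0) 100 * ny / (nh + ny) else NA)
  })
  do.call(rbind, rows)
}

#' TR binding-site density per genomic element
#'
#' Density is the summed (clipped) binding-site length within each class
#' divided by the cumulative class length, computed on the reduced class
#' union so it is invariant to how class intervals are split. Sites are
#' also labeled hypo/hyper by the majority direction of their
#' significant constituent CpGs (ties are "mixed" and excluded from the
#' directional counts).
#'
#' @param trSites `GRanges` of binding sites with a `tr` column.
#' @param catalog An [elementCatalog()].
#' @param results Output of [testCpGs()] used for the direction labels.
#' @return A `data.frame` with `class`, `density`, `nSites`, `nHypoSites`,
#'   `nHyperSites`, `classLength`.
#' @export
siteDensityByElement <- function(trSites, catalog, results) {
  dirs <- .siteDirections(trSites, results)
  rows <- lapply(.elementClasses, function(cl) {
    red <- GenomicRanges::reduce(GenomicRanges::granges(catalog[[cl]]),
                                 ignore.strand = TRUE)
    clen <- sum(BiocGenerics::width(red))
    if (clen == 0)
      return(data.frame(class = cl, density = NA_real_, nSites = 0L,
                        nHypoSites = 0L, nHyperSites = 0L,
                        classLength = 0L))
    hits <- GenomicRanges::findOverlaps(trSites, red, ignore.strand = TRUE)
    clippedLen <- sum(BiocGenerics::width(IRanges::pintersect(
      GenomicRanges::ranges(trSites)[S4Vectors::queryHits(hits)],
      GenomicRanges::ranges(red)[S4Vectors::subjectHits(hits)])))
    inClass <- unique(S4Vectors::queryHits(hits))
    data.frame(class = cl, density = clippedLen / clen,
               nSites = length(inClass),
               nHypoSites = sum(dirs[inClass] == "hypo", na.rm = TRUE),
               nHyperSites = sum(dirs[inClass] == "hyper", na.rm = TRUE),
               classLength = clen)
  })
  do.call(rbind, rows)
}

## majority-direction label per TR site from significant constituent CpGs
.siteDirections <- function(trSites, results) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$pos + 1L, width = 2L))
  hits <- GenomicRanges::findOverlaps(trSites, gr, ignore.strand = TRUE)
  dirs <- rep(NA_character_, length(trSites))
  if (!length(hits)) return(dirs)
  tab <- table(S4Vectors::queryHits(hits),
               factor(sig$direction[S4Vectors::subjectHits(hits)],
                      c("hypo", "hyper")))
  idx <- as.integer(rownames(tab))
  dirs[idx] <- ifelse(tab[, "hypo"] > tab[, "hyper"], "hypo",
                      ifelse(tab[, "hyper"] > tab[, "hypo"], "hyper",
                             "mixed"))
  dirs
}

#' Chromatin-signature coverage and rank per window
#'
#' Per window and signature class, the percent of window bases covered by
#' signature intervals; the rank is the percentile of that coverage
#' within a supplied background distribution (genome-wide coverage values
#' or a synthetic stand-in — the background cannot be derived from the
#' target region itself). Windows with zero coverage are not scored and
#' are excluded from the per-class mean rank.
#'
#' @param sigIntervals Named list of `GRanges`, one per signature class.
#' @param grid Window `GRanges`.
#' @param background Named list (or single numeric vector recycled per
#'   class) of background coverage percentages.
#' @return A list with `perWindow` (window x class coverage and rank) and
#'   `summary` (`class`, `meanRank`, `scoredWindows`).
#' @export
signatureCoverageRank <- function(sigIntervals, grid, background) {
  if (missing(background) || is.null(background))
    stop("a background coverage distribution is required for ranks")
  if (!is.list(background))
    background <- stats::setNames(rep(list(background),
                                      length(sigIntervals)),
                                  names(sigIntervals))
  perW <- data.frame(window = S4Vectors::mcols(grid)$window)
  summ <- data.frame(class = names(sigIntervals), meanRank = NA_real_,
                     scoredWindows = 0L)
  for (cl in names(sigIntervals)) {
    red <- GenomicRanges::reduce(sigIntervals[[cl]], ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(grid, red, ignore.strand = TRUE)
    covBp <- rep(0, length(grid))
    if (length(hits)) {
      w <- BiocGenerics::width(IRanges::pintersect(
        GenomicRanges::ranges(grid)[S4Vectors::queryHits(hits)],
        GenomicRanges::ranges(red)[S4Vectors::subjectHits(hits)]))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      covBp[as.integer(names(agg))] <- agg
    }
    covPct <- 100 * covBp / BiocGenerics::width(grid)
    rnk <- 100 * stats::ecdf(background[[cl]])(covPct)
    rnk[covPct == 0] <- NA
    perW[[paste0(cl, "_coverage")]] <- covPct
    perW[[paste0(cl, "_rank")]] <- rnk
    summ$meanRank[summ$class == cl] <- mean(rnk, na.rm = TRUE)
    summ$scoredWindows[summ$class == cl] <- sum(!is.na(rnk))
  }
  list(perWindow = perW, summary = summ)
}
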