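## Synthetic bisulfite-count cohorts with planted effects.
##
## The generator emulates the statistical structure the analysis assumes:
## a large imprinted target region with a piecewise methylation landscape
## (high background, low over gene loci), two cohorts (a small set of
## normal beta-cell samples vs a larger insulinoma-like cohort), focal
## planted blocks of hypo- and hypermethylation, three insulinoma
## sub-groups with planted signature CpGs, TR binding sites confined to
## (or scattered around) the planted blocks, islet enhancers inside the
## hypermethylated blocks, ATAC peaks anti-correlated with beta-cell
## methylation, and an expression table deliberately decoupled from
## promoter methylation. A truth record accompanies every dataset so that
## recovery can be measured.

#' Simulation configuration
#'
#' Returns the default configuration for the synthetic bisulfite-count
#' generator. The default scale is roughly one tenth of a 1.35 Mbp
#' target region (135 kb, ~3,000 CpGs at 22.2 CpG/kb) so that the whole
#' pipeline runs in seconds; [paperScaleConfig()] restores the full
#' 1.35 Mbp / ~30,000 CpG geometry and [nullSimConfig()] removes every
#' planted effect for calibration runs.
#'
#' Cohort sizes (5 beta vs 19 insulinoma in sub-groups of 8/6/5), mean
#' depth (22x, negative-binomial with size 5) and the beta-binomial
#' dispersion (rho = 0.02) are the study conditions; block deltas are in
#' methylation-fraction units and are clamped so every expected beta stays
#' in \[0.02, 0.98\].
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(...) {
  cfg <- list(
    chrom = "chr11",
    regionStart = 1850000,        # 0-based, browser-style
    regionLength = 135000,
    cpgPerKb = 22.2,
    nBeta = 5,
    nInsulinoma = 19,
    groupSizes = c(8, 6, 5),
    meanDepth = 22,
    depthSize = 5,
    rho = 0.02,                   # beta-binomial dispersion
    baselineHigh = 0.80,
    baselineLow = 0.20,
    ## islet-enhancer territory (the hypermethylated blocks) is lowly
    ## methylated in normal beta cells, as active enhancers are
    baselineEnhancer = 0.35,
    ## planted blocks: offsets are bp from region start
    hypoBlocks = data.frame(offset = c(10000, 70000),
                            width = c(30000, 20000)),
    broadHypoDelta = -0.20,
    deepCore = data.frame(offset = 12000, width = 10000),
    deepCoreDelta = -0.45,
    hyperBlocks = data.frame(offset = c(52000, 112000),
                             width = c(5000, 5000)),
    hyperDelta = 0.40,
    ## signature planting: each group's signature CpGs flip that group's
    ## expected methylation to its mirror (p -> 1 - p), the
    ## imprinting-switch pattern; variance-neutral, so the signature
    ## procedure's step-1 SD filter treats planted sites like background
    nSignaturePerGroup = 40,
    signatureMinP = 0.70,
    signatureMaxP = 0.92,
    ## annotation layout
    nBackgroundGenes = 6,
    geneLength = 6000,
    trNames = c("PDX1", "NFATC1", sprintf("TR%02d", seq_len(28))),
    plantedSites = 16,
    scatterSiteRange = c(18, 36),
    siteLength = 150,
    nGenericEnhancers = 12,
    scatterFlank = 1000,          # TR-hub halo around generic enhancers
    nAtacSamples = 4,
    atacSpacing = 5000,
    atacPeakWidth = 1000,
    exprNull = FALSE,
    exprSdLog2 = 1.5)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  if (sum(cfg$groupSizes) != cfg$nInsulinoma)
    stop("groupSizes must sum to nInsulinoma")
  blocks <- rbind(cfg$hypoBlocks, cfg$hyperBlocks, cfg$deepCore)
  if (nrow(blocks) &&
      any(blocks$offset < 0 | blocks$offset + blocks$width > cfg$regionLength))
    stop("planted blocks exceed the simulated region")
  structure(cfg, class = "SimConfig")
}

#' @describeIn simConfig Full-scale geometry: 1.35 Mbp, ~30,000 CpGs,
#'   135 windows of 10 kbp; planted blocks keep their absolute sizes and
#'   are spread across the larger region.
#' @export
paperScaleConfig <- function(...) {
  simConfig(regionLength = 1350000,
            hypoBlocks = data.frame(offset = c(100000, 700000),
                                    width = c(30000, 20000)),
            deepCore = data.frame(offset = 105000, width = 10000),
            hyperBlocks = data.frame(offset = c(310000, 1120000),
                                     width = c(5000, 5000)),
            nBackgroundGenes = 8,
            ...)
}

#' @describeIn simConfig Null configuration: no planted blocks and no
#'   sub-group shifts; the region length defaults to 90 kb (~2,000 CpGs).
#' @export
nullSimConfig <- function(...) {
  simConfig(regionLength = 90000,
            hypoBlocks = data.frame(offset = numeric(), width = numeric()),
            deepCore = data.frame(offset = numeric(), width = numeric()),
            hyperBlocks = data.frame(offset = numeric(), width = numeric()),
            nSignaturePerGroup = 0,
            ...)
}

.blocksToGRanges <- function(cfg, blocks) {
  if (is.null(blocks) || nrow(blocks) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(
    start = cfg$regionStart + blocks$offset + 1,
    width = blocks$width))
}

.simRegionGR <- function(cfg)
  regionInterval(cfg$chrom, cfg$regionStart,
                 cfg$regionStart + cfg$regionLength)

## place n intervals of length len uniformly inside 'allowed' (GRanges)
.sampleWithin <- function(allowed, n, len) {
  allowed <- GenomicRanges::reduce(allowed)
  allowed <- allowed[BiocGenerics::width(allowed) >= len]
  if (!length(allowed)) stop("infeasible placement: no room for intervals")
  room <- BiocGenerics::width(allowed) - len + 1
  pick <- sample.int(length(allowed), n, replace = TRUE, prob = room)
  off <- floor(stats::runif(n) * room[pick])
  GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(allowed))[pick],
    IRanges::IRanges(start = BiocGenerics::start(allowed)[pick] + off,
                     width = len))
}

.simGenes <- function(cfg) {
  region <- .simRegionGR(cfg)
  hypo <- .blocksToGRanges(cfg, cfg$hypoBlocks)
  hyper <- .blocksToGRanges(cfg, cfg$hyperBlocks)
  core <- .blocksToGRanges(cfg, cfg$deepCore)
  bodies <- GenomicRanges::GRanges()
  ## genes fill the hypomethylated blocks but keep clear of the deeply
  ## hypomethylated core, which sits on high-methylation background so
  ## its planted delta is realized in full
  for (i in seq_along(hypo)) {
    subs <- GenomicRanges::setdiff(hypo[i], core)
    subs <- subs[BiocGenerics::width(subs) >= 4000]
    for (j in seq_along(subs)) {
      s <- BiocGenerics::start(subs)[j]
      w <- BiocGenerics::width(subs)[j]
      if (w >= 12000) {
        g <- GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(
          start = c(s + round(0.05 * w), s + round(0.55 * w)),
          end = c(s + round(0.45 * w), s + round(0.90 * w))))
      } else {
        g <- GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(
          start = s + round(0.10 * w), end = s + round(0.85 * w)))
      }
      bodies <- c(bodies, g)
    }
  }
  ## background genes in the complement, avoiding hypermethylated blocks
  avoid <- GenomicRanges::reduce(c(hypo, hyper))
  free <- GenomicRanges::setdiff(region, avoid + 1000)
  nbg <- cfg$nBackgroundGenes
  gl <- cfg$geneLength
  free <- free[BiocGenerics::width(free) >= gl + 2000]
  placed <- GenomicRanges::GRanges()
  i <- 0
  while (length(placed) < nbg && i < 50 * nbg) {
    i <- i + 1
    cand <- .sampleWithin(free, 1, gl)
    if (!length(placed) ||
        !any(IRanges::overlapsAny(cand, placed + 1500)))
      placed <- c(placed, cand)
  }
  bodies <- BiocGenerics::sort(c(bodies, placed))
  BiocGenerics::strand(bodies) <- rep_len(c("+", "-"), length(bodies))
  S4Vectors::mcols(bodies)$gene <- sprintf("G%02d", seq_along(bodies))
  bodies
}

.simIsoforms <- function(genes) {
  iso <- GenomicRanges::GRanges()
  for (i in seq_along(genes)) {
    g <- genes[i]
    n <- 1 + (i %% 3)  # 1-3 isoforms, deterministic pattern
    s <- BiocGenerics::start(g); e <- BiocGenerics::end(g)
    w <- e - s + 1
    starts <- s; ends <- e
    if (n >= 2) {  # distinct TSS
      starts <- c(starts, s + round(0.25 * w)); ends <- c(ends, e)
    }
    if (n >= 3) {  # shared TSS, shorter
      starts <- c(starts, s); ends <- c(ends, e - round(0.3 * w))
    }
    ig <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                 IRanges::IRanges(starts, ends),
                                 strand = BiocGenerics::strand(g))
    S4Vectors::mcols(ig)$gene <- S4Vectors::mcols(g)$gene
    S4Vectors::mcols(ig)$isoform <-
      sprintf("%s.%d", S4Vectors::mcols(g)$gene, seq_len(n))
    iso <- c(iso, ig)
  }
  iso
}

.simEnhancers <- function(cfg, genes = GenomicRanges::GRanges()) {
  hyper <- .blocksToGRanges(cfg, cfg$hyperBlocks)
  islet <- GenomicRanges::GRanges()
  for (i in seq_along(hyper)) {
    s <- BiocGenerics::start(hyper)[i]
    w <- BiocGenerics::width(hyper)[i]
    e <- GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(
      start = s + round(w * c(0.08, 0.42, 0.72)), width = 800))
    islet <- c(islet, e)
  }
  islet <- IRanges::subsetByOverlaps(islet, hyper, type = "within")
  region <- .simRegionGR(cfg)
  core <- .blocksToGRanges(cfg, cfg$deepCore)
  hypo <- .blocksToGRanges(cfg, cfg$hypoBlocks)
  ## generic enhancers scatter across the region, a quarter of them in
  ## the intergenic parts of the broad hypomethylated blocks (never
  ## inside gene bodies, the islet-enhancer blocks or the deep core)
  nIn <- round(cfg$nGenericEnhancers / 4)
  inBlocks <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(hypo, core + 2000),
    GenomicRanges::granges(genes))
  generic <- GenomicRanges::GRanges()
  if (length(inBlocks) && nIn > 0)
    generic <- .sampleWithin(inBlocks, nIn, 800)
  avoid <- c(hyper, core, hypo)
  free <- if (length(avoid)) GenomicRanges::setdiff(region, avoid + 2000)
          else region
  generic <- c(generic,
               .sampleWithin(free, cfg$nGenericEnhancers - length(generic),
                             800))
  src <- c(rep("islet", length(islet)), rep("generic", length(generic)))
  out <- c(islet, generic)
  S4Vectors::mcols(out)$source <- src
  S4Vectors::mcols(out)$name <- sprintf("enh_%s_%02d", src,
                                        seq_along(out))
  out
}

## Binding sites cluster in enhancer hubs, as in curated ChIP compendia:
## the PDX1-like TR binds within the islet-enhancer (hypermethylated)
## blocks, the NFATC1-like TR within the deeply hypomethylated core, and
## every other TR within a halo around the generic enhancers.
.simTrSites <- function(cfg, enhancers) {
  region <- .simRegionGR(cfg)
  hyper <- .blocksToGRanges(cfg, cfg$hyperBlocks)
  core <- .blocksToGRanges(cfg, cfg$deepCore)
  hubs <- enhancers[S4Vectors::mcols(enhancers)$source == "generic"]
  hubs <- GenomicRanges::intersect(
    GenomicRanges::reduce(hubs + cfg$scatterFlank), region)
  out <- GenomicRanges::GRanges()
  for (tr in cfg$trNames) {
    if (tr == "PDX1" && length(hyper)) {
      gr <- .sampleWithin(hyper, cfg$plantedSites, cfg$siteLength)
    } else if (tr == "NFATC1" && length(core)) {
      gr <- .sampleWithin(core, cfg$plantedSites, cfg$siteLength)
    } else {
      ns <- sample(seq(cfg$scatterSiteRange[1], cfg$scatterSiteRange[2]), 1)
      gr <- .sampleWithin(hubs, ns, cfg$siteLength)
    }
    S4Vectors::mcols(gr)$tr <- tr
    out <- c(out, gr)
  }
  S4Vectors::mcols(out)$name <- S4Vectors::mcols(out)$tr
  BiocGenerics::sort(out)
}

## expected methylation landscape at positions (0-based), per cohort
.landscape <- function(cfg, pos0, genes) {
  inGene <- IRanges::overlapsAny(
    GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(pos0 + 1, width = 2)),
    genes, ignore.strand = TRUE)
  pBeta <- ifelse(inGene, cfg$baselineLow, cfg$baselineHigh)
  delta <- numeric(length(pos0))
  gr <- GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(pos0 + 1, width = 2))
  inHypo <- IRanges::overlapsAny(gr, .blocksToGRanges(cfg, cfg$hypoBlocks))
  inCore <- IRanges::overlapsAny(gr, .blocksToGRanges(cfg, cfg$deepCore))
  inHyper <- IRanges::overlapsAny(gr, .blocksToGRanges(cfg, cfg$hyperBlocks))
  pBeta[inHyper] <- cfg$baselineEnhancer
  delta[inHypo] <- cfg$broadHypoDelta
  delta[inCore] <- cfg$deepCoreDelta
  delta[inHyper] <- cfg$hyperDelta
  list(pBeta = .clamp(pBeta, 0.02, 0.98),
       pIns = .clamp(pBeta + delta, 0.02, 0.98))
}

.simAtac <- function(cfg, genes) {
  centers <- seq(cfg$atacSpacing / 2, cfg$regionLength - cfg$atacSpacing / 2,
                 by = cfg$atacSpacing)
  pos0 <- cfg$regionStart + centers
  land <- .landscape(cfg, pos0, genes)
  out <- GenomicRanges::GRanges()
  for (s in seq_len(cfg$nAtacSamples)) {
    sc <- (1.02 - land$pBeta) * exp(stats::rnorm(length(pos0), 0, 0.10))
    gr <- GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(
      start = pos0 - cfg$atacPeakWidth / 2 + 1, width = cfg$atacPeakWidth))
    S4Vectors::mcols(gr)$score <- sc
    S4Vectors::mcols(gr)$sample <- sprintf("atac_%d", s)
    out <- c(out, gr)
  }
  out
}

.simChromSignatures <- function(cfg, isoforms) {
  region <- .simRegionGR(cfg)
  tss <- GenomicRanges::promoters(isoforms, upstream = 500, downstream = 500)
  promSig <- GenomicRanges::reduce(tss[seq_len(ceiling(length(tss) * 0.6))])
  enhSig <- .sampleWithin(region, 20, 2000)
  dyaSig <- .sampleWithin(region, 8, 1500)
  list(promoter = promSig, enhancer = enhSig, dyadic = dyaSig)
}

.simLoopScores <- function(cfg) {
  hyper <- .blocksToGRanges(cfg, cfg$hyperBlocks)
  anchor <- if (length(hyper))
    (BiocGenerics::start(hyper)[1] + BiocGenerics::end(hyper)[1]) / 2
  else cfg$regionStart + cfg$regionLength / 2
  pos <- sort(round(stats::runif(150, cfg$regionStart + 1,
                                 cfg$regionStart + cfg$regionLength - 1)))
  sc <- exp(-abs(pos - anchor) / 20000) *
    exp(stats::rnorm(length(pos), 0, 0.3))
  gr <- GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(pos, width = 1))
  S4Vectors::mcols(gr)$score <- sc
  gr
}

#' Simulate the annotation stack and planted truth for a region
#'
#' Draws CpG positions to the configured density, lays out gene isoforms
#' (with shared and distinct TSSs), islet enhancers inside the planted
#' hypermethylated blocks, generic enhancers elsewhere, TR binding sites
#' (a PDX1-like TR confined to hypermethylated blocks, an NFATC1-like TR
#' confined to the deeply hypomethylated core, the rest scattered), ATAC
#' peaks whose scores are inversely tied to the local beta-cell
#' methylation landscape, chromatin-signature intervals and a 4C-style
#' loop-score track anchored at the first hypermethylated block.
#'
#' @param config A [simConfig()] list.
#' @param seed Integer seed; the full bundle is reproducible byte for byte.
#' @return A list with `region`, `sites` (CpG `GRanges`), `annotations`
#'   (list of `GRanges`: `isoforms`, `genes`, `enhancers`, `trSites`,
#'   `atacPeaks`, `chromSignatures`, `loopScores`) and `truth` (planted
#'   parameters; see Details).
#' @details The truth record carries the planted block intervals with
#'   direction (`dmrs`), per-group signature site ids, the planted TR
#'   classes, and the expression table, and is what recovery tests compare
#'   against.
#' @export
simulateRegion <- function(config = simConfig(), seed = 1) {
  set.seed(seed)
  cfg <- config
  region <- .simRegionGR(cfg)
  nCpG <- round(cfg$regionLength / 1000 * cfg$cpgPerKb)
  ## even offsets guarantee non-overlapping CG dinucleotides
  half <- floor(cfg$regionLength / 2) - 1
  pos0 <- cfg$regionStart + 2 * sort(sample.int(half, nCpG))
  sites <- GenomicRanges::GRanges(cfg$chrom,
                                  IRanges::IRanges(pos0 + 1, width = 2))
  S4Vectors::mcols(sites)$site_id <- seq_along(sites)
  genes <- .simGenes(cfg)
  isoforms <- .simIsoforms(genes)
  enhancers <- .simEnhancers(cfg, genes)
  trSites <- .simTrSites(cfg, enhancers)
  atac <- .simAtac(cfg, genes)
  chromSig <- .simChromSignatures(cfg, isoforms)
  loops <- .simLoopScores(cfg)
  expr <- simulateExpression(S4Vectors::mcols(genes)$gene, cfg,
                             seed = NULL)
  ## signature sites: drawn from the high-methylation background so that
  ## the mirrored (flipped) group lands at an equally low-variance level
  land <- .landscape(cfg, pos0, genes)
  truthSig <- list()
  taken <- integer()
  for (g in seq_along(cfg$groupSizes)) {
    if (cfg$nSignaturePerGroup == 0) {
      truthSig[[g]] <- integer()
      next
    }
    ok <- which(land$pIns >= cfg$signatureMinP &
                land$pIns <= cfg$signatureMaxP)
    ok <- setdiff(ok, taken)
    pick <- sort(sample(ok, min(cfg$nSignaturePerGroup, length(ok))))
    truthSig[[g]] <- pick
    taken <- c(taken, pick)
  }
  names(truthSig) <- paste0("group", seq_along(cfg$groupSizes))
  hypo <- .blocksToGRanges(cfg, cfg$hypoBlocks)
  core <- .blocksToGRanges(cfg, cfg$deepCore)
  hyper <- .blocksToGRanges(cfg, cfg$hyperBlocks)
  dmrs <- c(GenomicRanges::reduce(c(hypo, core)), hyper)
  if (length(dmrs))
    S4Vectors::mcols(dmrs)$direction <-
      c(rep("hypo", length(GenomicRanges::reduce(c(hypo, core)))),
        rep("hyper", length(hyper)))
  truth <- list(region = region, hypoBlocks = hypo, deepCore = core,
                hyperBlocks = hyper, dmrs = dmrs,
                signatureSites = truthSig,
                trClasses = c(PDX1 = "over-enriched+hyper",
                              NFATC1 = "over-enriched+hypo"),
                expression = expr)
  list(region = region, sites = sites,
       annotations = list(genes = genes, isoforms = isoforms,
                          enhancers = enhancers, trSites = trSites,
                          atacPeaks = atac, chromSignatures = chromSig,
                          loopScores = loops, expression = expr),
       truth = truth)
}

#' Simulate per-CpG bisulfite read counts
#'
#' Per cell, depth is negative-binomial around the configured mean and the
#' methylated count is beta-binomial with the cohort- (and, at planted
#' signature CpGs, sub-group-) specific expected methylation and a common
#' dispersion `rho`. `rho = 0` produces pure binomial counts.
#'
#' @param sim Output of [simulateRegion()].
#' @param config The same [simConfig()] used for the region.
#' @param seed Integer seed.
#' @return A [MethylationExperiment-class] with cohorts `beta` and
#'   `insulinoma` and sub-group labels `group1..group3`.
#' @export
simulateCounts <- function(sim, config = simConfig(), seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  pos0 <- BiocGenerics::start(sim$sites) - 1L
  land <- .landscape(cfg, pos0, sim$annotations$genes)
  nS <- length(pos0)
  groups <- rep(paste0("group", seq_along(cfg$groupSizes)), cfg$groupSizes)
  samples <- data.frame(
    sample = c(sprintf("Beta_%d", seq_len(cfg$nBeta)),
               sprintf("Ins_%02d", seq_len(cfg$nInsulinoma))),
    cohort = rep(c("beta", "insulinoma"), c(cfg$nBeta, cfg$nInsulinoma)),
    group = c(rep(NA_character_, cfg$nBeta), groups))
  P <- matrix(0, nS, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    p <- if (samples$cohort[j] == "beta") land$pBeta else land$pIns
    if (!is.na(samples$group[j])) {
      g <- match(samples$group[j], names(sim$truth$signatureSites))
      idx <- sim$truth$signatureSites[[g]]
      if (length(idx))
        p[idx] <- 1 - p[idx]  # imprinting-switch: mirror the group
    }
    P[, j] <- p
  }
  tot <- matrix(stats::rnbinom(nS * nrow(samples), mu = cfg$meanDepth,
                               size = cfg$depthSize), nS)
  pp <- if (cfg$rho > 0) {
    th <- (1 - cfg$rho) / cfg$rho
    matrix(stats::rbeta(nS * nrow(samples), c(P) * th, c(1 - P) * th), nS)
  } else P
  y <- matrix(stats::rbinom(nS * nrow(samples), c(tot), c(pp)), nS)
  MethylationExperiment(y, tot, sim$sites, samples)
}

#' Simulate a differential expression table
#'
#' Gene log2 fold changes are drawn independently of the methylation
#' landscape (the decoupling the promoter-expression integration is meant
#' to expose). The table also covers the TR gene set: the NFATC1-like TR
#' is overexpressed at log2FC = 3 and the PDX1-like TR is significantly
#' downregulated, matching their planted binding-site methylation classes.
#'
#' @param genes Character vector of region gene names.
#' @param config A [simConfig()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return A `data.frame` with `gene`, `log2fc`, `significant`.
#' @export
simulateExpression <- function(genes, config = simConfig(), seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  if (cfg$exprNull) {
    lfc <- rep(0, length(genes))
    sig <- rep(FALSE, length(genes))
  } else {
    lfc <- stats::rnorm(length(genes), 0, cfg$exprSdLog2)
    sig <- abs(lfc) > 1 & stats::runif(length(genes)) < 0.8
  }
  out <- data.frame(gene = genes, log2fc = lfc, significant = sig)
  trlfc <- stats::rnorm(length(cfg$trNames), 0, 1)
  trsig <- abs(trlfc) > 1
  tr <- data.frame(gene = cfg$trNames, log2fc = trlfc, significant = trsig)
  tr$log2fc[tr$gene == "NFATC1"] <- 3.0
  tr$significant[tr$gene == "NFATC1"] <- TRUE
  tr$log2fc[tr$gene == "PDX1"] <- -2.0
  tr$significant[tr$gene == "PDX1"] <- TRUE
  rbind(out, tr)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [simulateRegion()] and [simulateCounts()].
#'
#' @param config A [simConfig()].
#' @param seed Integer seed controlling the whole bundle.
#' @return A list with `me` (the [MethylationExperiment-class]), plus all
#'   fields of [simulateRegion()].
#' @export
simulateDataset <- function(config = simConfig(), seed = 1) {
  sim <- simulateRegion(config, seed = seed)
  sim$me <- simulateCounts(sim, config, seed = seed + 1000L)
  sim
}
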