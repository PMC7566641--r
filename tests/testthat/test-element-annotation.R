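isoGr <- function(starts, ends, strand, gene, isoform = NULL) {
  gr <- GenomicRanges::GRanges("chr11", IRanges::IRanges(starts, ends),
                               strand = strand)
  S4Vectors::mcols(gr)$gene <- gene
  S4Vectors::mcols(gr)$isoform <-
    if (is.null(isoform)) paste0(gene, ".1") else isoform
  gr
}

test_that("promoters span 1500 bp upstream and 500 bp downstream, by strand", {
  ## plus strand, TSS at 0-based 10000
  p <- buildPromoters(isoGr(10001, 15000, "+", "A"))
  expect_equal(BiocGenerics::start(p) - 1, 8500)
  expect_equal(BiocGenerics::end(p), 10500)
  expect_equal(BiocGenerics::width(p), 2000)
  ## minus strand, TSS at the half-open end 10000
  m <- buildPromoters(isoGr(5001, 10000, "-", "B"))
  expect_equal(BiocGenerics::start(m) - 1, 9500)
  expect_equal(BiocGenerics::end(m), 11500)
  ## clipping at the region edge is warned about
  expect_warning(
    cl <- buildPromoters(isoGr(601, 3000, "+", "C"),
                         region = regionInterval("chr11", 0, 50000)),
    "clipped")
  expect_equal(BiocGenerics::start(cl), 1)
  expect_error(buildPromoters(isoGr(100, 200, "*", "D")), "strand")
})

test_that("gene footprints take the outermost isoform extent", {
  iso <- c(isoGr(1, 100, "+", "A", "A.1"), isoGr(51, 200, "+", "A", "A.2"),
           isoGr(500, 600, "-", "B", "B.1"))
  fp <- geneFootprints(iso)
  expect_equal(BiocGenerics::start(fp[fp$gene == "A"]), 1)
  expect_equal(BiocGenerics::end(fp[fp$gene == "A"]), 200)
  expect_equal(BiocGenerics::width(fp[fp$gene == "B"]), 101)
  ## random isoforms match a brute-force min/max
  set.seed(61)
  st <- sample(1000, 5); en <- st + sample(200, 5)
  iso2 <- isoGr(st, en, "+", "G", paste0("G.", 1:5))
  fp2 <- geneFootprints(iso2)
  expect_equal(BiocGenerics::start(fp2), min(st))
  expect_equal(BiocGenerics::end(fp2), max(en))
})

test_that("CpG-by-element counts match brute-force membership enumeration", {
  region <- regionInterval("chr11", 0, 50000)
  iso <- isoGr(10001, 20000, "+", "A")
  enh <- GenomicRanges::GRanges("chr11", IRanges::IRanges(
    c(30001, 40001), width = 1000))
  S4Vectors::mcols(enh)$source <- c("islet", "generic")
  cat <- elementCatalog(iso, enh, region)
  pos <- c(8600, 10100, 15000, 19998, 30500, 40500, 45000, 25000,
           9000, 10400, 30800, 2000)
  dir <- rep(c("hypo", "hyper"), 6)
  res <- data.frame(site_id = seq_along(pos), chrom = "chr11", pos = pos,
                    delta = ifelse(dir == "hypo", -0.2, 0.2), p = 1e-6,
                    fdr = 1e-5, significant = TRUE, direction = dir,
                    tested = TRUE)
  got <- countSigCpGsByElement(res, cat)
  ## brute force membership per class
  classes <- list(promoters = c(8500, 10500), gene_bodies = c(10000, 20000),
                  islet_enhancers = c(30000, 31000),
                  generic_enhancers = c(40000, 41000))
  inAny <- rep(FALSE, length(pos))
  for (cl in names(classes)) {
    b <- classes[[cl]]
    hit <- pos + 2 > b[1] & pos < b[2]
    inAny <- inAny | hit
    expect_equal(got$nHypo[got$class == cl],
                 sum(hit & dir == "hypo"), info = cl)
    expect_equal(got$nHyper[got$class == cl],
                 sum(hit & dir == "hyper"), info = cl)
  }
  expect_equal(got$nHypo[got$class == "non_mapping"],
               sum(!inAny & dir == "hypo"))
  ## a CpG in both a promoter and a gene body counts in both classes
  expect_true(10100 %in% pos)  # inside [8500,10500) and [10000,20000)
  ## whole-region row recovers the significant total
  expect_equal(got$nHypo[got$class == "whole_region"] +
               got$nHyper[got$class == "whole_region"], length(pos))
  ## empty significant set: all zero
  none <- res[0, ]
  got0 <- countSigCpGsByElement(none, cat)
  expect_true(all(got0$nHypo == 0) && all(got0$nHyper == 0))
})

test_that("site density clips, deduplicates and matches a per-base oracle", {
  region <- regionInterval("chr11", 0, 10000)
  iso <- isoGr(1, 1000, "+", "A")   # gene body [0,1000), promoter clipped
  enh <- GenomicRanges::GRanges("chr11", IRanges::IRanges(5001, 6000))
  S4Vectors::mcols(enh)$source <- "islet"
  cat <- suppressWarnings(elementCatalog(iso, enh, region))
  sites <- GenomicRanges::GRanges("chr11", IRanges::IRanges(
    c(101, 951, 5201), width = 100))
  S4Vectors::mcols(sites)$tr <- "X"
  res <- data.frame(site_id = 1, chrom = "chr11", pos = 150, delta = -0.2,
                    p = 1e-6, fdr = 1e-5, significant = TRUE,
                    direction = "hypo", tested = TRUE)
  d <- siteDensityByElement(sites, cat, res)
  ## one full site + one half-clipped site in the 1000 bp gene body
  expect_equal(d$density[d$class == "gene_bodies"], 150 / 1000)
  expect_equal(d$density[d$class == "islet_enhancers"], 100 / 1000)
  expect_equal(d$nHypoSites[d$class == "gene_bodies"], 1L)
  ## random layout vs per-base counting oracle
  set.seed(62)
  rs <- randomRanges(30, span = 9000, maxLen = 150, chrom = "chr11")
  S4Vectors::mcols(rs)$tr <- "Y"
  d2 <- siteDensityByElement(rs, cat, res)
  gb <- GenomicRanges::reduce(GenomicRanges::granges(cat$gene_bodies))
  expect_equal(d2$density[d2$class == "gene_bodies"],
               bruteCoveredBp(rs, gb) / sum(BiocGenerics::width(gb)))
  ## density is invariant to splitting class intervals
  isoSplit <- c(isoGr(1, 500, "+", "A1"), isoGr(501, 1000, "+", "A2"))
  catSplit <- suppressWarnings(elementCatalog(isoSplit, enh, region))
  dS <- siteDensityByElement(sites, catSplit, res)
  expect_equal(dS$density[dS$class == "gene_bodies"],
               d$density[d$class == "gene_bodies"])
})

test_that("signature coverage ranks score only covered windows", {
  grid <- makeWindows(regionInterval("chr11", 0, 30000), 10000)
  sig <- list(promoter = GenomicRanges::GRanges(
    "chr11", IRanges::IRanges(c(1, 15001), c(10000, 17500))))
  bg <- list(promoter = seq(0, 100, by = 0.1))
  out <- signatureCoverageRank(sig, grid, bg)
  cov <- out$perWindow$promoter_coverage
  expect_equal(cov, c(100, 25, 0))
  ## uniform background: rank equals the coverage percentile
  expect_equal(out$perWindow$promoter_rank[1:2],
               100 * ecdf(bg$promoter)(c(100, 25)))
  expect_true(is.na(out$perWindow$promoter_rank[3]))  # unscored window
  expect_equal(out$summary$scoredWindows, 2L)
  expect_error(signatureCoverageRank(sig, grid, NULL), "background")
})

test_that("element direction echo holds on simulated data", {
  for (s in c(7, 15)) {
    ds <- simulateDataset(simConfig(), seed = s)
    me <- coverageFilter(ds$me)
    res <- testCpGs(me)
    cat <- elementCatalog(ds$annotations$isoforms, ds$annotations$enhancers,
                          ds$region)
    got <- countSigCpGsByElement(res, cat)
    expect_gte(got$pctHypo[got$class == "promoters"], 75)
    expect_gte(got$pctHypo[got$class == "gene_bodies"], 75)
    expect_gte(got$pctHyper[got$class == "islet_enhancers"], 75)
    ## class counts never exceed the whole-region total
    tot <- got$nHypo[got$class == "whole_region"] +
      got$nHyper[got$class == "whole_region"]
    expect_true(all(got$nHypo + got$nHyper <= tot))
  }
})
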