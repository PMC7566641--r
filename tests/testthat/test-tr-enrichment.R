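test_that("site CpG coverage clips at boundaries and never double counts", {
  site <- GenomicRanges::GRanges("chr11", IRanges::IRanges(101, 110))  # [100,110)
  ## one interior CpG covers 2 of 10 bp
  expect_equal(siteCpGCoverage(site, cpgAt(104)), 0.2)
  ## a CpG whose second base is the site's first base contributes 1 bp
  expect_equal(siteCpGCoverage(site, cpgAt(99)), 0.1)
  ## adjacent CpGs union to 4 bp, no double counting
  expect_equal(siteCpGCoverage(site, cpgAt(c(102, 104))), 0.4)
  ## overlapping queries collapse
  expect_equal(siteCpGCoverage(site, cpgAt(c(104, 105))), 0.3)
  ## coverage sum bound: 2 bp per CpG with equality iff no clipping/overlap
  set.seed(81)
  sites <- randomRanges(50, span = 5000, maxLen = 100, chrom = "chr11")
  cpgs <- cpgAt(sort(sample(seq(0, 5500, 2), 300)))
  cov <- siteCpGCoverage(sites, cpgs)
  covered <- cov * BiocGenerics::width(sites)
  nIn <- GenomicRanges::countOverlaps(sites, cpgs)
  expect_true(all(covered <= 2 * nIn))
})

test_that("TR scoring sums site coverages and ranks with average ties", {
  sites <- GenomicRanges::GRanges("chr11", IRanges::IRanges(
    c(101, 201, 301), width = 10))
  S4Vectors::mcols(sites)$tr <- c("A", "A", "B")
  cpgs <- cpgAt(c(104, 204, 304))
  sc <- trScores(sites, cpgs)
  expect_equal(sc$score[sc$tr == "A"], 0.4)
  expect_equal(sc$rank[sc$tr == "A"], 1)
  expect_equal(sc$rank[sc$tr == "B"], 2)
  ## zero-scoring TRs leave the ranked list
  sc2 <- trScores(sites, cpgAt(104))
  expect_false("B" %in% sc2$tr)
  expect_equal(attr(sc2, "N"), 1L)
  ## expressed filter restricts the universe; empty set errors
  expect_false("B" %in% trScores(sites, cpgs, expressed = "A")$tr)
  expect_error(trScores(sites[0], cpgs), "empty")
  ## 20 random TRs match a brute-force sort oracle
  set.seed(82)
  rs <- randomRanges(200, span = 20000, maxLen = 120, chrom = "chr11")
  S4Vectors::mcols(rs)$tr <- sample(sprintf("T%02d", 1:20), 200, TRUE)
  rc <- cpgAt(sort(sample(seq(0, 20500, 2), 600)))
  got <- trScores(rs, rc)
  want <- tapply(siteCpGCoverage(rs, rc), S4Vectors::mcols(rs)$tr, sum)
  want <- want[want > 0]
  expect_equal(got$score, as.vector(want[got$tr]))
  expect_equal(got$rank, rank(-got$score, ties.method = "average"))
})

test_that("normalized rank change follows the stated formula", {
  mkList <- function(trs, ranks, N) {
    d <- data.frame(tr = trs, score = max(ranks) - ranks + 1, rank = ranks)
    attr(d, "N") <- N
    d
  }
  base <- mkList(c("A", "B"), c(10, 20), 100)
  sig <- mkList(c("A", "B"), c(1, 10), 50)
  rc <- rankChange(base, sig)
  expect_equal(rc$deltaR[rc$tr == "A"], 0.10 - 0.02)
  ## identical lists give zero everywhere
  same <- rankChange(base, base)
  expect_true(all(same$deltaR == 0))
  ## reversal of a 3-TR list is antisymmetric about the middle TR
  b3 <- mkList(c("A", "B", "C"), c(1, 2, 3), 3)
  s3 <- mkList(c("A", "B", "C"), c(3, 2, 1), 3)
  rc3 <- rankChange(b3, s3)
  expect_equal(rc3$deltaR, c(-2 / 3, 0, 2 / 3))
  ## absentees are flagged, not ranked
  s1 <- mkList("A", 1, 1)
  rc1 <- rankChange(base, s1)
  expect_true(rc1$absentFromSignificant[rc1$tr == "B"])
  expect_true(is.na(rc1$deltaR[rc1$tr == "B"]))
})

test_that("cumulative methylation is a mean of site means", {
  sites <- GenomicRanges::GRanges("chr11", IRanges::IRanges(
    c(101, 201), width = 20))
  S4Vectors::mcols(sites)$tr <- "A"
  res <- data.frame(site_id = 1:4, chrom = "chr11",
                    pos = c(104, 110, 204, 500),
                    delta = c(0.2, 0.4, -0.1, 0.9), p = 1e-6, fdr = 1e-5,
                    significant = c(TRUE, TRUE, TRUE, TRUE),
                    direction = c("hyper", "hyper", "hypo", "hyper"),
                    tested = TRUE)
  dm <- trCumulativeMethylation(sites, res)
  ## site means {+0.3, -0.1} -> mean of means +0.1 (not the pooled mean)
  expect_equal(unname(dm["A"]), 0.1)
  pooled <- mean(c(0.2, 0.4, -0.1))
  expect_false(isTRUE(all.equal(unname(dm["A"]), pooled)))
  ## a TR with no significant constituent is undefined
  far <- GenomicRanges::GRanges("chr11", IRanges::IRanges(9001, 9020))
  S4Vectors::mcols(far)$tr <- "B"
  dm2 <- trCumulativeMethylation(c(sites, far), res)
  expect_true(is.na(dm2["B"]))
})

test_that("percentile classification labels corners and degenerates safely", {
  rec <- data.frame(tr = sprintf("T%02d", 1:30),
                    deltaR = c(rep(0, 28), 0.8, -0.8),
                    deltaM = c(rep(0, 28), 0.5, -0.5))
  cl <- classifyTRs(rec)
  expect_equal(cl$class[29], "over-enriched+hyper")
  expect_equal(cl$class[30], "under-enriched+hypo")
  expect_true(all(cl$class[1:28] == "unclassified"))
  ## all-equal records classify nothing
  flat <- data.frame(tr = rec$tr, deltaR = 1, deltaM = 1)
  expect_true(all(classifyTRs(flat)$class == "unclassified"))
})

test_that("planted TR classes are recovered end to end", {
  ds <- simulateDataset(simConfig(regionLength = 400000), seed = 83)
  me <- coverageFilter(ds$me)
  res <- testCpGs(me)
  rec <- trEnrichmentAnalysis(ds$annotations$trSites, cpgSites(me), res)
  expect_equal(rec$class[rec$tr == "PDX1"],
               unname(ds$truth$trClasses["PDX1"]))
  expect_equal(rec$class[rec$tr == "NFATC1"],
               unname(ds$truth$trClasses["NFATC1"]))
  ## direction bookkeeping: no site labeled hyper without a hyper CpG
  mp <- mapTRSites(ds$annotations$trSites, res, ds$truth$dmrs)
  pdx <- mp$perTR[mp$perTR$tr == "PDX1", ]
  expect_equal(pdx$nHypoSites, 0L)
  expect_gt(pdx$fracDiff, 0.9)
  nfat <- mp$perTR[mp$perTR$tr == "NFATC1", ]
  expect_equal(nfat$nHyperSites, 0L)
})

test_that("site maps count per target and a siteless TR yields zeros", {
  sites <- GenomicRanges::GRanges("chr11", IRanges::IRanges(
    c(101, 301, 901), width = 50))
  S4Vectors::mcols(sites)$tr <- c("A", "A", "B")
  res <- data.frame(site_id = 1:2, chrom = "chr11", pos = c(110, 920),
                    delta = c(0.3, -0.3), p = 1e-6, fdr = 1e-5,
                    significant = TRUE, direction = c("hyper", "hypo"),
                    tested = TRUE)
  targets <- GenomicRanges::GRanges("chr11", IRanges::IRanges(
    c(1, 801), c(400, 1000)))
  S4Vectors::mcols(targets)$name <- c("left", "right")
  mp <- mapTRSites(sites, res, targets)
  pt <- mp$perTarget
  expect_equal(pt$nSites[pt$tr == "A" & pt$target == "left"], 2L)
  expect_equal(pt$nHyperSites[pt$tr == "A" & pt$target == "left"], 1L)
  expect_equal(pt$nSites[pt$tr == "B" & pt$target == "left"], 0L)
  expect_equal(pt$nHypoSites[pt$tr == "B" & pt$target == "right"], 1L)
  expect_equal(mp$perTR$fracDiff[mp$perTR$tr == "A"], 0.5)
})

test_that("loop-score overlay preserves scores at native coordinates", {
  region <- regionInterval("chr11", 0, 30000)
  grid <- makeWindows(region, 10000)
  loops <- GenomicRanges::GRanges("chr11", IRanges::IRanges(
    c(500, 15000, 29000, 40000), width = 1))
  S4Vectors::mcols(loops)$score <- c(1, 2, 3, 4)
  cnt <- data.frame(window = 1:3, peaks = c(5, 0, 2))
  expect_message(ov <- overlayLoopScores(loops, cnt, grid, region),
                 "dropped 1")
  expect_equal(nrow(ov$loops), 3)          # every in-region score kept
  expect_equal(ov$loops$score, c(1, 2, 3)) # unnormalized
  expect_equal(ov$loops$window, c(1, 2, 3))
  expect_identical(ov$windows, cnt)        # read-only join
})
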