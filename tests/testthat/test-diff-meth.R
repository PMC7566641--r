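test_that("identical cohorts give zero delta and p = 1 everywhere", {
  set.seed(31)
  n <- 50
  tot <- matrix(rpois(n * 4, 20) + 5L, n)
  met <- matrix(rbinom(n * 4, tot, 0.5), n)
  me <- toyExperiment(cbind(met, met), cbind(tot, tot),
                      pos0 = seq(0, by = 100, length.out = n),
                      cohort = rep(c("beta", "insulinoma"), each = 4))
  res <- testCpGs(me)
  expect_true(all(res$delta == 0))
  expect_true(all(res$p == 1))
  expect_true(!any(res$significant))
})

test_that("the test is symmetric under cohort label swap", {
  ds <- simulateDataset(nullSimConfig(regionLength = 45000), seed = 32)
  me <- coverageFilter(ds$me)
  a <- testCpGs(me, control = "beta", case = "insulinoma")
  b <- testCpGs(me, control = "insulinoma", case = "beta")
  expect_equal(b$delta, -a$delta)
  expect_equal(b$p, a$p, tolerance = 1e-8)
})

test_that("BH FDR is monotone in the sorted p-values and untested sites stay NA", {
  ds <- simulateDataset(nullSimConfig(regionLength = 45000), seed = 33)
  me <- coverageFilter(ds$me)
  ## blank one site in the control cohort entirely: untestable
  m <- methReads(me); n <- totalReads(me)
  m[5, cohorts(me) == "beta"] <- NA
  n[5, cohorts(me) == "beta"] <- NA
  me2 <- MethylationExperiment(m, n, cpgSites(me),
                               data.frame(cohort = cohorts(me),
                                          group = sampleGroups(me)))
  res <- testCpGs(me2)
  expect_false(res$tested[5])
  expect_true(is.na(res$p[5]))
  o <- order(res$p[res$tested])
  expect_true(all(diff(res$fdr[res$tested][o]) >= -1e-12))
})

test_that("a strong planted difference is detected at stringent FDR", {
  set.seed(34)
  hits <- replicate(40, {
    tot <- matrix(pmax(rnbinom(24 * 10, mu = 22, size = 5), 1L), 10)
    p <- c(rep(0.4, 5), rep(0.8, 19))
    th <- 0.98 / 0.02
    pp <- matrix(rbeta(24 * 10, rep(p, each = 10) * th,
                       rep(1 - p, each = 10) * th), 10)
    y <- matrix(rbinom(24 * 10, tot, pp), 10)
    me <- toyExperiment(y, tot, pos0 = seq(0, by = 100, length.out = 10),
                        cohort = rep(c("beta", "insulinoma"), c(5, 19)))
    mean(testCpGs(me)$significant)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("DMR chaining follows the bandwidth and constituent rules", {
  mk <- function(pos, sig, delta = -0.3, fdr = 1e-4)
    data.frame(site_id = seq_along(pos), chrom = "chr11", pos = pos,
               delta = delta, p = fdr, fdr = ifelse(sig, fdr, 0.5),
               significant = sig,
               direction = ifelse(sig, ifelse(delta < 0, "hypo", "hyper"),
                                  NA),
               tested = TRUE)
  res <- mk(c(100, 500, 900), c(TRUE, TRUE, TRUE))
  d <- callDMRs(res, bandwidth = 1000, minCpgs = 3)
  expect_length(d, 1)
  expect_equal(BiocGenerics::start(d) - 1, 100)  # 0-based [100, 901)
  expect_equal(BiocGenerics::end(d), 901)
  expect_equal(d$nCpgs, 3L)
  expect_equal(d$direction, "hypo")
  ## two sites 5 kb apart never form a DMR at minCpgs = 3
  expect_length(callDMRs(mk(c(100, 5100), c(TRUE, TRUE))), 0)
  ## non-significant sites are never constituents
  res2 <- mk(c(100, 500, 900, 1300), c(TRUE, TRUE, FALSE, TRUE))
  d2 <- callDMRs(res2)
  expect_length(d2, 1)
  expect_false("3" %in% strsplit(d2$sites, ",")[[1]])
})

test_that("planted blocks are recovered as DMRs with high overlap", {
  ds <- simulateDataset(simConfig(), seed = 36)
  me <- coverageFilter(ds$me)
  res <- testCpGs(me)
  dmrs <- callDMRs(res)
  for (d in c("hypo", "hyper"))
    expect_gte(intervalJaccard(dmrs[dmrs$direction == d],
                               ds$truth$dmrs[ds$truth$dmrs$direction == d]),
               0.8)
})

test_that("the five-step signature procedure honors measurability and size", {
  ds <- simulateDataset(simConfig(), seed = 37)
  me <- coverageFilter(ds$me)
  sg <- groupSignature(me)
  ## signature is a subset of the everywhere-measurable set, ~5% of it
  expect_true(all(sg$signatureIds %in% sg$measurableIds))
  frac <- length(sg$signatureIds) / length(sg$eligibleIds)
  expect_lt(abs(frac - 0.05), 0.01)
  ## a CpG blanked in one group is excluded regardless of effect
  m <- methReads(me); n <- totalReads(me)
  g2 <- which(sampleGroups(me) == "group2")
  victim <- sg$signatureIds[1]
  row <- which(cpgSites(me)$site_id == victim)
  m[row, g2] <- NA; n[row, g2] <- NA
  me2 <- MethylationExperiment(m, n, cpgSites(me),
                               data.frame(cohort = cohorts(me),
                                          group = sampleGroups(me)))
  sg2 <- groupSignature(me2)
  expect_false(victim %in% sg2$measurableIds)
  expect_false(victim %in% sg2$signatureIds)
  ## a group of one sample cannot provide a standard deviation
  bad <- sampleGroups(me)
  bad[bad == "group3"] <- "group2"
  bad[which(cohorts(me) == "insulinoma")[1]] <- "group3"
  me3 <- MethylationExperiment(methReads(me), totalReads(me), cpgSites(me),
                               data.frame(cohort = cohorts(me), group = bad))
  expect_error(groupSignature(me3), "at least 2 samples")
})

test_that("null signatures are unbiased; planted signatures are recovered", {
  ## no planted structure: signature positions spread uniformly
  ds0 <- simulateDataset(nullSimConfig(regionLength = 67500), seed = 38)
  me0 <- coverageFilter(ds0$me)
  sg0 <- groupSignature(me0)
  pos <- BiocGenerics::start(cpgSites(me0))[
    cpgSites(me0)$site_id %in% sg0$signatureIds]
  span <- range(BiocGenerics::start(cpgSites(me0)))
  bins <- table(cut(pos, breaks = seq(span[1] - 1, span[2] + 1,
                                      length.out = 6)))
  expect_gt(chisq.test(bins)$p.value, 0.01)
  ## planted signatures: high sensitivity
  ds <- simulateDataset(simConfig(), seed = 39)
  sg <- groupSignature(coverageFilter(ds$me))
  expect_gte(mean(unlist(ds$truth$signatureSites) %in% sg$signatureIds),
             0.8)
})

test_that("direction-signature association reduces to the Pearson chi-square", {
  mk <- function(tab) {
    n <- sum(tab)
    data.frame(site_id = seq_len(n), chrom = "chr11",
               pos = seq_len(n) * 100,
               delta = rep(c(-0.2, -0.2, 0.2, 0.2), tab),
               p = 1e-5, fdr = 1e-4, significant = TRUE,
               direction = rep(c("hypo", "hypo", "hyper", "hyper"), tab),
               tested = TRUE)
  }
  res <- mk(c(10, 10, 10, 10))
  sig <- res$site_id[rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 10, 10, 10))]
  a <- directionSignatureAssociation(res, sig)
  expect_equal(a$statistic, 0)
  expect_equal(a$df, 1)
  res2 <- mk(c(20, 0, 0, 20))
  sig2 <- res2$site_id[res2$direction == "hypo"]
  a2 <- directionSignatureAssociation(res2, sig2)
  expect_equal(a2$statistic, 40)
  expect_error(directionSignatureAssociation(res, integer()), "empty margin")
})

test_that("ward clustering on 1-Pearson distance behaves deterministically", {
  set.seed(41)
  n <- 200
  ## two cohorts with distinct per-site methylation profiles, so that
  ## within-cohort sample columns are correlated
  pA <- runif(n, 0.1, 0.9)
  pB <- runif(n, 0.1, 0.9)
  base <- cbind(matrix(rbinom(n * 3, 20, pA), n),
                matrix(rbinom(n * 3, 20, pB), n))
  tot <- matrix(20L, n, 6)
  base[, 2] <- base[, 1]  # duplicate sample columns
  me <- toyExperiment(base, tot, pos0 = seq(0, by = 10, length.out = n),
                      cohort = rep(c("beta", "insulinoma"), each = 3))
  hc <- sampleDistanceCluster(me, k = 2)
  m1 <- hc$merge[1, ]
  expect_setequal(abs(m1), c(1, 2))      # identical columns merge first
  expect_equal(hc$height[1], 0)
  cl <- attr(hc, "clusters")
  expect_equal(length(unique(cl[1:3])), 1)  # planted split recovered
  expect_equal(length(unique(cl[4:6])), 1)
  expect_false(cl[1] == cl[4])
  ## permuting samples leaves merge heights unchanged
  perm <- c(4, 1, 5, 2, 6, 3)
  me2 <- toyExperiment(base[, perm], tot[, perm],
                       pos0 = seq(0, by = 10, length.out = n),
                       cohort = rep(c("beta", "insulinoma"), each = 3)[perm])
  expect_equal(sort(sampleDistanceCluster(me2)$height), sort(hc$height))
})
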