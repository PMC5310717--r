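test_that("allele frequencies are copy counts over typed gene copies", {
  # 12 diploids carrying 19 copies of allele 97 and 5 of allele 100
  pairs <- c(rep(list(c(97, 97)), 7), rep(list(c(97, 100)), 5))
  a1 <- vapply(pairs, `[`, 0, 1)
  a2 <- vapply(pairs, `[`, 0, 2)
  g <- newGenotypes(matrix(a1), matrix(a2), "C113")
  f <- alleleFrequencies(g)[["C113"]]
  expect_equal(round(unname(f["97"]), 3), 0.792)
  expect_equal(round(unname(f["100"]), 3), 0.208)

  hom <- genoFrom(c(100, 100), c(100, 100))
  expect_equal(unname(alleleFrequencies(hom)[["L1"]]["100"]), 1)

  # counting oracle on a random table
  set.seed(2)
  p <- studyPanel(seed = 2)
  gg <- simulateGenotypes(40, "pureA", p)
  f1 <- alleleFrequencies(gg)[[1]]
  tab <- table(c(gg@a1[, 1], gg@a2[, 1]))
  expect_equal(unname(f1), unname(as.numeric(tab) / 80))
  expect_error(alleleFrequencies(gg, integer(0)), "empty")
})

test_that("rarefied richness equals the exhaustive subsample average", {
  # N = 6 copies, counts (4, 2), g = 2: enumerate all C(6,2) subsamples
  copies <- c(1, 1, 1, 1, 2, 2)
  subs <- combn(6, 2)
  manual <- mean(apply(subs, 2, function(ix)
    length(unique(copies[ix]))))
  expect_equal(rarefiedAllelicRichness(c(4, 2), 2), manual)
  # full sample returns the observed allele count; monomorphic gives 1
  expect_equal(rarefiedAllelicRichness(c(4, 2), 6), 2)
  expect_equal(rarefiedAllelicRichness(c(9), 4), 1)
  expect_error(rarefiedAllelicRichness(c(4, 2), 0), "at least 1")
  # monotone non-decreasing in g
  ar <- vapply(1:10, function(g)
    rarefiedAllelicRichness(c(5, 3, 2), g), numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("unbiased He is zero only for monomorphic loci", {
  het <- heterozygosity(genoFrom(c(100, 100, 97, 100),
                                 c(100, 100, 97, 97)))
  expect_equal(het$He[1], 0)
  expect_gt(het$He[2], 0)
  expect_true(all(het$He >= 0 & het$He <= 1))
})

test_that("monomorphic markers are screened out before analysis", {
  p <- studyPanel(seed = 2, includeMonomorphic = TRUE)
  g <- simulateGenotypes(15, "pureA", p)
  sc <- screenMonomorphic(g)
  expect_true("EF15-Mluc" %in% sc$monomorphic)
  expect_false("EF15-Mluc" %in% lociNames(sc$genotypes))
})

test_that("HWE exact test matches enumeration and detects deficits", {
  # monomorphic: single possible array
  mono <- matrix(c(100, 100), 3, 2, byrow = TRUE)
  expect_equal(hweExactTest(mono)$p, 1)

  # (AA = 3, AB = 4, BB = 3): chain estimate within 3 SE of complete
  # enumeration
  gt <- rbind(matrix(c(97, 97), 3, 2, byrow = TRUE),
              matrix(c(97, 100), 4, 2, byrow = TRUE),
              matrix(c(100, 100), 3, 2, byrow = TRUE))
  pe <- hweExactTest(gt, method = "enumeration")
  pm <- hweExactTest(gt, method = "markov_chain", mc_burnin = 2000,
                     mc_steps = 40000, seed = 3)
  expect_lt(abs(pm$p - pe$p), 3 * max(pm$se, 1e-3))

  # strong heterozygote deficit: AA = 10, AB = 0, BB = 10
  def <- rbind(matrix(c(97, 97), 10, 2, byrow = TRUE),
               matrix(c(100, 100), 10, 2, byrow = TRUE))
  expect_lt(hweExactTest(def, method = "enumeration")$p, 0.001)
})

test_that("the LD permutation test flags perfect association", {
  set.seed(11)
  p <- studyPanel(seed = 2)
  g <- simulateGenotypes(40, "pureA", p)
  dup <- newGenotypes(cbind(g@a1[, 1], g@a1[, 1]),
                      cbind(g@a2[, 1], g@a2[, 1]), c("L1", "L2"))
  r <- genotypicLdTest(dup, "L1", "L2", permutations = 200, seed = 5)
  expect_lt(r$p, 0.02)
  # independent loci are usually unremarkable
  r2 <- genotypicLdTest(g, 1, 2, permutations = 200, seed = 5)
  expect_gte(r2$p, 1 / 201)
  # monomorphic locus is skipped with a reason
  mono <- newGenotypes(cbind(g@a1[, 1], 100L), cbind(g@a2[, 1], 100L),
                       c("L1", "L2"))
  expect_match(genotypicLdTest(mono, 1, 2)$skipped, "monomorphic")
})

test_that("LD permutation p-values are roughly uniform under the null", {
  set.seed(12)
  p <- makeParentalFrequencies(2, 4, 0, seed = 12)
  ps <- vapply(1:40, function(i) {
    g <- simulateGenotypes(30, "pureA", p)
    genotypicLdTest(g, 1, 2, permutations = 99, seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.001)
})

test_that("Weir-Cockerham theta behaves at the calibration points", {
  set.seed(13)
  p <- studyPanel(seed = 2)
  g <- simulateGenotypes(60, "pureA", p)
  # a group compared with itself: theta about zero
  dup <- newGenotypes(rbind(g@a1, g@a1), rbind(g@a2, g@a2), lociNames(p))
  th0 <- weirCockerhamFst(dup, rep(c("x", "y"), each = 60))
  expect_lt(abs(th0$overall), 0.01)
  # fixed alternative alleles: theta = 1
  fx <- genoFrom(c(97, 97), c(97, 97), c(100, 100), c(100, 100))
  th1 <- weirCockerhamFst(fx, c("a", "a", "b", "b"))
  expect_equal(th1$overall, 1)
  expect_error(weirCockerhamFst(fx, c("a", "a", "a", "a")), "two groups")
})

test_that("theta matches hand-computed variance components on a toy set", {
  # two populations, one diallelic locus:
  # pop1: 2 x 97/97, 2 x 97/100; pop2: 1 x 97/100, 3 x 100/100
  g <- genoFrom(c(97, 97), c(97, 97), c(97, 100), c(97, 100),
                c(97, 100), c(100, 100), c(100, 100), c(100, 100))
  grp <- rep(c("p1", "p2"), each = 4)
  # hand algebra (Weir & Cockerham 1984 components for allele 97):
  r <- 2; ni <- c(4, 4); nbar <- 4
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pi <- c(6 / 8, 1 / 8); hi <- c(2 / 4, 1 / 4)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  manual <- (2 * a) / (2 * (a + b + cc))   # both alleles double the sums
  th <- weirCockerhamFst(g, grp)
  expect_equal(th$overall, manual, tolerance = 1e-12)
})

test_that("theta ordering mirrors admixture structure", {
  set.seed(14)
  p <- studyPanel(seed = 2)
  gA <- simulateGenotypes(60, "pureA", p)
  gB <- simulateGenotypes(60, "pureB", p)
  gH <- simulateGenotypes(60, "F1", p)
  g <- newGenotypes(rbind(gA@a1, gB@a1, gH@a1),
                    rbind(gA@a2, gB@a2, gH@a2), lociNames(p))
  grp <- rep(c("A", "B", "H"), each = 60)
  th <- weirCockerhamFst(g, grp)
  expect_gt(th$pairwise["A", "B"], th$pairwise["A", "H"])
  expect_gt(th$pairwise["A", "B"], th$pairwise["B", "H"])
})

test_that("the G-test matches direct arithmetic and the chi-square null", {
  g <- genoFrom(c(97, 97), c(97, 97), c(97, 97), c(97, 97), c(97, 97),
                c(100, 100), c(100, 100), c(100, 100), c(100, 100),
                c(100, 100))
  grp <- rep(c("a", "b"), each = 5)
  r <- gtestAlleleHomogeneity(g, grp)
  expect_equal(r$G, 2 * 20 * log(2), tolerance = 1e-9)
  expect_equal(r$df, 1)
  # identical polymorphic groups give G = 0, p = 1
  mix <- genoFrom(c(97, 97), c(97, 100), c(100, 100))
  same <- newGenotypes(rbind(mix@a1, mix@a1), rbind(mix@a2, mix@a2), "L1")
  expect_error(gtestAlleleHomogeneity(same, rep("a", 6)), "two groups")
  r0 <- gtestAlleleHomogeneity(same, rep(c("a", "b"), each = 3))
  expect_equal(r0$G, 0)
  expect_equal(r0$p, 1)
})

test_that("G-test type-I rate is near nominal under the null", {
  set.seed(15)
  p <- makeParentalFrequencies(1, 4, 0, seed = 15)
  rej <- vapply(1:400, function(i) {
    g <- simulateGenotypes(60, "pureA", p)
    gtestAlleleHomogeneity(g, rep(c("a", "b"), 30))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("FDR adjustment reproduces the step-up arithmetic", {
  expect_equal(fdrAdjust(rep(1, 4)), rep(1, 4))
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.2), 0.2)
  expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("locus diversity summaries stay within their ranges", {
  set.seed(16)
  p <- studyPanel(seed = 2)
  gA <- simulateGenotypes(25, "pureA", p)
  gB <- simulateGenotypes(10, "pureB", p)
  g <- newGenotypes(rbind(gA@a1, gB@a1), rbind(gA@a2, gB@a2),
                    lociNames(p))
  div <- locusDiversity(g, rep(c("A", "B"), c(25, 10)))
  expect_true(all(div$Ho >= 0 & div$Ho <= 1))
  expect_true(all(div$He >= 0 & div$He <= 1))
  expect_true(all(div$Ar >= 1))
  expect_true(all(div$hwe_p >= 0 & div$hwe_p <= 1))
  # Ar never exceeds the observed allele count of the group
  for (i in seq_len(nrow(div))) {
    sub <- if (div$group[i] == "A") gA else gB
    l <- match(div$locus[i], lociNames(p))
    k <- length(unique(c(sub@a1[, l], sub@a2[, l])))
    expect_lte(div$Ar[i], k + 1e-9)
  }
})
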