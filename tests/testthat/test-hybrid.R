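test_that("genotype probabilities mix Hardy-Weinberg and cross terms", {
  al <- c(97L, 100L)
  # purebred Hardy-Weinberg at p = 0.5
  expect_equal(genotypeProbGivenClass(c(97, 100), "pureA", c(0.5, 0.5),
                                      c(1, 0), al), 0.5)
  expect_equal(genotypeProbGivenClass(c(97, 97), "pureA", c(0.5, 0.5),
                                      c(1, 0), al), 0.25)
  # F1 between fixed pools is a forced heterozygote
  expect_equal(genotypeProbGivenClass(c(97, 100), "F1", c(0, 1), c(1, 0),
                                      al), 1)
  # F2 between fixed pools: exhaustive F1-gamete-pair enumeration gives
  # 1/4, 1/2, 1/4
  expect_equal(genotypeProbGivenClass(c(100, 100), "F2", c(0, 1), c(1, 0),
                                      al), 0.25)
  expect_equal(genotypeProbGivenClass(c(97, 100), "F2", c(0, 1), c(1, 0),
                                      al), 0.5)
  expect_equal(genotypeProbGivenClass(c(97, 97), "F2", c(0, 1), c(1, 0),
                                      al), 0.25)
  expect_error(genotypeProbGivenClass(c(95, 97), "F1", c(0, 1), c(1, 0),
                                      al), "absent")
})

test_that("genotype probabilities sum to one over all genotypes", {
  set.seed(5)
  al <- as.integer(c(100, 102, 104, 106))
  fa <- as.numeric(rmultinom(1, 50, rep(0.25, 4))) / 50
  fb <- as.numeric(rmultinom(1, 50, c(0.4, 0.3, 0.2, 0.1))) / 50
  gens <- rbind(t(combn(al, 2)), cbind(al, al))
  for (cl in hybridClasses()) {
    tot <- sum(apply(gens, 1, function(g)
      genotypeProbGivenClass(g, cl, fa, fb, al)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("well-separated groups yield degenerate posteriors", {
  p <- fixedPanel(10)
  gA <- simulateGenotypes(20, "pureA", p)
  gB <- simulateGenotypes(20, "pureB", p)
  g <- newGenotypes(rbind(gA@a1, gB@a1), rbind(gA@a2, gB@a2),
                    lociNames(p))
  post <- fitHybridMixture(g, mcmcSettings(1e4, 1e5, seed = 2))
  q <- qMatrix(post)
  own1 <- pmax(q[1:20, "pureA"], q[1:20, "pureB"])
  own2 <- pmax(q[21:40, "pureA"], q[21:40, "pureB"])
  expect_true(all(own1 >= 0.99))
  expect_true(all(own2 >= 0.99))
  # the two groups sit in opposite clusters
  cl1 <- ifelse(q[1:20, "pureA"] > q[1:20, "pureB"], "A", "B")
  cl2 <- ifelse(q[21:40, "pureA"] > q[21:40, "pureB"], "A", "B")
  expect_equal(length(unique(cl1)), 1)
  expect_equal(length(unique(cl2)), 1)
  expect_false(cl1[1] == cl2[1])
})

test_that("mixture posterior agrees with grid-quadrature brute force", {
  # single diallelic locus, four individuals: integrate the exact
  # posterior over (pA, pB) on a midpoint grid and over the mixing
  # proportions analytically (Dirichlet-multinomial), summing over all
  # 6^4 class assignments
  al <- c(97L, 100L)
  g <- genoFrom(c(100, 100), c(97, 97), c(97, 100), c(100, 100))
  cls <- hybridClasses()
  grid <- seq(0.005, 0.995, by = 0.01)
  G <- length(grid)
  pa <- rep(grid, times = G)
  pb <- rep(grid, each = G)
  lik <- array(0, c(4, 6, G * G))
  for (i in 1:4) for (c in 1:6) {
    gt <- c(g@a1[i, 1], g@a2[i, 1])
    lik[i, c, ] <- vapply(seq_len(G * G), function(k)
      genotypeProbGivenClass(gt, cls[c], c(pa[k], 1 - pa[k]),
                             c(pb[k], 1 - pb[k]), al), numeric(1))
  }
  combos <- as.matrix(expand.grid(1:6, 1:6, 1:6, 1:6))
  qref <- matrix(0, 4, 6)
  for (r in seq_len(nrow(combos))) {
    zc <- combos[r, ]
    nc <- tabulate(zc, 6)
    logpz <- lgamma(6) - lgamma(6 + 4) + sum(lgamma(1 + nc))
    mass <- exp(logpz) *
      mean(lik[1, zc[1], ] * lik[2, zc[2], ] * lik[3, zc[3], ] *
             lik[4, zc[4], ])
    for (i in 1:4) qref[i, zc[i]] <- qref[i, zc[i]] + mass
  }
  qref <- qref / rowSums(qref)
  post <- fitHybridMixture(g, mcmcSettings(2e4, 6e5, seed = 4))
  expect_lt(max(abs(qMatrix(post) - qref)), 0.02)
})

test_that("threshold criteria implement the published assignment rules", {
  q <- rbind(c(0.80, 0.05, 0.05, 0.05, 0.03, 0.02),
             c(0.60, 0.05, 0.10, 0.10, 0.10, 0.05),
             c(0.04, 0.05, 0.40, 0.31, 0.10, 0.10))
  colnames(q) <- hybridClasses()
  third <- assignHybrids(q, Tq = 0.75, criterion = "third")
  expect_equal(as.character(third), c("pureA", "hybrid", "hybrid"))
  second <- assignHybrids(q, Tq = 0.75, criterion = "second")
  expect_equal(as.character(second),
               c("pureA", "unassigned", "hybrid"))
  # combined hybrid q of 0.91 at Tq = 0.90 is assigned hybrid
  q2 <- matrix(c(0.05, 0.04, 0.40, 0.31, 0.10, 0.10), 1,
               dimnames = list(NULL, hybridClasses()))
  expect_equal(as.character(assignHybrids(q2, 0.90, "second")), "hybrid")
  # ties at exactly Tq are assigned
  q3 <- matrix(c(0.75, 0.05, 0.05, 0.05, 0.05, 0.05), 1,
               dimnames = list(NULL, hybridClasses()))
  expect_equal(as.character(assignHybrids(q3, 0.75, "third")), "pureA")
  expect_error(assignHybrids(q3, 0.4), "Tq")
})

test_that("raising Tq moves calls monotonically", {
  set.seed(8)
  q <- matrix(rgamma(600, 0.5), 100, 6)
  q <- q / rowSums(q)
  colnames(q) <- hybridClasses()
  tqs <- c(0.6, 0.75, 0.9, 1)
  prev3 <- assignHybrids(q, tqs[1], "third")
  prev2 <- assignHybrids(q, tqs[1], "second")
  for (tq in tqs[-1]) {
    now3 <- assignHybrids(q, tq, "third")
    # a hybrid call never reverts to purebred under the third criterion
    expect_true(all(now3[prev3 == "hybrid"] == "hybrid"))
    now2 <- assignHybrids(q, tq, "second")
    # the second criterion only moves calls toward unassigned
    moved <- now2 != prev2
    expect_true(all(now2[moved] == "unassigned"))
    prev3 <- now3
    prev2 <- now2
  }
})

test_that("anchor genotypes label the clusters and flag violations", {
  q <- rbind(a1 = c(0.95, 0.01, 0.01, 0.01, 0.01, 0.01),
             a2 = c(0.01, 0.95, 0.01, 0.01, 0.01, 0.01),
             s1 = c(0.90, 0.04, 0.02, 0.02, 0.01, 0.01))
  colnames(q) <- hybridClasses()
  post <- new("HybridPosterior", q = q, freqA = list(), freqB = list(),
              alleles = list(), loci = character(0), settings = list())
  map <- labelClustersWithAnchors(post, c("a1", "a2"),
                                  c("M. myotis", "M. blythii"))
  expect_equal(unname(map["clusterA"]), "M. myotis")
  expect_equal(unname(map["clusterB"]), "M. blythii")
  # species without anchors stays unlabelled
  map1 <- labelClustersWithAnchors(post, "a1", "M. myotis")
  expect_true(is.na(map1["clusterB"]))
  # an anchor classified hybrid is a contract violation
  qh <- q
  qh["a1", ] <- c(0.2, 0.1, 0.3, 0.2, 0.1, 0.1)
  posth <- new("HybridPosterior", q = qh, freqA = list(), freqB = list(),
               alleles = list(), loci = character(0), settings = list())
  expect_error(labelClustersWithAnchors(posth, c("a1", "a2"),
                                        c("M. myotis", "M. blythii")),
               "hybrid")
})

test_that("degenerate inputs to the sampler raise errors", {
  g <- genoFrom(c(100, 100), c(100, 100))
  expect_error(fitHybridMixture(g), "monomorphic")
  expect_error(fitHybridMixture(g[1]), "2 individuals")
  expect_error(mcmcSettings(burn_in = 0), "positive")
})
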