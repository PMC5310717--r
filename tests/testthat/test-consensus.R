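onePanel <- function(loci = "L1") {
  new("LocusPanel", loci = loci,
      alleles = rep(list(c(97L, 98L, 100L, 101L)), length(loci)),
      freqA = rep(list(rep(0.25, 4)), length(loci)),
      freqB = rep(list(rep(0.25, 4)), length(loci)))
}

test_that("the recorded-twice rule drives per-locus consensus calls", {
  p <- onePanel()
  # two identical heterozygous reads
  r <- rbind(readRow("s1", "L1", 97, 100, replicate = 1),
             readRow("s1", "L1", 97, 100, replicate = 2))
  cons <- consensusFromReplicates(r, p)
  expect_equal(unname(cons$genotypes@a1[1, 1]), 97L)
  expect_equal(unname(cons$genotypes@a2[1, 1]), 100L)
  expect_true(cons$genotypes@meta$complete[1])

  # allele seen once is rejected and contradicts the single accepted one
  r <- rbind(readRow("s1", "L1", 97, 100, replicate = 1),
             readRow("s1", "L1", 97, NA, replicate = 2))
  cons <- consensusFromReplicates(r, p)
  expect_true(is.na(cons$genotypes@a1[1, 1]))
  expect_false(cons$genotypes@meta$complete[1])
  expect_equal(nInd(cons$complete), 0)

  # concordant single-allele reads call a homozygote
  r <- rbind(readRow("s1", "L1", 100, NA, replicate = 1),
             readRow("s1", "L1", 100, NA, replicate = 2))
  cons <- consensusFromReplicates(r, p)
  expect_equal(unname(cons$genotypes@a1[1, 1]), 100L)
  expect_equal(unname(cons$genotypes@a2[1, 1]), 100L)

  expect_error(consensusFromReplicates(readRow("s1", "LX", 97, 100), p),
               "outside the panel")
})

test_that("consensus calls are invariant to replicate order", {
  p <- onePanel(c("L1", "L2"))
  r <- rbind(readRow("s1", "L1", 97, 100, replicate = 1),
             readRow("s1", "L1", 97, 100, replicate = 2),
             readRow("s1", "L2", 98, NA, replicate = 1),
             readRow("s1", "L2", 98, NA, replicate = 2))
  c1 <- consensusFromReplicates(r, p)
  c2 <- consensusFromReplicates(r[rev(seq_len(nrow(r))), ], p)
  expect_identical(c1$genotypes@a1, c2$genotypes@a1)
  expect_identical(c1$genotypes@a2, c2$genotypes@a2)
})

test_that("mismatch counting compares allele pairs as multisets", {
  g <- genoFrom(c(97, 100, 98, 98),
                c(97, 100, 98, 98),
                c(97, 97, 98, 98),
                c(98, 101, 98, 98))
  mm <- mismatchMatrix(g)
  expect_equal(unname(mm[1, 2]), 0L)   # identical
  expect_equal(unname(mm[1, 3]), 1L)   # het vs hom sharing one allele
  expect_equal(unname(mm[1, 4]), 2L)   # disjoint pairs at one locus
  expect_true(isSymmetric(mm))
})

test_that("near-identity matching collapses samples into individuals", {
  # identical pair -> one individual; two-allele difference -> separate
  g <- genoFrom(c(97, 100, 98, 98),
                c(97, 100, 98, 98),
                c(98, 101, 98, 98))
  m <- matchIndividuals(g, max_mismatch = 1)
  expect_equal(nrow(m$individuals), 2)
  expect_equal(sort(m$individuals$n_samples), c(1L, 2L))
  expect_false(any(m$individuals$ambiguous))

  # non-transitive chain A-B 1, B-C 1, A-C 2: single linkage merges all
  # three and flags the cluster; verified against the exhaustive
  # pairwise mismatch matrix
  ch <- genoFrom(c(97, 97, 98, 98),
                 c(97, 100, 98, 98),
                 c(100, 100, 98, 98))
  mm <- mismatchMatrix(ch)
  expect_equal(unname(mm[1, 2]), 1L)
  expect_equal(unname(mm[2, 3]), 1L)
  expect_equal(unname(mm[1, 3]), 2L)
  mc <- matchIndividuals(ch, max_mismatch = 1)
  expect_equal(nrow(mc$individuals), 1)
  expect_true(mc$individuals$ambiguous[1])

  expect_error(matchIndividuals(genoFrom(c(NA, NA, 98, 98))), "complete")
})

test_that("matching is monotone in the mismatch threshold", {
  set.seed(20)
  p <- studyPanel(seed = 2)
  g <- simulateGenotypes(30, "pureA", p)
  n_prev <- Inf
  for (t in 0:4) {
    n_now <- nrow(matchIndividuals(g, max_mismatch = t)$individuals)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("error-free pipelines recover the true sample-individual map", {
  p <- studyPanel(seed = 2)
  ind <- makeTrueIndividuals(c(pureA = 30, pureB = 10, F1 = 5), p,
                             seed = 21)
  cfg <- colonyConfig(dropout_rate = 0, false_allele_rate = 0,
                      sample_failure_rate = 0, seed = 22)
  sim <- simulateColonyDataset(ind, p, cfg)
  cons <- consensusFromReplicates(sim$replicates, p)
  m <- matchIndividuals(cons$complete)
  truth <- sim$truth$individual_id[match(names(m$membership),
                                         sim$truth$sample_id)]
  # same partition: inferred ids are a relabelling of the true ids
  expect_equal(length(unique(m$membership)), length(unique(truth)))
  expect_true(all(tapply(truth, m$membership,
                         function(x) length(unique(x)) == 1)))
  # permuting sample order leaves the partition unchanged
  perm <- sample(nInd(cons$complete))
  m2 <- matchIndividuals(cons$complete[perm])
  part1 <- split(names(m$membership), m$membership)
  part2 <- split(names(m2$membership), m2$membership)
  canon <- function(p) unname(lapply(p, sort)[order(vapply(lapply(p, sort),
                                                           `[`, "", 1))])
  expect_identical(canon(part1), canon(part2))
})

test_that("per-date tallies report amplification success", {
  expect_equal(amplificationSuccess(50, 36), 72)
  expect_equal(amplificationSuccess(0, 0), 0)
  p <- onePanel()
  r <- rbind(readRow("s1", "L1", 97, 100, replicate = 1),
             readRow("s1", "L1", 97, 100, replicate = 2),
             readRow("s2", "L1", 97, NA, replicate = 1),
             readRow("s2", "L1", 100, NA, replicate = 2))
  cons <- consensusFromReplicates(r, p)
  m <- matchIndividuals(cons$complete)
  tl <- tallySamples(cons, m$membership)
  expect_equal(tl$collected[1], 2)
  expect_equal(tl$genotyped[1], 1)
  expect_equal(tl$individuals[1], 1)
  expect_equal(tl$success_pct[1], 50)
})
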