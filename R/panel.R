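#' Dirichlet draw
#' @noRd
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Allele-frequency differential between two populations
#'
#' The per-locus divergence \eqn{\delta = \frac12 \sum_a |p_{A,a} - p_{B,a}|}
#' (total-variation distance between the allele-frequency vectors; the
#' standard multi-allelic extension of the diallelic frequency differential).
#' \eqn{\delta = 1} means a fixed difference, 0 identical pools.
#'
#' @param pA,pB numeric frequency vectors over the same allele list.
#' @return delta in [0, 1].
#' @examples
#' alleleFreqDifferential(c(0.9, 0.1), c(0.2, 0.8))  # 0.7
#' @export
alleleFreqDifferential <- function(pA, pB) {
  if (length(pA) != length(pB))
    stop("frequency vectors must share the same allele support")
  sum(abs(pA - pB)) / 2
}

#' Construct parental allele-frequency pools with target differentials
#'
#' Builds a \linkS4class{LocusPanel} whose per-locus frequency vectors for
#' species A and B realise the requested allele-frequency differentials
#' exactly. Starting from a shared Dirichlet draw \eqn{m}, mass
#' \eqn{\delta/2} is transferred in opposite directions between two small
#' disjoint allele sets: a set I enriched in species A (and depleted in
#' B) and a set J enriched in B (and depleted in A), each set chosen as
#' the smallest prefix of the remaining largest alleles whose mass covers
#' the transfer. Because the donating side gives up most of its mass on
#' those alleles, the construction yields nearly species-private alleles
#' - the frequency structure strongly differentiated microsatellite
#' panels actually show (one allele common in one species and rare in the
#' other) - while realising \eqn{\frac12\sum_a |p_{A,a} - p_{B,a}|}
#' equal to the target exactly.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus integer vector (recycled) of allele counts.
#' @param delta_targets numeric vector (recycled) of target differentials
#'   in [0, 1].
#' @param seed integer RNG seed (the construction is stochastic through
#'   the Dirichlet draws).
#' @param locus_names optional character names; defaults to L1, L2, ...
#' @param allele_labels optional list of integer allele labels per locus;
#'   defaults to fragment sizes 100, 102, 104, ...
#' @return a \linkS4class{LocusPanel}.
#' @examples
#' p <- makeParentalFrequencies(3, 6, c(0, 0.5, 1), seed = 1)
#' @export
makeParentalFrequencies <- function(n_loci, alleles_per_locus, delta_targets,
                                    seed = NULL, locus_names = NULL,
                                    allele_labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ks <- rep_len(as.integer(alleles_per_locus), n_loci)
  ds <- rep_len(as.numeric(delta_targets), n_loci)
  if (is.null(locus_names)) locus_names <- paste0("L", seq_len(n_loci))
  if (any(ds < 0 | ds > 1)) stop("delta targets must lie in [0, 1]")
  alleles <- vector("list", n_loci)
  fA <- vector("list", n_loci)
  fB <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    k <- ks[l]
    d <- ds[l]
    if (d > 0 && k < 2)
      stop(sprintf(
        "locus %s: delta target %.2f unattainable with %d allele(s)",
        locus_names[l], d, k))
    alleles[[l]] <- if (is.null(allele_labels))
      as.integer(seq(100L, by = 2L, length.out = k))
    else as.integer(allele_labels[[l]])
    if (d == 0) {
      fA[[l]] <- fB[[l]] <- rdirichlet1(rep(1, k))
    } else if (d == 1) {
      # fixed difference: disjoint supports
      idxA <- seq_len(ceiling(k / 2))
      pa <- numeric(k); pb <- numeric(k)
      pa[idxA] <- rdirichlet1(rep(1, length(idxA)))
      pb[-idxA] <- rdirichlet1(rep(1, k - length(idxA)))
      fA[[l]] <- pa; fB[[l]] <- pb
    } else {
      tau <- d / 2
      # greedy cover of mass tau with minimal overshoot: take the largest
      # alleles until covered, then swap the last one for the smallest
      # unused allele that still covers the remainder
      cover <- function(m, avail, tau) {
        o <- avail[order(m[avail], decreasing = TRUE)]
        cum <- cumsum(m[o])
        if (cum[length(o)] < tau) return(NULL)
        nI <- which(cum >= tau)[1]
        I <- o[seq_len(nI)]
        needLast <- tau - (cum[nI] - m[o[nI]])
        unused <- setdiff(avail, I)
        swap <- unused[m[unused] >= needLast]
        if (length(swap) > 0) I[nI] <- swap[which.min(m[swap])]
        I
      }
      done <- FALSE
      for (try in seq_len(500)) {
        m <- rdirichlet1(rep(1, k))
        I <- cover(m, seq_len(k), tau)
        if (is.null(I)) next
        J <- cover(m, setdiff(seq_len(k), I), tau)
        if (is.null(J)) next
        sI <- sum(m[I]); sJ <- sum(m[J])
        pa <- m; pb <- m
        pa[I] <- m[I] * (1 + tau / sI)
        pa[J] <- m[J] * (1 - tau / sJ)
        pb[I] <- m[I] * (1 - tau / sI)
        pb[J] <- m[J] * (1 + tau / sJ)
        fA[[l]] <- pa; fB[[l]] <- pb
        done <- TRUE
        break
      }
      if (!done)
        stop(sprintf(
          "locus %s: delta target %.2f unattainable with %d allele(s)",
          locus_names[l], d, k))
    }
  }
  new("LocusPanel", loci = locus_names, alleles = alleles,
      freqA = fA, freqB = fB)
}

#' The 11-locus study panel
#'
#' Convenience constructor of a \linkS4class{LocusPanel} emulating the
#' microsatellite kit used for Myotis myotis / M. blythii colony
#' genotyping: 11 polymorphic loci with the published per-locus
#' allele-frequency differentials (0.25-0.79) and allelic richness in the
#' 6-11 alleles/locus range. The nearly diagnostic locus C113 is diallelic
#' (alleles 97/100). The twelfth kit marker (EF15-Mluc), monomorphic in
#' the colony, is excluded here; use \code{includeMonomorphic = TRUE} to
#' append it for tests of the screening rule.
#'
#' @param seed RNG seed for the frequency construction.
#' @param includeMonomorphic append a monomorphic EF15-Mluc locus
#'   (single allele 211) as in the raw typing panel.
#' @return a \linkS4class{LocusPanel}.
#' @export
studyPanel <- function(seed = 1, includeMonomorphic = FALSE) {
  loci <- c("D15", "F19", "G2-Mluc", "G6-Mluc", "G31-Mluc", "B8-Mluc",
            "C113", "D15-Mluc", "F19-Mluc", "G30-Mluc", "H23-Mluc")
  deltas <- c(0.62, 0.50, 0.71, 0.25, 0.68, 0.50,
              0.79, 0.66, 0.59, 0.71, 0.43)
  nall <- c(12L, 10L, 10L, 7L, 7L, 11L, 2L, 10L, 10L, 10L, 11L)
  labels <- lapply(seq_along(loci), function(l)
    as.integer(seq(100L, by = 2L, length.out = nall[l])))
  labels[[which(loci == "C113")]] <- c(97L, 100L)
  p <- makeParentalFrequencies(length(loci), nall, deltas, seed = seed,
                               locus_names = loci, allele_labels = labels)
  if (includeMonomorphic) {
    p <- new("LocusPanel",
             loci = c(p@loci, "EF15-Mluc"),
             alleles = c(p@alleles, list(211L)),
             freqA = c(p@freqA, list(1)),
             freqB = c(p@freqB, list(1)))
  }
  p
}

#' @describeIn alleleFreqDifferential per-locus differentials of a panel.
#' @param panel a LocusPanel.
#' @export
panelDelta <- function(panel) {
  setNames(vapply(seq_len(nLoci(panel)), function(l)
    alleleFreqDifferential(panel@freqA[[l]], panel@freqB[[l]]),
    numeric(1)), lociNames(panel))
}
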