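#' Per-locus allele frequencies
#'
#' Frequencies are allele copies over twice the number of typed
#' individuals at the locus.
#'
#' @param g \linkS4class{MultilocusGenotypes}.
#' @param group optional logical/integer index restricting to a subset of
#'   individuals.
#' @return named list (by locus) of named frequency vectors.
#' @export
alleleFrequencies <- function(g, group = NULL) {
  if (!is.null(group)) g <- g[group]
  if (nInd(g) == 0) stop("empty group")
  out <- lapply(seq_len(nLoci(g)), function(l) {
    al <- c(g@a1[, l], g@a2[, l])
    al <- al[!is.na(al)]
    if (length(al) == 0) return(numeric(0))
    tab <- table(al)
    setNames(as.numeric(tab) / length(al), names(tab))
  })
  setNames(out, lociNames(g))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of
#' \code{g} gene copies, the hypergeometric rarefaction estimator
#' \deqn{A_r = \sum_a \left[1 - \binom{N - N_a}{g} / \binom{N}{g}\right]}
#' where \eqn{N_a} are the observed allele copy counts and \eqn{N} their
#' total.
#'
#' @param allele_counts integer copy counts per allele.
#' @param g rarefaction sample size (gene copies), \code{1 <= g <= N}.
#' @return Ar, between 1 and the observed allele count.
#' @export
rarefiedAllelicRichness <- function(allele_counts, g) {
  allele_counts <- allele_counts[allele_counts > 0]
  N <- sum(allele_counts)
  if (g < 1) stop("rarefaction size must be at least 1")
  if (g > N) stop("rarefaction size exceeds available gene copies")
  sum(1 - exp(lchoose(N - allele_counts, g) - lchoose(N, g)))
}

#' Observed and unbiased expected heterozygosity
#'
#' He uses Nei's small-sample correction \eqn{\frac{2n}{2n-1}(1 - \sum_a p_a^2)}.
#' @param g \linkS4class{MultilocusGenotypes}.
#' @return data.frame with locus, n_typed, Ho, He.
#' @export
heterozygosity <- function(g) {
  out <- lapply(seq_len(nLoci(g)), function(l) {
    ok <- !is.na(g@a1[, l])
    n <- sum(ok)
    if (n == 0)
      return(data.frame(locus = lociNames(g)[l], n_typed = 0L,
                        Ho = NA_real_, He = NA_real_))
    ho <- mean(g@a1[ok, l] != g@a2[ok, l])
    p <- alleleFrequencies(g)[[l]]
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    data.frame(locus = lociNames(g)[l], n_typed = n, Ho = ho, He = he)
  })
  do.call(rbind, out)
}

#' Screen monomorphic loci
#'
#' A marker showing a single allele across all individuals carries no
#' information and is excluded from downstream statistics, mirroring the
#' usual post-genotyping marker screening.
#'
#' @param g \linkS4class{MultilocusGenotypes}.
#' @return list with \code{monomorphic} (locus names) and \code{genotypes}
#'   (g restricted to polymorphic loci).
#' @export
screenMonomorphic <- function(g) {
  mono <- vapply(seq_len(nLoci(g)), function(l) {
    al <- unique(stats::na.omit(c(g@a1[, l], g@a2[, l])))
    length(al) <= 1
  }, logical(1))
  keep <- which(!mono)
  sub <- new("MultilocusGenotypes",
             a1 = g@a1[, keep, drop = FALSE],
             a2 = g@a2[, keep, drop = FALSE],
             loci = g@loci[keep], meta = g@meta)
  list(monomorphic = lociNames(g)[mono], genotypes = sub)
}

## ---- Hardy-Weinberg exact test -------------------------------------------

# enumerate genotype arrays consistent with allele counts na; calls f(tab)
enumArrays <- function(na, f, max_tables = Inf) {
  k <- length(na)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  count <- 0L
  tab <- matrix(0L, k, k)
  rec <- function(p, rem) {
    if (count > max_tables) return(invisible())
    if (p > nrow(pairs)) {
      if (all(rem %% 2 == 0)) {
        diag(tab) <<- rem %/% 2
        count <<- count + 1L
        if (count <= max_tables) f(tab)
      }
      return(invisible())
    }
    a <- pairs[p, 1]; b <- pairs[p, 2]
    for (x in 0:min(rem[a], rem[b])) {
      tab[a, b] <<- x
      rem2 <- rem
      rem2[a] <- rem2[a] - x
      rem2[b] <- rem2[b] - x
      rec(p + 1, rem2)
    }
    tab[a, b] <<- 0L
  }
  rec(1, as.integer(na))
  count
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype array given allele counts
#' (Levene distribution): the p-value is the total probability of arrays
#' no more probable than the observed one. Complete enumeration is used
#' when the number of arrays is small; otherwise a Markov chain over
#' random pairings of gene copies (allele-switching proposals between two
#' individuals, uniformly accepted) estimates the p-value, with a
#' batch-means standard error.
#'
#' @param genotypes two-column integer matrix of allele pairs at one
#'   locus (rows = individuals, no missing rows), or a
#'   \linkS4class{MultilocusGenotypes} with \code{locus} given.
#' @param locus locus name/index when \code{genotypes} is a container.
#' @param method "auto", "enumeration" or "markov_chain".
#' @param mc_burnin,mc_steps Markov-chain lengths.
#' @param max_tables enumeration ceiling before switching to the chain.
#' @param seed RNG seed for the chain.
#' @return list with \code{p}, \code{method}, and for the chain
#'   \code{se}.
#' @export
hweExactTest <- function(genotypes, locus = NULL,
                         method = c("auto", "enumeration", "markov_chain"),
                         mc_burnin = 1e4, mc_steps = 1e5,
                         max_tables = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (is(genotypes, "MultilocusGenotypes")) {
    stopifnot(!is.null(locus))
    l <- if (is.character(locus)) match(locus, lociNames(genotypes))
         else locus
    ok <- !is.na(genotypes@a1[, l])
    genotypes <- cbind(genotypes@a1[ok, l], genotypes@a2[ok, l])
  }
  if (nrow(genotypes) < 1) stop("need at least one individual")
  alleles <- sort(unique(c(genotypes)))
  k <- length(alleles)
  if (k == 1) return(list(p = 1, method = "trivial", se = 0))
  i1 <- match(genotypes[, 1], alleles)
  i2 <- match(genotypes[, 2], alleles)
  tab <- matrix(0L, k, k)
  for (r in seq_len(nrow(genotypes))) {
    a <- min(i1[r], i2[r]); b <- max(i1[r], i2[r])
    tab[a, b] <- tab[a, b] + 1L
  }
  na <- tabulate(c(i1, i2), k)            # allele copy counts
  lobs <- logLeveneUpper(tab, na)
  tol <- 1e-9
  if (method != "markov_chain") {
    nt <- enumArrays(na, function(x) NULL, max_tables = max_tables)
    if (nt <= max_tables || method == "enumeration") {
      tot <- 0
      enumArrays(na, function(x) {
        lp <- logLeveneUpper(x, na)
        if (lp <= lobs + tol) tot <<- tot + exp(lp)
      })
      return(list(p = min(tot, 1), method = "enumeration", se = 0))
    }
  }
  # Markov chain over pairings: swap one gene copy between two individuals
  set.seed(seed)
  n <- nrow(genotypes)
  g1 <- i1; g2 <- i2
  cur <- tab
  lcur <- lobs
  hits <- numeric(0)
  nb <- 100L
  batch <- numeric(nb)
  per <- ceiling(mc_steps / nb)
  step <- function() {
    i <- sample.int(n, 2L)
    pi <- if (runif(1) < 0.5) 1L else 2L
    pj <- if (runif(1) < 0.5) 1L else 2L
    ai <- if (pi == 1L) g1[i[1]] else g2[i[1]]
    aj <- if (pj == 1L) g1[i[2]] else g2[i[2]]
    # remove old genotypes from tab, add swapped
    rm1 <- sort(c(g1[i[1]], g2[i[1]])); rm2 <- sort(c(g1[i[2]], g2[i[2]]))
    ad1 <- sort(c(if (pi == 1L) aj else g1[i[1]],
                  if (pi == 1L) g2[i[1]] else aj))
    ad2 <- sort(c(if (pj == 1L) ai else g1[i[2]],
                  if (pj == 1L) g2[i[2]] else ai))
    cur[rm1[1], rm1[2]] <<- cur[rm1[1], rm1[2]] - 1L
    cur[rm2[1], rm2[2]] <<- cur[rm2[1], rm2[2]] - 1L
    cur[ad1[1], ad1[2]] <<- cur[ad1[1], ad1[2]] + 1L
    cur[ad2[1], ad2[2]] <<- cur[ad2[1], ad2[2]] + 1L
    if (pi == 1L) g1[i[1]] <<- aj else g2[i[1]] <<- aj
    if (pj == 1L) g1[i[2]] <<- ai else g2[i[2]] <<- ai
    lcur <<- logLeveneUpper(cur, na)
  }
  for (s in seq_len(mc_burnin)) step()
  for (b in seq_len(nb)) {
    h <- 0
    for (s in seq_len(per)) {
      step()
      if (lcur <= lobs + tol) h <- h + 1
    }
    batch[b] <- h / per
  }
  p <- mean(batch)
  se <- stats::sd(batch) / sqrt(nb)
  list(p = p, method = "markov_chain", se = se)
}

# Levene log-probability for an upper-triangular genotype count matrix
logLeveneUpper <- function(tab, na) {
  n <- sum(tab)
  H <- sum(tab) - sum(diag(tab))
  counts <- tab[upper.tri(tab, diag = TRUE)]
  lfactorial(n) - sum(lfactorial(counts)) + H * log(2) +
    sum(lfactorial(na)) - lfactorial(2 * n)
}

## ---- linkage disequilibrium ----------------------------------------------

gStatistic <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sel <- tab > 0
  2 * sum(tab[sel] * log(tab[sel] / e[sel]))
}

#' Permutation exact test of genotypic linkage disequilibrium
#'
#' Log-likelihood-ratio (G) statistic on the two-locus genotype
#' contingency table, with the null distribution obtained by permuting
#' one locus's genotypes across individuals; p uses the add-one
#' correction.
#'
#' @param g \linkS4class{MultilocusGenotypes}.
#' @param locus1,locus2 locus names or indices.
#' @param permutations number of permutations.
#' @param seed RNG seed.
#' @return list with \code{p}, \code{G}, \code{skipped} (reason or NULL).
#' @export
genotypicLdTest <- function(g, locus1, locus2, permutations = 1000,
                            seed = 1L) {
  l1 <- if (is.character(locus1)) match(locus1, lociNames(g)) else locus1
  l2 <- if (is.character(locus2)) match(locus2, lociNames(g)) else locus2
  ok <- !is.na(g@a1[, l1]) & !is.na(g@a1[, l2])
  gt1 <- paste(g@a1[ok, l1], g@a2[ok, l1], sep = "/")
  gt2 <- paste(g@a1[ok, l2], g@a2[ok, l2], sep = "/")
  if (length(unique(gt1)) < 2 || length(unique(gt2)) < 2)
    return(list(p = NA_real_, G = NA_real_,
                skipped = "monomorphic locus in group"))
  obs <- gStatistic(table(gt1, gt2))
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(permutations)) {
    if (gStatistic(table(gt1, sample(gt2))) >= obs - 1e-12) ge <- ge + 1L
  }
  list(p = (1 + ge) / (1 + permutations), G = obs, skipped = NULL)
}

## ---- Weir-Cockerham F_ST --------------------------------------------------

#' Weir-Cockerham estimator of F_ST
#'
#' Variance-components estimator (theta) for diploid codominant data with
#' unequal sample sizes. Per-locus theta is the ratio of the
#' among-population component to the total; the multilocus estimate is
#' the ratio of components summed over loci and alleles. Slightly
#' negative values are an estimator property and are reported as
#' computed.
#'
#' @param g \linkS4class{MultilocusGenotypes}.
#' @param groups factor (or coercible) of group membership, one per
#'   individual.
#' @return list with \code{overall}, \code{per_locus} (named vector) and
#'   \code{pairwise} (matrix of pairwise multilocus theta).
#' @export
weirCockerhamFst <- function(g, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) == 0)) stop("group with no individuals")
  comp <- function(idx) {   # sum a, b, c over loci/alleles for groups idx
    grp <- droplevels(groups[idx])
    gg <- g[idx]
    suma <- 0; sumb <- 0; sumc <- 0
    perLocus <- setNames(numeric(nLoci(gg)), lociNames(gg))
    for (l in seq_len(nLoci(gg))) {
      ok <- !is.na(gg@a1[, l])
      r <- nlevels(grp)
      ni <- vapply(levels(grp), function(v) sum(ok & grp == v), 1)
      if (any(ni < 1)) { perLocus[l] <- NA; next }
      alleles <- sort(unique(c(gg@a1[ok, l], gg@a2[ok, l])))
      if (length(alleles) < 2) { perLocus[l] <- NA; next }
      nbar <- mean(ni)
      nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
      la <- 0; lb <- 0; lc <- 0
      for (al in alleles) {
        pi <- vapply(levels(grp), function(v) {
          sel <- ok & grp == v
          mean(c(gg@a1[sel, l], gg@a2[sel, l]) == al)
        }, 1)
        hi <- vapply(levels(grp), function(v) {
          sel <- ok & grp == v
          mean(gg@a1[sel, l] != gg@a2[sel, l] &
                 (gg@a1[sel, l] == al | gg@a2[sel, l] == al))
        }, 1)
        pbar <- sum(ni * pi) / (r * nbar)
        s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(ni * hi) / (r * nbar)
        a <- (nbar / nc) *
          (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
             (nbar - 1))
        b <- (nbar / (nbar - 1)) *
          (pbar * (1 - pbar) - s2 * (r - 1) / r -
             hbar * (2 * nbar - 1) / (4 * nbar))
        cc <- hbar / 2
        la <- la + a; lb <- lb + b; lc <- lc + cc
      }
      perLocus[l] <- if ((la + lb + lc) != 0) la / (la + lb + lc) else NA
      suma <- suma + la; sumb <- sumb + lb; sumc <- sumc + lc
    }
    list(theta = if ((suma + sumb + sumc) != 0)
      suma / (suma + sumb + sumc) else NA,
      per_locus = perLocus)
  }
  all <- comp(seq_along(groups))
  lv <- levels(groups)
  pw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  if (length(lv) > 2 || TRUE) {
    for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
      th <- comp(which(groups %in% lv[c(i, j)]))$theta
      pw[i, j] <- pw[j, i] <- th
    }
  }
  list(overall = all$theta, per_locus = all$per_locus, pairwise = pw)
}

## ---- G-test and FDR --------------------------------------------------------

#' G-test of allele-frequency homogeneity across groups
#'
#' Builds the groups x alleles copy-count table per locus, pools alleles
#' with expected count below 1 into an "other" class, sums
#' \eqn{G = 2 \sum o \ln(o/e)} across loci, with
#' \eqn{df = \sum (K_l - 1)(r - 1)} and a chi-square p-value.
#'
#' @param g \linkS4class{MultilocusGenotypes}.
#' @param groups factor of group membership.
#' @return list with \code{G}, \code{df}, \code{p}.
#' @export
gtestAlleleHomogeneity <- function(g, groups) {
  groups <- factor(groups)
  r <- nlevels(groups)
  if (r < 2) stop("need at least two groups")
  G <- 0; df <- 0
  for (l in seq_len(nLoci(g))) {
    ok <- !is.na(g@a1[, l])
    al <- c(g@a1[, l], g@a2[, l])
    gr <- rep(groups, 2)
    keep <- !is.na(al)
    tab <- table(gr[keep], al[keep])
    if (ncol(tab) < 2) next
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    # pool rare alleles (any group expectation < 1) into an "other" column
    rare <- apply(e < 1, 2, any)
    if (sum(rare) > 1) {
      tab <- cbind(tab[, !rare, drop = FALSE],
                   other = rowSums(tab[, rare, drop = FALSE]))
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    }
    if (ncol(tab) < 2) next
    sel <- tab > 0
    G <- G + 2 * sum(tab[sel] * log(tab[sel] / e[sel]))
    df <- df + (ncol(tab) - 1) * (r - 1)
  }
  list(G = G, df = df,
       p = if (df > 0) stats::pchisq(G, df, lower.tail = FALSE) else NA)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), delegated to
#' \code{stats::p.adjust(method = "BH")}.
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values.
#' @export
fdrAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-locus diversity summary by group
#'
#' Rarefied allelic richness (at the smallest per-group gene-copy count
#' for the locus, unless \code{g_size} is given), observed and unbiased
#' expected heterozygosity and the HWE exact-test probability, for each
#' locus in each group.
#'
#' @param g \linkS4class{MultilocusGenotypes}.
#' @param groups factor of group membership.
#' @param g_size optional fixed rarefaction size (gene copies).
#' @param hwe_seed seed forwarded to \code{\link{hweExactTest}}.
#' @return data.frame: locus, group, n_typed, Ar, Ho, He, hwe_p.
#' @export
locusDiversity <- function(g, groups, g_size = NULL, hwe_seed = 1L) {
  groups <- factor(groups)
  rows <- list()
  for (l in seq_len(nLoci(g))) {
    copies <- vapply(levels(groups), function(v)
      2 * sum(!is.na(g@a1[groups == v, l])), 1)
    gs <- if (is.null(g_size)) max(2, min(copies)) else g_size
    for (v in levels(groups)) {
      sub <- g[groups == v]
      ok <- !is.na(sub@a1[, l])
      if (sum(ok) == 0) next
      cnt <- table(c(sub@a1[ok, l], sub@a2[ok, l]))
      ho <- mean(sub@a1[ok, l] != sub@a2[ok, l])
      p <- as.numeric(cnt) / sum(cnt)
      n <- sum(ok)
      he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      hw <- hweExactTest(cbind(sub@a1[ok, l], sub@a2[ok, l]),
                         seed = hwe_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = lociNames(g)[l], group = v, n_typed = n,
        Ar = rarefiedAllelicRichness(as.integer(cnt), min(gs, sum(cnt))),
        Ho = ho, He = he, hwe_p = hw$p)
    }
  }
  do.call(rbind, rows)
}
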