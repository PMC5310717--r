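#' Genotype probability under a genotype-frequency class
#'
#' Probability of an unordered single-locus genotype given a hybrid class
#' and the two parental allele-frequency vectors: the mixture over gene
#' origins
#' \deqn{P(g \mid z) = \phi_{z,AA} P_{HW}(g \mid p_A)
#'   + \phi_{z,AB} P_{\times}(g \mid p_A, p_B)
#'   + \phi_{z,BB} P_{HW}(g \mid p_B),}
#' where \eqn{P_{\times}(a,b) = p_{A,a} p_{B,b} + p_{A,b} p_{B,a}} for
#' \eqn{a \neq b} and \eqn{p_{A,a} p_{B,a}} for homozygotes.
#'
#' @param genotype integer vector of length 2 (allele labels).
#' @param class one of \code{hybridClasses()}.
#' @param freqA,freqB named (by allele label) or plain frequency vectors.
#' @param alleles integer allele labels matching the frequency vectors.
#' @return probability in [0, 1].
#' @export
genotypeProbGivenClass <- function(genotype, class, freqA, freqB, alleles) {
  phi <- geneOriginTable()
  if (!class %in% rownames(phi)) stop("unknown class: ", class)
  ix <- match(genotype, alleles)
  if (any(is.na(ix)))
    stop("allele absent from locus model: ",
         paste(genotype[is.na(ix)], collapse = ", "))
  x <- ix[1]; y <- ix[2]
  if (x == y) {
    PA <- freqA[x]^2
    PC <- freqA[x] * freqB[x]
    PB <- freqB[x]^2
  } else {
    PA <- 2 * freqA[x] * freqA[y]
    PC <- freqA[x] * freqB[y] + freqA[y] * freqB[x]
    PB <- 2 * freqB[x] * freqB[y]
  }
  unname(phi[class, 1] * PA + phi[class, 2] * PC + phi[class, 3] * PB)
}

#' MCMC settings for the hybrid mixture sampler
#'
#' @param burn_in burn-in sweeps.
#' @param samples post-burn-in sweeps over which memberships are averaged.
#' @param seed RNG seed (all randomness goes through R's RNG).
#' @param freq_prior symmetric Dirichlet concentration of the
#'   allele-frequency prior (1 = uniform).
#' @param mix_prior symmetric Dirichlet concentration over the six
#'   classes.
#' @return list of class \code{mcmc_settings}.
#' @export
mcmcSettings <- function(burn_in = 1e4, samples = 1e5, seed = 1L,
                         freq_prior = 1, mix_prior = 1) {
  if (burn_in <= 0 || samples <= 0)
    stop("burn_in and samples must be positive")
  structure(list(burn_in = as.integer(burn_in),
                 samples = as.integer(samples), seed = as.integer(seed),
                 freq_prior = freq_prior, mix_prior = mix_prior),
            class = "mcmc_settings")
}

#' Fit the six-class Bayesian hybrid mixture by Gibbs sampling
#'
#' Classifies individuals as purebred A, purebred B, F1, F2 or backcross
#' with no prior species labels: the sampler jointly estimates the allele
#' frequencies of two putative parental populations and each individual's
#' posterior class membership q. One Gibbs sweep samples (i) every
#' individual's class given frequencies and mixing proportions, (ii) the
#' per-locus gene-origin latents given the class, (iii) species allele
#' frequencies from Dirichlet posteriors given origin-attributed allele
#' counts, and (iv) mixing proportions from a Dirichlet posterior.
#' Memberships are post-burn-in empirical class frequencies. Cluster
#' labels A/B are arbitrary (label-swap symmetry); anchor them with
#' \code{\link{labelClustersWithAnchors}}.
#'
#' @param g \linkS4class{MultilocusGenotypes}; missing loci contribute a
#'   factor 1 to the likelihood.
#' @param settings a \code{\link{mcmcSettings}} list.
#' @param panel optional \linkS4class{LocusPanel} supplying the allele
#'   dictionaries; by default the alleles observed in \code{g} are used.
#' @return a \linkS4class{HybridPosterior}.
#' @export
fitHybridMixture <- function(g, settings = mcmcSettings(), panel = NULL) {
  n <- nInd(g)
  if (n < 2) stop("need at least 2 individuals")
  L <- nLoci(g)
  alleles <- vector("list", L)
  for (l in seq_len(L)) {
    obs <- sort(unique(stats::na.omit(c(g@a1[, l], g@a2[, l]))))
    alleles[[l]] <- if (!is.null(panel))
      sort(unique(c(panel@alleles[[l]], obs))) else obs
  }
  poly <- vapply(alleles, length, 1L) >= 2
  if (!any(poly))
    stop("all loci monomorphic: no information to separate species")
  i1 <- matrix(-1L, n, L)
  i2 <- matrix(-1L, n, L)
  for (l in seq_len(L)) {
    i1[, l] <- match(g@a1[, l], alleles[[l]]) - 1L
    i2[, l] <- match(g@a2[, l], alleles[[l]]) - 1L
  }
  i1[is.na(i1)] <- -1L
  i2[is.na(i2)] <- -1L
  set.seed(settings$seed)
  fit <- gibbs_hybrid(i1, i2, vapply(alleles, length, 1L),
                      geneOriginTable(), settings$burn_in,
                      settings$samples, settings$freq_prior,
                      settings$mix_prior)
  q <- fit$q
  colnames(q) <- hybridClasses()
  rownames(q) <- sampleIds(g)
  new("HybridPosterior", q = q,
      freqA = setNames(fit$freqA, lociNames(g)),
      freqB = setNames(fit$freqB, lociNames(g)),
      alleles = setNames(alleles, lociNames(g)),
      loci = lociNames(g), settings = unclass(settings))
}

#' Threshold assignment of individuals to purebred or hybrid
#'
#' Applies the published assignment rules to posterior memberships at a
#' threshold \code{Tq}. Under the \emph{third} criterion an individual is
#' purebred when its best purebred-class membership reaches the threshold
#' and hybrid otherwise (no one is left unassigned). Under the
#' \emph{second} criterion all hybrid categories are combined: the
#' individual is purebred when a purebred-class q reaches \code{Tq},
#' hybrid when the combined hybrid q reaches \code{Tq}, and unassigned
#' otherwise. Ties at exactly \code{Tq} are assigned (the rules use >=).
#'
#' @param posterior a \linkS4class{HybridPosterior} or a q matrix.
#' @param Tq threshold in (0.5, 1]; 0.75 and 0.90 are the published
#'   values.
#' @param criterion "third" or "second".
#' @return factor with levels pureA, pureB, hybrid, unassigned.
#' @export
assignHybrids <- function(posterior, Tq = 0.75,
                          criterion = c("third", "second")) {
  criterion <- match.arg(criterion)
  if (Tq <= 0.5 || Tq > 1) stop("Tq must lie in (0.5, 1]")
  q <- if (is(posterior, "HybridPosterior")) qMatrix(posterior)
       else posterior
  qa <- q[, "pureA"]
  qb <- q[, "pureB"]
  qh <- 1 - qa - qb
  out <- character(nrow(q))
  if (criterion == "third") {
    pure <- pmax(qa, qb) >= Tq
    out[pure & qa >= qb] <- "pureA"
    out[pure & qa < qb] <- "pureB"
    out[!pure] <- "hybrid"
  } else {
    out[] <- "unassigned"
    out[qh >= Tq] <- "hybrid"
    out[qa >= Tq] <- "pureA"
    out[qb >= Tq] <- "pureB"
  }
  factor(out, levels = c("pureA", "pureB", "hybrid", "unassigned"))
}

#' Label the inferred clusters with species names using anchors
#'
#' The mixture separates two parental clusters without knowing which is
#' which; reference individuals of known species (e.g. genotyped corpses
#' identified morphologically) anchor the mapping. Each anchor must be
#' classified purebred; the mapping goes by majority anchor membership.
#' Anchors should then be excluded from downstream colony statistics.
#'
#' @param posterior a \linkS4class{HybridPosterior} covering anchors and
#'   colony samples together.
#' @param anchor_ids row ids (or indices) of the anchors.
#' @param anchor_species character vector, parallel to \code{anchor_ids},
#'   of species names.
#' @param Tq purebred threshold applied to anchors (third criterion).
#' @return named character vector \code{c(clusterA = ..., clusterB = ...)};
#'   a species with no anchors leaves its cluster \code{NA} (unlabelled).
#' @export
labelClustersWithAnchors <- function(posterior, anchor_ids, anchor_species,
                                     Tq = 0.75) {
  q <- qMatrix(posterior)
  ix <- if (is.character(anchor_ids)) match(anchor_ids, rownames(q))
        else as.integer(anchor_ids)
  if (any(is.na(ix))) stop("anchor ids not found in posterior")
  calls <- assignHybrids(posterior, Tq = Tq, criterion = "third")[ix]
  if (any(calls == "hybrid"))
    stop("anchor classified hybrid: ",
         paste(anchor_ids[calls == "hybrid"], collapse = ", "))
  mapping <- c(clusterA = NA_character_, clusterB = NA_character_)
  for (sp in unique(anchor_species)) {
    cl <- calls[anchor_species == sp]
    votesA <- sum(cl == "pureA")
    votesB <- sum(cl == "pureB")
    if (votesA > 0 && votesB > 0)
      stop("anchors for species ", sp, " split across clusters")
    side <- if (votesA > votesB) "clusterA" else "clusterB"
    if (!is.na(mapping[side]) && mapping[side] != sp)
      stop("two species map to the same cluster")
    mapping[side] <- sp
  }
  mapping
}
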