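#' @import methods
#' @importFrom stats rbinom rgamma runif setNames complete.cases
NULL

#' Six genotype-frequency classes
#'
#' Canonical order of the hybrid categories used throughout the package,
#' together with their gene-origin proportions: for each class the expected
#' proportions of loci whose two gene copies are (both from species A,
#' one from each, both from species B).
#'
#' @format \code{hybridClasses()} returns a character vector of length 6;
#'   \code{geneOriginTable()} a 6 x 3 numeric matrix with rows in the same
#'   order and columns \code{c("AA", "AB", "BB")}.
#' @examples
#' geneOriginTable()["F2", ]   # 0.25 0.50 0.25
#' @export
hybridClasses <- function() c("pureA", "pureB", "F1", "F2", "BxA", "BxB")

#' @rdname hybridClasses
#' @export
geneOriginTable <- function() {
  m <- rbind(
    pureA = c(1, 0, 0),
    pureB = c(0, 0, 1),
    F1    = c(0, 1, 0),
    F2    = c(0.25, 0.5, 0.25),
    BxA   = c(0.5, 0.5, 0),
    BxB   = c(0, 0.5, 0.5)
  )
  colnames(m) <- c("AA", "AB", "BB")
  m
}

#' LocusPanel: per-locus allele pools of two parental species
#'
#' Holds, for each microsatellite locus of the typing panel, the list of
#' allele labels (fragment sizes) and the allele-frequency vectors of the
#' two parental species A and B. This is the generative model every
#' simulation and likelihood computation draws on.
#'
#' @slot loci character vector of locus names.
#' @slot alleles list of integer vectors (one per locus) of allele labels.
#' @slot freqA,freqB lists of numeric frequency vectors, parallel to
#'   \code{alleles}; each sums to 1.
#' @seealso \code{\link{makeParentalFrequencies}}, \code{\link{studyPanel}}
#' @export
setClass("LocusPanel",
  representation(loci = "character", alleles = "list",
                 freqA = "list", freqB = "list"))

setValidity("LocusPanel", function(object) {
  L <- length(object@loci)
  if (L < 1) return("panel must contain at least one locus")
  if (length(object@alleles) != L || length(object@freqA) != L ||
      length(object@freqB) != L)
    return("alleles, freqA and freqB must have one entry per locus")
  for (l in seq_len(L)) {
    k <- length(object@alleles[[l]])
    if (k < 1) return(sprintf("locus %s has no alleles", object@loci[l]))
    if (length(object@freqA[[l]]) != k || length(object@freqB[[l]]) != k)
      return(sprintf("locus %s: frequency length != allele count",
                     object@loci[l]))
    for (fr in list(object@freqA[[l]], object@freqB[[l]])) {
      if (any(fr < 0)) return(sprintf("locus %s: negative frequency",
                                      object@loci[l]))
      if (abs(sum(fr) - 1) > 1e-9)
        return(sprintf("locus %s: frequencies do not sum to 1",
                       object@loci[l]))
    }
  }
  TRUE
})

#' MultilocusGenotypes: unordered allele pairs at panel loci
#'
#' The atom of every stage: a set of individuals (or samples) typed at the
#' same panel of loci, each locus holding an unordered allele pair or
#' missing (\code{NA}). Alleles are stored as two integer matrices of
#' allele labels with the convention \code{a1 <= a2} so that equal
#' genotypes compare equal elementwise.
#'
#' @slot a1,a2 integer matrices (individuals x loci) of allele labels,
#'   \code{NA} where the locus is missing; \code{a1 <= a2} elementwise.
#' @slot loci character vector of locus names (column order).
#' @slot meta data.frame of per-row metadata (ids, dates, sex, true class
#'   for simulated data); zero or \code{nrow(a1)} rows.
#' @export
setClass("MultilocusGenotypes",
  representation(a1 = "matrix", a2 = "matrix", loci = "character",
                 meta = "data.frame"))

setValidity("MultilocusGenotypes", function(object) {
  if (!is.integer(object@a1) || !is.integer(object@a2))
    return("allele matrices must be integer")
  if (!identical(dim(object@a1), dim(object@a2)))
    return("a1 and a2 must have identical dimensions")
  if (ncol(object@a1) != length(object@loci))
    return("number of columns must equal number of loci")
  if (nrow(object@meta) > 0 && nrow(object@meta) != nrow(object@a1))
    return("meta must have zero rows or one row per individual")
  bad <- !is.na(object@a1) & !is.na(object@a2) & object@a1 > object@a2
  if (any(bad)) return("allele pairs must be ordered a1 <= a2")
  if (any(xor(is.na(object@a1), is.na(object@a2))))
    return("half-missing allele pairs are not allowed")
  TRUE
})

#' HybridPosterior: posterior class memberships from the mixture model
#'
#' Result of \code{\link{fitHybridMixture}}: per-individual posterior
#' probabilities over the six genotype-frequency classes, plus
#' posterior-mean allele frequencies of the two inferred parental clusters.
#' Cluster labels A/B are arbitrary until anchored
#' (\code{\link{labelClustersWithAnchors}}).
#'
#' @slot q numeric matrix (individuals x 6), rows sum to 1, columns in
#'   \code{hybridClasses()} order.
#' @slot freqA,freqB lists of posterior-mean allele-frequency vectors per
#'   locus for the two inferred clusters.
#' @slot alleles list of integer allele labels per locus (frequency order).
#' @slot loci character locus names.
#' @slot settings list echoing the MCMC settings used.
#' @export
setClass("HybridPosterior",
  representation(q = "matrix", freqA = "list", freqB = "list",
                 alleles = "list", loci = "character", settings = "list"))

setValidity("HybridPosterior", function(object) {
  if (ncol(object@q) != 6) return("q must have six columns")
  if (!identical(colnames(object@q), hybridClasses()))
    return("q columns must be named by hybridClasses()")
  if (any(object@q < -1e-9)) return("negative posterior probability")
  if (any(abs(rowSums(object@q) - 1) > 1e-6))
    return("posterior rows must sum to 1")
  TRUE
})

#' ColonySizeEstimate: point estimate and interval for colony size
#'
#' @slot method "eggert" or "bayesian".
#' @slot estimate numeric point estimate.
#' @slot lower,upper interval bounds (95\%).
#' @slot distinct integer, number of distinct genotypes observed.
#' @slot reliable logical; \code{FALSE} when the accumulation curve does
#'   not saturate (Eggert) or the posterior piles against \code{N_max}
#'   (Bayesian), in which case the numbers should not be quoted alone.
#' @slot diagnostics list (fit parameters a, b for Eggert; posterior grid
#'   for the Bayesian estimator; warnings).
#' @export
setClass("ColonySizeEstimate",
  representation(method = "character", estimate = "numeric",
                 lower = "numeric", upper = "numeric",
                 distinct = "integer", reliable = "logical",
                 diagnostics = "list"))

setValidity("ColonySizeEstimate", function(object) {
  if (!object@method %in% c("eggert", "bayesian"))
    return("method must be 'eggert' or 'bayesian'")
  if (length(object@estimate) != 1) return("estimate must be scalar")
  if (object@reliable &&
      (object@lower > object@estimate + 1e-9 ||
       object@upper < object@estimate - 1e-9))
    return("interval must bracket the point estimate")
  TRUE
})
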