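#' Accessors for panel and genotype objects
#'
#' Small S4 accessor family: number of loci/individuals, locus names,
#' allele dictionaries, parental frequencies and per-locus allele-frequency
#' differentials of a \linkS4class{LocusPanel}; allele matrices and
#' metadata of a \linkS4class{MultilocusGenotypes}; the posterior matrix
#' and derived purebred/hybrid sums of a \linkS4class{HybridPosterior}.
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' @rdname accessors
#' @export
setGeneric("alleleList", function(x) standardGeneric("alleleList"))
#' @rdname accessors
#' @export
setGeneric("freqA", function(x) standardGeneric("freqA"))
#' @rdname accessors
#' @export
setGeneric("freqB", function(x) standardGeneric("freqB"))
#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("meta", function(x) standardGeneric("meta"))
#' @rdname accessors
#' @export
setGeneric("qMatrix", function(x) standardGeneric("qMatrix"))
#' @rdname accessors
#' @export
setGeneric("qSummary", function(x) standardGeneric("qSummary"))

setMethod("nLoci", "LocusPanel", function(x) length(x@loci))
setMethod("lociNames", "LocusPanel", function(x) x@loci)
setMethod("alleleList", "LocusPanel", function(x)
  setNames(x@alleles, x@loci))
setMethod("freqA", "LocusPanel", function(x) setNames(x@freqA, x@loci))
setMethod("freqB", "LocusPanel", function(x) setNames(x@freqB, x@loci))

setMethod("nLoci", "MultilocusGenotypes", function(x) length(x@loci))
setMethod("lociNames", "MultilocusGenotypes", function(x) x@loci)
setMethod("nInd", "MultilocusGenotypes", function(x) nrow(x@a1))
setMethod("sampleIds", "MultilocusGenotypes", function(x) rownames(x@a1))
setMethod("meta", "MultilocusGenotypes", function(x) x@meta)

setMethod("qMatrix", "HybridPosterior", function(x) x@q)

#' @describeIn accessors data.frame with q for each class plus the derived
#'   sums \code{q_pureA}, \code{q_pureB} and
#'   \code{q_hybrid = 1 - q_pureA - q_pureB}.
setMethod("qSummary", "HybridPosterior", function(x) {
  q <- x@q
  data.frame(id = rownames(q), q,
             q_hybrid = rowSums(q[, c("F1", "F2", "BxA", "BxB"),
                                  drop = FALSE]),
             row.names = NULL, check.names = FALSE)
})

setMethod("show", "LocusPanel", function(object) {
  d <- vapply(seq_along(object@loci), function(l)
    alleleFreqDifferential(object@freqA[[l]], object@freqB[[l]]),
    numeric(1))
  cat("LocusPanel with", length(object@loci), "loci\n")
  cat(sprintf("  alleles per locus: %s\n",
              paste(vapply(object@alleles, length, 1L), collapse = " ")))
  cat(sprintf("  delta (A vs B):    %s\n",
              paste(sprintf("%.2f", d), collapse = " ")))
})

setMethod("show", "MultilocusGenotypes", function(object) {
  miss <- mean(is.na(object@a1))
  cat("MultilocusGenotypes:", nrow(object@a1), "individuals x",
      length(object@loci), "loci;",
      sprintf("%.1f%% missing\n", 100 * miss))
  if (ncol(object@meta) > 0)
    cat("  meta columns:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "HybridPosterior", function(object) {
  cat("HybridPosterior for", nrow(object@q), "individuals\n")
  qh <- rowSums(object@q[, c("F1", "F2", "BxA", "BxB"), drop = FALSE])
  cat(sprintf("  q_hybrid: median %.3f, max %.3f\n",
              stats::median(qh), max(qh)))
  cat(sprintf("  sweeps: %s (burn-in %s)\n",
              object@settings$samples, object@settings$burn_in))
})

setMethod("show", "ColonySizeEstimate", function(object) {
  cat(sprintf("ColonySizeEstimate (%s): %s [%s; %s]%s\n",
              object@method, round(object@estimate),
              round(object@lower), round(object@upper),
              if (object@reliable) "" else "  (flagged unreliable)"))
})

#' Subset a MultilocusGenotypes object by individuals
#'
#' @param x MultilocusGenotypes.
#' @param i row index (individuals).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "MultilocusGenotypes", function(x, i, j, ..., drop = FALSE) {
  mt <- x@meta
  if (nrow(mt) > 0) mt <- mt[i, , drop = FALSE]
  new("MultilocusGenotypes",
      a1 = x@a1[i, , drop = FALSE], a2 = x@a2[i, , drop = FALSE],
      loci = x@loci, meta = mt)
})
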