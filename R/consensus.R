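#' Consensus genotypes from replicated PCR reads
#'
#' Applies the multiple-tubes rule to a long table of replicate reads:
#' at each locus an allele is accepted only if recorded in at least
#' \code{min_observations} reads. A locus is called heterozygous when
#' exactly two alleles are accepted; it is called homozygous when exactly
#' one allele is accepted and no read showed any other allele (the
#' "recorded twice" rule satisfied by the same single allele in both
#' reads); any other configuration (an accepted allele contradicted by an
#' extra read allele, no accepted allele, more than two accepted) leaves
#' the locus missing. Under the strict rule a sample whose consensus
#' misses any panel locus is flagged incomplete and discarded from
#' individual matching.
#'
#' @param replicates data.frame with columns sample_id, locus, allele1,
#'   allele2 (as written by \code{\link{simulateColonyDataset}}); extra
#'   columns (date, multiplex, replicate) are carried through.
#' @param panel a \linkS4class{LocusPanel} defining the locus set; reads
#'   at loci outside the panel are an error.
#' @param min_observations minimum number of reads an allele must appear
#'   in (default 2).
#' @return list with \code{genotypes}, a \linkS4class{MultilocusGenotypes}
#'   over all samples (missing loci as \code{NA}) whose metadata carries
#'   \code{sample_id}, \code{date} and \code{complete}; and
#'   \code{complete}, the subset of samples with no missing locus.
#' @export
consensusFromReplicates <- function(replicates, panel, min_observations = 2) {
  loci <- lociNames(panel)
  bad <- setdiff(unique(replicates$locus), loci)
  if (length(bad))
    stop("reads reference loci outside the panel: ",
         paste(bad, collapse = ", "))
  ids <- unique(replicates$sample_id)
  L <- length(loci)
  a1 <- matrix(NA_integer_, length(ids), L,
               dimnames = list(ids, loci))
  a2 <- a1
  spl <- split(replicates, replicates$sample_id)
  dates <- character(length(ids))
  for (i in seq_along(ids)) {
    rs <- spl[[ids[i]]]
    dates[i] <- if ("date" %in% names(rs)) as.character(rs$date[1]) else NA
    for (l in seq_len(L)) {
      rl <- rs[rs$locus == loci[l], , drop = FALSE]
      if (nrow(rl) == 0) next
      # read-wise allele sets; an allele counts once per read
      readsets <- lapply(seq_len(nrow(rl)), function(r)
        unique(stats::na.omit(c(rl$allele1[r], rl$allele2[r]))))
      allseen <- unlist(readsets)
      if (length(allseen) == 0) next
      cnt <- table(allseen)
      accepted <- as.integer(names(cnt)[cnt >= min_observations])
      if (length(accepted) == 2) {
        a1[i, l] <- min(accepted); a2[i, l] <- max(accepted)
      } else if (length(accepted) == 1) {
        if (all(allseen == accepted)) {          # concordant homozygote
          a1[i, l] <- accepted; a2[i, l] <- accepted
        }                                        # else: inconsistency
      }
    }
  }
  complete <- !apply(is.na(a1), 1, any)
  meta <- data.frame(sample_id = ids, date = dates, complete = complete)
  g <- new("MultilocusGenotypes", a1 = a1, a2 = a2, loci = loci, meta = meta)
  list(genotypes = g, complete = g[complete])
}

#' Allele-mismatch count between two complete multilocus genotypes
#'
#' Per locus the two unordered pairs are compared as multisets; the
#' mismatch is 2 minus the multiset-intersection size, summed over loci
#' (so one allele shared at a locus costs 1, none shared costs 2).
#'
#' @param g a \linkS4class{MultilocusGenotypes}.
#' @return symmetric integer matrix of pairwise mismatch counts.
#' @export
mismatchMatrix <- function(g) {
  n <- nInd(g)
  m <- matrix(0L, n, n, dimnames = list(sampleIds(g), sampleIds(g)))
  if (n < 2) return(m)
  a1 <- g@a1; a2 <- g@a2
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # multiset intersection per locus for ordered pairs (x1<=x2, y1<=y2):
    # 2 if identical; else 1 if any cross-equality; else 0
    same <- a1[i, ] == a1[j, ] & a2[i, ] == a2[j, ]
    one <- !same & (a1[i, ] == a1[j, ] | a1[i, ] == a2[j, ] |
                      a2[i, ] == a1[j, ] | a2[i, ] == a2[j, ])
    mm <- sum(2L * (!same) - one)
    m[i, j] <- m[j, i] <- as.integer(mm)
  }
  m
}

#' Collapse samples into individuals by near-identity matching
#'
#' Two samples are taken to originate from the same individual when their
#' complete multilocus genotypes are identical or differ by at most
#' \code{max_mismatch} alleles. Samples are clustered by single linkage on
#' the graph whose edges join pairs within the threshold; a cluster whose
#' internal diameter exceeds the threshold anywhere (a non-transitive
#' chain) is flagged ambiguous rather than silently merged or split.
#'
#' @param g complete \linkS4class{MultilocusGenotypes} (e.g. the
#'   \code{complete} element of \code{\link{consensusFromReplicates}}).
#' @param max_mismatch maximum allele mismatches treated as identity
#'   (default 1).
#' @return list with \code{individuals}: data.frame (individual_id,
#'   n_samples, sample_ids, dates, ambiguous), \code{membership}: named
#'   vector sample_id -> individual_id, \code{genotypes}: one
#'   representative \linkS4class{MultilocusGenotypes} row per individual
#'   (the first sample of each cluster), and \code{mismatch}: the pairwise
#'   matrix used.
#' @export
matchIndividuals <- function(g, max_mismatch = 1) {
  if (any(is.na(g@a1)))
    stop("matchIndividuals requires complete genotypes")
  n <- nInd(g)
  if (n == 0) stop("no genotypes to match")
  mm <- mismatchMatrix(g)
  # single linkage via union-find
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (mm[i, j] <= max_mismatch) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  root <- vapply(seq_len(n), find, integer(1))
  cl <- match(root, unique(root))
  ids <- sampleIds(g)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dates <- if ("date" %in% names(g@meta)) g@meta$date else rep(NA, n)
  k <- max(cl)
  indiv <- data.frame(
    individual_id = sprintf("I%03d", seq_len(k)),
    n_samples = as.integer(tabulate(cl, k)),
    sample_ids = vapply(seq_len(k), function(c)
      paste(ids[cl == c], collapse = ";"), character(1)),
    dates = vapply(seq_len(k), function(c)
      paste(sort(unique(dates[cl == c])), collapse = ";"), character(1)),
    ambiguous = vapply(seq_len(k), function(c) {
      w <- which(cl == c)
      length(w) > 1 && max(mm[w, w]) > max_mismatch
    }, logical(1)))
  firsts <- vapply(seq_len(k), function(c) which(cl == c)[1], integer(1))
  reps <- g[firsts]
  rownames(reps@a1) <- rownames(reps@a2) <- indiv$individual_id
  reps@meta <- data.frame(individual_id = indiv$individual_id,
                          n_samples = indiv$n_samples,
                          dates = indiv$dates,
                          ambiguous = indiv$ambiguous)
  list(individuals = indiv,
       membership = setNames(indiv$individual_id[cl], ids),
       genotypes = reps, mismatch = mm)
}

#' Per-date sample and individual tallies
#'
#' Summarises a sampling campaign the way colony field tables are
#' reported: per date, samples collected, samples with a complete
#' consensus genotype, distinct individuals among them, and the
#' amplification success (complete / collected, in percent).
#'
#' @param consensus result of \code{\link{consensusFromReplicates}}.
#' @param membership named vector sample_id -> individual_id from
#'   \code{\link{matchIndividuals}} (only complete samples appear in it).
#' @return data.frame with one row per date plus a Total row.
#' @export
tallySamples <- function(consensus, membership) {
  meta <- consensus$genotypes@meta
  dates <- sort(unique(meta$date))
  rows <- lapply(dates, function(d) {
    sub <- meta[meta$date == d, , drop = FALSE]
    comp <- sub$sample_id[sub$complete]
    data.frame(date = d,
               collected = nrow(sub),
               genotyped = length(comp),
               individuals = length(unique(membership[comp])),
               success_pct = amplificationSuccess(nrow(sub), length(comp)))
  })
  out <- do.call(rbind, rows)
  total <- data.frame(date = "Total",
                      collected = sum(out$collected),
                      genotyped = sum(out$genotyped),
                      individuals = length(unique(membership)),
                      success_pct = amplificationSuccess(
                        sum(out$collected), sum(out$genotyped)))
  rbind(out, total)
}

#' Amplification success percentage
#'
#' @param collected samples collected.
#' @param complete samples with a complete consensus genotype.
#' @return percentage (0 when nothing was collected).
#' @examples
#' amplificationSuccess(50, 36)  # 72
#' @export
amplificationSuccess <- function(collected, complete) {
  if (collected == 0) return(0)
  100 * complete / collected
}
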