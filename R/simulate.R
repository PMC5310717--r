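#' Build a MultilocusGenotypes object from allele matrices
#'
#' Orders each allele pair (smaller label first) and attaches metadata.
#' @param a1,a2 integer matrices (individuals x loci) of allele labels.
#' @param loci character locus names.
#' @param meta optional data.frame of per-individual metadata.
#' @param ids optional row ids.
#' @return a \linkS4class{MultilocusGenotypes}.
#' @export
newGenotypes <- function(a1, a2, loci, meta = data.frame(), ids = NULL) {
  a1 <- matrix(as.integer(a1), nrow = NROW(a1))
  a2 <- matrix(as.integer(a2), nrow = NROW(a2))
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  colnames(lo) <- colnames(hi) <- loci
  if (!is.null(ids)) rownames(lo) <- rownames(hi) <- as.character(ids)
  new("MultilocusGenotypes", a1 = lo, a2 = hi, loci = loci, meta = meta)
}

#' Simulate multilocus genotypes of a given hybrid class
#'
#' Draws complete genotypes from a parental panel according to the
#' gene-origin proportions of the class: at each locus the origin pair of
#' the two gene copies is (both-A, one-each, both-B) with the class's
#' probabilities, independently across loci (unlinked markers), and each
#' gene copy is then drawn from the corresponding species' allele pool.
#' Purebreds are two independent draws from one pool; F1 one gene from
#' each species; F2 two independent F1 gametes; backcrosses one F1 gamete
#' and one purebred gamete.
#'
#' @param n number of genotypes.
#' @param class one of \code{hybridClasses()}.
#' @param panel a \linkS4class{LocusPanel}.
#' @return a \linkS4class{MultilocusGenotypes} with a \code{true_class}
#'   metadata column.
#' @examples
#' p <- makeParentalFrequencies(4, 6, 0.6, seed = 1)
#' g <- simulateGenotypes(10, "F1", p)
#' @export
simulateGenotypes <- function(n, class, panel) {
  phi <- geneOriginTable()
  if (!class %in% rownames(phi))
    stop(sprintf("unknown hybrid class '%s'", class))
  w <- phi[class, ]
  L <- nLoci(panel)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    al <- panel@alleles[[l]]
    o <- sample.int(3L, n, replace = TRUE, prob = w)
    # gene 1 from A unless both-B; gene 2 from B unless both-A
    g1A <- o != 3L
    g2A <- o == 1L
    # index-based draw: safe for single-allele (monomorphic) loci
    drawA <- function(k) al[sample.int(length(al), k, replace = TRUE,
                                       prob = panel@freqA[[l]])]
    drawB <- function(k) al[sample.int(length(al), k, replace = TRUE,
                                       prob = panel@freqB[[l]])]
    g1 <- integer(n); g2 <- integer(n)
    g1[g1A] <- drawA(sum(g1A)); g1[!g1A] <- drawB(sum(!g1A))
    g2[g2A] <- drawA(sum(g2A)); g2[!g2A] <- drawB(sum(!g2A))
    a1[, l] <- pmin(g1, g2)
    a2[, l] <- pmax(g1, g2)
  }
  newGenotypes(a1, a2, lociNames(panel),
               meta = data.frame(true_class = rep(class, n)))
}

#' Simulate the true individuals of a mixed colony
#'
#' @param class_counts named integer vector over (a subset of)
#'   \code{hybridClasses()}.
#' @param panel a \linkS4class{LocusPanel}.
#' @param female_prob probability that an individual is female; the
#'   default 0.94 reflects a maternity colony.
#' @param seed optional RNG seed.
#' @return \linkS4class{MultilocusGenotypes} with metadata columns
#'   \code{individual_id}, \code{true_class}, \code{sex}.
#' @export
makeTrueIndividuals <- function(class_counts, panel, female_prob = 0.94,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bad <- setdiff(names(class_counts), hybridClasses())
  if (length(bad)) stop("unknown class: ", paste(bad, collapse = ", "))
  parts <- lapply(names(class_counts), function(cl)
    simulateGenotypes(class_counts[[cl]], cl, panel))
  a1 <- do.call(rbind, lapply(parts, function(x) x@a1))
  a2 <- do.call(rbind, lapply(parts, function(x) x@a2))
  n <- nrow(a1)
  meta <- data.frame(
    individual_id = sprintf("ind%03d", seq_len(n)),
    true_class = unlist(lapply(parts, function(x) x@meta$true_class)),
    sex = ifelse(runif(n) < female_prob, "F", "M"))
  newGenotypes(a1, a2, lociNames(panel), meta = meta,
               ids = meta$individual_id)
}

#' Default configuration for the colony-sampling simulator
#'
#' Defaults emulate the study conditions of a guano-sampled maternity
#' colony: five sampling dates, one to four samples per individual with
#' most individuals sampled once, two PCR replicates per sample and
#' multiplex, and small per-read error rates (allelic dropout, false
#' alleles, amplification failure) whose compound effect over a full
#' 11-12 locus panel under the strict all-loci consensus rule lands the
#' overall amplification success in the 72-90\% band.
#'
#' @param samples_per_individual probabilities over 1..4 samples.
#' @param dropout_rate per-replicate probability that one allele of a
#'   heterozygous locus drops out.
#' @param false_allele_rate per-replicate probability that a spurious
#'   allele replaces a true one at a locus.
#' @param sample_failure_rate per-replicate per-locus amplification
#'   failure probability (no alleles read).
#' @param dates ISO-8601 sampling dates.
#' @param seed RNG seed.
#' @return list of class \code{colony_config}.
#' @export
colonyConfig <- function(samples_per_individual = c(0.65, 0.22, 0.09, 0.04),
                         dropout_rate = 0.01,
                         false_allele_rate = 0.002,
                         sample_failure_rate = 0.003,
                         dates = c("2012-05-22", "2012-06-20", "2012-07-10",
                                   "2012-08-03", "2012-08-29"),
                         seed = 1L) {
  stopifnot(length(samples_per_individual) == 4,
            abs(sum(samples_per_individual) - 1) < 1e-9)
  for (p in c(dropout_rate, false_allele_rate, sample_failure_rate))
    if (p < 0 || p > 1) stop("error rates must be probabilities")
  structure(list(samples_per_individual = samples_per_individual,
                 dropout_rate = dropout_rate,
                 false_allele_rate = false_allele_rate,
                 sample_failure_rate = sample_failure_rate,
                 dates = dates, seed = as.integer(seed)),
            class = "colony_config")
}

#' Simulate replicated-PCR guano sampling of a colony
#'
#' Every individual contributes 1-4 guano samples (per the configured
#' distribution), each typed in two multiplexes with two PCR replicates
#' per multiplex. Each replicate read independently suffers amplification
#' failure, allelic dropout (heterozygote allele silently lost) and false
#' alleles (a true allele replaced by a uniform draw from the locus's
#' other alleles).
#'
#' @param individuals \linkS4class{MultilocusGenotypes} from
#'   \code{\link{makeTrueIndividuals}} (complete genotypes).
#' @param panel the \linkS4class{LocusPanel} typed.
#' @param config a \code{\link{colonyConfig}} list.
#' @return list with \code{replicates} (long data.frame: sample_id, date,
#'   multiplex, replicate, locus, allele1, allele2; \code{NA} = not read)
#'   and \code{truth} (sample_id, individual_id, true_class, sex, date).
#' @export
simulateColonyDataset <- function(individuals, panel, config = colonyConfig()) {
  n <- nInd(individuals)
  if (n == 0) stop("empty individual list")
  if (any(is.na(individuals@a1)))
    stop("true individuals must carry complete genotypes")
  set.seed(config$seed)
  L <- nLoci(panel)
  loci <- lociNames(panel)
  multiplex <- rep(1:2, c(ceiling(L / 2), floor(L / 2)))
  nsamp <- sample.int(4L, n, replace = TRUE,
                      prob = config$samples_per_individual)
  reps <- vector("list", sum(nsamp) * 4L)
  truth <- vector("list", sum(nsamp))
  sid <- 0L
  k <- 0L
  for (i in seq_len(n)) {
    for (s in seq_len(nsamp[i])) {
      sid <- sid + 1L
      sample_id <- sprintf("S%04d", sid)
      date <- sample(config$dates, 1L)
      truth[[sid]] <- data.frame(
        sample_id = sample_id,
        individual_id = individuals@meta$individual_id[i],
        true_class = individuals@meta$true_class[i],
        sex = individuals@meta$sex[i], date = date)
      for (mx in 1:2) {
        lset <- which(multiplex == mx)
        for (r in 1:2) {
          o1 <- individuals@a1[i, lset]
          o2 <- individuals@a2[i, lset]
          r1 <- o1
          r2 <- o2
          for (j in seq_along(lset)) {
            l <- lset[j]
            if (runif(1) < config$sample_failure_rate) {
              r1[j] <- NA_integer_; r2[j] <- NA_integer_
              next
            }
            if (o1[j] != o2[j] && runif(1) < config$dropout_rate) {
              # lose one allele of the heterozygote, uniformly
              keep <- if (runif(1) < 0.5) o1[j] else o2[j]
              r1[j] <- keep; r2[j] <- NA_integer_
            }
            if (runif(1) < config$false_allele_rate) {
              pool <- setdiff(panel@alleles[[l]], c(o1[j], o2[j]))
              if (length(pool) > 0) {
                fake <- pool[sample.int(length(pool), 1L)]
                present <- c(r1[j], r2[j])
                avail <- which(!is.na(present))
                if (length(avail) > 0) {
                  present[avail[sample.int(length(avail), 1L)]] <- fake
                  r1[j] <- present[1]; r2[j] <- present[2]
                }
              }
            }
          }
          k <- k + 1L
          # a read holds 0, 1 or 2 alleles: allele1 set whenever anything
          # was read, allele2 only for two-allele reads
          lo <- ifelse(is.na(r1) & is.na(r2), NA_integer_,
                       pmin(r1, r2, na.rm = TRUE))
          hi <- ifelse(is.na(r1) | is.na(r2), NA_integer_,
                       pmax(r1, r2))
          reps[[k]] <- data.frame(
            sample_id = sample_id, date = date, multiplex = mx,
            replicate = r, locus = loci[lset],
            allele1 = as.integer(lo), allele2 = as.integer(hi))
        }
      }
    }
  }
  list(replicates = do.call(rbind, reps[seq_len(k)]),
       truth = do.call(rbind, truth))
}
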