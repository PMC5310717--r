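#' Design of the hybrid-detection performance study
#'
#' @param n_individuals sample size per simulated dataset (default 200).
#' @param hybrid_proportions true hybrid fractions tested.
#' @param replicates simulated datasets per proportion (default 20).
#' @param pool_size genotypes generated per class pool (default 10000).
#' @param policies data.frame with columns \code{criterion}
#'   ("second"/"third") and \code{Tq}; default full 2 x 2 grid at 0.75
#'   and 0.90.
#' @param settings \code{\link{mcmcSettings}} used for each classifier
#'   run; the default uses the reduced 1e4 + 1e5 chain.
#' @param seed master seed; replicate r of proportion p uses a derived
#'   sub-seed so the whole design is reproducible.
#' @return list of class \code{evaluation_design}.
#' @export
evaluationDesign <- function(n_individuals = 200,
                             hybrid_proportions = c(0, 0.05, 0.10),
                             replicates = 20,
                             pool_size = 10000,
                             policies = expand.grid(
                               criterion = c("second", "third"),
                               Tq = c(0.75, 0.90),
                               stringsAsFactors = FALSE),
                             settings = mcmcSettings(),
                             seed = 1L) {
  if (any(hybrid_proportions < 0 | hybrid_proportions > 1))
    stop("hybrid proportions must lie in [0, 1]")
  if (n_individuals > 2 * pool_size)
    stop("n_individuals exceeds the purebred pools")
  structure(list(n_individuals = as.integer(n_individuals),
                 hybrid_proportions = hybrid_proportions,
                 replicates = as.integer(replicates),
                 pool_size = as.integer(pool_size),
                 policies = policies, settings = settings,
                 seed = as.integer(seed)),
            class = "evaluation_design")
}

#' Genotype pools for each genotype-frequency class
#'
#' Generates \code{pool_size} complete genotypes per class from a
#' parental panel (the simulation feedstock of the performance study).
#'
#' @param panel \linkS4class{LocusPanel}.
#' @param pool_size genotypes per class.
#' @param seed RNG seed.
#' @return named list of \linkS4class{MultilocusGenotypes}, one per
#'   class in \code{hybridClasses()}.
#' @export
buildClassPools <- function(panel, pool_size = 10000, seed = 1L) {
  set.seed(seed)
  setNames(lapply(hybridClasses(), function(cl)
    simulateGenotypes(pool_size, cl, panel)), hybridClasses())
}

#' Compose one labelled evaluation dataset
#'
#' Draws, without replacement within each pool, a sample of
#' \code{design$n_individuals} genotypes containing exactly
#' \code{round(n * hp)} hybrids. The hybrid fraction is split into equal
#' thirds F1 / F2 / backcross (largest-remainder rounding, F1 first) and
#' the backcross third evenly between BxA and BxB (odd remainder to BxA);
#' purebreds are split equally between the two species (odd remainder to
#' A).
#'
#' @param pools output of \code{\link{buildClassPools}}.
#' @param design an \code{\link{evaluationDesign}}.
#' @param hp true hybrid proportion.
#' @param seed RNG seed for this replicate.
#' @return \linkS4class{MultilocusGenotypes} with \code{true_class}
#'   metadata, rows shuffled.
#' @export
buildSimulatedDataset <- function(pools, design, hp, seed) {
  n <- design$n_individuals
  h <- round(n * hp)
  if (h > 0 && h > min(vapply(pools, nInd, 1L)))
    stop("hybrid count exceeds pool size")
  base <- h %/% 3
  counts <- c(F1 = base, F2 = base, Bx = base)
  rem <- h - 3 * base
  if (rem >= 1) counts["F1"] <- counts["F1"] + 1
  if (rem == 2) counts["F2"] <- counts["F2"] + 1
  bxa <- ceiling(counts["Bx"] / 2)
  npure <- n - h
  comp <- c(pureA = ceiling(npure / 2), pureB = floor(npure / 2),
            F1 = unname(counts["F1"]), F2 = unname(counts["F2"]),
            BxA = unname(bxa), BxB = unname(counts["Bx"] - bxa))
  set.seed(seed)
  picked <- lapply(names(comp), function(cl) {
    k <- comp[[cl]]
    if (k == 0) return(NULL)
    pools[[cl]][sample.int(nInd(pools[[cl]]), k)]
  })
  picked <- picked[!vapply(picked, is.null, TRUE)]
  a1 <- do.call(rbind, lapply(picked, function(x) x@a1))
  a2 <- do.call(rbind, lapply(picked, function(x) x@a2))
  cls <- unlist(lapply(picked, function(x) x@meta$true_class))
  ord <- sample.int(nrow(a1))
  newGenotypes(a1[ord, , drop = FALSE], a2[ord, , drop = FALSE],
               lociNames(pools[[1]]),
               meta = data.frame(true_class = cls[ord]),
               ids = sprintf("sim%03d", seq_len(nrow(a1))))
}

#' Performance measures of a classified sample
#'
#' Computes the published validation measures from assignments and truth:
#' the estimated hybrid proportion HP (hybrids called / sample size),
#' efficiency (correctly identified individuals of a category / actual
#' number of that category), accuracy (correct / total assigned to the
#' category), and type-I error (purebreds wrongly called hybrid / actual
#' purebreds). Hybrid and purebred are treated as the two categories
#' (hybrid classes combined); unassigned individuals are excluded from
#' accuracy denominators but counted in \code{n_unassigned}.
#'
#' @param assignments factor from \code{\link{assignHybrids}}.
#' @param truth character vector of true classes (six-class labels).
#' @return one-row data.frame of metrics.
#' @export
evaluateAssignments <- function(assignments, truth) {
  if (length(assignments) != length(truth))
    stop("truth/assignment length mismatch")
  hybCls <- c("F1", "F2", "BxA", "BxB")
  trueHyb <- truth %in% hybCls
  callHyb <- assignments == "hybrid"
  callPure <- assignments %in% c("pureA", "pureB")
  n <- length(truth)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(
    n = n,
    n_hybrids_called = sum(callHyb),
    HP = sum(callHyb) / n,
    efficiency_hybrid = rate(sum(callHyb & trueHyb), sum(trueHyb)),
    efficiency_purebred = rate(sum(callPure & !trueHyb), sum(!trueHyb)),
    accuracy_hybrid = rate(sum(callHyb & trueHyb), sum(callHyb)),
    accuracy_purebred = rate(sum(callPure & !trueHyb), sum(callPure)),
    type_I_error = rate(sum(callHyb & !trueHyb), sum(!trueHyb)),
    n_unassigned = sum(assignments == "unassigned"))
}

#' Run the full performance study
#'
#' For every hybrid proportion and replicate, composes a labelled dataset,
#' fits the hybrid mixture once, applies every assignment policy in the
#' design, and aggregates per-cell means over replicates; the report rows
#' carry the mean and sd of hybrid counts, estimated HP (\%), the mean
#' squared error of HP\% about the true proportion under both the
#' divisor-n and divisor-(n-1) conventions, mean efficiencies, accuracies,
#' type-I error and unassigned counts.
#'
#' @param design an \code{\link{evaluationDesign}}.
#' @param panel \linkS4class{LocusPanel} for the parental pools.
#' @param pools optional precomputed \code{\link{buildClassPools}} result.
#' @param progress print one line per replicate.
#' @return list with \code{report} (one row per hp x criterion x Tq cell)
#'   and \code{raw} (per-replicate metrics).
#' @export
runDesign <- function(design, panel, pools = NULL, progress = FALSE) {
  if (is.null(pools))
    pools <- buildClassPools(panel, design$pool_size, seed = design$seed)
  raw <- list()
  for (pi in seq_along(design$hybrid_proportions)) {
    hp <- design$hybrid_proportions[pi]
    for (r in seq_len(design$replicates)) {
      sub <- design$seed + 1000L * pi + r
      ds <- buildSimulatedDataset(pools, design, hp, seed = sub)
      st <- design$settings
      st$seed <- sub
      post <- fitHybridMixture(ds, st)
      for (k in seq_len(nrow(design$policies))) {
        pol <- design$policies[k, ]
        m <- evaluateAssignments(
          assignHybrids(post, Tq = pol$Tq, criterion = pol$criterion),
          ds@meta$true_class)
        raw[[length(raw) + 1L]] <- cbind(
          data.frame(hp = hp, replicate = r, criterion = pol$criterion,
                     Tq = pol$Tq), m)
      }
      if (progress)
        message(sprintf("hp=%.2f replicate %d/%d done", hp, r,
                        design$replicates))
    }
  }
  raw <- do.call(rbind, raw)
  cells <- unique(raw[, c("hp", "criterion", "Tq")])
  report <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- raw$hp == cells$hp[i] & raw$criterion == cells$criterion[i] &
      raw$Tq == cells$Tq[i]
    x <- raw[sel, , drop = FALSE]
    hp_pct <- 100 * x$HP
    true_pct <- 100 * cells$hp[i]
    data.frame(
      hp = cells$hp[i], criterion = cells$criterion[i], Tq = cells$Tq[i],
      n_hybrids_true = round(cells$hp[i] * design$n_individuals),
      mean_hybrids = mean(x$n_hybrids_called),
      sd_hybrids = stats::sd(x$n_hybrids_called),
      estimated_HP_pct = mean(hp_pct),
      mse_HP = mean((hp_pct - true_pct)^2),
      mse_HP_nm1 = if (nrow(x) > 1)
        (mean(hp_pct) - true_pct)^2 + stats::var(hp_pct) else NA_real_,
      efficiency_hybrid = mean(x$efficiency_hybrid, na.rm = TRUE),
      efficiency_purebred = mean(x$efficiency_purebred, na.rm = TRUE),
      accuracy_hybrid = mean(x$accuracy_hybrid, na.rm = TRUE),
      accuracy_purebred = mean(x$accuracy_purebred, na.rm = TRUE),
      type_I_error = mean(x$type_I_error, na.rm = TRUE),
      mean_unassigned = mean(x$n_unassigned))
  }))
  list(report = report, raw = raw)
}
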