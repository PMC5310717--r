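#' Genotype accumulation curve
#'
#' Mean cumulative number of distinct genotypes as samples are analysed
#' one by one, averaged over random orderings of the sample sequence.
#'
#' @param ids vector mapping each sample to its individual.
#' @param n_orderings random permutations averaged (default 100).
#' @param seed RNG seed.
#' @return data.frame with \code{x} (samples analysed) and \code{y}
#'   (mean distinct genotypes).
#' @export
accumulationCurve <- function(ids, n_orderings = 100, seed = 1L) {
  ids <- as.character(ids)
  T <- length(ids)
  if (T == 0) stop("empty sample sequence")
  set.seed(seed)
  acc <- numeric(T)
  for (r in seq_len(n_orderings)) {
    o <- ids[sample.int(T)]
    acc <- acc + cumsum(!duplicated(o))
  }
  data.frame(x = seq_len(T), y = acc / n_orderings)
}

#' Colony size from the accumulation-curve asymptote (Eggert)
#'
#' Fits \eqn{y = a (1 - e^{b x})} (with \eqn{b < 0}) to the genotype
#' accumulation curve by nonlinear least squares; the asymptote
#' \eqn{\hat a} estimates the number of individuals contributing samples.
#' The interval is the 2.5/97.5 percentile of \eqn{\hat a} over
#' parametric bootstrap replicates: capture sequences of the same length
#' resimulated from an equal-catchability colony of size
#' \eqn{\hat a}. (Nonparametric resampling of the sample sequence is
#' structurally biased here: duplicated samples masquerade as extra
#' recaptures and drag every resampled asymptote downward.) A curve with
#' no recaptures at all, a fit with \eqn{b \ge 0}, or \eqn{\hat a}
#' beyond \code{cap} times the distinct count is flagged unreliable
#' instead of returning a silent number.
#'
#' @param ids sample-to-individual sequence.
#' @param n_orderings orderings per curve.
#' @param bootstrap_reps bootstrap resamples for the interval.
#' @param cap reliability ceiling on \eqn{\hat a} as a multiple of the
#'   distinct genotype count.
#' @param seed RNG seed.
#' @return a \linkS4class{ColonySizeEstimate}.
#' @export
eggertEstimate <- function(ids, n_orderings = 100, bootstrap_reps = 1000,
                           cap = 100, seed = 1L) {
  ids <- as.character(ids)
  d <- length(unique(ids))
  if (length(ids) < 5 || d < 2)
    stop("need at least 5 samples and 2 distinct genotypes")
  set.seed(seed)
  fit1 <- function(curve) {
    start <- list(a = max(curve$y) * 1.5,
                  b = -1 / max(2, max(curve$x) / 3))
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(b * x)), data = curve,
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) return(c(NA, NA))
    stats::coef(f)
  }
  curve <- accumulationCurve(ids, n_orderings,
                             seed = sample.int(.Machine$integer.max, 1))
  cf <- fit1(curve)
  a_hat <- unname(cf[1]); b_hat <- unname(cf[2])
  # a sequence with no recapture at all carries no information on the
  # asymptote: flagged regardless of what the optimiser returns
  reliable <- d < length(ids) && !is.na(a_hat) && !is.na(b_hat) &&
    b_hat < 0 && a_hat <= cap * d && a_hat >= d * 0.5
  boots <- rep(NA_real_, bootstrap_reps)
  if (reliable) {
    Nsim <- max(2L, round(a_hat))
    for (r in seq_len(bootstrap_reps)) {
      bs <- sample.int(Nsim, length(ids), replace = TRUE)
      if (length(unique(bs)) < 2 ||
          length(unique(bs)) == length(bs)) next
      cv <- accumulationCurve(bs, n_orderings,
                              seed = sample.int(.Machine$integer.max, 1))
      cb <- fit1(cv)
      if (!is.na(cb[2]) && cb[2] < 0) boots[r] <- cb[1]
    }
  }
  qs <- if (any(!is.na(boots)))
    stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  else c(NA_real_, NA_real_)
  est <- if (is.na(a_hat)) NA_real_ else round(a_hat)
  new("ColonySizeEstimate", method = "eggert",
      estimate = if (reliable) max(est, d) else est,
      lower = if (reliable) unname(min(qs[1], max(est, d))) else qs[1],
      upper = if (reliable) unname(max(qs[2], max(est, d))) else qs[2],
      distinct = as.integer(d), reliable = reliable,
      diagnostics = list(a = a_hat, b = b_hat,
                         bootstrap = boots[!is.na(boots)]))
}

#' Labelled-sequence capture likelihood for the Bayesian estimator
#'
#' For a chronological sequence of genotype captures, the likelihood of a
#' colony of size N is the product over samples of \eqn{(N - d_j)/N} when
#' the sample is a new genotype (with \eqn{d_j} genotypes seen before it)
#' and \eqn{1/N} when it recaptures a specific previously seen genotype.
#' The first sample contributes \eqn{N/N = 1}.
#'
#' @param ids sample-to-individual sequence, in sampling order.
#' @param N colony size (vectorised).
#' @return likelihood values, one per N.
#' @export
colonyLikelihood <- function(ids, N) {
  ids <- as.character(ids)
  new <- !duplicated(ids)
  d_before <- cumsum(new) - new       # distinct genotypes seen before j
  vapply(N, function(nn) {
    if (nn < sum(new)) return(0)
    prod(ifelse(new, (nn - d_before) / nn, 1 / nn))
  }, numeric(1))
}

#' Sequential Bayesian colony-size estimator
#'
#' Discrete posterior over colony size N on \eqn{[d, N_{max}]} (d =
#' distinct genotypes observed) with a uniform prior and the
#' new-versus-recapture likelihood of \code{\link{colonyLikelihood}};
#' point estimate is the posterior median, interval the central 95\%
#' credible interval. An all-distinct sequence puts its mass against
#' \eqn{N_{max}} and is flagged prior-sensitive.
#'
#' @param ids sample-to-individual sequence in sampling order.
#' @param N_max grid ceiling; default 50 x distinct genotypes.
#' @return a \linkS4class{ColonySizeEstimate}.
#' @export
bayesEstimate <- function(ids, N_max = NULL) {
  ids <- as.character(ids)
  d <- length(unique(ids))
  if (length(ids) < 1) stop("need at least one sample")
  if (is.null(N_max)) N_max <- 50L * d
  if (N_max < d) stop("N_max below the number of distinct genotypes")
  grid <- d:N_max
  # work in logs for long sequences
  new <- !duplicated(ids)
  d_before <- cumsum(new) - new
  loglik <- vapply(grid, function(nn)
    sum(ifelse(new, log(nn - d_before) - log(nn), -log(nn))),
    numeric(1))
  w <- exp(loglik - max(loglik))
  post <- w / sum(w)
  cdf <- cumsum(post)
  med <- grid[which(cdf >= 0.5)[1]]
  lo <- grid[which(cdf >= 0.025)[1]]
  hi <- grid[which(cdf >= 0.975)[1]]
  prior_sensitive <- post[length(post)] > 1e-3 ||
    hi >= N_max - max(1, 0.01 * N_max)
  new("ColonySizeEstimate", method = "bayesian",
      estimate = as.numeric(med), lower = as.numeric(lo),
      upper = as.numeric(hi), distinct = as.integer(d),
      reliable = !prior_sensitive,
      diagnostics = list(grid = grid, posterior = post,
                         warning = if (prior_sensitive)
                           "posterior mass near N_max: prior-dominated"
                         else NULL))
}

#' Sex ratio as males over sexed individuals
#'
#' @param males,females counts of sexed individuals.
#' @return M / (M + F); 0 when no males.
#' @examples
#' sexRatio(7, 19)  # 0.269...
#' @export
sexRatio <- function(males, females) {
  if (males + females == 0) return(NA_real_)
  males / (males + females)
}

#' Composition proportions over bat types
#'
#' @param counts named numeric vector of per-type individual counts.
#' @return proportions in percent, summing to 100.
#' @examples
#' typeProportions(c(myotis = 11, blythii = 10, hybrid = 7))
#' @export
typeProportions <- function(counts) {
  100 * counts / sum(counts)
}

#' Per-date colony composition summaries
#'
#' Counts individuals by type and sex on each sampling date (an
#' individual sampled on several dates is counted on each of them but
#' once in the overall totals), and derives the sex ratio (males over
#' sexed individuals) and type composition.
#'
#' @param records data.frame with one row per individual per date:
#'   columns \code{individual_id}, \code{date}, \code{type},
#'   \code{sex} ("F", "M" or NA).
#' @return list with \code{per_date} (date, counts by type, F/M/NA
#'   counts, sex_ratio, composition percents) and \code{overall}.
#' @export
dateSummaries <- function(records) {
  stopifnot(all(c("individual_id", "date", "type", "sex") %in%
                  names(records)))
  types <- unique(records$type)
  per <- lapply(sort(unique(records$date)), function(d) {
    sub <- unique(records[records$date == d,
                          c("individual_id", "type", "sex")])
    cnt <- table(factor(sub$type, levels = types))
    f <- sum(sub$sex == "F", na.rm = TRUE)
    m <- sum(sub$sex == "M", na.rm = TRUE)
    out <- data.frame(date = d, t(as.matrix(cnt)),
                      F = f, M = m, NAsex = sum(is.na(sub$sex)),
                      sex_ratio = sexRatio(m, f), check.names = FALSE)
    comp <- typeProportions(as.numeric(cnt))
    names(comp) <- paste0("pct_", names(cnt))
    cbind(out, t(comp))
  })
  per <- do.call(rbind, per)
  ov <- unique(records[, c("individual_id", "type", "sex")])
  cnt <- table(factor(ov$type, levels = types))
  overall <- data.frame(
    t(as.matrix(cnt)),
    F = sum(ov$sex == "F", na.rm = TRUE),
    M = sum(ov$sex == "M", na.rm = TRUE),
    sex_ratio = sexRatio(sum(ov$sex == "M", na.rm = TRUE),
                         sum(ov$sex == "F", na.rm = TRUE)),
    check.names = FALSE)
  list(per_date = per, overall = overall)
}

#' Pearson correlation between per-date abundances
#'
#' Product-moment correlation with the t-transform two-sided p-value and
#' a residual-normality model check (Shapiro-Wilk on the residuals of the
#' linear fit).
#'
#' @param x,y equal-length numeric vectors of per-date counts, n >= 3.
#' @return list with \code{r}, \code{df}, \code{p},
#'   \code{shapiro_p}.
#' @export
abundanceCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  ct <- stats::cor.test(x, y)
  res <- stats::residuals(stats::lm(y ~ x))
  sw <- tryCatch(stats::shapiro.test(res)$p.value,
                 error = function(e) NA_real_)
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, shapiro_p = sw)
}
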