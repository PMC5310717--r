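#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the six-class genotype-frequency mixture.
//
// Latent structure per sweep:
//   (i)   z_i   : class of individual i, given current allele frequencies
//                 and mixing proportions;
//   (ii)  o_il  : gene-origin pair (both-A / one-each / both-B) at each
//                 locus given z_i, plus, for heterozygous one-each loci,
//                 which allele came from which species;
//   (iii) p_A,l, p_B,l : species allele frequencies from Dirichlet
//                 posteriors given the origin-attributed allele counts;
//   (iv)  pi    : mixing proportions from a Dirichlet posterior.
// Posterior memberships q are post-burn-in empirical class frequencies.
// Uses R's RNG, so results are reproducible under set.seed().
//
// Hot loops run per locus over contiguous per-locus blocks (the data are
// column-major), with the genotype-class components cached between the
// class-sampling and origin-sampling passes.
//
// a1, a2: n x L matrices of 0-based allele indices, -1 for missing.
// K: alleles per locus. phi: 6 x 3 gene-origin table.
// [[Rcpp::export]]
List gibbs_hybrid(IntegerMatrix a1, IntegerMatrix a2, IntegerVector K,
                  NumericMatrix phi, int burnin, int sweeps,
                  double freqPrior, double mixPrior) {
  const int n = a1.nrow(), L = a1.ncol(), C = phi.nrow();
  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + K[l];
  const int T = off[L];

  // column-major copies of the genotype index matrices
  std::vector<int> A1((size_t)n * L), A2((size_t)n * L);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < n; ++i) {
      A1[(size_t)l * n + i] = a1(i, l);
      A2[(size_t)l * n + i] = a2(i, l);
    }
  std::vector<double> phiA(C), phiC(C), phiB(C);
  for (int c = 0; c < C; ++c) {
    phiA[c] = phi(c, 0); phiC[c] = phi(c, 1); phiB[c] = phi(c, 2);
  }

  std::vector<double> pA(T), pB(T), cntA(T), cntB(T);
  std::vector<double> sumA(T, 0.0), sumB(T, 0.0);
  std::vector<double> pi(C, 1.0 / C), ccount(C);
  std::vector<int> z(n, 0);
  std::vector<double> qcnt((size_t)n * C, 0.0);
  // cached per-(individual, locus) genotype components, column-major
  std::vector<double> CA((size_t)n * L), CC((size_t)n * L),
      CB((size_t)n * L);
  std::vector<double> lik((size_t)n * C);

  for (int l = 0; l < L; ++l) {
    double sa = 0.0, sb = 0.0;
    for (int a = 0; a < K[l]; ++a) {
      pA[off[l] + a] = R::rgamma(freqPrior, 1.0);
      pB[off[l] + a] = R::rgamma(freqPrior, 1.0);
      sa += pA[off[l] + a];
      sb += pB[off[l] + a];
    }
    for (int a = 0; a < K[l]; ++a) {
      pA[off[l] + a] /= sa;
      pB[off[l] + a] /= sb;
    }
  }

  const int total = burnin + sweeps;
  for (int s = 0; s < total; ++s) {
    std::fill(cntA.begin(), cntA.end(), 0.0);
    std::fill(cntB.begin(), cntB.end(), 0.0);
    std::fill(ccount.begin(), ccount.end(), 0.0);

    for (int i = 0; i < n; ++i)
      for (int c = 0; c < C; ++c) lik[(size_t)i * C + c] = pi[c];

    for (int l = 0; l < L; ++l) {
      const double *fA = &pA[off[l]], *fB = &pB[off[l]];
      const int *x1 = &A1[(size_t)l * n], *x2 = &A2[(size_t)l * n];
      double *ca = &CA[(size_t)l * n], *cc = &CC[(size_t)l * n],
             *cb = &CB[(size_t)l * n];
      for (int i = 0; i < n; ++i) {
        const int x = x1[i], y = x2[i];
        double PA, PC, PB;
        if (x < 0) {
          PA = PC = PB = 1.0;             // missing locus: factor 1
        } else if (x == y) {
          PA = fA[x] * fA[x]; PC = fA[x] * fB[x]; PB = fB[x] * fB[x];
        } else {
          PA = 2.0 * fA[x] * fA[y];
          PC = fA[x] * fB[y] + fA[y] * fB[x];
          PB = 2.0 * fB[x] * fB[y];
        }
        ca[i] = PA; cc[i] = PC; cb[i] = PB;
        double *lk = &lik[(size_t)i * C];
        for (int c = 0; c < C; ++c)
          lk[c] *= phiA[c] * PA + phiC[c] * PC + phiB[c] * PB;
      }
    }

    for (int i = 0; i < n; ++i) {
      double *lk = &lik[(size_t)i * C];
      double tot = 0.0;
      for (int c = 0; c < C; ++c) tot += lk[c];
      int zi;
      if (!(tot > 0.0) || !std::isfinite(tot)) {
        zi = (int)(unif_rand() * C); if (zi >= C) zi = C - 1;
      } else {
        const double u = unif_rand() * tot;
        double acc = 0.0; zi = C - 1;
        for (int c = 0; c < C; ++c) {
          acc += lk[c];
          if (u <= acc) { zi = c; break; }
        }
      }
      z[i] = zi; ccount[zi] += 1.0;
    }

    for (int l = 0; l < L; ++l) {
      const double *fA = &pA[off[l]], *fB = &pB[off[l]];
      const int *x1 = &A1[(size_t)l * n], *x2 = &A2[(size_t)l * n];
      const double *ca = &CA[(size_t)l * n], *cc = &CC[(size_t)l * n],
                   *cb = &CB[(size_t)l * n];
      double *nA = &cntA[off[l]], *nB = &cntB[off[l]];
      for (int i = 0; i < n; ++i) {
        const int x = x1[i], y = x2[i];
        if (x < 0) continue;
        const int zi = z[i];
        const double wA = phiA[zi] * ca[i];
        const double wC = phiC[zi] * cc[i];
        const double wB = phiB[zi] * cb[i];
        const double wt = wA + wC + wB;
        if (!(wt > 0.0)) continue;
        const double u = unif_rand() * wt;
        if (u <= wA) {
          nA[x] += 1.0; nA[y] += 1.0;
        } else if (u <= wA + wC) {
          if (x == y) {
            nA[x] += 1.0; nB[x] += 1.0;
          } else {
            const double pxA = fA[x] * fB[y];
            const double pyA = fA[y] * fB[x];
            if (unif_rand() * (pxA + pyA) <= pxA) {
              nA[x] += 1.0; nB[y] += 1.0;
            } else {
              nA[y] += 1.0; nB[x] += 1.0;
            }
          }
        } else {
          nB[x] += 1.0; nB[y] += 1.0;
        }
      }
    }

    for (int l = 0; l < L; ++l) {
      double sa = 0.0, sb = 0.0;
      for (int a = 0; a < K[l]; ++a) {
        pA[off[l] + a] = R::rgamma(freqPrior + cntA[off[l] + a], 1.0);
        pB[off[l] + a] = R::rgamma(freqPrior + cntB[off[l] + a], 1.0);
        sa += pA[off[l] + a]; sb += pB[off[l] + a];
      }
      for (int a = 0; a < K[l]; ++a) {
        pA[off[l] + a] /= sa; pB[off[l] + a] /= sb;
      }
    }
    {
      double sp = 0.0;
      for (int c = 0; c < C; ++c) {
        pi[c] = R::rgamma(mixPrior + ccount[c], 1.0);
        sp += pi[c];
      }
      for (int c = 0; c < C; ++c) pi[c] /= sp;
    }

    if (s >= burnin) {
      for (int i = 0; i < n; ++i) qcnt[(size_t)i * C + z[i]] += 1.0;
      for (int t = 0; t < T; ++t) { sumA[t] += pA[t]; sumB[t] += pB[t]; }
    }
  }

  NumericMatrix q(n, C);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < C; ++c)
      q(i, c) = qcnt[(size_t)i * C + c] / sweeps;
  List fa(L), fb(L);
  for (int l = 0; l < L; ++l) {
    NumericVector va(K[l]), vb(K[l]);
    for (int a = 0; a < K[l]; ++a) {
      va[a] = sumA[off[l] + a] / sweeps;
      vb[a] = sumB[off[l] + a] / sweeps;
    }
    fa[l] = va; fb[l] = vb;
  }
  return List::create(_["q"] = q, _["freqA"] = fa, _["freqB"] = fb);
}
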