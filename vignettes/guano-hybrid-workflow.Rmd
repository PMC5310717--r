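---
title: "Methods: consensus genotyping, hybrid mixtures and colony-size estimation from guano"
author: "guanotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus genotyping, hybrid mixtures and colony-size estimation from guano}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guanotype)
```

This vignette documents the statistical machinery of `guanotype`: the
models, their assumptions, the tunable parameters, the numerical choices,
and the places where the design was genuinely open and we had to decide.

## 1. The data and the consensus rules

The atom of every stage is a multilocus microsatellite genotype: an
unordered pair of integer allele labels (fragment sizes) at each of ~11–12
loci, possibly missing at some loci. Faecal DNA yields unreliable single
reads, so genotypes come from a *multiple-tubes* design: two PCR replicates
per sample and multiplex, and an allele enters the consensus only when
recorded in at least two reads (`min_observations`, default 2).

Three per-locus outcomes follow from that rule as we interpret it:

* two accepted alleles → heterozygote;
* one accepted allele and *no read showing anything else* → homozygote
  (this is the only reading under which a 2-replicate design can ever call
  a homozygote: the single allele is the one "recorded twice");
* anything else — an accepted allele contradicted by an extra read allele,
  or nothing accepted — leaves the locus missing.

A sample missing any panel locus is discarded before matching (the strict
rule used for the field data). Completeness is judged against the
*configured* panel, before any marker is screened out analytically:
monomorphic-marker exclusion (`screenMonomorphic`) happens downstream, as
in the original workflow where one marker was dropped only after
genotyping.

Samples collapse into individuals when their complete genotypes differ by
at most `max_mismatch` alleles (default 1), counting per-locus multiset
differences (2 − |intersection|, summed over loci). The published rule
does not say what happens when near-identity is not transitive (A≈B, B≈C,
A≠C); we resolve it by **single linkage with an ambiguity flag**, because
silent merging hides risk and splitting contradicts the software behaviour
the rule came from. Matching is monotone in the threshold and invariant to
sample order; both properties are tested.

## 2. The six-class genotype-frequency mixture

Individuals are classified with no prior species labels into six classes
defined by gene-origin proportions $\phi_z$ = (both-A, one-each, both-B):
pure A (1,0,0), pure B (0,0,1), F1 (0,1,0), F2 (¼,½,¼), BxA (½,½,0),
BxB (0,½,½). The class set stops at second-generation hybrids: with ~11
microsatellites deeper backcrosses are statistically indistinguishable,
which is also why assignment criteria that try to separate hybrid
categories are not offered.

Per locus, $P(g \mid z) = \phi_{z,AA} P_{HW}(g \mid p_A) +
\phi_{z,AB} P_\times(g \mid p_A, p_B) + \phi_{z,BB} P_{HW}(g \mid p_B)$,
with $P_\times(a,b) = p_{A,a} p_{B,b} + p_{A,b} p_{B,a}$ for heterozygotes
and $p_{A,a} p_{B,a}$ for homozygotes. Loci are treated as unlinked and
populations as in Hardy–Weinberg proportions *within gene-origin class* —
the standard assumptions of this model family. Missing loci contribute a
factor 1.

`fitHybridMixture` runs a Gibbs sampler (compiled, single chain, R's RNG
for reproducibility). One sweep: (i) each individual's class given
frequencies and mixing proportions; (ii) per-locus gene-origin latents
given the class — including, for heterozygous one-each loci, which allele
came from which species; (iii) species allele frequencies from Dirichlet
posteriors over origin-attributed allele counts; (iv) mixing proportions
from a Dirichlet posterior. Memberships $q$ are post-burn-in class
frequencies.

Tunables, with defaults and reasons:

* `burn_in` = 10^4, `samples` = 10^5 sweeps. These are the lengths used
  throughout the simulation study and the tests; they give $q$ Monte Carlo
  noise well under the 0.75/0.90 decision thresholds for ~200 individuals
  and 11 loci. Longer chains change nothing detectable.
* `freq_prior` = 1 (uniform Dirichlet per allele), `mix_prior` = 1 over
  the six classes. Uniform priors keep the sampler comparable with the
  brute-force posterior used as an oracle; both are configurable.
* Cluster labels A/B are **not identified**: the posterior is invariant
  under the label swap (pureA↔pureB, BxA↔BxB). In practice a
  well-separated chain stays in one mode; species names are attached
  afterwards with anchor genotypes of known species
  (`labelClustersWithAnchors`), and anchors must classify as purebreds.
* Initialisation: frequencies drawn from the prior, classes from the
  resulting likelihood in the first sweep. With informative panels the
  chain locks onto the two-cluster solution within a few hundred sweeps.

Assignment (`assignHybrids`) implements the two published rules. Ties at
exactly $Tq$ are assigned (the rules use ≥). Under the third criterion
nobody is unassigned; raising $Tq$ can only move purebreds to hybrid.
Under the second criterion raising $Tq$ can only move calls toward
unassigned. Both monotonicities are property-tested.

## 3. The synthetic-data generator

No raw genotypes were ever deposited for the study system, so the
generator *is* the study conditions; its defaults are fixed once:

* **Panel**: `studyPanel()` builds 11 loci with the published per-locus
  differentials (0.25–0.79) and allelic richness in the 6–11 range; the
  nearly diagnostic locus C113 is diallelic (97/100).
* **Pool construction**: for a target differential $\delta$,
  `makeParentalFrequencies` starts from a shared Dirichlet draw and
  transfers mass $\delta/2$ in opposite directions between two small
  disjoint allele sets chosen to cover the transfer with minimal excess.
  The donating side gives up most of its mass on those alleles, so each
  species ends with nearly-private alleles — the structure strongly
  differentiated microsatellite panels actually show (the field data's
  diagnostic locus has cross-species frequencies of ~0.004 vs 0.79). An
  earlier draft spread the transfer proportionally over all alleles; it
  met the same $\delta$ targets but carried visibly less classification
  information than real panels of equal $\delta$, so the private-allele
  form was adopted. Realised $\delta$ is exact by construction and
  re-verified against the definition in tests. $\delta = 1$ needs ≥ 2
  alleles (disjoint supports); $\delta > 0$ at a monomorphic locus is an
  error naming the locus.
* **Hybrid genotypes**: per-locus independent gene-origin draws from
  $\phi_z$ (unlinked markers), each gene copy then drawn from its
  species' pool.
* **Guano sampling**: 1–4 samples per individual with probabilities
  (0.65, 0.22, 0.09, 0.04) — about 1.5 samples/individual, matching 250
  droppings from 165 individuals; five sampling dates; two replicates per
  multiplex. Per-read errors: allelic dropout 0.01 (a heterozygote allele
  silently lost), false alleles 0.002 (a true allele replaced by a
  uniform draw from the locus's other alleles — the simplest model
  consistent with fragment-size panels), amplification failure 0.003 per
  locus. These per-event rates look small, but the strict all-loci rule
  compounds them across ~12 loci and 4 reads: the defaults land overall
  amplification success in the 72–90% band observed in the field. The
  heterozygote-survival probability has a closed form,
  $((1-d)^2 + d^2/2)^{L}$, used as an oracle in tests.
* **Sex**: Bernoulli with female probability 0.94 (a maternity colony);
  no generative sex model exists in the source material, so this is a
  package choice.

What the generator does **not** emulate: correlated sample quality (in
real guano, bad samples fail at many loci at once; our failures are
independent), allele-size-dependent dropout, null alleles, contamination,
within-roost spatial structure, and linkage. Passing tests therefore show
the *pipeline* is correct under the stated error model, not that real
colonies will match the simulated error structure.

## 4. The performance study

`runDesign` reproduces the validation protocol: pools of 10,000 genotypes
per class; samples of n = 200 with hybrid proportions 0, 5, 10%; 20
replicates per proportion; each replicate classified once and then
assigned under every criterion × threshold. The hybrid fraction is split
into equal thirds F1/F2/backcross (largest remainder to F1, then F2;
backcrosses split evenly, odd one to BxA) and purebreds equally between
species — the source protocol never states the mix, so these are package
choices, configurable in `buildSimulatedDataset`.

Metrics follow the published definitions exactly: HP = hybrids called /
sample size; efficiency = correct calls / actual members of the category;
accuracy = correct calls / total assigned to the category; type-I error =
purebreds called hybrid / actual purebreds. Unassigned individuals stay
in efficiency and HP denominators but leave accuracy denominators. The
MSE of HP (in %) is reported under both conventions — mean squared
deviation (divisor n) and squared bias + sample variance (divisor n−1) —
because the published table is internally consistent with the divisor-n
form (its 5%-row reconstructs to 0.975 exactly) but the printed rounding
cannot exclude the other; the ambiguity is documented rather than
resolved.

At these settings the scaled-down study (20 replicates at hp = 0, 5 at
each hybrid level) reproduces the published operating characteristics:
zero spurious hybrids under the combined-hybrid criterion at 0.75,
hybrid-detection efficiency ≥ 0.8 with type-I error ≤ 0.02 under the
all-assigned criterion at 0.75, and hybrid calls rising with the
threshold. The full-size design (20 replicates everywhere, the complete
criterion grid) is a configuration change, not a code path change.

## 5. Population-genetic statistics

* **Allele frequencies**: copy counts over typed gene copies.
* **Differential** $\delta = \frac12\sum_a |p_{A,a}-p_{B,a}|$: the
  standard multi-allelic extension; the source prints $\delta$ values but
  never the formula.
* **Rarefied allelic richness**: the hypergeometric estimator
  $A_r = \sum_a [1 - \binom{N-N_a}{g}/\binom{N}{g}]$, computed with
  `lchoose` for stability. The rarefaction size $g$ defaults to the
  smallest per-group gene-copy count at the locus (standard practice; the
  source names only "a rarefaction procedure").
* **Heterozygosity**: $H_E$ uses Nei's unbiased $\frac{2n}{2n-1}$
  correction (the estimator is unstated in the source; this is the usual
  one).
* **HWE exact test**: conditional on allele counts (Levene distribution);
  complete enumeration when the number of genotype arrays is ≤ 10^5,
  otherwise a Markov chain over random pairings of gene copies
  (allele-switch proposals between two individuals, uniformly accepted —
  uniform over labelled pairings induces exactly the Levene distribution
  on arrays), with a batch-means standard error. The p-value comparison
  "no more probable than observed" uses a 10^-9 log-tolerance so
  floating-point noise cannot flip the inclusion of tied arrays.
* **Linkage disequilibrium**: G statistic on the two-locus genotype
  table with a permutation null (one locus's genotypes shuffled across
  individuals, add-one correction). The original toolchain used a Markov
  chain on contingency tables; both are exact conditional tests, and the
  permutation form is simpler to verify (monomorphic loci are skipped
  with a reason, never silently).
* **Weir–Cockerham $\theta$**: the variance-components estimator for
  unequal sample sizes; multilocus and pairwise values are ratios of
  summed components. Slightly negative estimates are reported as
  computed.
* **G-test** of allele-frequency homogeneity: alleles with any expected
  count < 1 are pooled into an "other" class per locus (no pooling rule
  exists in the source; this keeps the chi-square reference usable).
* **FDR**: Benjamini–Hochberg through `stats::p.adjust`.

## 6. Colony-size estimators

The accumulation curve averages cumulative distinct-genotype counts over
random orderings (default 100; unstated in the source — 100 brings the
Monte Carlo wobble well below the fit's own uncertainty).

**Eggert**: nonlinear least squares of $y = a(1-e^{bx})$, $b<0$
(`minpack.lm::nlsLM`; start values $a = 1.5\,y_{max}$,
$b = -3/x_{max}$). The interval is a **parametric bootstrap**: capture
sequences resimulated from an equal-catchability colony of size
$\hat a$. We first implemented the more obvious nonparametric bootstrap
over the sample sequence and discarded it on evidence: resampling with
replacement duplicates *samples*, and a duplicated sample is an
artificial instant recapture, so every resampled curve saturates too
early (bootstrap mean ≈ 44 against a known truth of 50, interval
coverage 50%). The parametric version restores ~90% coverage on the same
benchmark. Sequences with *no* recapture at all are flagged unreliable
regardless of what the optimiser returns — a fit to a straight line has
no asymptote information — as are fits with $b \ge 0$ or
$\hat a > 100\times$ the distinct count.

**Sequential Bayesian**: discrete uniform prior on $[d, N_{max}]$
($d$ = distinct genotypes; $N_{max}$ defaults to $50d$), likelihood
product over the chronological sequence with factor $(N-d_j)/N$ for a
new genotype and $1/N$ for a recapture of a specific seen genotype (the
labelled-sequence form; the "any recapture" form $d_j/N$ differs by an
N-free constant and yields the identical posterior). Point estimate =
posterior median, interval = central 95% credible interval. When the
posterior piles against $N_{max}$ (all-distinct sequences, few
recaptures) the estimate is flagged prior-dominated — the behaviour the
field estimates showed, where sparse recaptures produced intervals like
[138; 3901].

Rounding conventions for reported ratios and percentages: two decimals
for ratios, one for percentages, half away from zero.

## 7. Problem sizes and numerical choices in the test suite

The suite runs the mixture oracle on a 1-locus/4-individual toy against a
final-axis brute force (6^4 class assignments × Dirichlet-multinomial ×
101×101 frequency grid; agreement within 0.02 total variation), the HWE
chain against complete enumeration within 3 standard errors, the
accumulation curve against exhaustive 3! enumeration, and the scaled-down
performance study described in §4 with full-length chains. Colony-size
recovery uses 10 seeded replications of 150 samples from a colony of 50.
These sizes keep the default suite in the ten-minute range on one core
while leaving every statistical check at its stated tolerance.

## 8. Known limitations

* Genotyping errors are independent across reads and loci; real guano
  data violate this, and amplification success will vary more between
  dates than the simulator shows.
* The mixture stops at second-generation hybrids; later-generation
  introgression is absorbed mostly by the backcross classes.
* Equivalence with the original clustering software is behavioural
  (oracle agreement on small instances, reproduction of the published
  performance table at scale), not bit-for-bit: its exact priors and
  update schedule are unpublished.
* Both colony-size estimators assume demographic closure within a
  sampling date and equal catchability; the field data violate closure,
  so estimates are comparative indices rather than censuses.
* The Eggert interval methodology is not identical to the one behind the
  published brackets (which is unstated); it is validated by simulation
  recovery instead.
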