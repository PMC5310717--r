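# guanotype

Non-invasive genetic monitoring of mixed-species bat colonies from guano:
consensus microsatellite genotyping, Bayesian hybrid classification,
population-genetic summaries and genotype-based colony-size estimation.

## The problem

*Myotis myotis* and *M. blythii* are sibling bat species, morphologically
almost identical, that share large maternity roosts and occasionally
hybridize. Because the animals cannot be handled, the only practical way to
ask "who is in this colony?" is to genotype the droppings they leave behind.
That raises four linked statistical problems, each covered by a module of
this package:

1. **Consensus genotyping** (`consensusFromReplicates`, `matchIndividuals`).
   Faecal DNA is degraded, so every sample is amplified twice per multiplex
   and an allele is accepted only if recorded twice (the multiple-tubes
   approach). Samples with any incomplete locus are discarded; surviving
   samples are collapsed into individuals when their multilocus genotypes
   are identical or differ by at most one allele (single-linkage, with an
   ambiguity flag for non-transitive chains).

2. **Hybrid classification** (`fitHybridMixture`, `assignHybrids`). With no
   prior species labels, individuals are assigned to six
   genotype-frequency classes — purebred A, purebred B, F1, F2 and the two
   backcrosses — defined by their expected gene-origin proportions
   &phi;<sub>z</sub> = (P(both genes from A), P(one from each), P(both from B)):

   | class | &phi; |
   |-------|-------------------|
   | pure A | (1, 0, 0) |
   | pure B | (0, 0, 1) |
   | F1     | (0, 1, 0) |
   | F2     | (&frac14;, &frac12;, &frac14;) |
   | BxA    | (&frac12;, &frac12;, 0) |
   | BxB    | (0, &frac12;, &frac12;) |

   The single-locus genotype likelihood is the mixture
   P(g | z) = &phi;<sub>z,AA</sub> P<sub>HW</sub>(g | p<sub>A</sub>) +
   &phi;<sub>z,AB</sub> P<sub>&times;</sub>(g | p<sub>A</sub>, p<sub>B</sub>) +
   &phi;<sub>z,BB</sub> P<sub>HW</sub>(g | p<sub>B</sub>),
   and a Gibbs sampler (Rcpp) jointly estimates the parental allele
   frequencies p<sub>A</sub>, p<sub>B</sub>, the mixing proportions and each
   individual's posterior membership *q*. Assignment uses the published
   threshold rules (*Tq* = 0.75 or 0.90; "third" criterion: purebred iff
   max purebred *q* &ge; *Tq*, otherwise hybrid; "second" criterion:
   combined hybrid *q* &ge; *Tq* calls a hybrid, neither reaching *Tq*
   leaves the individual unassigned).

3. **Population-genetic summaries** (`locusDiversity`, `weirCockerhamFst`,
   `hweExactTest`, `genotypicLdTest`, `gtestAlleleHomogeneity`,
   `fdrAdjust`): allele-frequency differentials
   &delta; = &frac12;&sum;<sub>a</sub>|p<sub>A,a</sub> &minus; p<sub>B,a</sub>|,
   rarefied allelic richness, Nei-corrected heterozygosities, exact HWE
   and linkage tests, Weir–Cockerham &theta;.

4. **Colony-size estimation** (`eggertEstimate`, `bayesEstimate`): the
   asymptote *a* of the genotype accumulation curve
   y = a(1 &minus; e<sup>bx</sup>), and a sequential Bayesian posterior over
   colony size from the sequence of new-vs-recaptured genotypes.

A synthetic-data module (`studyPanel`, `makeParentalFrequencies`,
`simulateGenotypes`, `simulateColonyDataset`) generates parental pools with
prescribed per-locus &delta;, hybrid genotypes of every class, and
replicated-PCR guano datasets with allelic dropout and false alleles, so the
whole pipeline is testable end to end without any field data. A
simulation-based validation harness (`runDesign`, `evaluateAssignments`)
reproduces the hybrid-detection performance study (efficiency, accuracy,
type-I error, MSE of the estimated hybrid proportion).

## Worked example

```r
library(guanotype)
panel  <- studyPanel(seed = 1)                       # 11-locus panel
colony <- makeTrueIndividuals(c(pureA = 50, pureB = 6, F1 = 3, BxB = 1),
                              panel, seed = 7)
sim   <- simulateColonyDataset(colony, panel, colonyConfig(seed = 7))
cons  <- consensusFromReplicates(sim$replicates, panel)
match <- matchIndividuals(cons$complete)
tallySamples(cons, match$membership)
```

```
        date collected genotyped individuals success_pct
1 2012-05-22        23        21          15    91.30435
2 2012-06-20        22        13          12    59.09091
...
6      Total        99        77          50    77.77778
```

99 simulated droppings gave 77 complete consensus genotypes (78%
amplification success, inside the 72–90% band typical of guano studies)
belonging to 50 distinct individuals. Classification and a colony-size
estimate:

```r
post  <- fitHybridMixture(match$genotypes, mcmcSettings(seed = 7))
table(assignHybrids(post, Tq = 0.75, criterion = "third"))
#  pureA  pureB hybrid unassigned
#      4     43      3          0
bayesEstimate(match$membership[cons$complete@meta$sample_id])
# ColonySizeEstimate (bayesian): 84 [66; 117]
```

The sampler separates the two parental clusters (labels A/B are arbitrary
until anchored with reference genotypes via `labelClustersWithAnchors`; here
the majority species landed in cluster B) and flags 3 of the 50 recovered
individuals as hybrids. The Bayesian size estimate overshoots the true 60
because recaptures are few — the same prior sensitivity the field estimates
show; `eggertEstimate` gives the accumulation-curve alternative.

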