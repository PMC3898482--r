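---
title: "Dissecting parent-of-origin effects in multiparental outbred populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting parent-of-origin effects in multiparental outbred populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poehs)
```

## The problem

A parent-of-origin effect (PoE) is present when the phenotypic effect of an
allele depends on whether it was inherited from the mother or the father.
Genomic imprinting is the best-known mechanism, but purely parental effects
(e.g. maternal environment) produce similar signatures.  In a multiparental
outbred stock — a population descended from a small panel of inbred founder
strains through many generations of pseudo-random mating — every chromosome
is a fine mosaic of founder haplotypes, and siblings share far more of their
genome through common parents than unrelated animals do.  That sharing is
*intrinsically confounded* with parent of origin: the excess similarity of
siblings arrives through parents of the same sex.  `poehs` implements an
analysis architecture that makes this confounding explicit and works around
it:

1. **Phasing**: a trio-aware hidden Markov model assigns each animal, at
   each locus, a probability over *ordered* founder pairs (paternal,
   maternal haplotype).
2. **Kinship decomposition**: ordinary marker kinship is split as
   `K± = K+ + K-`, where `K+` accumulates sharing through parents of the
   same sex and `K-` through parents of opposite sexes.
3. **Two-component heritability**: `var(y) = K+ s2g+ + K- s2g- + I s2e`,
   fitted by REML; `h2+ > h2-` across many traits is the population-level
   signature of PoE (or of parental effects — the design cannot separate
   them).
4. **iQTL scan**: at a locus, an additive model in the symmetrized
   diplotype probabilities is compared with a model giving maternal and
   paternal haplotype copies separate effects; the region statistic
   `DeltaLogP` is referred to an *empirical null* built by simulating
   non-imprinted complex traits through the identical pipeline.
5. **Reciprocal-cross analysis**: nested mixed models and sequential ANOVA
   separate sex, genotype, parental and parent-of-origin terms in F1
   crosses between a KO line and wild type.

A forward-in-time simulator of pedigreed founder-mosaic populations makes
every stage testable without any external data.

## Phasing model

The hidden state at marker `L` is an ordered founder pair `(s, t)`; by
convention the first index is the *paternally* inherited haplotype
everywhere in the package (sharing statistics are invariant to the global
choice).  Paternal and maternal chains switch founders independently with
per-interval probability `1 - exp(-d * lambda)`, where `d` is the map
distance in cM and `lambda` (default 0.05/cM) sets the mosaic grain; the
new founder is uniform on the panel.  Larger `lambda` emulates more
accumulated generations of recombination (roughly, generations/100 per cM).

Parental genotypes enter through *phase weights*: at a heterozygous marker
the probability that the ordered genotype is `ab` rather than `ba` is
proportional to the probability that the father transmits `a` and the
mother `b`.  Homozygous parents of opposite genotypes phase an offspring
perfectly; double-heterozygous trios leave it unphased (`w = 0.5`), and a
homozygous offspring is conventionally assigned `w = 0.5` for its single
duplicated ordering.  Genotype reads carry a symmetric error rate
(default 0.01), so Mendelian-impossible trios cannot zero the likelihood;
they additionally fall back to `w = 0.5` with a warning rather than
failing.  The forward-backward pass is run per chromosome with per-locus
rescaling; `phase_individual()` is checked against exhaustive enumeration
over all ordered founder-path pairs on small instances.

## Kinship algebra and scaling

With `phi` and `psi` the paternal and maternal marginals of the ordered
diplotype posterior, the expected number of alleles two animals share via
same-sex parents at a locus is `phi_i.phi_j + psi_i.psi_j` and via
opposite-sex parents `phi_i.psi_j + psi_i.phi_j`; averaging over loci gives
`K+` and `K-`.  Their sum is the ordinary kinship.  The matrices are
jointly rescaled by `D K D` with `D = diag(1/sqrt(diag(K±)))`, which makes
the diagonal of the scaled `K±` exactly one while preserving additivity.
(The unit-diagonal postcondition requires the square root; a plain
reciprocal would not achieve it.)

Two practical points discovered during development and encoded in the
tests:

* **`K-` is indefinite by construction.**  When kinship is estimated from
  too few loci its negative eigenvalues become extreme, and the restricted
  likelihood of the two-component model develops spurious optima at
  near-singular covariance matrices — a bare Cholesky can even "succeed"
  numerically on an indefinite matrix and report a meaningless likelihood.
  The fitter therefore enforces positive definiteness of
  `V = K+ s2g+ + K- s2g- + I s2e` with a margin of `1e-6 * var(y)`, and
  kinship should be built from a dense map (hundreds of loci or more).
* **Mating-scheme artifacts at shallow pedigree depth.**  When matings
  avoid full sibs inside a *small* parental pool, mated couples are
  systematically less related than random cross-family pairs, which
  depresses `K-` between siblings.  The simulator therefore defaults to
  roomy intermediate generations; the deep real stock does not suffer the
  effect at a measurable level.

## Heritability estimation

`fit_two_component()` is an average-information REML with EM fallback and
step-halving, components floored at zero (boundary flagged), convergence on
a flat restricted likelihood, and standard errors from the inverse average
information; `h2` standard errors use the delta method.  When
`s2g+ = s2g-` the model collapses to the ordinary kinship model
(`fit_one_component()`), whose fitted covariance also supplies the
whitening transform `W^-1` (symmetric square root of `V`) used by the
scan.  Fits on identity-like kinship are flagged unidentifiable via the
conditioning of the information matrix.  The iterative fit is tested
against a direct likelihood-surface search at small `n`, and against
planted-parameter recovery at `n` in the hundreds.

## The scan and its empirical null

At a locus the additive (no-PoE) model regresses the whitened phenotype on
founder dosages `phi + psi` (F − 1 free columns after the intercept), and
the PoE model on `phi` and `psi` separately (2(F − 1) columns): exactly
twice the haplotype parameters, the additive-PoE restriction.  Each model
is scored by a partial F-test against the covariate-only model;
`DeltaLogP` is the difference of the two curve maxima over a region
(default ten loci), which may be negative and whose peaks may sit at
different loci — one of the reasons single-locus tests are unreliable here.

The null distribution of `DeltaLogP` comes from simulating non-imprinted
complex traits (default seven additive QTLs of 5% variance each) on the
same genotypes and pushing them through the same REML + whitening + scan
machinery.  The tests demonstrate the motivating negative result directly:
calling regions from the best per-locus partial F-test fires at roughly
twice its nominal rate on such traits, while calls referred to the
simulated null stay controlled.  FDR at a threshold is the expected null
exceedance count over the observed count, clipped to [0, 1] and
monotonized; cis expression QTLs use the simpler rule of a direct
model-comparison peak with `logP > 5` within 5 Mb of the cognate gene,
because single-QTL expression architectures do not show the confounding.

## The simulator as a study design

The generator is the package's definition of the study conditions, not a
tuning knob: 8 fully inbred founders; several generations of
random-avoid-sib mating; a final generation organised in full-sib
families; Haldane (no-interference) recombination with crossover count
Poisson in the map length; biallelic markers with allele frequencies drawn
uniformly on (0.1, 0.9) and monomorphic panel columns resampled; traits
built from per-founder effects rescaled so each QTL's realized in-sample
variance fraction is exact, with Gaussian noise topping the variance up to
one.  Reciprocal crosses plant sex, genotype, purely-parental and PoE
effects on a quadratic growth curve with a per-animal random intercept.

What it does **not** emulate: linkage disequilibrium of real founder
panels, genotyping platforms' missingness patterns, selection, mutation,
X-chromosome dosage, litter/cage environment, and the full 50-generation
depth of a real heterogeneous stock (the reduced default is 3 generations,
125 families of 4, i.e. 500 phenotyped animals over 2,000 markers on 20
chromosomes — desk-scale while preserving the sib/non-sib contrast the
analysis exploits).  Passing tests therefore validate the statistical
machinery and its calibration on a faithful miniature, not the biology of
any particular dataset.  In particular the simulated-null median
`h2+/h2-` on this miniature comes out just below one (about 0.97–1.00
across seeds), a touch under the published simulated-null value of 1.08
obtained on the real, much more deeply structured genotypes.

## Numerical and design choices

* Coordinates are 0-based half-open for regions (BED convention); marker
  maps are strictly increasing per chromosome; region subsetting takes
  markers within a 3 Mb flank by default.
* Circular permutation of region lists shifts all regions by one common
  offset modulo chromosome length, preserving count and covered length —
  the location null used to show that "imprinted-region" marker subsets
  behave like any subset that tags family structure equally well.
* Ties at curve maxima resolve to the leftmost locus; negative `DeltaLogP`
  values are retained.
* The sign comparison of `h2+` vs `h2-` across traits excludes exact ties
  and uses the exact one-sided binomial tail by direct summation.
* Growth-ladder comparisons use maximum-likelihood fits (as nested
  fixed-effect tests require); sequential type-I ANOVA follows the term
  order age, sex, parental genotype, offspring genotype, their
  interaction; in homozygous crosses, where every F1 is heterozygous, the
  transmitting-parent main effect *is* the parent-of-origin term.
* Count dispersion uses `s = sigma2 / (mu + 1)` on library-size-normalized
  counts within replicate groups, a mean-scaled variance suited to
  approximately negative-binomial data.

## Known limitations

* Phasing requires genotyped parents for full power; without them the
  posterior is phase-symmetric by construction and carries no PoE
  information.
* `h2+ - h2-` is an upper bound on parent-of-origin heritability: shared
  environment and maternal effects load on the same component.
* The two-component REML needs dense-map kinship (see above); with tens of
  loci the `K-` spectrum is too noisy.
* The simulated-null heritability ratio and scan power depend on pedigree
  depth and sibship sizes; the defaults state the package's reference
  conditions, and all simulation-based checks quote the sizes they used.
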