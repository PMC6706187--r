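---
title: "Methods: chemotyping, morphometrics and population genetics in chemotaxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemotyping, morphometrics and population genetics in chemotaxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chemotaxa implements an integrative workflow for delimiting cryptic insect
species: cuticular-hydrocarbon (CHC) chemotyping through a
haplotype-network-style discretization of compositional profiles,
multivariate ratio analysis of linear measurements, COI population
genetics, and environmental association models.  This vignette documents
the statistical models, the parameter choices and their rationale, the
synthetic-data generator that the test suite runs on, and the numerical
conventions — the material a reviewer or maintainer needs to judge what a
passing test suite does and does not establish.

## 1. Compositional model and the chemical network

CHC abundances are compositional: only relative proportions carry
information, so every analysis starts from closed rows
(`normalize_closure()`) and, for geometry-sensitive steps, the centered
log-ratio transform `clr(x)_i = ln x_i - mean_j ln x_j`.  The clr maps the
simplex into a zero-sum Euclidean space in which ordinary covariance PCA
is meaningful.  Zeros (below-detection substances) are replaced
multiplicatively with `delta = 1e-5` — one order of magnitude below the
0.1% filtering floor, so replacement never competes with retained signal —
and the non-zero parts are shrunk proportionally before re-closure.

The chemical network discretizes the continuous clr-PCA scores into
haplotype-like category sequences:

* axes are retained if they explain at least 5% of the total variance;
* a retained axis explaining between 5% and 10% receives 2 categories,
  otherwise `k = round(pct / 5)` categories;
* per axis, a score becomes `round((s - min) / (max - min) * (k - 1))`.

Two conventions here were genuinely open design choices and deserve
comment.  First, the "eigenvalue" scale of the 5-and-divide-by-5 rule is
interpreted as *percent variance explained*: raw covariance eigenvalues
are unit-dependent (they scale with the square of the clr dispersion), so
a fixed threshold of 5 is only meaningful on the percentage scale.
Second, the normalized score is multiplied by `k - 1` before rounding:
rounding the bare 0-1 normalized score would always produce just two
categories regardless of `k`, so the `k - 1` factor is what makes `k`
categories actually realizable, with the axis minimum mapping to category
0 and the maximum to `k - 1`.  Rounding is half-to-even everywhere,
fixed for reproducibility; a sample tied exactly between categories is
therefore assigned deterministically.

Identical category sequences collapse into *chemical types*; the distance
between types is the summed per-axis absolute category difference (the
one-dimensional Euclidean distance per axis, summed — an integer L1
metric).  Types are joined by a minimum spanning tree (Kruskal, ascending
weight, ties broken lexicographically by node-label pair) and, optionally,
by equal-cost alternative links: a non-tree edge is added when its weight
equals the maximum edge weight on the tree path between its endpoints.
Alternative links are off by default; empirical chemotype networks are
near-trees, and the deterministic tree makes downstream operations (such
as cutting the heaviest edge to split the network) unambiguous.

## 2. Compositional statistics

`bray_curtis()` wraps the standard Bray-Curtis dissimilarity.
`permanova()` implements the one-way permutational MANOVA directly from
its sums-of-squares definition (`SS_total = (1/n) sum d^2` over all pairs,
`SS_within` accumulated per group) with whole-row label permutations and
the add-one Monte-Carlo convention `p = (1 + #exceed)/(B + 1)`, so p is
never exactly zero.  Only one-way designs are provided; all uses in this
workflow are single-factor.  Its pseudo-F provably equals the classical
ANOVA F when the distances are Euclidean distances of one-dimensional
data, and the implementation is cross-checked against `vegan::adonis2` in
the tests.  Class-aggregate tables in which a substance class is absent
from several samples produce zero-distance pairs that PERMANOVA cannot
handle; `jitter_zero_classes()` adds minute truncated-normal noise (mean
and sd `1e-8`, truncated at zero to preserve non-negativity) to the
affected classes for *all* samples.

`mantel_test()` correlates the strictly-lower triangles of two distance
matrices (Pearson) and permutes rows and columns of the second jointly;
the alternative is one-sided ("greater"), matching the convention of the
standard implementations.  Geographic distances are plain Euclidean
distances in degree space — deliberately, because the source workflow
computed them that way over a ~2.5-degree extent; a haversine option
exists but is off by default.

## 3. Multivariate ratio analysis

Measurement reliability is screened with the one-way random-effects
intraclass correlation ICC(1,1),
`(MS_between - MS_within) / (MS_between + (k - 1) MS_within)`, per
variable; variables below 0.85 are dropped and surviving repeats are
averaged.  Isometric size is the geometric mean of an individual's
measurements.  The shape PCA log-transforms the data and removes the
isometric direction `u = (1, ..., 1)/sqrt(p)` by subtracting each row's
mean log-measurement, then performs covariance PCA on the remainder.
Shape scores are therefore *exactly* invariant to multiplying any
individual's measurements by a positive constant — the property the tests
assert at 1e-9.  The PCA ratio spectrum orders variables by their loading
on a shape axis; the two extremes form the best single-ratio reading of
that axis.  Bootstrap CIs (default 68%, 1,000 replicates in analyses, 200
in the pipeline default for speed) resample individuals, refit, and align
each replicate's loading vector to the original axis by the sign of their
dot product — without this alignment the axis sign ambiguity would destroy
the intervals.  Group tests use Pillai's trace MANOVA with sequential
(type-I) sums of squares, species entered before location, and Welch's
t for isometric size.

## 4. COI population genetics

Haplotype collapsing uses complete deletion (sites with any gap or
ambiguity are excluded), deterministic `H1, H2, ...` labels by decreasing
frequency.  Haplotype networks reuse the chemical-network MST machinery on
Hamming distances.  This is a minimum-spanning approximation of
statistical-parsimony (TCS-style) networks: it preserves what those
networks are read for — clade separation and substitution counts on edges
— but does not compute parsimony connection probabilities; an optional
`max_link` cutoff can sever deeply divergent clades in the same spirit as
a connection limit.

Pairwise ΦST comes from the standard two-level AMOVA variance components
with the number of differing sites as the (squared) distance — the default
for sequence data in the common AMOVA tools; a haplotype-identity (0/1)
variant is available behind `distance = "haplotype"`.  Estimates may be
negative; significance is by permuting individuals between the two
populations (add-one convention).  TN93 distances are computed via
`ape::dist.dna` with pairwise deletion, with saturation-undefined pairs
returned as `NaN` and listed in an attribute; the tests verify the values
against a direct evaluation of the published TN93 formula and the
correction property `TN93 >= p-distance`.

Tajima's D uses the textbook constants (`a1, a2, b1, b2, c1, c2, e1, e2`)
and the beta-distribution approximation of its null distribution for the
p-value, with `Dmin = (2/n - 1/a1)/sqrt(e2)` and
`Dmax = ((n + 1)/(2n) - 1/a1)/sqrt(e2)`.  The coalescent-simulation
p-values of some field tools will differ slightly; the beta approximation
is deterministic and adequate for flagging strongly negative D.

## 5. Environmental association

The partner test is Pearson's chi-squared with Yates continuity correction
on the 2x2 co-occurrence table — the correction is on by default because
that is the convention under which the printed worked example
(`chi2 = 1.76`, `p = .18` from counts 100/65/96/44) reproduces.  The 19
climate variables mix units (degrees C, mm), so the climate PCA is
correlation-based (unit standardization); PC1 serves as the climate
gradient covariate.  Species occurrence is modeled with a fixed-effects
binomial GLM (logit link).  The source workflow calls its models "mixed"
but specifies no random effect, and its reported df = 1 chi-squared term
tests are exactly what fixed-effects analysis of deviance produces, so no
random effect is included here.  Backward stepwise reduction uses
`drop1`-based AIC steps, which respect marginality (an interaction is
removed before its main effects); ties break by term order.  Separation
(diverging coefficients, fitted probabilities at 0/1) is detected and
flagged rather than silently reported.

## 6. The synthetic-data generator

The generator produces all four input families with known ground truth.
Its defaults *are* the study conditions of the test suite:

| parameter | default | meaning |
|---|---|---|
| `n_colonies_per_chemotype` | 60 | colonies per chemotype (120 total) |
| `n_substances` / `n_marker_substances` | 40 / 10 | CHC peaks; markers differ between chemotypes |
| `chemotype_shift` | 2 clr units | marker offset between chemotypes |
| `within_noise_sd` | 0.5 clr units | colony-level log-scale noise |
| `n_populations` | 4 | sampling sites |
| `fixed_snps_between_species` | 16 | fixed differences between species clades |
| `theta` | 1 | Poisson mean of private substitutions |
| `migration` | 0.2 | probability of drawing a foreign founder |
| `n_individuals_morpho` | 80 | measured individuals (40 + 40) |
| `shape_offset` | 0.1 log units | species offset on 3 of 10 measurements |
| `allometry_slope` | 0.1 | size-dependence of the first measurement |
| `climate_slope` | 2 | logistic coefficient on the climate gradient |
| `detection_limit` | 1e-4 | proportion floor below which values are zeroed |

Compositions are logistic-normal: Gaussian noise on the log scale around a
chemotype mean, then closure — exactly the generative model under which
clr-PCA is the natural analysis, which is the point: the generator
emulates the *statistical structure* the analyses assume (two chemotype
centroids 2 clr units apart on a quarter of the substances, a 449-bp
two-clade alignment, allometric log-linear measurements, one latent
climate gradient behind 19 noisy indicator variables).  It does not
emulate chromatographic reality (peak shapes, co-elution, integration
error), linkage or recombination, coalescent genealogies (within-species
variation is a star genealogy: founder + private mutations, which biases
Tajima's D negative — visible in the pipeline output), or spatial
autocorrelation of climate beyond the single gradient.  Passing tests
therefore demonstrate correctness of the algorithms under their assumed
models, not robustness to real-data pathologies.

COI population structure works by giving each (species, population)
founder Poisson(`theta`) private substitutions; each colony inherits its
own population's founder with probability `1 - migration` and a uniformly
random population's founder otherwise, then adds Poisson(`theta`) private
substitutions of its own.  `migration = 1` is panmixia (ΦST ≈ 0);
`migration = 0` with `theta > 0` yields population differentiation;
`theta = 0` collapses each species to a single haplotype.

Every generator is a pure function of its configuration: the global seed
expands deterministically into per-stage child seeds, so stages are
reproducible in isolation and the pipeline manifest is byte-identical
across runs with the same configuration.

## 7. Numerical conventions and problem sizes

* Closure to row sums of 1 within 1e-9; clr rows sum to 0 within 1e-9.
* Rounding is half-to-even wherever a rounding step is part of an
  algorithm (category counts, score discretization).
* All Monte-Carlo p-values use the add-one convention.
* PCA sign convention: per axis, the largest-magnitude loading is positive
  (applied identically in clr PCA, shape PCA and climate PCA), making
  scores and loadings deterministic.
* MST ties break lexicographically by node-label pair.

The test suite exercises the pipeline at deliberately moderate sizes —
120 colonies, 40 substances, 80 individuals, 500 null simulations with
199–499 permutations, 20 replicate recovery scenarios — chosen so the
whole suite runs in about a minute while keeping Monte-Carlo standard
errors (about 0.01 on a rejection rate of 0.05 at 500 simulations) small
against the asserted tolerances.  Calibration checks reject at
`p <= 0.05` with 499 permutations, for which the 5% level is exactly
attainable under the add-one convention; deviance-test null simulations
use n = 300 per dataset, matching the sample sizes at which the asymptotic
chi-squared reference is accurate (at n = 100 the likelihood-ratio test is
measurably liberal, around 0.058).

## 8. Known limitations

* The discretization constant (`k - 1`) and the percent-variance reading
  of the eigenvalue rule are reconstructions of a loosely specified
  procedure; both are documented above and fixed by tests.
* ΦST uses pairwise-difference distances only (plus the 0/1 variant); no
  substitution-model-corrected AMOVA.
* The haplotype network is an MST approximation, not statistical
  parsimony; reticulations beyond equal-cost alternatives are not shown.
* The GLM stage fits fixed effects only; if sampling sites induce strong
  dependence, a mixed model would be more appropriate than what either
  this package or the source workflow's reported statistics use.
* Star-genealogy COI simulation exaggerates singleton haplotypes relative
  to a coalescent, so simulated haplotype counts are upper-bound-like and
  simulated Tajima's D is negative even without selection.
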