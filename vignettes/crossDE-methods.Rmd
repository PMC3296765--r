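---
title: "Calling differential expression between diverged species: the crossDE model"
author: "crossDE maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differential expression between diverged species: the crossDE model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossDE)
```

## The problem

When RNA-Seq counts are compared between samples of *different species*,
the observed difference for a gene mixes four components: true genetic
divergence of expression, the gene's response to residual environmental
variation between cultures, technical imprecision of library
preparation and sequencing, and Poisson counting noise. In well
controlled yeast experiments the environmental component alone can
account for more than half of the apparent cross-species variance, so a
test that only accounts for Poisson noise calls a large fraction of
*replicate* genes "differentially expressed" — a sure sign of an
anti-conservative test. crossDE implements a testing framework built
around that observation: every piece of the variance is measured from
replicates, and the test is explicitly calibrated so that replicate
self-comparisons behave like the null.

## The test statistic

For a gene with observed counts $C$ (control sample) and $T$ (test
sample), the null hypothesis is that both were drawn from a common
distribution whose per-sample means differ only by the sequencing-depth
scaling between the samples. The statistic is a two-by-one chi-square:

$$X^2 = \frac{(C-\mu_C)^2}{\sigma_C^2} + \frac{(T-\mu_T)^2}{\sigma_T^2}$$

Two ingredients make this usable across species:

**Null means by midpoint projection.** The depth scaling $m$ is the
median over genes of the test/control count ratio
(`medianRatioSlope()`), which is robust to a few highly expressed
outlier genes that can dominate total read counts, and only uses genes
present in both species. The per-gene null means are the midpoint of
the segment of the line $y = mx$ bounded by the two projections of the
observation, $(C,\ Cm)$ and $(T/m,\ T)$:

$$\mu_C = \tfrac{1}{2}(C + T/m), \qquad \mu_T = m\,\mu_C$$

This weights both samples evenly regardless of depth and requires no
count rescaling (`distributionMeans()`).

**Variance composition.** Poisson noise and the remaining
("non-Poisson") variation are independent, so the per-sample variance
composes as

$$\sigma^2(\mu) = \mu + (\sigma_{nP}\,\mu)^2$$

where $\sigma_{nP}$ is a *relative* (fractional) non-Poisson standard
deviation. This composition rule is fixed package-wide: it is used in
the statistic, in the calibration, and in the fold-change error
propagation, so all parts of the framework are consistent with each
other.

Although two observations enter the sum, the null means are estimated
from the same two observations, so one degree of freedom is lost and
$X^2 \sim \chi^2(1)$ under the null. The simulation suite checks this
directly (the null mean of $X^2$ sits within a few percent of 1 at
$n = 10{,}000$ genes).

## Measuring the non-Poisson variance

Per gene and species, the replicate variance $\sigma^2_{reps}$
(sample variance, $n-1$ denominator) contains Poisson noise whose
expectation is the mean replicate count $R$; the relative non-Poisson
SD is

$$\sigma_m = \frac{\sqrt{\max(0,\ \sigma^2_{reps} - R)}}{R}$$

(`replicateNonPoissonSD()`). The clamp at zero is needed because with
two replicates many variances are measured at or below the Poisson
expectation by chance. When the two replicate libraries differ in
depth, the pair is first rescaled to its common (geometric-mean) scale
through the median-ratio slope so the depth difference does not
masquerade as biological variance.

Three corrections turn these noisy per-gene estimates into usable
variances:

1. **Technical floor** (`applyTechnicalFloor()`). A uniform
   over-dispersion $\sigma_t$ calibrated on *technical* replicates
   (coding genes only) measures the resolution of the assay; no gene's
   $\sigma_{nP}$ is allowed below it: $\sigma_{nP} = \max(\sigma_m,
   \sigma_t)$. Genes closer in expression than the technology can
   resolve should not be callable.
2. **Cross-species pooling** (`pooledGeneVariance()`). Gene function,
   and hence environmental responsiveness, is assumed conserved, so
   per-species estimates are averaged, weighted by the mean read count
   behind each estimate. Estimates based on fewer than 30 mean reads
   are discarded as Poisson-dominated; genes with no reliable estimate
   anywhere fall back to the species' uniform $U$.
3. **Species rescaling** (`speciesRescale()`). Each species' replicate
   pair reproduces with a slightly different overall over-dispersion
   $U_s$; gene-specific sigmas used for species $s$ are multiplied by
   $U_s / \bar{U}$.

The pooling order adopted here is: drop unreliable estimates, take the
read-weighted mean of the per-species relative SDs, then apply the
floor to the pooled value. Flooring each estimate before pooling would
also be defensible; flooring after pooling is the slightly less
aggressive choice and keeps the floor's meaning ("the final sigma is
never below the assay resolution") exact.

## Calibrating the uniform over-dispersion U

In a replicate self-comparison the null holds for every gene, so at
level $\alpha$ exactly a fraction $\alpha$ of genes should reach
$p < \alpha$. `calibrateU()` finds the smallest $U$ on a grid (step
0.001, upper bound 2 — artifact choices; the search is a bisection made
exact by monotonicity) such that running the test between the two
replicates with $\sigma_{nP} = U$ everywhere yields at most
$\alpha \cdot n$ positives: with 10,000 calibrated genes at
$\alpha = 0.05$, the minimal $U$ with at most 500 positive genes. Genes
with a mean count below 10 across the two replicates are excluded so
that Poisson-dominated genes do not skew the calibration; "mean across
the two replicates" (not each separately) is the reading adopted.

A caveat established by simulation and worth knowing: the calibrated
$U$ is an *operational* quantity, not an unbiased estimator of a
generative over-dispersion. Because the statistic plugs the estimated
midpoint mean into its own variance denominator, skewed multiplicative
noise couples the numerator and denominator; with log-normal latent
noise the calibrated $U$ under-shoots a planted relative SD by about
0.003 at 0.16 and 0.02 at 0.30 (and symmetric Gaussian noise
over-shoots by a similar margin). The bias does not shrink with the
number of genes. Recovery is exact to the grid at small
over-dispersion. None of this affects the calibration's defining
property — the replicate false-positive fraction equals the nominal
level by construction — it only means $U$ should not be read as a
physical noise parameter.

## Batches, combined tests, and fold changes

Replicates grown on different days carry shared day effects; comparing
across days inflates apparent differences. Comparisons are therefore
restricted to same-day pairs (replicate $i$ versus replicate $i$), each
batch is tested independently, and the per-batch p-values are combined
with Fisher's method ($-2\sum \ln p_i \sim \chi^2(2k)$,
`combineBatches()`).

The reported effect size is the log2 ratio of size-normalized counts of
one batch pair (the first, by default), with the geometric mean of the
two library sizes as the common reference — fold changes are invariant
to that reference choice. Uncertainty is propagated from the same
variance composition:

$$\sigma_{FC} = \sqrt{\left(\frac{\sigma_T}{T\ln 2}\right)^2 +
                      \left(\frac{\sigma_C}{C\ln 2}\right)^2},
  \qquad \sigma_X^2 = X + (\sigma_{nP} X)^2$$

and the reported interval is $\log_2 FC \pm 2\sigma_{FC}$ (~95%).
Genes with a zero count on either side have undefined fold changes and
are reported as `NA` rather than pseudo-counted.

A limitation inherited from total-count size normalization: if a large
fraction of the transcriptome truly changes in one direction-asymmetric
way, library totals absorb part of the signal and every fold change
shifts by the same offset. The test itself is immune (it uses the
median-ratio slope), and the coverage simulations in this package use a
DE fraction of 0.2 — the order of what cross-species yeast comparisons
actually show — precisely so that size normalization stays anchored by
the unchanged majority.

## Inclusion criteria and the core set

Cross-species comparisons are restricted to genes measurable as 1:1
orthologs (`measurableOrtholog()`): annotated in the reference species;
exactly one annotated ortholog in the other species; a complete ORF;
annotated length within 90–110% of the reference length (closed
interval — the boundary reading is an artifact choice); at least 90% of
aligned reads aligning uniquely; protein coding (non-coding genes
reproduce poorly in technical replicates). "Core" genes pass in every
species (`coreGeneSet()`) and are the common currency of multi-species
analyses; adding a species can only shrink the set. Candidate gene
duplications are held to a stricter standard: both copies must cover
more than 60% of the reference gene and be uniquely alignable
(`duplicationCandidates()`); further sequence-level filters can be
supplied as a predicate.

## Evolutionary analyses

**Lineage assignment** (`assignLineage()`). A change is attributed to a
branch of the fixed four-taxon tree `((cer,par),(mik,bay))` when every
pairwise comparison that crosses the branch is significant (combined
p-value, $\alpha = 0.01$) with a consistent direction — every species
on one side above every species on the other. Terminal branches need
three consistent pairs; the internal branch needs all four cross-split
pairs. Direction is evaluated on the combined-batch fold-change sign (a
per-batch reading would be stricter; combined was adopted). A gene may
be assigned to several branches.

**The expression-divergence clock** (`divergenceRegression()`). If
expression evolves multiplicatively and clock-like, the variance of
per-gene log2 fold changes grows linearly with sequence divergence.
Each sample pair contributes one point: its fold-change variance
against the intergenic substitution rate separating the samples, with
replicate self-pairs at rate 0. Ordinary least squares gives the
divergence rate (slope) and the replicate variance (intercept). Class
comparisons (TATA status, CDS length, and similar) use an analysis of
covariance: the p-value of the rate-by-class interaction in
`var ~ rate * class` (`compareClassSlopes()`).

**Clustering** (`clusterSamples()`). Samples are clustered on
$1 - \rho_{Spearman}$ with average linkage (the linkage is an artifact
choice; the distance is the framework's). Spearman on counts is
invariant to monotone depth effects.

## The simulator

`simulateDataset()` generates data with exactly the structure the test
assumes: per-gene expected counts $\mu_g$ log-normal (meanlog 5, sdlog
1.5 by default — tens to tens of thousands of reads, >95% of genes
above 10 reads, the regime of a deeply sequenced yeast experiment);
per-sample latent expression factors $e$ log-normal with mean 1 and
relative SD $\sigma_g$ (noise acts multiplicatively, as expression
regulation does); counts Poisson with rate $\mu_g e \cdot$ depth.
Over-dispersion is uniform ($\sigma_g = U$, default 0.16 — the
technical-resolution magnitude) or per-gene log-normal. Injected
differential expression shifts the last species' $\mu_g$
multiplicatively for a chosen fraction of genes, with magnitude either
fixed in log2 units or expressed as Cohen's D times the null log2
fold-change SD at the gene's depth,
$\sqrt{2(1/\mu + \sigma^2)}/\ln 2$, so that "effect size" means the
same thing at every expression level.

What the generator deliberately does *not* model: gene-length and
sequence-content biases, correlated gene modules responding jointly to
the environment, batch effects beyond the pairing structure, and
mappability differences between species. Passing simulations therefore
validate the statistical machinery — calibration, type-I error control,
interval coverage, parameter recovery — not robustness to those
real-data artifacts, which the inclusion criteria and batch pairing are
designed to contain.

Problem sizes used by the validation suite were chosen to make each
check's Monte-Carlo error small relative to its tolerance: 10,000 genes
for calibration and null-distribution checks, 5,000 for interval
coverage, 8,000 for the conservatism check, 100,000 for
calibration-recovery precision, 20,000 fold changes per point for the
clock recovery.

## Numerical and degenerate-input conventions

* Genes with both null means zero return $X^2 = 0$, $p = 1$, `NA` fold
  change (no divide-by-zero, no pseudocounts).
* Ratios for the normalization slope exclude zero-control genes; an
  even-length ratio list takes the mean of the two central values.
* Negative estimated non-Poisson variances clamp to zero before the
  floor.
* Under-dispersed replicate pairs calibrate to $U = 0$ with an explicit
  flag and warning rather than an error.
* Result tables serialize numerics at full double precision with an
  `NA` sentinel, and round-trip losslessly.
* All simulation randomness flows through a single integer seed;
  identical seed and spec reproduce results byte-for-byte.

## A worked example

```{r example}
spec <- simulationSpec(nGenes = 2000L, nSpecies = 2L,
                       deFraction = 0.05, effectModel = "cohen",
                       effectSize = 3)
sim <- simulateDataset(spec, seed = 42)
sim$counts

## replicate-calibrated uniform over-dispersion per species
calA <- calibrateSpecies(sim$counts, "Scer")
calB <- calibrateSpecies(sim$counts, "Spar")
calA

## gene-specific variances pooled across species, floored at 0.16
genes <- referenceGenes(sim$orthologs)
vm <- buildVarianceModel(sim$counts, sim$orthologs, genes,
                         c(Scer = uValue(calA), Spar = uValue(calB)),
                         sigmaT = 0.16)
res <- callDE(sim$counts, sim$orthologs, vm, c("Scer", "Spar"),
              genes = genes, alpha = 0.01)
res

ev <- evaluateFprPower(res, sim$truth, alpha = 0.01)
unlist(ev[c("fpr", "power")])
```

## Known limitations

* Two replicates per species give very noisy per-gene variance
  estimates; the floor and the cross-species pooling are what make the
  test usable, at the price of conservatism for genuinely low-variance
  genes and reduced sensitivity for genes whose variance differs
  between species.
* The calibrated $U$ is operational, not generative (see above).
* Total-count fold-change normalization is sensitive to strongly
  asymmetric global expression shifts.
* The degrees-of-freedom argument is asymptotic in the count size; for
  genes with fewer than ~10 reads the $\chi^2(1)$ reference is rough,
  which is why such genes are excluded from calibration and flagged
  `low_count` in results.
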