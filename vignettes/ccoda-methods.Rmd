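---
title: "Covariate-corrected dispersion analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-corrected dispersion analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccoda)
```

## The question

Shotgun metagenomes of a host-associated microbial community can be summarized
as a matrix of read counts per gene family (for instance KEGG Orthology
groups) per sample. Most differential-abundance tools ask whether a family's
*mean* abundance differs between groups. `ccoda` asks a different question:
across a population of samples, which gene families are more variable — or
more *in*variable — than expected given their mean abundance? Because counts
are intrinsically noisy, and noisier at low abundance, "variable" can only be
defined against a null model of the mean–variance relationship; and because
public cohorts come from different studies with different protocols, the
statistic must first remove between-study shifts.

## Normalization

Raw counts are confounded by gene length and sequencing effort. We normalize
to reads per kilobase of genome equivalents (RPKG):

* **AFL** (average family length, bp): the average length of the reference
  genes a family's reads matched, per family per sample. Cells with no reads
  have no AFL; they are imputed with the family's mean AFL across samples
  (`impute_afl()`), with an optional global default for families never
  observed.
* **Genome equivalents**: `GE = total_reads × read_length / AGS`, where AGS
  is the community's average genome size in bp (an input, typically from a
  single-copy-marker estimator). Dividing by GE expresses abundance per
  genome rather than per read, making samples with different depth and
  community genome size comparable.

The transform is `log_rpkg = ln(((count + pseudocount) / (AFL/1000)) / GE)`.
The pseudocount keeps zeros finite; its magnitude defaults to 1 read and is
exposed as a parameter because it mildly shapes the low-abundance end of the
scale. The natural log acts as a variance stabilizer: raw RPKG means and
variances are almost perfectly rank-correlated, and the log removes most of
that trivial coupling.

For phylum-restricted analyses a whole-metagenome AGS is not meaningful, so
`marker_normalize()` instead divides each sample by the median abundance of a
set of universal single-copy marker families, which also absorbs overall
changes in the focal clade's abundance.

## The study-effect model and the statistic

For log-RPKG value $D_{g,s}$ of family $g$ in sample $s$,

$$D_{g,s} = \mu_g + \sum_{y} I_{y,s}\,\beta_{g,y} + \varepsilon_{g,s},$$

where $\mu_g$ is the family's grand mean, $I_{y,s}$ indicates membership of
sample $s$ in study $y$, and $\beta_{g,y}$ is the study-mean offset. With
only categorical study effects the least-squares fit is exact: residuals are
obtained by subtracting per-study means. The statistic of interest is the
**residual variance** $V^\varepsilon_g$, the sample variance of
$\varepsilon_{g,\cdot}$ pooled over all $m$ samples.

Two numerical conventions are deliberate:

* the variance denominator is $m-1$. The choice only rescales observed and
  null statistics by the same constant, so p-values are unaffected (a test
  asserts this);
* no degrees-of-freedom correction is applied for the fitted study means —
  the null replicates are pushed through the *identical* computation, so the
  comparison stays calibrated.

## The parametric-bootstrap null

Under the null hypothesis, counts for every family in study $y$ follow a
negative binomial with the family's observed per-study mean and a *single*
study-wide size parameter $k_y$ (variance $\mu + \mu^2/k$; small $k$ =
strong overdispersion). The test then:

1. estimates, per family and study, the method-of-moments size
   $\hat k = \hat\mu^2 / (\hat\sigma^2 - \hat\mu)$ wherever the sample
   variance exceeds the mean (elsewhere the estimator is undefined and the
   cell is excluded — a count of exclusions is retained);
2. summarizes each study by the **mode** of a Gaussian kernel density
   estimate fitted to $\ln \hat k$ (normal-reference bandwidth, 512 grid
   points over the observed range padded by three bandwidths); the mode is
   robust to the minority of genuinely variable/invariable families that
   contaminate the per-gene estimates, whereas the median and harmonic mean
   are dragged whenever the contamination is asymmetric. Both alternatives
   remain available for comparison (`estimate_study_k(estimator=)`);
3. draws $B$ replicate count matrices from $\mathrm{NB}(\hat\mu_{g,y},
   \hat k_y)$ (default $B = 750$), re-applies pseudocount, normalization,
   model fit and residual variance to each, giving null statistics
   $V^{\varepsilon_0}_{g,b}$;
4. computes a two-tailed bootstrap p-value from squared relative deviations
   about the family's null mean:

$$p_g = \frac{\#\left\{b :
  \left(\tfrac{V^{\varepsilon_0}_{g,b} - \bar V^{\varepsilon_0}_g}
  {\bar V^{\varepsilon_0}_g}\right)^2 \ge
  \left(\tfrac{V^{\varepsilon}_{g} - \bar V^{\varepsilon_0}_g}
  {\bar V^{\varepsilon_0}_g}\right)^2\right\} + 1}{B + 1}.$$

The smallest attainable p is $1/(B+1)$; ties count as exceedances. When
$\bar V^{\varepsilon_0}_g > 0$ this ordering is identical to ranking by
$|V - \bar V^{\varepsilon_0}|$, which a test asserts. Families whose null
mean is zero (e.g. all-zero counts) have no usable null scale; they get
$p = 1$ and a flag. Direction is assigned by the sign of
$V^\varepsilon_g - \bar V^{\varepsilon_0}_g$: above-null families are
candidates for "variable", below-null for "invariable". This is the only
reading under which a single two-tailed p yields the two one-sided call
families.

Multiple testing uses Storey q-values, implemented in the package: $\pi_0$
from the smoother method ($\pi_0(\lambda)$ over $\lambda = 0.05, \dots,
0.95$, cubic smoothing spline, value at the largest $\lambda$, clamped to
$(0,1]$; a bootstrap-$\lambda$ variant is available), then
$q_i = \pi_0 \min_{p_j \ge p_i} m p_j / r_j$, monotone in $p$.

**Cluster bootstrap (optional).** The parametric null draws families
independently, discarding the covariance that operons and genomes induce.
`cluster_bootstrap_adjust()` resamples whole samples with replacement within
each study, recomputes the statistic, and centers/scales the resulting
non-parametric statistics to the parametric null's per-family mean and sd;
the adjusted ensemble replaces the parametric one in the p-value. Families
with degenerate bootstrap sd fall back to their parametric rows and are
flagged.

## Simulation framework and empirical FDR

`simulate_dataset()` generates the study conditions used throughout the
package's evaluation: three studies, per-study size
$k_y \sim \mathrm{lognormal}(-0.65, 0.57)$ and family means
$\sim \mathrm{lognormal}(2.94, 2.23)$ — parameter values representative of
healthy-gut shotgun cohorts — with family means shared across studies and
one matrix spanning all study blocks. A "variable" true positive divides
$k_y$ by an effect size $z$, an "invariable" one multiplies it by $z$. The
effect size is not pinned down by any published value; the package defaults
to $z = 4$, states it in calibration output, and exposes it as a parameter
rather than hiding the sensitivity.

The realized false discovery rate of the test differs between directions —
detecting *extra* overdispersion in already overdispersed counts is harder
than detecting its absence — so a single q cutoff misstates the FDR.
`calibrate_empirical_fdr()` simulates labeled datasets with 43% true
positives over a grid of variable:invariable ratios
$\{0.1, 0.2, 0.5, 1, 2, 5, 10\}$, and per direction finds the largest q
cutoff whose realized FDR among same-direction calls stays at or below the
target, stepping over observed q values without interpolation
(conservative and deterministic); the reported cutoff is the median across
the grid. `ccoda_cutoffs()` ships a reference calibration of this procedure
(5%: 0.0238 variable / 0.108 invariable; 10%: 0.0669 / 0.180; 25%: 0.181 /
0.294) used as default call thresholds.

**What the simulations do and do not emulate.** They reproduce multi-study
negative-binomial counts with realistic mean and dispersion spread, shared
means, and per-study dispersion. They do not emulate zero inflation,
between-family covariance (operons/genomes — partially restored by the
cluster bootstrap), compositional coupling, or AFL/AGS measurement error
(simulated data use a constant 1-kb family length and unit genome
equivalents, so the normalization reduces to `ln(count + 1)`). Passing
simulation-based tests therefore demonstrates calibration and power under
the stated generative model, not under every failure mode of real data.

**Evaluating type-I error.** When the test is evaluated on simulated null
data with *known* parameters, the generating $k_y$ **and** means are
supplied to the null generator (`ccoda_test(k =, mu =)`); the measured
fraction of null families at $p \le 0.05$ is then 0.05 up to Monte-Carlo
error. When the null is instead conditioned on means estimated from the
same data — as it must be on real data — the test becomes conservative for
low-abundance families (observed and null statistics are positively coupled
through the estimated mean), and the empirical $\alpha$ falls below
nominal, decreasing further with sample size. This conservatism is one
reason the empirical-FDR calibration, which runs the full estimated
pipeline, is the operative guarantee for calls on real data.

## Associations, enrichment, zeros

* **Partial Kendall's τ** (`partial_kendall_tau()`): τ-b (tie-corrected —
  important because taxa with zero abundance share ranks) between a
  family's residuals and a covariate, partialing out study indicator
  columns via inversion of the pairwise τ matrix. Significance comes from
  permuting the covariate *within* studies ($P = 250$ by default) with
  $p = (\#\{|\tau'| \ge |\tau|\} + 1)/(P+1)$; the $+1$ correction avoids
  zero p-values where the plain fraction would be ambiguous. Taxa tables
  should be clr-transformed first (`clr_transform()`, offset $10^{-6}$) to
  blunt compositional artifacts.
* **Enrichment** (`fisher_enrichment()`): two-tailed Fisher exact tests of
  a gene set against pathway/module annotations over a background of
  observed ∩ annotated families; summarized at $q \le 0.25$ with odds
  ratio > 1. `subsample_family_sets()` supports annotation-bias designs
  that compare equal-sized draws from phylum-private and shared pools.
* **Zero inflation** (`zero_inflation_test()`): intercept-only
  zero-inflated negative binomial versus plain negative binomial. The
  inflation term is assessed by a likelihood-ratio test (1 df). A Wald test
  on the inflation intercept was considered and rejected: on the logit
  scale that Wald statistic tests $\pi = 0.5$, not $\pi = 0$, so it is
  uninformative exactly when inflation is strong ($\hat\pi \approx 0.5$
  gives $z \approx 0$). The LRT reference distribution is conservative at
  the boundary, which suits a screen. Count vectors with no zeros get
  $p = 1$ by definition.

## Phylogenetic distribution

`tree_density()` scores a family's gene tree by the sum of branch lengths
divided by the mean root-to-tip height — a rate-corrected breadth measure:
an $L$-leaf star with equal branches scores exactly $L$, and global
branch-length scaling cancels. Trees must have branch lengths everywhere
and at least five leaves by default (fewer representatives make the density
unreliable); unrooted inputs are midpoint-rooted, a deterministic choice
needed because tip height requires a root and standard tree builders emit
unrooted trees. For families with too few sequences, `predict_pd()`
extrapolates density from the total annotation count by least squares on
the log–log scale — both quantities span orders of magnitude, so a linear
fit on raw scales would be leverage-dominated — and reports a 5-fold
cross-validated mean absolute percentage error alongside predictions, which
carry an explicit `predicted` flag.

## Problem sizes and reproducibility

Every stochastic step accepts a seed and is bit-reproducible given (seed,
B, inputs); family and sample order are taken from input files and never
sorted, so positional seeding is stable. The package's own evaluation suite
runs the full pipeline at 1000 families × 60–480 samples with
$B = 150$–$200$ and a handful of replicates per condition — sizes chosen so
the entire evaluation, including a seven-ratio calibration grid, completes
in minutes on a single core while keeping Monte-Carlo error small relative
to the tolerances asserted.

## Known limitations

* The null is a plain negative binomial; zero-inflated data are screened
  (`ccoda_zero_inflation()`) but not modeled in the null.
* With means estimated from data the test is conservative at low abundance
  (see above); heavily zero-inflated, low-mean families tend toward
  non-significance rather than false positives.
* The per-study size summary assumes fewer than half of families are truly
  differentially dispersed; gross violations bias $k_y$.
* Calibrated cutoffs are functions of the simulation conditions (effect
  size, true-positive fraction, ratio grid); the calibration report states
  them so users can re-calibrate for their own regime.
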