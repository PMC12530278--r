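---
title: "Methods: detecting compositional thresholds along a disturbance gradient"
author: "mesothresh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting compositional thresholds along a disturbance gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesothresh)
```

## The scientific question

Terrestrial plant material entering a pond acts as a continuous disturbance:
as the loaded mass increases, dissolved organic carbon and water colour
rise, oxygen falls, and the free-living microbial community may not respond
smoothly but instead flip between compositional states at a critical
loading. This package provides the statistical machinery to (i) partition
multivariate community variance among experimental factors, (ii) locate the
loading at which composition changes most sharply, (iii) relate loading,
environment and composition through competing linear and piecewise models,
and (iv) summarize the functional side of the shift through
community-weighted genome traits and differential metabolic pathways. A
simulator of the full experimental design supplies ground truth so each
stage can be checked end to end.

## Variance partitioning

For a Bray–Curtis dissimilarity matrix $D$ on $n$ samples, the total sum of
squares is $SS_T = \sum_{i<j} d_{ij}^2 / n$, the trace of the
Gower-centered matrix $G = -\tfrac12 J D^{(2)} J$ with $J = I - \mathbf{1}
\mathbf{1}^\top / n$. Model terms enter sequentially (Type-I): for the
cumulative design matrix of the first $k$ terms with hat matrix $H_k$, the
$k$-th term's sum of squares is $\mathrm{tr}(H_k G) -
\mathrm{tr}(H_{k-1} G)$, and pseudo-F is the usual ratio of term to
residual mean squares. Sequential decomposition makes term order part of
the declared analysis — the pipeline enters burning treatment, then
loading, then sampling day, so "day" is interpreted conditional on the
design gradient. Continuous covariates enter through their centered model
matrix with one degree of freedom, exactly like factor contrasts.

P-values come from free permutation of sample labels (rows and columns of
$G$ permuted jointly), with one set of permutations shared across terms,
and the unbiased-from-zero convention $p = (b+1)/(m+1)$. Sampling days are
repeated measures on mesocosms; the pipeline follows the convention of
including time as a fixed term rather than restricting permutations, but a
`strata` argument provides within-stratum permutation when a restricted
test is wanted. When an explicit permutation matrix is supplied (e.g. all
$n!$ relabellings for a small exactness check) it is treated as the
complete null set and $p$ is the plain proportion.

## The threshold scan

Every observed loading value $t$ with at least two samples on each side of
the split defines a candidate binary factor $\mathbb{1}[\text{loading} \le
t]$; a one-term PERMANOVA per candidate yields an $R^2$ profile over $t$,
and the argmax is the compositional threshold. Ties are broken toward the
smaller threshold and flagged. Because the reported best-candidate p-value
is the maximum of ~a dozen highly correlated tests, it is selection-biased;
the scan optionally re-runs itself on each permutation and compares the
observed maximum $R^2$ against the permutation distribution of maxima
(`correct = TRUE`), which restores proper control. The default reports the
raw value, matching how such scans are usually reported, with the
correction available and the bias documented rather than hidden.

## Ordination and vector fitting

PCoA is the eigendecomposition of $G$; scores are eigenvectors scaled by
the square roots of their eigenvalues, negative eigenvalues are reported
but carry no scores. NMDS minimizes Kruskal stress-1,
$\sqrt{\sum (\hat d - d^*)^2 / \sum \hat d^2}$, where $d^*$ are monotone
disparities obtained by isotonic regression of the configuration distances
on the input dissimilarity order (primary tie treatment: tied
dissimilarities are ordered by current distance, so they may take distinct
disparities). The configuration is initialized from PCoA and updated by a
Guttman transform; each proposed update is accepted only if it lowers
stress, with step halving otherwise, so the recorded stress trace is
non-increasing by construction and the final stress can never exceed that
of the metric start. Two dimensions are the default, matching how such
ordinations are displayed. Axis signs are arbitrary, so `orient_axes()`
flips each axis to correlate non-negatively with a covariate (by default
the loading gradient), keeping plots and downstream axis-1 regressions
consistent.

Vector fitting regresses each centered variable on the ordination scores;
$r^2$ is the coefficient of determination, the direction the unit
coefficient vector, and significance comes from permuting the variable.
Constant variables return $r^2 = 0$, $p = 1$ with a warning rather than an
error, since real chemistry tables occasionally contain degenerate columns.

## Linear vs piecewise models

Environmental state is summarized as the first principal coordinate of the
nine standardized variables — equivalent to PC1 of a standardized PCA, and
oriented to correlate positively with loading. For a response $y$ against
gradient $x$, the piecewise model is $y \sim 1 + x + (x - c)_+$ with a
single unknown breakpoint $c$. The fit minimizes RSS over a deterministic
grid (the admissible interior observed $x$ values), then refines between
the best candidate's neighbours by golden-section search — a global,
derivative-free alternative to iterative linearization that cannot diverge
and is exactly reproducible. The breakpoint is counted as a consumed
parameter: residual degrees of freedom are $n - 4$, and the comparison with
the nested linear fit uses $F = ((RSS_{lin} - RSS_{pw})/2) /
(RSS_{pw}/(n-4))$ on $F(2, n-4)$, selecting the piecewise model when $p <
0.01$. Because the breakpoint is profiled out, this reference distribution
is approximate and mildly liberal; the realized null selection rate at
$\alpha = 0.01$ is measured in the test suite (about 1% over 1000 linear
null replicates) rather than assumed. RSS differences at rounding-noise
scale relative to the response's total variation are treated as zero so
that exactly-linear data yield $F = 0$ and a linear verdict.

The microbiome-side response is NMDS axis 1 (after orientation), regressed
on environment PC1 with the same machinery — the pipeline reports both the
loading-to-environment and environment-to-microbiome model choices per day.

## Traits and pathways

Relative genomic plasticity of taxon $i$ is
$\mathrm{mean}_{j \ne i}\,\big(d^{gene}_{ij} - d^{prot}_{ij}\big)$: how far
the taxon's functional (proteome) divergence departs from its marker-gene
divergence. The literal gene-minus-proteome sign is the default; because
either direction of decoupling can be the quantity of interest, the
opposite sign and an absolute-value variant are explicit options rather
than silent choices. Community-weighted means renormalize relative
abundances over trait-complete taxa per trait and report the covered read
fraction, so partially annotated trait tables degrade transparently.
Growth rate is derived from doubling time as $\ln 2 / t_d$.

Pathway abundance sums member-taxon counts. Differential testing
depth-normalizes by median-of-ratios size factors, regresses
$\log_2(\text{normalized} + 1)$ on centered-and-scaled loading — the slope
is the log2 fold change per 1 SD of loading — and takes two-sided
permutation p-values with one set of loading permutations shared across
pathways. This is a deliberate, assumption-light replacement for
negative-binomial shrinkage estimators: the scientifically defined content
here is the per-SD fold-change scale and the three-clause filter
($p < 0.01$, $|log2FC| > 2$, $\ge 5$ member taxa), which are reproduced
exactly. The pseudocount (default 1) is configurable since zero handling
is a genuine free choice. Pathways constant in raw abundance are skipped —
after size-factor division a constant row varies numerically but carries no
information.

## The simulator and what it does (not) emulate

`simulate_experiment()` generates the full design: 30 mesocosms split
15/15 between burned and unburned treatments, loadings on a fixed 0–400 g
grid (25 g steps through 200 g, then 50 g), water communities at days 10,
59 and 89, and host/plant-associated communities (Daphnia, mosquito, sage,
willow) at the final day as convex mixtures of a source-specific
composition with the mesocosm's water community.

Composition follows a two-state logistic mixture: per-taxon log-abundance
tilts of SD `effect_size` (default 1) separate the states, and the mixing
weight $w = \mathrm{logit}^{-1}(0.08\,(\text{loading} - 100))$ switches
states across a true threshold of 100 g over roughly ±40 g — one dominant
transition, the minimal structure that produces a threshold rather than a
smooth gradient. Burning is a weak log tilt (SD 0.15) on the expected
composition, sized to explain on the order of 1% of community variance;
temporal drift is a per-day tilt (SD 0.6) with the first day as baseline.
Expected compositions pass through a Dirichlet stage (concentration 200)
for compositional overdispersion and a negative-binomial sequencing depth
(mean 12 000, size 30) feeding a multinomial draw, so rarefaction to the
default 5258 reads almost never drops samples. The nine environmental
variables are hinge functions of loading with their breakpoint at 100 g;
the above-hinge slope relaxes exponentially toward the below-hinge slope
with a 20-day time constant, so day 10 carries a clear hinge and later
days are nearly linear — reproducing the design where piecewise models win
early and lose late. Genome traits are log-uniform in realistic ranges
(2–8 Mb, 1–30 h doubling) with state-2 taxa biased toward smaller, faster
genomes; pathway membership probabilities are tilted by a per-pathway
state affinity so the pathway table carries loading-differential signal.
With per-taxon tilts of SD 1, aggregate pathway fold changes stay below
the |log2FC| > 2 filter — passing that filter requires near-complete taxon
turnover, which the default conditions deliberately do not impose — so the
filter logic is validated on constructed signals in the test suite.

What passing tests on this generator do **not** show: real amplicon data
have sparser, heavier-tailed taxon distributions, phylogenetically
structured (not independent) taxon responses, sequencing batch effects,
and chemistry measured with correlated instrument error. The simulator
validates the statistical machinery, not the biology of any particular
system.

## Numerical choices and degenerate inputs

Permutation p-values use $(b+1)/(m+1)$ everywhere except explicit
exhaustive enumeration. The NMDS update tolerance is $10^{-6}$ stress per
iteration with a 500-iteration cap; non-convergence returns the best
configuration with a warning flag rather than an error. Exact Wilcoxon
p-values are computed by full enumeration of group assignments (tie-aware,
two-sided by doubling the smaller tail, capped at 1) whenever both groups
have at most 10 values; larger groups use the normal approximation with
tie-corrected variance and no continuity correction. Grouping letters use
the insert-and-absorb construction, and no multiple-testing correction is
applied by default (a `p_adjust` option exists). All-zero count rows,
constant model terms, confounded designs, orphan samples and missing
environment values raise errors naming the offending identifiers; missing
environmental values can be mean-imputed only by explicit request. Control
mesocosms can be kept at 0 g or excluded (`control_handling`), since how
no-addition controls enter a loading gradient is a genuine analysis choice.

## Problem sizes

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes: 100 replicate experiments for threshold
recovery, 500 label-permutation nulls for PERMANOVA calibration, 1000
linear nulls for the breakpoint selection rate, 500 replicates for envfit
p-value uniformity, and permutation counts of 19–999 depending on the
resolution each check needs. These sizes are the package's own choices of
statistical resolution; all scale up by changing one argument.

## Known limitations

Sequential (order-dependent) variance partitioning is the only mode;
marginal (Type-III-like) tests are not implemented. The threshold scan
considers a single binary split — nested or multiple thresholds are out of
scope, as are beta-dispersion tests, UniFrac-type phylogenetic metrics,
multi-breakpoint models and Davies-type tests for breakpoints unidentified
under the null. The piecewise F reference is approximate (documented
above). BIOM support covers the classic JSON variant only.
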