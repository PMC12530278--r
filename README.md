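# mesothresh

Threshold analysis for freshwater communities along a continuous
disturbance gradient.

When terrestrial material washes into ponds and lakes — for example after a
wildfire — the mass of material ("loading", in grams) acts as a continuous
disturbance gradient: dissolved organic carbon and water colour rise,
dissolved oxygen falls, and microbial communities can flip into a different
compositional state once loading crosses a critical amount. `mesothresh`
implements the statistical pipeline used to locate and characterize such
compositional thresholds in mesocosm experiments, together with a fully
parameterized simulator of the experimental design so every stage can be
validated against known ground truth.

The package is aimed at community ecologists and microbiome analysts working
with sample-by-taxon count tables (e.g. 16S amplicon data), per-sample
environmental chemistry, and predicted genome traits.

## What it computes

* **Variance partitioning (PERMANOVA).** For a Bray–Curtis dissimilarity
  matrix *D*, total sum of squares `SS_T = Σ_{i<j} d²_ij / n` and a
  sequential (Type-I) decomposition of the Gower-centered matrix
  `G = -½ J D² J` over an ordered term list; pseudo-F per term is
  `(SS_term/df_term) / (SS_res/df_res)` with p-values from free permutation
  of sample labels, `p = (b + 1)/(m + 1)`.
* **Threshold scan.** One-term PERMANOVAs of the binary indicator
  `loading ≤ t` over every admissible observed loading value *t*; the *t*
  maximizing R² is the compositional threshold. An optional max-statistic
  permutation correction accounts for selection over candidates.
* **Ordination.** Classical PCoA (eigendecomposition of *G*) and NMDS
  minimizing Kruskal stress-1 via isotonic regression and a monotone
  (step-halved Guttman) update, plus `envfit`-style vector fitting of
  environmental or genome-trait variables onto ordination scores with
  permutation p-values.
* **Breakpoint models.** Environment summarized as PC1 of the nine
  standardized variables (%DO, DOC, FI, BIX, HIX, Sr, SUVA254, pH,
  temperature); linear vs single-breakpoint piecewise fits
  (`y ~ 1 + x + (x − c)₊`, grid search refined by golden section) compared
  with `F = ((RSS_lin − RSS_pw)/2) / (RSS_pw/(n − 4))` on F(2, n−4), the
  piecewise model selected when p < 0.01.
* **Community-weighted genome traits.** Abundance-weighted mean genome
  size, coding sequences, growth rate (`ln 2 / doubling time`), and
  relative genomic plasticity — per taxon, the mean difference between its
  marker-gene dissimilarity and its proteome dissimilarity to all other
  taxa.
* **Differential pathways.** Median-of-ratios depth normalization,
  log2 abundance regressed on centered-and-scaled loading (log2 fold change
  per 1 SD of loading), permutation p-values, and the three-clause filter
  p < 0.01, |log2FC| > 2, ≥ 5 member taxa, with early/late-day
  categorization.
* **Simulator.** A Dirichlet-multinomial generator of complete experiments:
  30 mesocosms (15 burned / 15 unburned), 0–400 g loadings, a logistic
  two-state compositional mixture with its switch at a true threshold
  (default 100 g), hinge-shaped environment–loading relationships that
  relax toward linearity at later sampling days, host/plant-associated
  microbiomes as convex mixtures with the water community, genome traits
  biased by compositional state, and pathway incidences associated with
  state. Ground truth is recorded for recovery testing.

## Worked example

```r
library(mesothresh)

report <- run_pipeline(seed = 11, run = run_config(n_permutations = 199))
report
#> mesothresh pipeline report
#>   PERMANOVA R2: treatment 0.012, loading 0.134, day 0.348
#>   threshold: 100 g (R2 0.314, p 0.005)
#>   environment breakpoint day 10: 102.6 g (piecewise, p 1.145e-09)

tidy(report$permanova)
#> # A tibble: 5 × 6
#>   term         df    SS     R2     F      p
#>   <chr>     <int> <dbl>  <dbl> <dbl>  <dbl>
#> 1 treatment     1 0.102 0.0125  2.09  0.06
#> 2 loading_g     1 1.10  0.134  22.5   0.005
#> 3 day           2 2.86  0.348  29.2   0.005
#> 4 Residual     85 4.16  0.506  NA    NA
#> 5 Total        89 8.22  1      NA    NA
```

Burning treatment explains ~1% of community variation while loading and
sampling day dominate — the simulated design deliberately makes burning a
weak effect. The threshold scan run at the first sampling day finds the
largest binary-split R² (31.4%) exactly at the simulator's true 100 g state
switch:

```r
day10 <- report$days[["10"]]
glance(day10$threshold_scan)
#> # A tibble: 1 × 5
#>   best_threshold best_r2 best_p tie   best_p_corrected
#>            <dbl>   <dbl>  <dbl> <lgl>            <dbl>
#> 1            100   0.314  0.005 FALSE               NA
autoplot(day10$threshold_scan)      # R² profile over candidate thresholds
```

Environmental vectors fitted to the day-10 NMDS show dissolved oxygen
pointing toward low-loading communities and DOC toward high-loading ones
(r² = 0.80 and 0.68, both p = 0.005), and the loading–environment
relationship at day 10 prefers a piecewise model with its breakpoint near
the true 100 g hinge:

```r
tidy(day10$breakpoint_loading_env$comparison)
#> # A tibble: 1 × 6
#>       f   df1   df2             p selected  alpha
#>   <dbl> <int> <int>         <dbl> <chr>     <dbl>
#> 1  50.3     2    26 0.00000000115 piecewise  0.01
```

At later simulated days the hinge relaxes and the linear model wins — the
same model-selection contrast the pipeline is designed to expose on real
data.

A thin command-line wrapper covers the same stages
(`inst/cli/mesothresh.R`): `simulate`, `rarefy`, `diversity`, `ordinate`,
`envfit`, `permanova`, `threshold-scan`, `breakpoint`, `traits`,
`pathways`, `report`.

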