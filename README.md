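# puddleclass

Top-down analysis of bacterial community surveys: distance decay of
community similarity across spatial scales, unsupervised detection of
recurrent community classes, and class-specific functional signatures fitted
with multi-group path models.

The package is aimed at microbial ecologists working with OTU count tables
from replicated natural environments (the motivating system is rainwater
pools that form at the base of beech trees, sampled from metres to >100 km
apart together with laboratory assays of community function). All
user-facing functions take data frames (tibbles) first and return tibbles,
so analyses compose with the pipe; fitted objects come with broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()` methods.

## What it computes

**β-diversity.** Two sample-by-sample dissimilarities over relative
abundances *p*, *q*:

- Jensen-Shannon divergence, `JSD(p,q) = H(m) − (H(p)+H(q))/2` with
  `m = (p+q)/2`; base-2 entropy by default and `√JSD` (a metric) as the
  reported distance.
- A SparCC-derived distance: the log-ratio variance estimator applied with
  *samples as the compositional components*. With pseudocounted fractions
  `f`, `t_ij = var_a log(f_ai/f_aj)` over taxa, the basis variances solve
  `t_i· = (n−2)ω_i² + Σ_j ω_j²`, correlations are
  `ρ_ij = (ω_i² + ω_j² − t_ij)/(2ω_iω_j)` clipped to [−1, 1], and the
  distance is `(1−ρ)/2` (or its square root).

**Distance decay.** Samples are clustered in space by complete-linkage
agglomeration cut at thresholds `√A` (default ladder `10^0.5 … 10^5` m), and
at every scale the β-diversity matrix is tested against the spatial
classification with from-formula implementations of ANOSIM
(`R = (mean rank between − mean rank within)/(M/2)`), MRPP (weighted mean
within-group dissimilarity δ and chance-corrected `A = 1 − δ/E[δ]`) and
PERMANOVA (pseudo-F from the Gower sums-of-squares identity), each with
seeded label-permutation p-values using the +1 rule. A scenario simulator
produces artificial distance matrices with controlled within/between-location
means and variances to interpret the observed shapes: a rising between-
location mean with low variance leaves ANOSIM R ≈ 1 while MRPP δ climbs,
whereas inflating the between-location variance produces the characteristic
decay of ANOSIM R with scale.

**Community classes.** Partitioning around medoids (via `cluster::pam`) for
`k = 2…20`, scored by a Calinski-Harabasz index generalised to arbitrary
dissimilarities (`CH = (SS_B/(k−1))/(SS_W/(n−k))` with the PERMANOVA SS
identities); `k_opt = argmax_k CH`. Agreement between classifications is
quantified with the adjusted Rand index and normalised mutual information,
and an ANOSIM report compares day/month/site/class groupings.

**Functional path models.** Recursive path models over seven community
functions — exoenzyme activities X (xylosidase), G (β-glucosidase), N
(β-chitinase), P (phosphatase), plus ATP, cell Yield and cumulative CO2 —
fitted by per-equation least squares (the ML solution for recursive systems
with uncorrelated errors), with χ², RMSEA (90% CI by noncentrality
inversion) and AIC. Multi-group fits share edge coefficients within blocks
of classes; a greedy AIC search frees or merges one edge-class block at a
time to find the constraint pattern the data support. Backdoor adjustment
sets are derived from the DAG by d-separation, and per-pathway regressions
with class interactions (treatment-coded against the largest, reference
class) test which classes deviate.

**Synthetic data.** Seeded generators for (a) scenario distance matrices,
(b) class-structured Dirichlet-multinomial communities whose class identity
is driven by a tree-hole succession process (regional rain pulses reset a
latent stage that advances at a tree-specific rate, so sampling *date* is
more informative than *site*), and (c) functional measurements drawn from a
known path model. These make every pipeline property testable end to end.

## Worked example

```r
library(puddleclass)

sim    <- simulate_succession_communities(succession_spec(seed = 1))
counts <- filter_samples_taxa(sim$counts,
                              min_reads_per_sample = 10000,
                              min_reads_per_taxon  = 100)
d  <- jsd_matrix(counts)
cm <- find_classes(d, k_range = 2:12)
glance(cm)
#> # A tibble: 1 × 4
#>   k_opt ch_max pam_objective weak_structure
#>   <int>  <dbl>         <dbl> <lgl>
#> 1     6   215.          114. FALSE

compare_classifications(tidy(cm), sim$classes)
#> # A tibble: 1 × 2
#>     ari   nmi
#>   <dbl> <dbl>
#> 1     1     1

grouping_anosim_report(d, sim$metadata, classes = tidy(cm),
                       n_perm = 999, seed = 2)
#> # A tibble: 4 × 5
#>   grouping n_groups testable anosim_R anosim_p
#>   <chr>       <int> <lgl>       <dbl>    <dbl>
#> 1 day             6 TRUE       0.268     0.001
#> 2 month           3 TRUE       0.0416    0.001
#> 3 site           10 TRUE       0.0111    0.134
#> 4 class           6 TRUE       1         0.001
```

The CH curve peaks at six classes (`k_opt = 6`, no weak-structure flag) and
the recovered labels match the generator's truth exactly (ARI = NMI = 1).
The ANOSIM report shows the ordering the generator is built to produce:
sampling day (R = 0.27) is far more informative about composition than site
(R = 0.01) or month (R = 0.04), and the community classes themselves
separate perfectly (R = 1).

Functional signatures, with one class generated to convert ATP into yield
differently (−0.3 instead of the shared 0.5):

```r
f   <- simulate_functions(path_model_spec(seed = 3,
         coefficients = list("ATP->Yield" =
           c(C1 = .5, C2 = .5, C3 = .5, C4 = .5, C5 = .5, C6 = -.3))),
         sim$classes)
sel <- select_constraint_model(f, tidy(cm), default_path_dag())
glance(sel)
#> # A tibble: 1 × 10
#>   scenario loglik n_params   aic chi_square    df rmsea rmsea_lo rmsea_hi     n
#>   <chr>     <dbl>    <dbl> <dbl>      <dbl> <dbl> <dbl>    <dbl>    <dbl> <int>
#> 1 partial  -2320.       95 4830.       77.5    91     0        0   0.0188   300

interaction_regression(f, tidy(cm), default_path_dag(), "ATP", "Yield")
#> # A tibble: 5 × 5
#>   class estimate std_error       p_value signif
#>   <chr>    <dbl>     <dbl>         <dbl> <chr>
#> 1 1     -0.00772     0.132 0.953         ""
#> 2 3     -0.942       0.150 0.00000000136 "**"
#> 3 4     -0.156       0.139 0.262         ""
#> 4 5      0.0191      0.150 0.899         ""
#> 5 6     -0.0481      0.151 0.751         ""
```

AIC selects a *partial* constraint pattern (between "all shared" and "all
free"), and the confounder-adjusted interaction regression flags exactly one
class — the recovered cluster corresponding to the planted deviator — as
converting ATP into yield differently from the reference class (`**`:
p < 0.001), with the other interaction terms indistinguishable from zero.

The whole chain can also be run as one call: `run_pipeline(pipeline_config(
out_dir, seed))` executes simulate → filter → β-diversity → scale scan →
classes → path models and writes every artifact (TSVs, `pathmodel.json`)
plus a checksummed `manifest.json`; identical config and seed give
byte-identical outputs.

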