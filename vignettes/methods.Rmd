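---
title: "Methods: distance decay, community classes and functional path models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance decay, community classes and functional path models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

puddleclass implements a top-down workflow for community surveys of
replicated natural habitats: quantify β-diversity, ask how community
similarity decays with geographic distance and at which scales grouping is
informative, reduce the survey to a small number of recurrent community
classes, and test whether those classes carry distinct functional
signatures. This vignette records the models, the parameter choices, and the
numerical conventions, so that every default is traceable.

## β-diversity metrics

`jsd_matrix()` computes the Jensen-Shannon divergence between the relative
abundance profiles of two samples,
$\mathrm{JSD}(p,q) = H(m) - \tfrac{1}{2}(H(p)+H(q))$, $m = (p+q)/2$, with
$0 \log 0 \equiv 0$. Two conventions are switchable in
`beta_div_options()` because the literature uses both: the entropy base
(2, giving values in $[0,1]$, or $e$) and whether the square root is taken.
The defaults are base 2 with the square root, which is a proper metric; the
triangle inequality is verified on random triples in the test suite.

`sparcc_distance_matrix()` adapts the SparCC log-ratio variance estimator to
produce a *sample-by-sample* dissimilarity. SparCC is written for taxa; here
each sample's pseudocounted taxon fractions play the role of component
fractions, which is the orientation a β-diversity needs. For samples $i,j$,
$t_{ij} = \mathrm{var}_a \log(f_{ai}/f_{aj})$ over taxa $a$; the basis
variances $\omega_i^2$ solve the linear system
$t_{i\cdot} = (n-2)\,\omega_i^2 + \sum_j \omega_j^2$ (a sparse-correlation
approximation), correlations are
$\rho_{ij} = (\omega_i^2+\omega_j^2-t_{ij})/(2\omega_i\omega_j)$ clipped to
$[-1,1]$, and the distance is $(1-\rho)/2$ by default (its square root is
available). The pseudocount (default 0.5) and an optional iterative
exclusion of the most-correlated pair are exposed because the exact
transformation used in prior studies varies; the defaults here are declared
package conventions, not reconstructions of any particular study. Basis
variances that come out non-positive raise an error suggesting more samples
or a larger pseudocount, rather than being clipped silently.

`mantel_test()` correlates the strictly-lower-triangle entries of two
distance matrices and permutes rows/columns of the second matrix jointly.
The p-value is two-sided on $|r|$ with the add-one rule,
$p = (1 + \#\{|r^*| \ge |r|\})/(1 + n_\mathrm{perm})$, so $p$ is never 0.

## Group statistics and the permutation engine

ANOSIM, MRPP and PERMANOVA are implemented from their defining formulas
(vegan is used in the tests as an independent cross-check, never as the
implementation):

- ANOSIM ranks all $n(n-1)/2$ dissimilarities with average ranks for ties
  and reports $R = (\bar r_B - \bar r_W)/(M/2)$, one-sided (large $R$).
- MRPP reports $\delta = \sum_g w_g \bar d_g$ over groups with $\ge 2$
  members, $w_g = n_g/\sum n_g$ by default ($w_g \propto n_g - 1$ is
  exposed), and $A = 1 - \delta/E[\delta]$ with $E[\delta]$ estimated as the
  mean of the permutation null; one-sided (small $\delta$).
- PERMANOVA uses the Gower identity
  $SS_\mathrm{tot} = \tfrac1n\sum_{i<j} d_{ij}^2$,
  $SS_W = \sum_g \tfrac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$,
  pseudo-$F = \frac{SS_B/(k-1)}{SS_W/(n-k)}$; on Euclidean distances of 1-D
  points this reduces exactly to the classical one-way ANOVA $F$, which the
  tests assert to $10^{-10}$.

All three share one permutation convention: group labels are permuted over
samples, the observed statistic is compared against the null in the
conventional one-sided direction, and $p = (1+\mathrm{hits})/(1+n_\mathrm{perm})$.
Default $n_\mathrm{perm} = 999$; every seeded call is bit-reproducible.
Groupings qualify when at least two groups have two or more members;
singleton groups are allowed and contribute only between-group pairs.

## Spatial scaling

`spatial_distance_matrix()` supports planar metres and spherical haversine
distances (Earth radius 6,371,000 m). `cluster_at_threshold()` performs
agglomerative clustering cut at height $h$; complete linkage is the default
because it bounds cluster diameters by $h$, which makes a cutoff of
$\sqrt{A}$ a reasonable proxy for grouping samples within areas of size $A$.
Single and average linkage are provided since nothing in the method depends
on the choice. The default threshold ladder is ten half-decade cutoffs
$10^{0.5}, 10^{1}, \dots, 10^{5}$ m (about 3 m to 100 km); any
strictly-increasing ladder can be supplied, e.g. to scan areas from
10 m² to 100 km² instead. `scale_scan()` marks a threshold untestable when
fewer than two clusters have two or more members, rather than skipping it
silently.

The scenario generator `simulate_distance_scenario()` builds artificial
dissimilarity matrices with controlled moments: locations are placed on a
line at geometrically spaced positions spanning the ladder, samples jitter
within ±0.5 m, within-location entries are drawn from
$N(\mu_W, \sigma_W)$ and between-location entries from
$N(\mu_B(d), \sigma_B)$, all truncated to $[0,1]$ by inverse-CDF sampling
(exact, no rejection or boundary clumping). Truncated normals were chosen
because dissimilarities are bounded and the scenarios manipulate means and
variances directly; no triangle-inequality repair is attempted since the
rank- and SS-based statistics do not require metricity. A warning is issued
when, for most pairs, most of the normal mass lies outside $[0,1]$ (the
requested moments are then not attainable). The two canonical presets are
`scenario_mean_increase()` (μ_B rising 0.4→0.8 in log distance, all σ =
0.03) and `scenario_variance_inflated()` (same means, σ_B = 0.25): the
first keeps ANOSIM R above 0.9 at every scale while MRPP δ climbs, the
second produces the monotone decay of ANOSIM R that inflated between-
location variance implies — the diagnostic contrast between dispersal-
limited means and overlapping similarity distributions.

## Community classes

`find_classes()` runs PAM (`cluster::pam`, BUILD + SWAP) for each $k$ in
`k_range` (default 2–20, wide enough that the optimum is interior in all our
simulations) and scores each partition with a Calinski-Harabasz index
generalised to arbitrary dissimilarities through the same Gower identity as
PERMANOVA. $k_\mathrm{opt}$ is the CH argmax, taking the smallest $k$ on
ties; ties and assignments inherit `cluster::pam`'s deterministic behaviour,
so the pipeline has no hidden randomness. When the within-cluster SS is 0
(duplicated points), CH returns `Inf` as an explicit sentinel. A
`weak_structure` flag is raised when the CH maximum is below 1.5× the median
of the CH curve: in single-class simulations the curve is flat (ratio near
1), while planted multi-class data give maxima several-fold above the
median, so 1.5 separates the regimes with margin; it is a reporting aid,
not a test.

`compare_classifications()` returns the adjusted Rand index (permutation-
model expectation correction) and normalised mutual information with
arithmetic-mean normalisation; when both partitions are single-cluster the
agreement is defined as 1. `grouping_anosim_report()` assembles the ANOSIM
R for groupings by calendar day, calendar month (year + month), site label
and, optionally, detected classes, marking degenerate groupings untestable.

## Succession generator

`simulate_succession_communities()` emulates the study design the package
targets: `n_sites` sites scattered over a ~100 km extent, `trees_per_site`
tree-holes jittered within ±25 m of their site centre, every tree sampled on
a shared set of dates. Regional rain events reset a latent successional
stage; between rains the stage advances as (tree-specific rate) × (days
since last rain), with rates uniform on 0.6–1.6 stage units/day.
Thresholding the stage at breaks {8, 12, 17, 23, 30} yields six ordered
classes. The default calendar (six sampling dates across autumn 2013, three
rain dates) makes days-since-rain take values {7, 11, 21, 25}, which spreads
the 300 samples (10 × 5 × 6) across all six classes at roughly comparable
sizes while keeping class identity strongly date-driven — by construction
the sampling date carries more information about class than the site does,
and a `class_driver = "site"` converse control reverses this. Compositions
are Dirichlet-multinomial: each class boosts its own block of
`n_taxa/n_classes` taxa to concentration 4 over a background of 0.1
(expected profiles then differ at pairwise JSD > 0.5, i.e. well-separated),
and sequencing depth is lognormal with median 30,000 reads, so the default
10,000-read sample filter passes essentially all samples. Sizes (6 classes,
600 taxa, 300 samples) are the package's reference conditions; they mirror
the scale of the motivating survey while running comfortably on a desktop.

What the generator does *not* emulate is worth stating: no sequencing-error
or chimera model, no compositional bias between classes beyond the block
profiles, no spatial autocorrelation in community composition beyond what
the class process induces, and no taxon-taxon interaction structure.
Passing the recovery tests therefore shows the pipeline recovers planted
class structure of realistic size and noise — not that real surveys contain
such structure.

## Functional path models

The default DAG over the seven functions treats the four exoenzyme
activities X, G, N, P as exogenous and freely covarying, with
N, G, P → ATP; X, ATP → Yield; G, P, Yield → CO2. DAGs are user-editable as
plain `"A -> B"` / `"A ~~ B"` lines.

`fit_path_model()` estimates each equation by least squares — for recursive
systems with uncorrelated errors this is the maximum-likelihood fit — and
assembles the implied covariance $\Sigma = (I-B)^{-1}\Psi(I-B)^{-\top}$ with
the exogenous block of $\Psi$ saturated at the ML sample covariance. Fit
indices follow the standard ML discrepancy: $\chi^2 = (n-1)F_{ML}$ against
the saturated model, $df = p(p+1)/2 - \#\mathrm{params}$,
$\mathrm{RMSEA} = \sqrt{\max(0, (\chi^2-df)/(df\,(n-1)))}$, with the 90% CI
obtained by inverting the noncentral χ² CDF (bisection via `uniroot`, the
bound set to 0 when the CDF condition is already met at zero
noncentrality). Saturated models return $\chi^2 = 0$, $df = 0$,
RMSEA = 0 exactly. Variables are standardized by default (a flag restores
raw scales); AIC $= -2\ell + 2\,\#\mathrm{params}$ throughout.

`fit_multigroup()` fits each equation as one pooled regression with
class-specific intercepts, sharing each edge coefficient within the blocks
of a constraint pattern via block-indicator design expansion. Residual
variances are pooled per equation and exogenous covariances are saturated
per class, so the likelihood separates into per-equation and exogenous
parts; this keeps every candidate pattern's AIC comparable and cheap to
update. The three scenarios are one block per edge (fully constrained), one
block per class (fully free), and anything between (partial).

`select_constraint_model()` starts fully constrained and greedily applies
the single split (freeing one class out of a block on one edge) or merge
(joining two blocks on one edge) that most lowers AIC, stopping when no move
helps; the two extreme scenarios are always evaluated as well and ties
within $10^{-9}$ go to the fewer-parameter model. A property of AIC worth
knowing when reading results: a spurious one-parameter split is accepted
whenever it improves the deviance by more than 2, which happens with
probability ≈ 0.16 per candidate under the null, so the search typically
frees a few small extra blocks beyond any real deviation. The planted
deviation itself — a class whose coefficient on an edge truly differs — is
isolated in its own block essentially always at n = 600/class, which is the
recovery property the acceptance tests measure; exact recovery of the
all-constrained null pattern is not a property AIC selection has.

`adjustment_set()` derives, for an exposure-outcome pathway, the canonical
backdoor set: the exposure's directed parents plus exogenous nodes sharing a
free covariance with it, then minimised by removing (in alphabetical order,
for determinism) any node whose exclusion still blocks all backdoor paths.
Blocking is checked by d-separation on the latent-augmented graph (each
`~~` becomes a latent common cause) using the ancestral moral graph
construction. The result is removal-minimal; it need not be the globally
smallest valid set, which matches how adjustment sets are conventionally
reported from parent sets. `interaction_regression()` then fits
`outcome ~ exposure × class + adjustment set` with treatment coding against
the largest (reference) class and reports each class's interaction
coefficient — its slope deviation from the reference — with significance
codes `*` p < 0.01, `**` p < 0.001. Classes with fewer rows than predictors
are dropped with a warning.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → filter → β-diversity → scale scan →
classes → path models, writing TSV/JSON artifacts and a manifest with md5
checksums. A single global seed is expanded as `seed + 100 × stage index`,
so disabling one stage leaves the others' randomness untouched; rerunning an
identical config reproduces byte-identical artifacts (timing information
goes to the log, never into the outputs). Filtering applies the sample rule
strictly (totals > threshold) before the taxon rule (totals ≥ threshold,
computed over retained samples), the order that makes taxon totals refer to
the samples actually analysed; the operation is idempotent.

## Problem sizes and numerical conventions

The test suite runs the full property set at deliberately chosen reference
sizes: 1,000 brute-force fuzz instances at n ≤ 8; permutation calibration
with 500 replicates of n = 20 at 199 permutations; 100 seeded runs per
distance-decay scenario (10 locations × 10 samples); 100 succession runs at
300 samples × 600 taxa for class recovery; single-fit coefficient recovery
at n = 10⁴ and constraint-selection recovery over 100 runs at 600
samples/class. These sizes give the Monte-Carlo bands used in the tests
(e.g. type-I error within [0.03, 0.07] at α = 0.05 over 500 replicates)
while keeping a full run in the minutes range. Symmetry of input distance
matrices is enforced to 10⁻⁸ and then exactly symmetrised; JSD guards tiny
negative rounding with a floor at 0; CH returns `Inf` on zero within-SS;
permutation p-values are never 0 by the add-one rule.

## Limitations

- The SparCC-derived distance inherits the sparse-correlation approximation;
  with few samples or extreme compositions the basis system can produce
  non-positive variances, which is reported as an error rather than patched.
- PERMANOVA is single-factor; no nested or multi-factor designs.
- Path models are recursive (no latent variables, no feedback), estimated
  per equation; CFI/TLI are not reported — χ², RMSEA and AIC carry the
  selection logic.
- The succession generator is a stylised stand-in for field data: its
  classes are exactly Dirichlet-multinomial and its succession clock is
  deterministic given the rain calendar, so recovery rates on it are upper
  bounds on what noisier real surveys would give.
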