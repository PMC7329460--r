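---
title: "Models and methods: GBLUP with neighbor and spatial effects in a semi-field row trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The setting

The package analyses trials in which genotyped winter-wheat lines are sown
as single rows in long experimental beds of a semi-field phenotyping
facility. Beds are built in pairs; rows sit side by side along each pair,
so every row has a west and an east neighbor. A sub-irrigation gradient
splits each row into a *wet* and a *dry* harvest area that are combined
separately, giving up to `beds x rows x 2` grain records. One bed per pair
carries minirhizotron tubes under the rows, from which depth-resolved root
images give per-tube root-length traits.

Four grain traits are handled: grain yield (GY, t/ha), thousand-kernel
weight (TKW, g), protein concentration (PC, %) and total nitrogen content,
computed as `NC = GY * PC / 6.25` evaluated unit-consistently,
`NC [kg N/ha] = 1.6 * GY [t/ha] * PC [%]` (6.25 is the standard
protein-to-nitrogen factor). Root traits are total root length between 1.2
and 2.0 m soil depth per tube (TRL, cm) and root length per 0.2 m depth
interval (IRL, four records per tube).

## Mixed models

All models are Gaussian linear mixed models fitted by REML. The grain
models are

* **GM1**: `y = X b + Z_l g + Z_l l + Z_r r + Z_s1 s1 + Z_s2 s2 + e`
* **GM2**: GM1 plus `(Z_ne + Z_nw) g_n + (Z_ne + Z_nw) l_n`

with `b` the bed-by-area cell means (8 for a four-bed trial); `g` the
direct genomic effects, `g ~ N(0, G sigma2_g)` with `G` the VanRaden
method-1 relationship matrix `ZZ' / (2 sum p(1-p))` from centred allele
dosages; `l ~ N(0, I sigma2_l)` the line effects capturing genetic
variation not explained by markers plus non-additive effects; `r` the row
effects tying together the wet and dry record of a row; `s1`, `s2` the
spatial fields of the wet and dry areas with their own variances (the
spatial pattern differs along the water gradient); and `g_n`, `l_n` the
indirect (neighbor) genomic and line effects. East and west neighbor
incidences are summed into one effect vector with a single variance: in
the preliminary analyses that motivated these models the two sides were
correlated near 1. Genotype-by-water-availability interaction terms are
deliberately absent from all presets (the motivating analyses found the
interaction variance near zero); the generator can simulate such a term
(`gxa`) for power studies only.

The root models are **RM1** for TRL (fixed bed and camera; random `g`,
`l`, one spatial field `s`) and **RM2** for IRL (RM1 plus fixed depth
interval and random tube effects `r` for the repeated records per tube).

### The running-sum spatial field

Each record's spatial effect is the sum of iid location effects over the
11 field positions centred on its row (offsets -5..+5). Five *virtual*
positions are appended at each field end so border rows keep a full
11-wide window; a four-bed facility with 150 rows per bed therefore has
`2 x 150 + 10 = 310` locations per harvest area, with the two bed pairs
mapped onto the *same* location levels by within-pair position. This
contiguous-pair/shared-levels reading is the only one consistent with a
310-length spatial vector for four beds; it is a design decision, and the
layout builder can instead break windows at declared positions
(`segment_breaks`) or be given explicit positions per pair. The running
sum induces covariance `(11 - d) sigma2_s` between same-area records at
position distance `d <= 10`, and zero beyond — a triangular correlation
that substitutes for an explicit AR structure while staying a plain
variance component.

### Fixed-effect coding

Cell means for the first factor, drop-first-level contrasts for the rest:
full-rank `X` without generalized inverses, with the textbook effect
dimensions (8 bed-by-area cells for grain; bed + camera (+ depth interval)
for root models). Rank deficiency raises an error naming the factor.

## REML estimation

Variance components are estimated by average-information (AI) REML on the
mixed-model equations, with an EM-REML fallback whenever a quasi-Newton
step would leave the parameter space or reduce the restricted likelihood;
accepted iterations never decrease it. Implementation notes:

* Every correlated term is eigen-reparameterised, `u = L a` with
  `K = L L'`, so the engine only sees identity-structured effects. The
  VanRaden `G` built with observed allele frequencies is always singular
  (centred dosages sum to zero); the reparameterisation handles this
  without ridge inflation, dropping eigenvalues below `1e-10 x` the
  largest. BLUPs map back as `u = L a`, which also yields genomic
  predictions for lines with no records. An optional ridge on `G` remains
  available but defaults to zero.
* Components at the lower boundary (`1e-8 x var(y)`) are handled by an
  active set: a pinned component with an outward-pointing score is dropped
  from the Newton system and released as soon as its score points inward.
  Without this, fits with a collapsing component crawl.
* Convergence requires both a likelihood change below `1e-8` and relative
  parameter stability below `1e-6`.
* Initial values are an equal split of `var(y)` over all components
  (nothing better is stated anywhere); cross-validation folds warm-start
  from the full-data estimates.
* All linear algebra is dense: the largest system (GM2 at full facility
  size) is about 1,600 equations, well within one CPU's comfort.

Standard errors come from the inverse AI matrix; delta-method standard
errors of smooth functions of the components use central differences
(relative step `1e-6`). A fit flags *confounded* pairs of random terms
(identical incidence and identical covariance, e.g. `g` and `l` under
`G = I`): only their sum is then identified.

## Variance partitioning

The line-mean phenotypic variance weights each component by how often a
line mean averages over it:

`sigma2_P = Gbar sigma2_g + sigma2_l [+ 2 Gbar sigma2_gn + 2 sigma2_ln]
+ sigma2_r / n_r + 11 sigma2_si / n_si + sigma2_e / n_e`

with `Gbar` the average diagonal of `G`, `n_r` the average number of rows
per line, `n_si` the average per-area spatial replicates and `n_e` the
average records per line pooled over areas (`n_e` is defined across all
fields, hence pooled; RM1 omits the row term). Relative variance
components (RVCs) divide the weighted components by `sigma2_P`, so they
sum to one per area. The RVC of `g` is the line-mean narrow-sense
heritability `h2`; `g` plus `l` gives the broad-sense `H2`. Grain traits
are partitioned per harvest area (the spatial variance is heterogeneous)
and reported with the unweighted wet/dry average. The coefficient of
genetic variation is `cv = 100 sqrt(sigma2_g) / mean(y)`, the plain
ratio without a `Gbar` weight; a `Gbar`-weighted variant is exposed as an
option.

## Cross-validation, accuracy, inflation

Corrected phenotypes subtract the full-data fixed-effect estimates,
`y_c = y - X b_hat`, and are averaged per line pooling wet and dry. In
leave-one-line-out CV every line's records are dropped in turn and the
line's GEBV is predicted through `G`; neighbor and spatial incidences of
the retained records are untouched (the held-out line still appears as a
neighbor). Variance components are re-estimated per fold by default; a
plug-in mode reuses the full-data components and makes each fold a single
solve. Accuracy is `ACC = sign(cor) sqrt(cor(ybar_c, ghat)^2 / h2)` with
the full-data wet/dry-averaged `h2` (the single `h2` for root traits) —
an estimate of the correlation between GEBVs and true breeding values for
lines without records; values above 1 are warned about, never clipped.
Inflation is the OLS slope of `ybar_c` on `ghat` (1 = no inflation), with
a two-sided t-test against 1 as the minimal reading of "not significantly
different from unity".

## Root-image editing

The editing pipeline applies, in this fixed order: (1) drop failed
observations; (2) bin depths into eight 0.2 m intervals spanning
0.4-2.0 m (the published bin table lives in a supplement; the analysis
window 1.2-2.0 m with four intervals forces 0.2 m bins, and the edges are
overridable) and keep the 1.2-2.0 m window; (3) within each analysis
interval drop records outside mean ± 3 sd, statistics computed from the
step-1-2 survivors, boundary ties kept; (4) keep genotyped lines only.
Per-step retention counts are attached to the result. One defect of the
rule as specified: it is *not* idempotent, because re-running step 3 on
filtered output recomputes a tighter sd and can remove further records;
the first pass's thresholds are therefore attached (`outlier_stats`) and
can be supplied to make re-application exactly idempotent. TRL per tube is
the sum of retained image lengths; IRL sums within analysis intervals, so
a tube's four IRL values add to its TRL by construction.

## The synthetic world

The generator states the facility's conditions: 84 lines, 4 beds x 150
rows (one replicate per bed, remaining rows filled at random — imperfect
randomization, so a line can neighbor itself), wet/dry split per row,
two-sided neighbors, the 11-position running-sum field with virtual border
locations receiving simulated effects like real ones, and for root data
minirhizotron tubes in one bed per pair with cameras cycling over four
adjacent tubes and four depth intervals. Default grain variances
(`g = 0.40, l = 0.35, g_n = 0.02, l_n = 0.04, r = 0.25, s_wet = 0.03,
s_dry = 0.06, e = 1.0`) put the line-mean `h2` near 0.4, the level
reported for yield; root defaults put `h2` below 0.1 with spatial and
residual noise dominating, as observed for root length. Neighbor truth
uses one shared east/west effect vector, matching the combined model term.

Marker panels default to a founder-crossing scheme (each line a cross of
two founders from a pool of 16): this gives the family relatedness of a
breeding panel, without which `G` is near-diagonal and leave-one-line-out
prediction cannot transfer information between lines. Independent
Binomial(2, p) dosages remain available (`n_founders = NULL`) and are the
mode whose marginal frequency properties are asserted in tests. No linkage
disequilibrium, selection or multi-year structure is simulated — a green
test establishes correctness of the estimation machinery under the stated
generative law, not realism of wheat genomes. Grain records are complete
(the real trial lost ~13% of rows to establishment failures; missingness
is orthogonal to the estimators under test). Wet and dry fixed cells
differ by construction so phenotype correction is exercised non-trivially.

## Numerical choices and limitations

* Boundary floor `1e-8 x var(y)`; G-eigenvalue cut `1e-10 x` max; MME
  jitter only on Cholesky failure (`1e-10 x` max diagonal).
* Sample (n-1) standard deviations everywhere.
* Depth-bin edges are rounded to 10 decimals so floating-point drift in
  `seq()` cannot shift a bin across the 1.2 m window boundary.
* Heterogeneous residual variances are not modelled (wet/dry
  heterogeneity enters through the spatial terms only); no multi-trait
  REML, no pedigree models, no AR1xAR1 spatial alternatives.
* Wald variance-component intervals rely on asymptotics that are rough at
  84 lines; near-boundary components get wide, truncated intervals.
* The orchestration layer uses R constructor arguments rather than a YAML
  config (no YAML parser among the package's allowed dependencies); a
  thin CLI lives in `inst/cli/semifieldgp-cli.R`.
* Acceptance testing is property-based (closed forms, independent oracle
  optimizers, brute-force filters, Monte-Carlo laws); no real trial data
  ships with the package, so validation against measured records is left
  to the user. The ACC-unbiasedness
  check runs at reduced dimensions (24 lines, 2 beds) with plug-in folds
  to stay inside the test-time budget; the parameter-recovery check runs
  at the full stated dimensions.
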