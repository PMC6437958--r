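---
title: "Multiscale zonation ensembles and simulation intervals for the MAUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale zonation ensembles and simulation intervals for the MAUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maupsi)
```

## The problem

Any analysis of spatially aggregated data is exposed to the modifiable
areal unit problem (MAUP): summary statistics and association estimates
depend on the arbitrary choice of the spatial units over which the data
were aggregated, through both the *scale* of the units (how large they
are) and the *zonation* (where their boundaries happen to fall).
Associations estimated at scales coarser than the minimal meaningful
geographical unit are systematically biased relative to the minimal-level
effect, and different zonations at the same scale produce differently
biased estimates.

`maupsi` operationalises a constructive response: instead of trusting any
single aggregation, it *exploits* the MAUP.  It builds a large ensemble
of random contiguity-constrained zonations at many population scales,
fits the association model at every scale-by-zonation combination,
models how the estimates vary with scale, and inverts that relationship
by simulation to recover an interval of minimal-level effects — a
*simulation interval* (SI) — that could plausibly have generated the
observed multiscale pattern.

## The models

The package supports one-covariate association models at whatever level
of aggregation the data sit:

* **Negative-binomial rate model** (`negbin_rate`), the workhorse for
  small-area health counts: outcome counts $y_z$ in zone $z$ with
  population $P_z$ and covariate $x_z$ follow
  $y_z \sim \mathrm{NB}(\mu_z, \theta)$ with
  $\log \mu_z = \alpha + \beta x_z + \log P_z$ and variance
  $\mu_z + \mu_z^2/\theta$ (NB2; larger $\theta$ means less
  overdispersion).  $\beta$ is a log rate-ratio per unit covariate;
  $e^\beta$ is the rate ratio.  Fitting is maximum likelihood with
  $\theta$ profiled (`MASS::glm.nb`).
* **Poisson rate model** (`poisson_rate`): as above without
  overdispersion.
* **Weighted Gaussian model** (`gaussian_weighted`) for continuous
  outcomes such as income: weighted least squares with weights equal to
  zone population.  The residual standard error (RSE) from these fits is
  population-inflated; when simulating at the minimal level the per-unit
  standard deviation is $\mathrm{RSE}/\sqrt{P_i}$.
* **Individual-level Poisson** (`poisson_individual`) for discretised
  individual outcomes (e.g. a comorbidity index), with no offset and
  "populations" of one.

Covariates (and continuous outcomes) are aggregated as
population-weighted means; populations and counts are summed, so all
totals are conserved exactly.

## Automated zone design

Zones are grown from minimal "building-block" units under a contiguity
constraint.  The target population $t$ of a scale carries a minimum
population threshold tied to it by the quadratic
$\mathrm{threshold}(t) = a\,t + b\,t^2$, where $(a, b)$ solve the pair of
anchor equations fixing the threshold at 60% of target at the smallest
scale and 80% at the largest.  For scales 500–10,000 this gives
$a = 0.589$ and $b = 2.11\times10^{-5}$.  The rising fraction keeps fine
scales flexible (so zones of very few units remain feasible) while
forcing coarse zones to be close to their target.  No maximum threshold
is imposed.

The zone-design algorithm is AZP-style and heuristic: a number of
independent runs (`n_runs`, default 50) of seeded random region growing —
a random unassigned unit seeds a zone, which absorbs random unassigned
neighbours until it reaches the threshold, stopping once a further
absorption would overshoot the target; under-threshold remnants are
dissolved and merged into the adjacent zone with the smallest population
— followed by boundary-swap optimisation cycles (`n_swap_cycles`, default
10) that accept a move when it reduces
$\sum_z |\mathrm{pop}_z - t|$ while keeping the donor zone contiguous
and above threshold.  The best run by that objective is returned.  The
objective is a design choice (any target-population criterion yields a
valid ensemble for the downstream statistics) and is recorded in the
zonation metadata.  Everything is driven by an explicit seed: candidate
lists are sorted by unit id before random selection, so a given (map,
configuration, seed) triple reproduces byte-identical zonations on any
platform.  Ensembles derive zonation seeds as `base_seed + index`.

Zero-population units may exist in a map but are absorbed into growing
zones; they can never form zones alone.  Disconnected geographies are
refused unless per-component zonation is requested explicitly.  Polygon
inputs (GeoJSON) are reduced to rook adjacency by default — the
census-geography convention; queen adjacency is available by flag.

## Scaling curves and extrapolated intercepts

For each parameter ($\beta$, $\alpha$, and the nuisance $\theta$ or RSE)
the scale-by-zonation estimates are regressed on the mean polygon
population of their zonation (total population / number of zones, the
natural x-axis because realised zone sizes drift above their targets).
Quadratic polynomials in $\log x$ are the default; with estimates at
only two distinct scales the degree falls back to one (a straight
line).  Both axes are log-transformed so that extrapolation cannot cross
zero: since slope and intercept estimates are typically negative in the
motivating applications, the y-axis transform for sign-definite
parameters is a *signed log-magnitude* — $\log|y|$ is fitted and the
common sign restored on back-transformation.  If an estimate set mixes
signs, the transform falls back to the identity with a warning, and the
choice is recorded on the curve object.  For the weighted-Gaussian
family only the RSE is log-transformed on the y-axis.  Points are
unweighted: every scale-by-zonation estimate counts once.

Evaluating the fitted curve at the minimal-level mean unit population
gives the *extrapolated intercept* (EI) of each parameter.  The EI is an
interim quantity — **not** an estimate of the minimal-level parameter —
and the SI built from it need not even contain it in extreme cases.

## Simulation intervals

Given the observed $EI_\beta$ (with $EI_\alpha$ and $EI_\theta$ held
fixed), the SI at coverage $1-2q$ is the pair $(A, B)$ such that the
upper $1-q$ quantile of the EI density at candidate truth $A$, and the
lower $q$ quantile at $B$, both equal $EI_\beta$.  An EI density at a
candidate value $V$ is formed by simulating `n_inner_sim` minimal-level
datasets with slope $V$, pushing each through the identical
aggregate–fit–curve–extrapolate pipeline (same ensemble, same stopping
point, same degree fallback), and collecting the extrapolated
intercepts.  Quantiles are type-7 (linear interpolation of order
statistics).

Numerical choices in the bound search:

* **Common random numbers.**  Counts are simulated by inverse-cdf
  coupling: one fixed uniform per unit per inner dataset, with a fixed
  Gamma$(\theta,\theta)$ frailty for the NB mixture, evaluated as
  `qpois(U, mu * G)`.  Each simulated count is therefore non-decreasing
  in $V$, making the quantile curves smooth and monotone along the
  search — the monotonicity the construction relies on, imposed by
  coupling rather than hoped for.  Marginally the draws are exactly
  NB/Poisson/Gaussian.
* **Root finding.**  The search walks from $V_0 = EI_\beta$ with secant
  steps capped at a few multiples of the current residual, brackets the
  root, then applies Illinois-type regula falsi with a bisection
  fallback.  Convergence is declared when the quantile matches
  $EI_\beta$ to within $0.1\% \times |EI_\beta|$.  Because counts make
  the quantile curve a fine staircase, an exact quantile match can be
  unattainable at small inner sample sizes; the bracket on $V$ is then
  accepted once its width falls below ten times that tolerance (about
  1% of $|EI_\beta|$, far below the staircase tread and the Monte Carlo
  noise of the bounds).
* **Diagnostics.**  Every density evaluation (candidate $V$, both tail
  quantiles, sample spread) is retained; monotonicity of the sampled
  quantile curves is checked along the trajectory within twice the
  Monte Carlo standard error of a tail quantile, and violations produce
  a warning, not a silent adjustment.  Inner pipeline failures are
  redrawn deterministically up to three times and then dropped; a
  density with more than 20% failures is an error.
* **Nuisance parameters.**  $EI_\alpha$ and $EI_\theta$ are plugged in
  as-is during inner simulation.  When nuisance estimates are not
  consistent the nominal coverage is approximate; this surfaces in the
  coverage experiment rather than being corrected for.

By construction, higher nominal coverage yields nested, wider
intervals under the same seed, and `coverage_experiment()` verifies the
defining property empirically: the fraction of replicate SIs containing
the true generating slope should match the nominal level, within
binomial error.

## The synthetic scenarios

`synth_scenario()` fixes the study conditions for all packaged
experiments: a rectangular lattice of minimal units with rook
contiguity, log-normal populations with mean 400 (near the mean
population of the smallest census units in the motivating urban
geography; coefficient of variation about 0.3, `pop_sdlog = 0.3`), an
independent uniform covariate on $[0, 100]$ read as a socioeconomic
percentile, and negative-binomial outcomes with
$(\alpha, \beta, \theta) = (-3.97, -0.0144, 2.7851)$ — a realistic
urban health-event regime of a few events per unit per period with
substantial overdispersion.  An optional smoothed covariate field
(rook-neighbour averaging, re-standardised) is provided purely to
stress-test: aggregation distortion arises with or without spatial
autocorrelation, and the packaged experiments use the unsmoothed field.

The packaged coverage experiment uses a 12×12 lattice (144 units, total
population ≈ 57,600), ensembles of 5 zonations at each of the 4 target
scales 500, 1000, 2000 and 4000 (so the finest scale sits just above the
minimal mean unit population of ≈ 400, as the motivating applications
place it, and zone counts run from ≈ 120 down to ≈ 14), 100 inner
datasets per density, and 50 replicate intervals; zone design uses 10
runs and 5 swap cycles per zonation.  These sizes are deliberately
modest — they keep a full calibration experiment at a few minutes on a
single core while leaving every structural property of the method
intact.  What passing does and does not show: the generator draws
populations and covariates independently across units, so the packaged
experiments demonstrate calibration of the machinery, not robustness to
strong spatial structure, boundary effects of real geographies, or
model misspecification at the minimal level — on real data the declared
minimal-level model family remains an assumption the analyst owns.

A second packaged experiment exercises the two-scale extreme: a 16×16
lattice with an ensemble at scales 500/1000/2000 (8 zonations per
scale) and a stopping point of 900, which discards the finest scale and
leaves estimates at exactly two scales, forcing straight-line scaling
fits.  Thirty replicate 95% intervals are constructed; all must
converge and their empirical coverage must be statistically compatible
with the nominal level.  The geography is larger and the retained
scales sit closer to the minimal level than in the four-scale
experiment because the two-scale restriction is where the method is
most fragile: with only two distant scales on a small map, the
straight-line extrapolation of the dispersion is far from consistent,
inner densities become too narrow, and empirical coverage degrades
visibly below nominal (we observed this directly with two retained
scales at 5–10 times the minimal population on a 12×12 and a 20×20
map).  That degradation is the nuisance-inconsistency approximation at
work, and the package reports it rather than correcting for it; the
packaged configuration keeps the extrapolation short enough for the
approximation to hold at the resolution a 30-replicate binomial check
can see.

Grid-shift analysis (`estimates_across_shifts()`) treats the minimal
grid itself as modifiable: when each minimal unit comprises $s \times s$
subcells, the grid can be shifted right or up by up to $s-1$ subcells,
giving $2(s-1)+1$ single-direction configurations (99 at $s = 50$).
Partial edge blocks under a shift are dropped rather than merged — every
analysed minimal unit keeps the same footprint — and the number of
dropped subcells is reported.  The ordered caterpillar plot of the
per-configuration estimates and CIs, with the fraction of CIs excluding
zero, is the reproducibility display for a modifiable minimal unit.

## Univariate overlay statistics

For one variable at a time, zones whose rate (or weighted mean) is
statistically above (below) the study-wide reference under a one-sided
exact Poisson test (default $\alpha = 0.05$, no multiplicity
adjustment) are flagged, flags are expanded to member minimal units, and
per-unit counts across the ensemble form the overlay map.  The
repeat-appearance probability between zonations $i$ and $j$ is the
fraction of units flagged in $i$ that are also flagged in $j$; its mean
over $j \neq i$, and the 2.5%/97.5% quantiles of those means across
zonations, summarise how (un)reliable a single-zonation map is.  The
flagging rule is a convention recorded in the output metadata —
published repeat probabilities are rule-dependent.

## Known limitations

* Single covariate only; no interactions, no spatial-autocorrelation
  error terms (extensions the framework admits but this package does not
  implement).
* The zone-design algorithm is a heuristic with a simple objective; it
  makes no claim of optimal partitioning and imposes no compactness or
  homogeneity constraints.
* SIs inherit approximation error from inconsistent nuisance-parameter
  extrapolation; the coverage experiment is the honest check.
* Fits on fewer than 5 zones are refused by default (`min_zones`), and
  failed fits are dropped from estimate sets with a warning — at very
  coarse scales an estimate set can therefore thin out.
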