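---
title: "Methods: migrant-resident aggregation analysis on gridded plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: migrant-resident aggregation analysis on gridded plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridfrog)
```

This vignette documents the statistical model behind `gridfrog`, the
assumptions it makes, the tunable parameters and their defaults, and the
design decisions taken where several reasonable conventions exist.

## Study design and data model

The unit of observation is a capture event: one individual, on one survey
of one gridded plot, located to a single grid cell, with its snout-vent
length (SVL, mm) and a sex marker (`M`/`F`, or `U` for juveniles whose
sex cannot be scored). The default geometry is a 12 m x 9 m plot of
forty-eight 1.5 m x 1.5 m cells; the cell centre `((col + 0.5) s,
(row + 0.5) s)` is the canonical coordinate of a capture, since the cell
is the data's true spatial resolution. Captures are pooled into five
three-to-four-month seasonal windows spanning February 1982 to August
1983, tracking the regional dry/wet cycle; the windows are configurable
(`season_windows()`).

## Cohort classification

Within each plot-season an individual is:

* `J` (juvenile) iff every capture that season is below 19 mm SVL;
* a **resident** adult (`RF`/`RM`) if it was observed in the same plot in
  the immediately preceding season — any capture counts, including
  captures as a juvenile, so a maturing juvenile that stays in its plot
  becomes a resident automatically; all first-season adults are residents
  because tenure cannot be assessed there;
* otherwise a **migrant** adult (`MF`/`MM`).

Two conventions had to be fixed where the classification rules are
ambiguous. First, "observed in the previous season" means the immediately
preceding window, not any earlier one, so an adult absent for a full
season reverts to migrant on return; this is the symmetric application of
the tenure rule. Second, sex is taken from the first adult-stage capture
(by date, study-wide); adults whose sex marker is `U` are excluded from
cohort analyses and reported in the `excluded` attribute. Individuals
captured in more than one plot are processed independently per plot
(plots are separate populations).

Spatial analyses use the subsetted dataset: individuals with at least
three captures study-wide (`subset_min_captures()`), removing transient
visitors whose "home range" would be a single sighting. Classification is
performed on the full dataset first, so tenure information from rarely
captured seasons still informs residency.

## Seasonal centroids and the Clark-Evans R

Each individual's seasonal centroid is the arithmetic mean of its capture
cell centres in that plot-season. For a migrant class against a resident
class, the nearest-neighbour distance (NND) runs **from** each migrant
centroid **to** its nearest resident centroid; the index is

R = r_obs / r_E,

where r_obs is the mean cross-type NND and r_E its expectation under
complete spatial randomness with Donnelly's boundary correction,

r_E(n) = 0.5 sqrt(A/n) + (0.0514 + 0.041/sqrt(n)) P/n,

with A = 108 m^2 and P = 42 m for the default window. The correction was
derived for a single pattern of n points, in which each point has n - 1
competitors. We therefore evaluate it at the *pattern-size equivalent*,
the number of competitor points plus one: `n_to + 1` for cross-type
distances (each focal point competes against all `n_to` reference
points), and `n_to` when the two inputs are literally the same pattern
(self-distances excluded). This convention is the package's own design
choice; evaluating at `n_to` directly leaves a visible negative bias at
small n (the binomial nearest-neighbour distribution is stochastically
smaller than its Poisson approximation), while the competitors + 1 rule
centres the CSR calibration: the test suite verifies that the mean R over
1000 simulated CSR patterns with 20 points per class lies in
[0.97, 1.03]. A pooled mode (`r_mode = "pooled"`), concatenating the two
classes into one pattern, is available because published R values do not
always state which convention was used.

## G(r), the spatial Kaplan-Meier correction, and the MAD test

The NND distribution function under CSR at reference intensity
lambda = n_to / A is G(r) = 1 - exp(-lambda pi r^2). The empirical curve
is estimated with the spatial Kaplan-Meier (product-limit) estimator:
each focal point contributes the time d_i = min(nnd_i, b_i), where b_i is
its distance to the nearest plot edge, with event indicator
nnd_i <= b_i. Points whose NND is censored by the border thus contribute
exactly the information they carry. Ties in event times are aggregated
before the product; with no censoring the estimator reduces exactly to
the empirical CDF (both properties are tested, the latter against the
`survival` package's product-limit fit). Coincident points are legal —
two individuals can share a cell centre — and no jitter is applied.

Curves are evaluated on an equally spaced grid of 512 steps from 0 to one
quarter of the window's shorter side (0-2.25 m by default), the
conventional range for NND summaries in bounded windows; the departure
statistic is the maximum absolute deviation
u = max_r |Ghat(r) - G_ref(r)|, with the sign of the deviation at the
argmax reported (positive = clustering). The reference curve defaults to
the theoretical CSR G at the observed reference intensity
(`mad_reference = "theoretical"`); an alternative mode uses the pointwise
mean of the simulated null curves. The per-unit Monte-Carlo test
(`mad_test_p()`) is the one-sided exchangeable rank of the observed u
among null-replicate u values computed identically, so its type-I error
is exact by construction; the acceptance suite confirms a rejection rate
of 5% (+/- 2 points) over 500 CSR units with 199 null replicates each.

## Shared sites

Per survey and per migrant-resident pair, the shared-site proportion is
the number of cells occupied by at least one individual of *each* class
of the pair, divided by the number of cells occupied by *either* class
(`denominator = "pair"`, the default; `"all"` divides by all occupied
cells instead, since the published definition is ambiguous on this
point). An individual recaptured within one survey counts once, at its
first cell. The matching null model is discrete: each individual occupies
an independently uniform cell (multinomial), preserving per-survey class
counts. For one individual per class the null expectation is exactly
1/48; the Monte-Carlo engine is checked against that value and against
full enumeration of small configurations.

## Null ensembles and paired contrasts

Every observed unit (plot x season for R and MAD; plot x survey for
shared sites) is compared with N = 10 density-matched null replicates —
the published replication level, kept as the default for fidelity;
calibration work should raise it (>= 199). Sub-seeds are derived
deterministically from the master seed and the unit key
(`derive_seed()`), so any unit's null stream is reproducible in
isolation and replicate streams are independent across units.

The contrast is an intercept-only linear mixed model on the paired
differences (observed - null mean) with random intercepts for plot and
for season nested within plot, the nesting accounting for seasonal
abundance differences. With one observation per plot-season cell the
nested variance component is confounded with the residual; `nlme` usually
still converges, but when it does not the model falls back to a plot-only
random intercept and finally to a seeded sign-flip randomization test,
and the route taken is recorded in the result's `method` field. R and
shared-site contrasts are two-sided; the MAD contrast is one-tailed
toward clustering by default, matching the one-tailed use of the MAD
statistic as an aggregation proxy. alpha = 0.05 throughout, with no
multiple-testing correction across the six class pairs — a deliberate
mirror of the published analysis; readers should treat the per-pair
p-values accordingly.

## Abundance models

Observed counts of juveniles, females and males per plot-season (from the
subsetted dataset) are modelled with five candidate mean structures —
null, season, group, group + season, group x season — as Gaussian linear
mixed models with a plot random intercept, fitted by maximum likelihood
and ranked by AICc = -2l + 2k + 2k(k+1)/(n-k-1), where k counts all
estimated parameters including variance components. Akaike weights are
exp(-delta/2), normalised. Counts are treated as Gaussian, a documented
simplification (no count-family alternative is fitted); with per-cell
counts around 5-20 this is mild, but weights should not be
over-interpreted for sparse designs.

## The synthetic generator

`generate_captures()` emulates the study design: 4 plots, the five
default seasons, 3-4 surveys per month on a deterministic calendar
(mean 3.5 — the published mean effort; the occasional months of much
higher effort in the original design are not replicated). Each plot is
founded by 8 resident females and 4 resident males (roughly the 2:1
female-biased structure the system shows) holding fixed home centres for
the whole study; every season 8 new migrants arrive per plot (40%
juveniles; adult arrivals 2:1 female) with home centres either uniform
(`"csr"`) or displaced from a randomly chosen resident by Gaussian
scatter with `cluster_sd` = 0.5 m (`"attraction"`, a Thomas-like
settlement rule whose truth parameter maps monotonically onto all three
statistics). On each survey every present individual is detected with
probability `detection_p` = 0.5 and recorded in the cell containing a
draw from its home-range scatter (sd 1.0 m for females, 0.7 m for males
and juveniles — female home ranges are the larger in this system),
truncated to the window. Juveniles start at 13-18 mm and grow 3 mm per
season, crossing the 19-mm threshold to exercise the maturation rule.
Generation is byte-reproducible from the config seed, and generated
tables always pass capture validation.

What the generator does **not** emulate: real per-survey detectability is
far lower than 0.5 (the original study averaged ~3.6 captures per
individual over 19 months), detection is independent across surveys
(no trap response), home ranges are isotropic Gaussian, and there is no
territorial exclusion, mortality or emigration. Passing the known-truth
tests therefore shows the pipeline recovers planted spatial structure
under idealised observation, not that field data meet these assumptions.

## Known numerical behaviour and limitations

* **Centroid edge truncation.** Captures are confined to the plot, so the
  seasonal centroid of an individual whose home centre lies near an edge
  is pulled inward. Observed centroid patterns are therefore slightly
  denser than the uniform CSR nulls even when settlement is truly random,
  which gives the R contrast a small anti-conservative (negative) bias —
  on the default synthetic design, a pooled mean difference of roughly
  -0.08 against a planted-attraction effect of about -0.38, as measured
  by the recovery tests. The MAD and shared-site contrasts do not show
  this bias (the KM border correction absorbs edge effects; the discrete
  null is resolution-matched). Real analyses should weigh R-based
  conclusions against the other two statistics.
* **Small-n units.** Units need at least one individual per class; units
  failing that are skipped, and contrasts require two or more usable
  units. MAD values from one or two focal points are noisy and sit high
  on [0, 1]; they are only meaningful relative to their own null
  replicates.
* **Problem sizes in the test suite** (the package's own choices): CSR
  calibration uses 1000 patterns (5000 in the acceptance script); MAD
  type-I calibration uses 500 units x 199 nulls; known-truth recovery
  uses 12 clustered and 12 random replicate studies at the default
  generator settings, asserting detection power above 0.8 for the R and
  shared-site contrasts and calibration for the rest.
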