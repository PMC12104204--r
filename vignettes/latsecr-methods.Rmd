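---
title: "Methods: one-dimensional SECR space use and stressor exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-dimensional SECR space use and stressor exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`latsecr` estimates where individual, photo-identifiable animals concentrate
their activity along a one-dimensional (latitudinal) survey corridor, and how
much of several anthropogenic stressors each individual is thereby exposed
to. It was built for nearshore marine systems -- the motivating case is a
gray whale feeding aggregation surveyed by small boat -- where sighting
positions vary essentially along one axis, so a 1-D grid of latitude bins is
an adequate spatial support.

## The observation model

The study corridor is tiled into `n_bins` half-open latitude bins of width
`bin_width` degrees (defaults 55 and 0.01; a 0.01-degree bin is 1.1 km of
coastline). For individual $i$, bin $l$ and year $t$, the number of
encounters $S_{i,l,t}$ is modelled as

$$S_{i,l,t} \sim \text{Poisson}(\lambda_{i,l,t}), \qquad
\lambda_{i,l,t} = \begin{cases}
0 & e_{l,t} = 0\\
\gamma_{i,l,t}\, \exp\!\big(-d_{i,l,t}^2 / 2\sigma^2_{i,t}\big) & \text{otherwise,}
\end{cases}$$

a half-normal decay of the expected sighting rate with the distance
$d_{i,l,t}$ (degrees) between the bin centroid and the individual's latent
annual *activity center* $C_{i,t}$. The *activity range* $\sigma^2_{i,t}$
controls how diffuse the individual's space use is. The baseline rate

$$\gamma_{i,l,t} = A_{i,t}\,\exp\!\big(R_{i,t} + \beta_e\, \tilde e_{l,t}\big)$$

combines a latent presence indicator $A_{i,t}$, an individual-year
*residency* intercept $R_{i,t}$, and a log-linear effect of survey effort.
Effort (surveyed area in km^2 per bin-year) enters after scaling by its
single global maximum to a $[0, 10]$ range (`scale_effort()`), so
$\beta_e$ is per unit of scaled effort. A bin-year without effort cannot
produce sightings, and an individual absent in a year ($A_{i,t}=0$)
produces none anywhere.

The hierarchy is completed by

$$\log \sigma^2_{i,t} = \mu + M_{i,t}, \quad M_{i,t} \sim N(0, \omega^2),
\quad R_{i,t} \sim N(0, 1), \quad A_{i,t} \sim \text{Bernoulli}(0.5),$$

with $C_{i,t}$ uniform over the grid extent. The $C$ prior is continuous
over the extent (the union of the bins) rather than discretised to bin
centroids: the activity center is a continuous quantity and the bins only
discretise the *observations*. The residency prior standard deviation is
fixed at 1 (it sets the scale of the log baseline rate); the remaining
hyperpriors are configurable through `prior_spec()`, with defaults
$\mu \sim N(-5, 3^2)$ on the log degrees-squared scale (centred near the
scale implied by ranges of a few tens of kilometres),
$\omega \sim \text{half-}N(1)$ and $\beta_e \sim N(0, 10^2)$. These are
deliberately weak; a prior-sensitivity rerun is a configuration change, not
a code change.

When an individual-year is estimated absent, its $(C, \sigma^2)$ are
reported at a pinned placeholder state (52 degrees N, 0.001 degrees^2 by
default) that never enters the likelihood, so the large uncertainty of
unseen individual-years cannot contaminate the estimates of observed ones.
All space-use and exposure summaries exclude these pinned values: an absent
draw contributes zero occurrence and zero residency instead.

## Data preparation and the inclusion filter

`assign_latitude_bins()` places each sighting in the half-open bin
$[\text{edge}_l, \text{edge}_{l+1})$ containing its latitude (lower edge
inclusive, 1-based indexing); out-of-extent sightings are dropped with a
count. `build_encounter_array()` aggregates counts and effort to the
annual scale and applies the inclusion filter: an individual must be seen
on at least `min_days` (default 5) *distinct survey dates* within a year.
Distinct dates -- not sighting rows -- carry the information here, because
several encounters of one individual within a day are common and all of
them enter the counts $S_{i,l,t}$.

Individuals that qualify in at least one year contribute rows for *all*
study years: unobserved years are informative zeros that the presence
indicator $A_{i,t}$ absorbs. The `inclusion` table records which
individual-years met the criterion on their own, so summaries can also be
restricted to qualifying individual-years only, and all downstream
reference summaries (e.g. the exposure mean-of-medians lines) use the
qualifying set.

## Fitting

`secr_fit()` runs an adaptive Metropolis-within-Gibbs sampler written in
C++ (via Rcpp). Each scalar of $C$, $M$, $R$, $\mu$, $\omega$, $\beta_e$
takes a Gaussian random-walk Metropolis update; step sizes adapt in batches
of 50 towards 44% acceptance *during burn-in only*, so the post-burn-in
kernel is fixed and targets the exact posterior. $A_{i,t}$ takes an exact
two-point Gibbs draw from its full conditional, which forces $A = 1$
whenever the individual-year has any sighting. While $A_{i,t} = 0$, the
case's $C$, $M$, $R$ drop out of the likelihood and are refreshed by exact
draws from their priors (their full conditionals), keeping the chain mobile
across the presence/absence regimes. Chains differ only by their seed
stream (`seed + chain`), and a fit is bit-reproducible for a fixed
configuration.

Defaults follow the full-scale protocol of the motivating analysis: 3
chains of 400,000 iterations, 50,000 burn-in, 1-in-100 thinning. The
package's tests, examples and acceptance script use scaled-down
configurations (typically 2-3 chains of 3,000-60,000 iterations on
15-36 individual-year problems with 20-30 bins), which complete in seconds
to tens of seconds; these sizes were chosen so the whole suite runs
comfortably on a laptop while leaving the Monte-Carlo checks enough
precision to be meaningful.

Convergence is assessed with `gelman_rubin()` (classic between/within
potential scale reduction, flagged at 1.1) and `effective_sample_size()`
(Geyer initial-positive-sequence truncation, summed over chains, flagged
at 400). Parameters with zero within-chain variance report `NA` rather
than failing: a pinned or fixed quantity has no meaningful diagnostic.

## Space use and exposure

At each retained draw, the *relative occurrence* of an individual in bin
$l$ is the normal probability mass between the bin's edges,
$\Phi\big((\text{edge}_{l+1}-C)/\sigma\big) -
\Phi\big((\text{edge}_l-C)/\sigma\big)$. Mass beyond the grid is truncated,
not renormalised, so occurrence sums to at most 1 -- an individual whose
range extends past the corridor is genuinely less present in it.

Residency weights are built per draw: the $R_{i,t}$ of all present
individual-years are min-max rescaled jointly across the dataset to
$[0, 1]$, absent individual-years receive 0, and if all present values
coincide they map to 1 (a lone observed individual is fully resident, not
absent). Rescaling within a draw -- rather than across posterior summaries
or within years -- keeps years comparable and propagates the joint
uncertainty of $R$ into every downstream quantity; the alternative scopes
would either mix draws that never co-occurred or make residency
incomparable between years. `space_use_distribution()` averages occurrence
times rescaled residency over draws, one distribution per individual-year.

Stressor layers are per-bin relative intensities, scaled to $[0, 1]$ by
their single maximum (`scale_layer()`); dynamic (monthly) layers are scaled
by their global maximum across bins, years and months so years remain
comparable, and reduced to annual values by averaging the months available
in each year (`annualize_dynamic()`). Where only a source location is known
(a port, a discharge site), `proximity_proxy()` builds a linear
proximity proxy $\max_d - |{\text{centroid}} - \text{point}|$, maximal at
the source and zero at the farthest bin; since no canonical decay exists
for such proxies, a reciprocal alternative is selectable, and only the
direction (closer means more exposed) should be interpreted.

Exposure of an individual-year at one draw is
$E = \big(\sum_l \text{occ}_l\, s_l\big) \times R'$, with $s_l$ the scaled
stressor value and $R'$ the rescaled residency. With occurrence summing to
at most 1 and both factors in $[0,1]$, every exposure value lies in
$[0, 1]$. `exposure_distribution()` returns per-individual-year posterior
medians, means and central 90% intervals, plus annual and overall
mean-of-medians reference values over qualifying individual-years.

## Post hoc summaries

`sigma_to_km()` converts an activity-range $\sigma$ (degrees) to a
kilometre range as $4 \sigma \times 110$: four standard deviations span
the central 95% of the normal space-use distribution, and 110 km per
degree follows from 1.1 km per 0.01-degree bin. `range_summaries()`
applies this per draw, excluding absent draws. `group_center_contrast()`
compares two groups of individual-years (e.g. juvenile vs. mature,
labelled per individual-year so that maturation mid-study is respected):
at each draw it averages $C$ over each group's present members and reports
the fraction of difference draws above zero, counting exact ties half
towards each direction; draws where a group is entirely absent are skipped
and counted.

## The synthetic-data generator

`simulate_dataset()` generates surveys, individuals, sightings and
stressor layers with exactly the statistical structure the model assumes,
plus the ground truth needed for recovery experiments. Defaults emulate
the magnitudes of the motivating field study: a 55-bin 0.01-degree grid,
about 30 survey days per June-October season over 8 years, ~25 marked
individuals with presence probability 0.5, and population log-range
$\mu_{\text{true}} = -5.4$ (a typical $\sigma$ of 0.067 degrees, i.e. a
~30 km range), $\omega_{\text{true}} = 0.75$, $\beta_{e,\text{true}} =
0.05$. Effort can be uniform, north-heavy or patchy; the patchy pattern
guarantees bin-years with zero effort, exercising the step-function part
of the rate.

Annual per-bin counts are drawn Poisson at the model's annual rate and
then apportioned among the bin-year's survey days in proportion to daily
effort -- the annual rate the model sees is preserved exactly, while the
records carry the dated structure the inclusion filter needs. Within-bin
latitudes are uniform (the model only uses bin membership). Every
generator stage derives its RNG stream from the scenario seed with a fixed
offset, so stages are independently reproducible.

What the generator does *not* emulate: two-dimensional movement, temporal
structure within a season (sighting dates are effort-proportional, a
modelling convenience), behavioural states, prey-driven attraction, and
misidentification. Passing recovery tests therefore show the estimator is
consistent with its own assumptions -- they cannot show those assumptions
hold for any particular field system.

## Numerical choices and degenerate inputs

* Half-open bins, lower edge inclusive; a latitude exactly on a shared
  edge belongs to the northern bin.
* `scale_effort()` and `scale_layer()` reject all-zero inputs as
  degenerate rather than returning NaN.
* An individual with all sightings in a single bin is valid; its
  $\sigma^2$ posterior is then bounded from below mostly by the prior --
  no special casing.
* Exposure and space use treat an `A = 0` draw as zero occurrence and zero
  residency; the pinned absent state never leaks into summaries.
* `log_likelihood` returns $-\infty$ (not an error) when a positive count
  coincides with a zero rate, so impossible states are rejected inside the
  sampler; a sighting recorded in a zero-*effort* bin-year, however, is a
  data inconsistency and errors with the offending rows named.
* Contrast ties (difference draws exactly 0) count half towards each
  direction, making label swaps map $p \mapsto 1 - p$ exactly.

## What the recovery experiment can and cannot show

The bundled recovery experiment (15 individuals, 30 bins, 3 years, 3
chains of 20,000 iterations thinned by 10) checks two things: that 95%
credible intervals for activity centers cover the simulated truth at
roughly their nominal rate, and that posterior-median centers sit close to
truth. Coverage is the sharper instrument. The mean absolute error of the
posterior median is bounded below by the posterior width -- approximately
$\sqrt{2/\pi}$ times the posterior standard deviation when the intervals
are calibrated -- and with activity ranges at the ~30 km scale and
realistic encounter numbers (tens per individual-year) that width is one
to two bin widths. A mean error much below one bin width would actually be
suspicious: it would require either far richer data than such surveys
produce or overconfident intervals. The package's tests assert both the
coverage rate and the error magnitude so that regressions in either
direction (bias or overdispersion) are caught.

## Known limitations

* One spatial dimension: suitable only where the sighting distribution is
  effectively linear (a nearshore corridor); no 2-D detection surface.
* Annual resolution: within-season movement and intra-seasonal exposure
  patterns are invisible.
* No density or abundance estimation: the open use of the study area by
  the population is accommodated by the presence indicator, which is
  incompatible with closed-population density estimands.
* Exposure is relative, not absolute: layers are unit-scaled intensities
  or proximity proxies, so exposure values support comparisons across
  individuals, years and stressors -- not dose.
* With spatially uniform effort the scaled effort $\tilde e$ is constant
  wherever positive, and $\beta_e$ is then only weakly identified from
  $R$ (their sum drives the rate); heterogeneous effort identifies both.
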