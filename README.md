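# latsecr

Bayesian spatially explicit capture–recapture (SECR) on a one-dimensional
latitudinal grid, with downstream residency-weighted stressor-exposure
analysis.

## What problem this solves

Photo-identification surveys of nearshore marine megafauna (the motivating
system is a gray whale feeding aggregation surveyed by small boat) produce
repeat sightings of known individuals along an essentially one-dimensional
corridor, under survey effort that varies strongly in space and time. Two
questions follow:

1. **Where does each individual concentrate its activity, and how diffusely?**
2. **Given that space use, how exposed is each individual to mapped
   anthropogenic stressors** (ports, effluent discharge, whale watching,
   pot fisheries, recreational fishing) — not just the population on
   average, but individual by individual and year by year?

`latsecr` answers both with a hierarchical Bayesian SECR model. Encounters
of individual $i$ in latitude bin $l$ and year $t$ are Poisson,

$$S_{i,l,t} \sim \mathrm{Poisson}(\lambda_{i,l,t}),\qquad
\lambda_{i,l,t} = A_{i,t}\,e^{R_{i,t} + \beta_e \tilde e_{l,t}}\;
e^{-d_{i,l,t}^2 / 2\sigma^2_{i,t}},$$

with rate zero wherever effort $e_{l,t}=0$. Here $d_{i,l,t}$ is the
distance from the bin centroid to the individual's latent annual activity
center $C_{i,t}$ (uniform prior over the grid), $\sigma^2_{i,t}$ its
activity range with $\log\sigma^2_{i,t} = \mu + M_{i,t}$,
$M_{i,t}\sim N(0,\omega^2)$, $R_{i,t}\sim N(0,1)$ an individual-year
residency intercept, $\tilde e$ effort scaled to $[0,10]$, and
$A_{i,t}\sim\mathrm{Bernoulli}(0.5)$ a presence indicator. Fitting is by
an adaptive Metropolis-within-Gibbs sampler (Rcpp core) with
Brooks–Gelman–Rubin and effective-sample-size diagnostics.

From the posterior, per-bin relative occurrence (normal mass between bin
edges) is weighted by min–max-rescaled residency to give individual space
use, and summed against unit-scaled stressor layers to give one exposure
value per posterior draw — a full exposure distribution per individual,
year and stressor. Post hoc tools convert activity ranges to kilometres
($4\sigma \times 110$) and contrast group mean activity centers (e.g.
juvenile vs. mature) probabilistically.

A seeded synthetic-data generator (`simulate_dataset()`) reproduces the
assumed data structure with known ground truth, so the whole pipeline is
testable by parameter recovery; the methods vignette
(`vignettes/latsecr-methods.Rmd`) documents the model, priors, numerical
choices and limitations.

## Worked example

```r
library(latsecr)
library(dplyr)

scenario   <- sim_scenario(n_bins = 30, n_years = 3, n_individuals = 15, seed = 42)
dataset    <- simulate_dataset(scenario)
sightings  <- assign_latitude_bins(dataset$sightings, dataset$grid)
encounters <- build_encounter_array(sightings, dataset$effort, dataset$grid)
encounters
#> <encounter_data> 10 individuals x 30 bins x 3 years; 1215 sightings;
#>   17 qualifying individual-years (>= 5 survey days)

fit <- secr_fit(encounters, model_config(n_chains = 3, n_iter = 20000,
                                         burn_in = 5000, thin = 10, seed = 1))
glance(fit)
#> # A tibble: 1 x 8
#>   n_individuals n_years n_individual_years n_chains n_draws max_rhat min_ess
#>           <int>   <int>              <int>    <int>   <int>    <dbl>   <dbl>
#> 1            10       3                 30        3    1500     1.07    66.8

tidy(fit) |> filter(term %in% c("mu", "omega", "beta_e"))
#> # A tibble: 3 x 7
#>   term   estimate    mean conf.low conf.high  rhat   ess
#> 1 mu      -5.06   -5.06    -5.46      -4.66   1.00 213.
#> 2 omega    0.816   0.842    0.508     1.26    1.00 973.
#> 3 beta_e   0.0712  0.0708   0.0297    0.108   1.07  66.8
```

Ten of the 15 simulated individuals were seen on five or more distinct
survey days in at least one year and enter the model; the population mean
log activity range `mu` is recovered near its generative value of −5.4
(the interval −5.46 to −4.66 covers it). Activity ranges in kilometres and
exposure to a port-proximity stressor follow directly:

```r
range_summaries(fit) |> filter(included) |> pull(median_km) |> summary()
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   20.41   25.97   39.78   36.67   46.27   57.54

port     <- scale_layer(proximity_proxy(44.55, dataset$grid, name = "port"))
exposure <- exposure_distribution(fit, port)
as_tibble(exposure) |> filter(included) |> arrange(desc(median)) |> head(4)
#> # A tibble: 4 x 8
#>   individual_id  year included stressor median  mean  lo90  hi90
#> 1 W005           2016 TRUE     port      0.600 0.598 0.544 0.642
#> 2 W012           2017 TRUE     port      0.241 0.241 0.170 0.315
#> 3 W012           2016 TRUE     port      0.219 0.221 0.129 0.320
#> 4 W010           2018 TRUE     port      0.174 0.177 0.113 0.254
```

Exposure is relative, on $[0,1]$: individual W005 in 2016 spent its
(residency-weighted) time close to the port source, the others much less —
the kind of individual-level heterogeneity the method exists to reveal.
`autoplot()` methods draw space-use fields and exposure summaries;
`run_pipeline(run_config(...))` drives the whole
simulate → prepare → fit → exposure → posthoc chain from one YAML
configuration with a manifest of checksummed outputs.

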