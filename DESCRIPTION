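Package: latsecr
Title: One-Dimensional Bayesian Spatially Explicit Capture-Recapture and
    Stressor Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individual space use of photo-identified animals along a
    one-dimensional (latitudinal) survey grid with a Bayesian spatially
    explicit capture-recapture model, and combines the posterior with scaled
    anthropogenic stressor layers to quantify residency-weighted individual
    stressor exposure. Sightings are modelled as Poisson counts whose expected
    rate decays half-normally with distance from a latent annual activity
    center; baseline rates depend on survey effort, an individual-year
    residency random effect, and a latent presence indicator. Fitting is by an
    adaptive Metropolis-within-Gibbs sampler with Brooks-Gelman-Rubin and
    effective-sample-size diagnostics. Includes a seeded synthetic-data
    generator with known ground truth for parameter-recovery experiments, and
    post hoc summaries of activity-range size in kilometres and posterior
    contrasts of group mean activity centers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr
Config/testthat/edition: 3
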