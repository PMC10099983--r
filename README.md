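# nestipm

Integrated population models (IPMs) and transient life-table-response
experiments (LTREs) for nestbox-breeding migratory passerines such as the
pied flycatcher (*Ficedula hypoleuca*).

Long-term nestbox studies produce three structurally different data streams
about the same female population: individual nest records (laying date,
clutch size, fledged young, the mother's identity and age), individual
capture histories from ringing, and annual population-level tallies (first
clutches laid, total eggs, total fledglings, newly ringed adult females).
`nestipm` fits one joint Bayesian model to all of them and then asks the
retrospective question conservation ecology actually cares about: *which
demographic rates drove the observed changes in population growth?*

## The model

Females are censused just before breeding in two age classes, yearlings (Y)
and adults (A). The female segment of the population projects as

```
[ N_Y ]        [ 0.5 F_Y sJ   0.5 F_A sJ ] [ N_Y ]     [ ImmY ]
[     ]      = [                          ] [     ]  +  [      ]
[ N_A ] t+1    [     sA           sA     ] [ N_A ] t   [ ImmA ] t+1
```

with age-specific fecundity `F_a = pB_a * CS_a * pNS * sN_a` (breeding
probability, clutch size, nest success, per-egg survival to fledging),
juvenile and adult apparent survival `sJ`, `sA`, and immigrant females
`ImmY`, `ImmA`. The data likelihoods are:

* an age-structured Cormack–Jolly–Seber model for capture histories, with
  recapture probability `pB_a[t] * pCapB[t]` where `pCapB` is the observed
  proportion of nests whose breeding female was identified;
* Poisson / Binomial-mixture GLMMs for clutch sizes and nest fates of
  known-age mothers (a zero-fledged nest mixes complete failure with
  success followed by loss of every egg);
* Poisson observation models for the four annual count series, including
  newly ringed adult females as a `pCapB`-thinned count of immigrant
  arrivals;
* a state-space process model for the latent abundances with
  demographic-stochasticity kernels.

All rates carry normally distributed random year effects on the link scale;
nest success and nestling survival respond to post-hatching rainfall and
minimum temperature, and juvenile survival to post-fledging rainfall, in
phenology-anchored windows built from the nest records (8 days either side
of the first-quartile hatch date; 7 days from fledging). Estimation is by
an adaptive Metropolis-within-Gibbs sampler written in C++ (latent integer
abundances are sampled natively).

Posterior draws feed three transient LTRE designs that decompose
short-term variance in realized growth (`random`), year-to-year growth
changes (`fixed`), and changes in geometric mean growth between periods
(`period`, with direct and structure-mediated real-time elasticities),
including the contribution of immigration.

## Worked example

```r
library(nestipm)

# a complete synthetic population with known parameters
sim <- simulate_dataset(default_truth(), seed = 42)
data <- as_ipm_data(sim)
fit <- fit_ipm(data, fit_config(profile = "test", seed = 1))
fit
#> Integrated population model fit
#>   years: 1980-2019 (40)
#>   components: cjs, clutch, nestfate, counts, state
#>   chains: 3 x 1500 retained draws (of 20000 iterations, burn-in 5000, thin 10)
#>   max R-hat (top-level): 1.014

round(coef(fit)[c("sA", "sJ", "CS_A", "pNS")], 3)
#>    sA    sJ  CS_A   pNS
#> 0.442 0.100 6.607 0.851
```

The generating values were `sA = 0.45`, `sJ = 0.10`, `CS_A = 6.5`,
`pNS = 0.85`; every 95% credible interval of this fit covers its truth.
Decomposing the among-year variance in realized growth:

```r
posterior_ltre(fit, "random")
#> Posterior transient LTRE (random design), 4500 draws
#>         group   median  lower95 upper95
#>   immigration  0.03419  0.02395 0.04934
#>  reproduction  0.00033 -0.00033 0.00119
#>     structure -0.00008 -0.00044 0.00047
#>      survival  0.00611  0.00213 0.01083
```

Immigration carries most of the short-term variance in growth — the
pattern this class of models was built to quantify. `predict(fit)` returns
the posterior-predictive check table against the observed count series,
and `simulate(fit, horizon = 10)` runs stochastic forward projections from
the posterior medians.

A file-based workflow (`run_simulate`, `run_fit`, `run_ltre`,
`run_project`) and a thin command-line wrapper (`inst/cli/nestipm.R`,
subcommands `simulate | fit | diagnose | ltre | project`) drive the same
functions from a YAML/JSON config.

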