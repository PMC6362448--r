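# occrich

Community species richness from multispecies occupancy–detection models
with data augmentation.

## The problem

Replicated detection/non-detection surveys (S sites, J visits, binary
records `y[i,j,k]` per species) miss species in two ways: a species may be
absent from every sampled site, or present but never detected. `occrich`
estimates the total community richness **N** — including species never
recorded — for ecologists analysing multi-species survey data, and for
methodologists who want to study how well that estimation works.

The model couples single-species occupancy models through logit-normal
species random effects and uses parameter-expanded data augmentation:

```
w_k ~ Bernoulli(Omega)                    # community membership, k = 1..M
z_ik ~ Bernoulli(w_k * psi_ik)            # presence at site i
y_ijk ~ Bernoulli(z_ik * p_ijk)           # detection at visit j
logit(psi_ik) = beta_0k + beta_1k x_1i + ...,   beta_mk ~ N(mu, sigma)
logit(p_ijk)  = alpha_0k + alpha_1k v_1ij + ...,  alpha_mk ~ N(mu, sigma)
```

The observed n species are padded with all-zero "potential species" up to
M, and `N = sum(w)` is a derived posterior quantity. A bespoke
Metropolis-within-Gibbs sampler (collapsed membership updates, adaptive
random-walk Metropolis on species effects, conjugate/slice hyperparameter
updates) fits the model; Gelman–Rubin diagnostics and an
augmentation-adequacy audit (posterior mass in the top tenth of
`[min N, M]` must stay below 1%) come built in, along with the three
standard prior regimes (`prior_set("set1" | "set2" | "set3")`).

A full simulation laboratory is included: ideal logit-normal communities
(`occ_scenario_ideal()`), five alternative detectability distributions for
assumption-violation studies (`det_violation()`, `tune_det_location()`),
closed-form/Monte-Carlo calculators for the probability that a species is
completely missed, `m_k = (1 - psi_k (1 - (1-p_k)^J))^S`
(`prob_missed()`, `expected_missed_fraction()`, `table1_grid()`), and a
scenario-grid driver with performance summaries (`run_grid()`,
`summarize_performance()`).

## Worked example

Simulate an ideal 50-species community surveyed at 150 sites with 6
visits, then estimate N with prior set 3:

```r
library(occrich)

spec <- occ_scenario_ideal("Occ1", S = 150, J = 6, n_species = 50)
sim  <- simulate_dataset(spec, seed = 101)
sum(sim$truth$detected)
#> [1] 50

fit <- run_mcmc(augment(sim$data, 50), priors = prior_set("set3"),
                config = mcmc_config(seed = 7))
fit
#> Multispecies occupancy fit: S = 150, J = 6, 50 observed + 50 augmented (M = 100)
#>   3 chains x 4500 kept draws; priors set3; converged (max Rhat 1.040, 1 block)
#> N: median 50, 95% CI [50, 51] (50 detected)

round(summary(fit), 3)
#>                   mean    sd   2.5%    50%  97.5%  Rhat
#> omega            0.496 0.049  0.400  0.497  0.592 1.000
#> N               50.122 0.366 50.000 50.000 51.000 1.000
#> mu_beta_int     -0.947 0.068 -1.085 -0.947 -0.820 1.004
#> sigma_beta_int   0.262 0.080  0.121  0.257  0.431 1.040
#> mu_alpha_int    -2.018 0.148 -2.310 -2.017 -1.733 1.001
#> sigma_alpha_int  0.989 0.121  0.786  0.977  1.258 1.002
```

All 50 species were detected, and the posterior concentrates on N = 50
with a tight interval; the occupancy hyperparameters (truth: mu = -1,
sigma = 0.3) and detection hyperparameters (truth: mu = -2, sigma = 1)
are recovered. Under sparse designs (e.g. Occ2 with S = 25, J = 2, where
~50% of species go undetected) the posterior instead becomes strongly
right-skewed and prior-sensitive — the regime the simulation tools are
designed to expose:

```r
tb <- table1_grid(n_mc = 1e6, seed = 1)
subset(tb, S == 25 & J == 2)
#>    scenario  S J    missed      absent missed_pct absent_pct
#> 1      Occ1 25 2 0.2733194 0.001442388         27          0
#> 10     Occ2 25 2 0.5030412 0.080710511         50          8
```

`missed` is the expected fraction of community species with no detection
anywhere; `absent` (constant in J) is the fraction present at none of the
sampled sites.

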