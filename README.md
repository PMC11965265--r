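# solaroccu

Bayesian multispecies (community) auto-logistic dynamic occupancy modelling
for repeated-visit bird surveys around a utility-scale solar facility —
with DIC model selection over enumerated candidate sets, posterior
predictive model checking, habitat-contrast statistics, and a synthetic
data generator that emulates the distance-stratified study design, so the
whole pipeline can be exercised and validated without field data.

## The scientific problem

Detection/non-detection surveys never observe occupancy directly: a
species can be present and missed. For a community of songbirds surveyed
at *i = 1…I* plots, on *j = 1…J* visits, in *t = 1…T* breeding seasons,
the package models, for each species *k*:

- **Process model.** True occupancy is latent:
  `z[i,k,t] ~ Bernoulli(psi[i,k,t])`, with first-season occupancy on the
  logit scale `logit(psi[i,k,1]) = beta0_k + sum_c beta_kc * x[i,c,1]`, and
  later seasons adding an auto-logistic persistence term
  `... + phi_k * z[i,k,t-1]`, so occupancy depends on whether the plot was
  occupied the previous season. This puts inference directly on occupancy
  probability rather than separate colonization/extinction parameters.
- **Observation model.** `y[i,j,k,t] ~ Bernoulli(p[i,j,k,t] * z[i,k,t])`
  with `logit(p[i,j,k,t]) = alpha0_{k,t} (+ alpha . x_det)` — species- and
  year-specific detection intercepts, optional shared detection covariates.
- **Community structure.** For the insectivore guild, species-level
  intercepts and slopes are draws from shared normal distributions
  (`beta0_k ~ N(mu_beta0, sigma_beta0^2)` and likewise for each slope,
  the persistence offset, and each year's detection intercept), so common
  species lend strength to rare ones. A small synanthropic guild (two
  species) is fitted with fixed effects instead.

Fitting is by Metropolis-within-Gibbs with latent-state data augmentation
(the `z` are sampled alongside the parameters), written in C++ for speed
and driven entirely by R's RNG, so every result is reproducible from a
seed. Candidate models (subsets of: distance to the facility, orthopteran
abundance, forb cover, grass cover) are scored by DIC, and absolute fit is
checked with a posterior predictive Bayesian p-value using a Freeman–Tukey
discrepancy on per-plot detection totals. Inside/outside habitat
contrasts use Kruskal–Wallis tests (with an exact-permutation option for
small samples) and two-group linear regressions.

## Worked example

Simulate a survey at the study design (100 plots — 20 inside the facility
and 20 in each of four outside distance bins — 4 visits × 2 years, six
insectivores, two synanthropic species), fit the generating model, and
inspect the community-level effects:

```r
library(solaroccu)

sim <- sim_dataset(seed = 42)  # detections, covariates, retained truth
f   <- occu_formula(c("dist_solar", "orthoptera", "forb"), guild = "insectivore")
fit <- fit_occu(sim$detections, sim$covariates, f,
                config = mcmc_config(n_chains = 3, n_iter = 6000,
                                     n_burnin = 3000, thin = 5, seed = 1))
s <- tidy(fit)              # posterior mean, sd, 85% CrI, split-chain R-hat
s[grepl("^mu_beta", s$term), ]
#>   term                  mean    sd  lower  upper  rhat
#> 1 mu_beta0             0.957 1.24  -0.627  2.79   1.02
#> 2 mu_beta[dist_solar]  1.09  0.664  0.341  2.07   1.07
#> 3 mu_beta[orthoptera]  2.33  1.29   0.576  4.10   1.02
#> 4 mu_beta[forb]       -1.33  0.742 -2.36  -0.366  1.02
```

The `mu_beta` rows are the community-mean effects of each (scaled)
covariate on the logit of occupancy; the generating values here were 1.0,
1.5 and −0.75, and each 85% credible interval excludes zero on the correct
side. `glance()` gives the one-row model summary and `bayes_pvalue()` the
posterior predictive check (values near 0.5 = adequate fit):

```r
glance(fit)
#>   model                 guild       n_species n_chains n_draws max_rhat  dic   p_d
#> 1 Solar + Insect + Forb insectivore         6        3    1800     1.26 2395.  47.7
set.seed(1); bayes_pvalue(fit)$p_value
#> [1] 0.37
```

(The short chains above are for illustration; `mcmc_config()` defaults to
3 × 20,000 iterations, which brings every R-hat under 1.1.)

Habitat contrasts on the simulated covariates reproduce the inside/outside
structure the generator encodes — orthopterans and forbs higher inside the
facility, grass higher outside (standardized response, outside = 1
coding, so "higher inside" is negative):

```r
hab <- habitat_contrasts(sim$covariates)
hab[hab$scaling == "standardized", c("covariate", "estimate", "std_error", "p_value")]
#>   covariate  estimate std_error  p_value
#> 1 orthoptera    -1.81     0.122 7.48e-34
#> 2 grass          1.84     0.120 1.61e-35
#> 3 forb          -1.99     0.106 9.57e-46
```

Model selection over the built-in 12-model insectivore candidate set and
predicted occupancy curves:

```r
tab <- run_model_set(sim$detections, sim$covariates, insectivore_model_set(),
                     config = mcmc_config(seed = 2))
curves <- predict_occupancy(fit, "orthoptera")   # species + community curves
autoplot(curves)
```

A thin command-line front end over the same functions is installed at
`inst/cli/solar-occu.R` with verbs `simulate`, `fit`, `model-select`,
`habitat-stats` and `report`, all seed-deterministic.

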