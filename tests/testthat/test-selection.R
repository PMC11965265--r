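test_that("conditional deviance matches hand evaluation and handles edge cases", {
  design <- make_design(I = 1, J = 1, K = 1, T = 1)
  pp <- species_params(beta0 = 0, beta = matrix(0, 1, 0), phi = NULL,
                       alpha0 = matrix(0, 1, 1))
  y1 <- array(1L, c(1, 1, 1, 1))
  z1 <- array(1L, c(1, 1, 1))
  # y=1, z=1, p=0.5: -2 log(0.5)
  expect_equal(obs_deviance(y1, z1, pp, design), -2 * log(0.5),
               tolerance = 1e-12)
  # detection at an unoccupied cell: infinite deviance
  expect_equal(obs_deviance(y1, array(0L, c(1, 1, 1)), pp, design), Inf)
  # empty data: deviance 0
  ym <- array(NA_integer_, c(1, 1, 1, 1))
  expect_equal(obs_deviance(ym, z1, pp, design), 0)
  # near-perfect fit: deviance -> 0
  pp_perfect <- species_params(beta0 = 0, beta = matrix(0, 1, 0), phi = NULL,
                               alpha0 = matrix(20, 1, 1))
  expect_lt(obs_deviance(y1, z1, pp_perfect, design), 1e-6)
})

test_that("the built-in model sets enumerate the candidate models", {
  ins <- insectivore_model_set()
  syn <- synanthropic_model_set()
  expect_length(ins, 12)
  expect_length(syn, 8)
  expect_equal(vapply(ins, `[[`, character(1), "name")[c(1, 12)],
               c("Solar + Insect + Forb", "Null"))
  expect_equal(vapply(syn, `[[`, character(1), "name")[c(1, 7)],
               c("Forb + Grass", "Null"))
  # synanthropic candidates never include orthopteran abundance
  expect_false(any(vapply(syn, function(f) "orthoptera" %in% f$occ, logical(1))))
  # synanthropic guild uses fixed effects (two species only)
  expect_true(all(vapply(syn, `[[`, character(1), "effects") == "fixed"))
  expect_false(anyDuplicated(vapply(ins, `[[`, character(1), "name")) > 0)
})

test_that("DIC decomposition behaves on a fitted model", {
  sim <- gen_dataset(sim_config(design = make_design(I = 25, J = 3, K = 3, T = 2),
                                seed = 61, occ_covariates = "orthoptera"))
  f <- occu_formula("orthoptera", guild = "insectivore")
  fit <- fit_occu(sim$detections, sim$covariates, f,
                  config = mcmc_config(n_chains = 2, n_iter = 800,
                                       n_burnin = 400, thin = 2, seed = 8))
  d <- dic(fit)
  expect_true(is.finite(d$dic))
  expect_equal(d$dic, d$Dbar + d$pD, tolerance = 1e-12)
  expect_gt(d$pD, 0) # a fitted model uses some effective parameters
  # too few draws is rejected
  small <- fit
  small$deviance <- list(1:5)
  expect_error(dic(small), "too few")
})

test_that("model-set tables are complete, ordered, and delta-referenced to the best model", {
  sim <- gen_dataset(sim_config(design = make_design(I = 20, J = 3, K = 3, T = 2),
                                seed = 62, occ_covariates = "orthoptera"))
  set <- list(occu_formula("orthoptera", guild = "insectivore"),
              occu_formula(character(), guild = "insectivore"),
              occu_formula("grass", guild = "insectivore"))
  tab <- run_model_set(sim$detections, sim$covariates, set,
                       config = mcmc_config(n_chains = 2, n_iter = 600,
                                            n_burnin = 300, thin = 3, seed = 9))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$delta_dic[1], 0)
  expect_true(all(diff(tab$dic) >= 0))
  expect_true(all(tab$bayes_p >= 0 & tab$bayes_p <= 1))
  expect_true(all(is.na(tab$error)))
  # a failing model is reported in its row, not fatal
  set_bad <- c(set, list(occu_formula("no_such_covariate",
                                      guild = "insectivore", name = "Broken")))
  tab2 <- run_model_set(sim$detections, sim$covariates, set_bad,
                        config = mcmc_config(n_chains = 2, n_iter = 600,
                                             n_burnin = 300, thin = 3, seed = 9))
  expect_equal(nrow(tab2), 4)
  expect_true(any(!is.na(tab2$error)))
  expect_equal(tab2$delta_dic[1], 0)
})

test_that("the Bayesian p-value pipeline produces draws of both discrepancies", {
  sim <- gen_dataset(sim_config(design = make_design(I = 25, J = 4, K = 3, T = 2),
                                seed = 63, occ_covariates = "orthoptera"))
  f <- occu_formula("orthoptera", guild = "insectivore")
  fit <- fit_occu(sim$detections, sim$covariates, f,
                  config = mcmc_config(n_chains = 2, n_iter = 800,
                                       n_burnin = 400, thin = 4, seed = 10))
  set.seed(99)
  bp <- bayes_pvalue(fit)
  expect_gte(bp$p_value, 0)
  expect_lte(bp$p_value, 1)
  expect_length(bp$T_rep, fit$n_save * 2)
  expect_true(all(bp$T_obs >= 0) && all(bp$T_rep >= 0))
  # draws without latent states are rejected
  fit$z <- NULL
  expect_error(bayes_pvalue(fit), "save_z")
})
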