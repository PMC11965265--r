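# a minimal fake fit object for exercising summaries without sampling
fake_fit <- function(chains) {
  nm <- colnames(chains[[1]])
  structure(list(draws = chains, param_names = nm, n_save = nrow(chains[[1]])),
            class = "occu_fit")
}

test_that("latent initialization is maximal and consistent with detections", {
  y <- array(0L, c(3, 2, 2, 2))
  z <- init_latent(y)
  expect_true(all(z == 1))
  y[2, 1, 1, 2] <- 1L
  expect_true(all(init_latent(y) == 1)) # maximal init covers detections
})

test_that("latent full conditional matches the hand-derived Bernoulli probability", {
  # one site/visit/year, psi = 0.5, p = 0.5, y = 0:
  # P(z=1 | y=0) = psi (1-p) / (psi (1-p) + (1-psi)) = 1/3
  design <- make_design(I = 1, J = 1, K = 1, T = 1)
  pp <- species_params(beta0 = 0, beta = matrix(0, 1, 0), phi = NULL,
                       alpha0 = matrix(0, 1, 1))
  y <- array(0L, c(1, 1, 1, 1))
  x <- array(0, c(1, 0, 1))
  set.seed(31)
  n <- 10000
  draws <- replicate(n, update_z(y, pp, x, array(1L, c(1, 1, 1)), design)[1, 1, 1])
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(mean(draws) - 1 / 3), 3 * se)
})

test_that("latent full conditional accounts for the following year's persistence", {
  # T=2, no covariates: P(z1 | y1=0, z2) by direct Bayes enumeration
  design <- make_design(I = 1, J = 1, K = 1, T = 2)
  pp <- species_params(beta0 = 0.2, beta = matrix(0, 1, 0), phi = 1.2,
                       alpha0 = matrix(-0.4, 1, 2))
  x <- array(0, c(1, 0, 2))
  y <- array(c(0L, NA), c(1, 1, 1, 2)) # year 2 unobserved
  psi1 <- plogis(0.2); p <- plogis(-0.4)
  for (z2 in 0:1) {
    num <- psi1 * (1 - p) * dbinom(z2, 1, plogis(0.2 + 1.2))
    den <- num + (1 - psi1) * dbinom(z2, 1, plogis(0.2))
    target <- num / den
    set.seed(32 + z2)
    z0 <- array(c(1L, z2), c(1, 1, 2))
    draws <- replicate(4000, {
      # freeze year 2 at z2: only read z1 from the sweep
      update_z(y, pp, x, z0, design)[1, 1, 1]
    })
    se <- sqrt(target * (1 - target) / 4000)
    expect_lt(abs(mean(draws) - target), 4 * se)
  }
})

test_that("near-perfect detection makes undetected cells unoccupied", {
  design <- make_design(I = 1, J = 2, K = 1, T = 1)
  pp <- species_params(beta0 = 0, beta = matrix(0, 1, 0), phi = NULL,
                       alpha0 = matrix(10, 1, 1))
  y <- array(0L, c(1, 2, 1, 1))
  x <- array(0, c(1, 0, 1))
  set.seed(33)
  draws <- replicate(300, update_z(y, pp, x, array(1L, c(1, 1, 1)), design)[1])
  expect_lt(mean(draws), 0.01)
  # and a detection pins the cell at occupied
  y[1, 1, 1, 1] <- 1L
  draws <- replicate(50, update_z(y, pp, x, array(0L, c(1, 1, 1)), design)[1])
  expect_true(all(draws == 1))
})

test_that("fits are reproducible under a fixed seed and differ across seeds", {
  sim <- gen_dataset(sim_config(design = make_design(I = 20, J = 3, K = 3, T = 2),
                                seed = 44, occ_covariates = "orthoptera"))
  f <- occu_formula("orthoptera", guild = "insectivore")
  cfg <- mcmc_config(n_chains = 2, n_iter = 400, n_burnin = 200, thin = 2,
                     seed = 5)
  fit1 <- fit_occu(sim$detections, sim$covariates, f, config = cfg)
  fit2 <- fit_occu(sim$detections, sim$covariates, f, config = cfg)
  expect_identical(fit1$draws, fit2$draws)
  cfg3 <- mcmc_config(n_chains = 2, n_iter = 400, n_burnin = 200, thin = 2,
                      seed = 6)
  fit3 <- fit_occu(sim$detections, sim$covariates, f, config = cfg3)
  expect_false(identical(fit1$draws, fit3$draws))
})

test_that("posterior summaries: quantile intervals, R-hat conventions, monotone levels", {
  set.seed(51)
  m1 <- matrix(rnorm(4000), ncol = 2,
               dimnames = list(NULL, c("a", "const")))
  m1[, "const"] <- 7
  m2 <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "const")))
  m2[, "const"] <- 7
  fit <- fake_fit(list(m1, m2))
  s <- summarize_fit(fit, level = 0.85)
  # standard-normal draws: 85% interval ~ (-1.44, 1.44)
  row_a <- s[s$term == "a", ]
  expect_equal(row_a$lower, qnorm(0.075), tolerance = 0.08)
  expect_equal(row_a$upper, qnorm(0.925), tolerance = 0.08)
  expect_lt(row_a$rhat, 1.02)
  # constant draws: point mass, R-hat 1 by convention
  row_c <- s[s$term == "const", ]
  expect_equal(row_c$mean, 7)
  expect_equal(row_c$lower, 7)
  expect_equal(row_c$upper, 7)
  expect_equal(row_c$rhat, 1)
  # widening the level never narrows an interval
  s95 <- summarize_fit(fit, level = 0.95)
  expect_true(all(s95$lower <= s$lower + 1e-12))
  expect_true(all(s95$upper >= s$upper - 1e-12))
  expect_error(summarize_fit(fit, level = 1.2), "level")
  # split-chain R-hat flags disagreeing chains
  m3 <- m1; m3[, "a"] <- m3[, "a"] + 5
  s_bad <- summarize_fit(fake_fit(list(m1, m3)))
  expect_gt(s_bad$rhat[s_bad$term == "a"], 1.5)
})

test_that("degenerate proposals freeze the chain; adapted acceptance lands in the band", {
  sim <- gen_dataset(sim_config(design = make_design(I = 30, J = 4, K = 4, T = 2),
                                seed = 45, occ_covariates = "orthoptera"))
  f <- occu_formula("orthoptera", guild = "insectivore")
  frozen <- fit_occu(sim$detections, sim$covariates, f,
                     config = mcmc_config(n_chains = 1, n_iter = 200,
                                          n_burnin = 100, thin = 1, seed = 2,
                                          init_proposal_scale = 1e-12,
                                          adapt = FALSE))
  v <- draws_of(frozen, frozen$param_names[1])
  expect_equal(var(v), 0) # proposal scale ~ 0: no movement
  expect_gt(mean(unlist(frozen$accept), na.rm = TRUE), 0.97)

  adapted <- fit_occu(sim$detections, sim$covariates, f,
                      config = mcmc_config(n_chains = 1, n_iter = 3000,
                                           n_burnin = 1500, thin = 5, seed = 3))
  acc <- unlist(adapted$accept)
  acc <- acc[!is.na(acc)]
  # bulk of the per-block acceptance rates inside the target band
  expect_gt(mean(acc >= 0.2 & acc <= 0.55), 0.9)
})

test_that("model construction rejects random effects for a one-species guild", {
  d <- make_design(I = 4, J = 2, K = 1, T = 1)
  sim <- gen_dataset(sim_config(design = d, seed = 1,
                                occ_covariates = character()))
  f <- occu_formula(character(), guild = "insectivore", effects = "random")
  expect_error(fit_occu(sim$detections, sim$covariates, f,
                        config = mcmc_config(n_chains = 1, n_iter = 20,
                                             n_burnin = 10)),
               "2 species")
})
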