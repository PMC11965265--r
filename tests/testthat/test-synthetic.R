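test_that("generated covariates reproduce the inside/outside contrast structure", {
  cfg <- sim_config(seed = 5)
  covs <- gen_covariates(cfg)
  strat <- cfg$design$sites$stratum[match(covs$site, cfg$design$sites$site)]
  inside <- strat == "inside"
  expect_gt(mean(covs$orthoptera[inside]), mean(covs$orthoptera[!inside]))
  expect_gt(mean(covs$forb[inside]), mean(covs$forb[!inside]))
  expect_lt(mean(covs$grass[inside]), mean(covs$grass[!inside]))
  expect_true(all(covs$dist_solar[inside] == 0))
  expect_true(all(covs$dist_solar[!inside] > 0))
  # distances stay within their stratum bands
  for (band in list(c("out_0_400", 1, 400), c("out_1201_1600", 1201, 1600))) {
    d <- covs$dist_solar[strat == band[1]]
    expect_true(all(d >= as.numeric(band[2]) & d <= as.numeric(band[3])))
  }
})

test_that("zero stratum sds give covariates exactly at the stratum means", {
  cm <- list(orthoptera = list(inside = c(30, 0), outside = c(15, 0)),
             grass = list(inside = c(18, 0), outside = c(40, 0)),
             forb = list(inside = c(25, 0), outside = c(10, 0)))
  covs <- gen_covariates(sim_config(seed = 2, covariate_model = cm))
  strat <- attr(covs, "design")$sites$stratum[
    match(covs$site, attr(covs, "design")$sites$site)]
  expect_true(all(covs$orthoptera[strat == "inside"] == 30))
  expect_true(all(covs$orthoptera[strat != "inside"] == 15))
  expect_true(all(covs$grass[strat != "inside"] == 40))
})

test_that("the generator is seed-deterministic and seed-sensitive", {
  a <- gen_dataset(sim_config(seed = 9))
  b <- gen_dataset(sim_config(seed = 9))
  c <- gen_dataset(sim_config(seed = 10))
  expect_identical(a$detections, b$detections)
  expect_identical(a$covariates$orthoptera, b$covariates$orthoptera)
  expect_identical(a$truth$params$beta0, b$truth$params$beta0)
  expect_false(identical(a$detections$y, c$detections$y))
})

test_that("detections respect the latent states", {
  sim <- gen_dataset(sim_config(seed = 3))
  y <- detection_array(sim$detections)
  z <- sim$truth$z_true
  # z = 0 forces y = 0 at every visit
  for (t in 1:2) {
    zero <- which(z[, , t] == 0, arr.ind = TRUE)
    ysub <- apply(y[, , , t], c(1, 3), max)
    expect_true(all(ysub[zero] == 0))
  }
})

test_that("near-perfect detection records every occupied cell", {
  d <- make_design(I = 10, J = 3, K = 2, T = 2)
  cfg <- sim_config(
    design = d, seed = 4, occ_covariates = character(),
    community = list(mu_alpha = c(12, 12), sigma_alpha = 1e-6)
  )
  sim <- gen_dataset(cfg)
  y <- detection_array(sim$detections)
  agg <- apply(y, c(1, 3, 4), max)
  expect_equal(agg, array(sim$truth$z_true,
                          dim(sim$truth$z_true),
                          dimnames = dimnames(agg)),
               ignore_attr = TRUE)
})

test_that("single-visit detection frequency matches the closed form psi * p", {
  # psi = 0.5 (beta0 = 0, no covariates), p = 0.5 -> P(y=1) = 0.25
  d <- make_design(I = 10000, J = 1, K = 1, T = 1)
  cfg <- sim_config(
    design = d, seed = 8, occ_covariates = character(),
    community = list(mu_beta0 = 0, sigma_beta0 = 1e-9,
                     mu_alpha = 0, sigma_alpha = 1e-9,
                     mu_phi = 0, sigma_phi = 1e-9)
  )
  sim <- gen_dataset(cfg)
  phat <- mean(sim$detections$y)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(phat - 0.25), 3 * se)
})

test_that("year-1 occupancy frequency matches the covariate model at large I", {
  d <- make_design(I = 10000, J = 1, K = 1, T = 1)
  cfg <- sim_config(
    design = d, seed = 12, occ_covariates = "orthoptera",
    community = list(mu_beta0 = -0.3, sigma_beta0 = 1e-9,
                     mu_beta = c(orthoptera = 0.8), sigma_beta = 1e-9,
                     mu_phi = 0, sigma_phi = 1e-9)
  )
  sim <- gen_dataset(cfg)
  xs <- scale_covariates(sim$covariates)
  target <- mean(plogis(-0.3 + 0.8 * xs$orthoptera))
  got <- mean(sim$truth$z_true)
  se <- sqrt(target * (1 - target) / 10000)
  expect_lt(abs(got - target), 3 * se)
})

test_that("positive persistence raises year-2 occupancy for previously occupied sites", {
  d <- make_design(I = 4000, J = 1, K = 1, T = 2)
  cfg <- sim_config(
    design = d, seed = 13, occ_covariates = character(),
    community = list(mu_beta0 = 0, sigma_beta0 = 1e-9, mu_phi = 1.5,
                     sigma_phi = 1e-9)
  )
  sim <- gen_dataset(cfg)
  z <- sim$truth$z_true
  p11 <- mean(z[z[, 1, 1] == 1, 1, 2])
  p01 <- mean(z[z[, 1, 1] == 0, 1, 2])
  expect_gt(p11, p01)
  expect_equal(p11, plogis(1.5), tolerance = 0.05)
  expect_equal(p01, 0.5, tolerance = 0.05)
})

test_that("the misspecified generator adds site-level detection heterogeneity", {
  base <- gen_dataset(sim_config(seed = 21))
  noisy <- gen_dataset(sim_config(seed = 21, det_noise_sd = 2))
  # same latent process (same seed up to the noise draw), different detections
  expect_false(identical(base$detections$y, noisy$detections$y))
  expect_equal(noisy$truth$det_noise_sd, 2)
})
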