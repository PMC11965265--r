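test_that("occupancy probabilities follow the logit model with persistence offset", {
  p0 <- species_params(beta0 = 0, beta = matrix(0, 1, 0), phi = 2,
                       alpha0 = matrix(0, 1, 1))
  x <- matrix(numeric(0), 3, 0)
  expect_equal(occupancy_probs(p0, x)[, 1], rep(0.5, 3))
  # previous-year occupancy shifts the logit by phi
  zprev <- matrix(c(1, 0, 1), 3, 1)
  psi <- occupancy_probs(p0, x, z_prev = zprev)
  expect_equal(psi[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(psi[2, 1], 0.5)
  # monotone in a covariate with positive coefficient
  p1 <- species_params(beta0 = 0, beta = matrix(1.3, 1, 1), phi = NULL,
                       alpha0 = matrix(0, 1, 1))
  xs <- matrix(seq(-2, 2, length.out = 7), 7, 1)
  expect_true(all(diff(occupancy_probs(p1, xs)[, 1]) > 0))
})

test_that("detection probabilities use species-and-year intercepts", {
  design <- make_design(I = 2, J = 3, K = 1, T = 2)
  pp <- species_params(beta0 = 0, beta = matrix(0, 1, 0), phi = 0,
                       alpha0 = matrix(c(0, -1.25), 1, 2))
  p <- detection_probs(pp, design)
  expect_equal(unique(as.numeric(p[, , 1, 1])), 0.5)
  # a logit-scale intercept of -1.25 gives p ~ 0.2227
  expect_equal(unique(as.numeric(p[, , 1, 2])), plogis(-1.25))
  expect_equal(round(plogis(-1.25), 4), 0.2227)
})

test_that("complete-data log-likelihood matches hand-evaluated cases", {
  design <- make_design(I = 1, J = 1, K = 1, T = 1)
  pp <- species_params(beta0 = 0, beta = matrix(0, 1, 0), phi = NULL,
                       alpha0 = matrix(0, 1, 1))
  p <- detection_probs(pp, design)
  psi <- array(0.5, c(1, 1, 1))
  y1 <- array(1L, c(1, 1, 1, 1))
  z1 <- array(1L, c(1, 1, 1))
  # z=1 (psi=0.5) then y=1 (p=0.5): log(0.5) + log(0.5)
  expect_equal(complete_data_loglik(y1, z1, psi, p), log(0.5) + log(0.5),
               tolerance = 1e-12)
  # z=0, y=0: log(1-psi) + log(1)
  y0 <- array(0L, c(1, 1, 1, 1))
  z0 <- array(0L, c(1, 1, 1))
  expect_equal(complete_data_loglik(y0, z0, psi, p), log(0.5), tolerance = 1e-12)
  # inconsistent augmentation: detection at unoccupied cell
  expect_equal(complete_data_loglik(y1, z0, psi, p), -Inf)
  # all-missing data: only process terms remain
  ym <- array(NA_integer_, c(1, 1, 1, 1))
  expect_equal(complete_data_loglik(ym, z1, psi, p), log(0.5))
})

test_that("marginal likelihood equals direct enumeration on a hand case", {
  # T=1, J=2, psi=0.5, p=0.5, y=(0,0): 0.5*0.25 + 0.5*1
  design <- make_design(I = 1, J = 2, K = 1, T = 1)
  pp <- species_params(beta0 = 0, beta = matrix(0, 1, 0), phi = NULL,
                       alpha0 = matrix(0, 1, 1))
  y <- array(0L, c(1, 2, 1, 1))
  x <- array(0, c(1, 0, 1))
  expect_equal(marginal_loglik(y, pp, x, design), log(0.625), tolerance = 1e-12)
  # a detection forces the occupied branch
  y[1, 1, 1, 1] <- 1L
  expect_equal(marginal_loglik(y, pp, x, design), log(0.5 * 0.5 * 0.5),
               tolerance = 1e-12)
})

test_that("forward recursion equals brute-force enumeration on random instances", {
  set.seed(401)
  for (rep in 1:120) {
    inst <- random_instance(I = sample(1:3, 1), J = sample(1:3, 1),
                            K = sample(1:2, 1), T = sample(1:3, 1))
    got <- marginal_loglik(inst$y, inst$params, inst$x, inst$design)
    want <- enum_marginal(inst$y, inst$params, inst$x, inst$design)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("marginal likelihood dominates any consistent complete-data likelihood", {
  set.seed(402)
  for (rep in 1:25) {
    inst <- random_instance(I = 2, J = 2, K = 1, T = 2)
    y <- inst$y
    z <- array(1L, dim(y)[c(1, 3, 4)]) # maximal z is always consistent
    p <- detection_probs(inst$params, inst$design)
    psi <- array(NA_real_, dim(z))
    C <- ncol(inst$params$beta)
    for (t in seq_len(dim(z)[3])) {
      xt <- matrix(inst$x[, seq_len(C), t], dim(y)[1], C)
      zprev <- if (t > 1) z[, , t - 1, drop = FALSE][, , 1] else NULL
      if (!is.null(zprev)) zprev <- matrix(zprev, dim(y)[1], dim(z)[2])
      psi[, , t] <- occupancy_probs(inst$params, xt, z_prev = zprev)
    }
    expect_gte(marginal_loglik(y, inst$params, inst$x, inst$design),
               complete_data_loglik(y, z, psi, p) - 1e-12)
  }
})

test_that("with near-perfect detection the marginal reduces to the observed process", {
  # p -> 1: non-detection implies unoccupied, so the marginal approaches
  # the likelihood of the directly observed occupancy sequence
  design <- make_design(I = 1, J = 1, K = 1, T = 2)
  pp <- species_params(beta0 = 0.3, beta = matrix(0, 1, 0), phi = 1,
                       alpha0 = matrix(12, 1, 2)) # p ~ 1 - 6e-6
  x <- array(0, c(1, 0, 2))
  y <- array(c(1L, 0L), c(1, 1, 1, 2)) # occupied year 1, absent year 2
  psi1 <- plogis(0.3)
  closed <- log(psi1 * plogis(12)) + log(1 - plogis(0.3 + 1))
  expect_equal(marginal_loglik(y, pp, x, design), closed, tolerance = 1e-4)
})
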