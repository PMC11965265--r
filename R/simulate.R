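#' Configuration for the synthetic-data generator
#'
#' The generator emulates the distance-stratified study design: 100 plots
#' (20 inside the facility, 20 in each of four outside distance bins), two
#' seasons of four visits, six insectivores whose effects are drawn from
#' community normal distributions and two synanthropic species with fixed
#' species-level parameters. Covariates are generated on their natural
#' scales with an inside/outside contrast matching the observed sign
#' structure -- orthopteran abundance and forb cover higher inside the
#' facility, grass cover higher outside, distance zero inside -- and are
#' centered/scaled by the same code path the real-data pipeline uses, so
#' the true effects are per-standard-deviation logit-scale coefficients.
#'
#' @param design A [survey_design()].
#' @param seed Integer seed; fully determines the output.
#' @param occ_covariates Covariates that truly affect occupancy (the
#'   generating model), default `dist_solar + orthoptera + forb`.
#' @param community True community hyperparameters for the insectivore
#'   guild: `mu_beta0, sigma_beta0`, named `mu_beta` (over
#'   `occ_covariates`), `sigma_beta`, `mu_alpha` (per year), `sigma_alpha`,
#'   `mu_phi, sigma_phi`. All sigmas must be > 0.
#' @param fixed True parameters for each synanthropic species: a named list
#'   of lists with `beta0`, `beta` (named over `occ_covariates`), `phi`,
#'   `alpha0` (per year).
#' @param covariate_model Per-stratum generating means/sds for each
#'   covariate (see defaults in the source).
#' @param det_noise_sd Standard deviation of site-level random effects
#'   added to the logit of detection probability. The default 0 matches
#'   the fitted model; positive values give a deliberately misspecified
#'   (extra-binomial) generator for posterior predictive checking.
#' @param missing_prob Probability a visit record is dropped (missing), 0
#'   by default.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(design = default_design(), seed = 1,
                       occ_covariates = c("dist_solar", "orthoptera", "forb"),
                       community = list(), fixed = NULL,
                       covariate_model = NULL, det_noise_sd = 0,
                       missing_prob = 0) {
  T <- design$n_years
  com <- utils::modifyList(list(
    mu_beta0 = 0, sigma_beta0 = 1,
    mu_beta = stats::setNames(c(1, 1.5, -0.75),
                              c("dist_solar", "orthoptera", "forb")),
    sigma_beta = 0.5,
    mu_alpha = rep(-1.5, T), sigma_alpha = 1,
    mu_phi = 1, sigma_phi = 0.5
  ), community)
  com$mu_beta <- com$mu_beta[occ_covariates]
  if (anyNA(com$mu_beta)) {
    com$mu_beta[is.na(com$mu_beta)] <- 0
    names(com$mu_beta) <- occ_covariates
  }
  sig <- c(com$sigma_beta0, com$sigma_beta, com$sigma_alpha, com$sigma_phi)
  if (any(sig <= 0)) stop("sigma hyperparameters must be > 0", call. = FALSE)
  if (is.null(covariate_model)) {
    covariate_model <- list(
      orthoptera = list(inside = c(30, 6), outside = c(15, 6)),
      grass = list(inside = c(18, 8), outside = c(40, 8)),
      forb = list(inside = c(25, 5), outside = c(10, 5))
    )
  }
  if (is.null(fixed)) {
    syn <- design$species$species[design$species$guild == "synanthropic"]
    fixed <- stats::setNames(lapply(seq_along(syn), function(s) {
      list(beta0 = -2 - 0.5 * (s - 1),
           beta = stats::setNames(rep(0, length(occ_covariates)), occ_covariates),
           phi = 1.5, alpha0 = rep(-1, T))
    }), syn)
  }
  structure(
    list(design = design, seed = as.integer(seed),
         occ_covariates = occ_covariates, community = com, fixed = fixed,
         covariate_model = covariate_model, det_noise_sd = det_noise_sd,
         missing_prob = missing_prob),
    class = "sim_config"
  )
}

#' Generate site-by-year covariates
#'
#' Distance to the facility edge is 0 for inside sites and uniform within
#' each outside stratum's distance band; orthopteran abundance (count,
#' truncated at zero) and percent grass/forb cover (clamped to 0-100) are
#' normal draws around stratum means, redrawn each year. With stratum sds
#' set to zero the covariates equal the stratum means exactly.
#'
#' @param config A [sim_config()].
#' @return An unscaled `covariate_table`.
#' @export
gen_covariates <- function(config) {
  set.seed(config$seed)
  gen_covariates_impl(config)
}

gen_covariates_impl <- function(config) {
  design <- config$design
  bands <- list(out_0_400 = c(1, 400), out_401_800 = c(401, 800),
                out_801_1200 = c(801, 1200), out_1201_1600 = c(1201, 1600))
  strat <- design$sites$stratum
  n <- design$n_sites
  dist <- numeric(n)
  for (s in names(bands)) {
    idx <- strat == s
    dist[idx] <- stats::runif(sum(idx), bands[[s]][1], bands[[s]][2])
  }
  draw <- function(spec) {
    m <- ifelse(strat == "inside", spec$inside[1], spec$outside[1])
    s <- ifelse(strat == "inside", spec$inside[2], spec$outside[2])
    stats::rnorm(n, m, s)
  }
  rows <- purrr::map_dfr(design$years, function(yr) {
    tibble::tibble(
      site = design$sites$site, year = yr,
      dist_solar = round(dist, 1),
      orthoptera = pmax(0, round(draw(config$covariate_model$orthoptera))),
      grass = pmin(100, pmax(0, round(draw(config$covariate_model$grass), 1))),
      forb = pmin(100, pmax(0, round(draw(config$covariate_model$forb), 1)))
    )
  })
  as_covariates(rows, design)
}

#' Generate a full synthetic dataset with retained truth
#'
#' Draws covariates, species-level parameters (community normals for the
#' insectivore guild, fixed values for the synanthropic guild), latent
#' occupancy states (year 1 from the covariate model, later years with the
#' auto-logistic persistence term), and detection histories, all under the
#' configured seed. The generating parameter values and latent states are
#' returned alongside the data for recovery testing.
#'
#' @param config A [sim_config()].
#' @return A list with `detections` (long tibble over all cells),
#'   `covariates` (unscaled `covariate_table`), and `truth` (species
#'   parameters per guild, `z_true`, and the config).
#' @export
gen_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- config$design
  covs <- gen_covariates_impl(config)
  scaled <- scale_covariates(covs)
  x <- covariate_array(scaled, config$occ_covariates)
  I <- design$n_sites; J <- design$n_visits; T <- design$n_years
  C <- length(config$occ_covariates)
  sp <- design$species
  K <- nrow(sp)
  com <- config$community

  beta0 <- numeric(K); phi <- numeric(K)
  beta <- matrix(0, K, C, dimnames = list(sp$species, config$occ_covariates))
  alpha0 <- matrix(0, K, T)
  sig_beta <- rep(com$sigma_beta, length.out = C)
  sig_alpha <- rep(com$sigma_alpha, length.out = T)
  for (k in seq_len(K)) {
    if (sp$guild[k] == "insectivore") {
      beta0[k] <- stats::rnorm(1, com$mu_beta0, com$sigma_beta0)
      if (C) beta[k, ] <- stats::rnorm(C, com$mu_beta, sig_beta)
      phi[k] <- stats::rnorm(1, com$mu_phi, com$sigma_phi)
      alpha0[k, ] <- stats::rnorm(T, com$mu_alpha, sig_alpha)
    } else {
      fx <- config$fixed[[sp$species[k]]]
      if (is.null(fx)) stop("no fixed truth for ", sp$species[k], call. = FALSE)
      beta0[k] <- fx$beta0
      if (C) beta[k, ] <- fx$beta[config$occ_covariates]
      phi[k] <- fx$phi
      alpha0[k, ] <- fx$alpha0
    }
  }
  params <- species_params(beta0, beta, phi, alpha0)

  z <- array(0L, c(I, K, T))
  psi <- array(NA_real_, c(I, K, T))
  for (t in seq_len(T)) {
    xt <- matrix(x[, seq_len(C), t], I, C)
    zprev <- if (t > 1) z[, , t - 1] else NULL
    psi[, , t] <- occupancy_probs(params, xt, z_prev = zprev)
    z[, , t] <- array(stats::rbinom(I * K, 1, psi[, , t]), c(I, K))
  }

  u_site <- if (config$det_noise_sd > 0) {
    stats::rnorm(I, 0, config$det_noise_sd)
  } else {
    rep(0, I)
  }
  cells <- tidyr::crossing(year_i = seq_len(T), visit = seq_len(J),
                           k = seq_len(K), i = seq_len(I))
  pdet <- clamp_prob(stats::plogis(
    alpha0[cbind(cells$k, cells$year_i)] + u_site[cells$i]))
  zz <- z[cbind(cells$i, cells$k, cells$year_i)]
  yv <- stats::rbinom(nrow(cells), 1, pdet * zz)
  det <- tibble::tibble(
    site = design$sites$site[cells$i],
    year = design$years[cells$year_i],
    visit = cells$visit,
    species = sp$species[cells$k],
    y = as.integer(yv)
  )
  if (config$missing_prob > 0) {
    det <- det[stats::runif(nrow(det)) >= config$missing_prob, , drop = FALSE]
  }
  det <- dplyr::arrange(det, .data$site, .data$year, .data$visit, .data$species)
  attr(det, "design") <- design
  truth <- list(
    params = params,
    species = sp,
    community = com,
    occ_covariates = config$occ_covariates,
    z_true = z, psi_true = psi,
    det_noise_sd = config$det_noise_sd,
    config = config
  )
  list(detections = det, covariates = covs, truth = truth)
}

#' @rdname gen_dataset
#' @param ... Passed to [sim_config()].
#' @export
sim_dataset <- function(...) gen_dataset(sim_config(...))
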