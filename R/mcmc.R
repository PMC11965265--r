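#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler. Proposal scales are
#' tuned adaptively during burn-in (toward an acceptance band around
#' `target_accept`) and frozen afterward, so the retained draws come from a
#' valid time-homogeneous chain. Priors are vague: Normal(0, `mu_sd`) for
#' community means and fixed-effect coefficients, Uniform(0, `sigma_upper`)
#' for community standard deviations.
#'
#' @param n_chains Number of chains (>= 2 for R-hat).
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burnin Burn-in iterations discarded (and used for adaptation).
#' @param thin Thinning interval for saved draws.
#' @param seed Integer seed; chain c runs under `seed + 1000 * c`.
#' @param target_accept Mid-point of the desired acceptance band
#'   (0.30-0.45 by default).
#' @param init_proposal_scale Initial random-walk proposal sd.
#' @param adapt,adapt_interval Adapt proposal scales during burn-in, every
#'   `adapt_interval` iterations.
#' @param mu_sd,fixed_sd,sigma_upper Prior constants (see above).
#' @param save_z Keep latent-state draws (needed for DIC and posterior
#'   predictive checks; on by default).
#' @param separate_first_year Fit a separate first-year occupancy intercept
#'   instead of sharing one intercept across years (default shared).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 20000, n_burnin = 10000,
                        thin = 10, seed = 1, target_accept = 0.375,
                        init_proposal_scale = 0.5, adapt = TRUE,
                        adapt_interval = 50, mu_sd = 10, fixed_sd = 10,
                        sigma_upper = 5, save_z = TRUE,
                        separate_first_year = FALSE) {
  stopifnot(n_burnin < n_iter, thin >= 1, n_chains >= 1,
            init_proposal_scale > 0, mu_sd > 0, fixed_sd > 0,
            sigma_upper > 0, target_accept > 0, target_accept < 1)
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         n_burnin = as.integer(n_burnin), thin = as.integer(thin),
         seed = as.integer(seed), target_accept = target_accept,
         init_proposal_scale = init_proposal_scale, adapt = adapt,
         adapt_interval = as.integer(adapt_interval), mu_sd = mu_sd,
         fixed_sd = fixed_sd, sigma_upper = sigma_upper, save_z = save_z,
         separate_first_year = separate_first_year),
    class = "mcmc_config"
  )
}

# column names matching the C++ draw layout
param_names <- function(formula, gdesign, config) {
  sp <- gdesign$species$species
  yrs <- gdesign$years
  sep <- config$separate_first_year
  auto <- formula$autologistic
  nm <- character(0)
  for (s in sp) {
    nm <- c(nm, sprintf("beta0[%s]", s))
    if (sep) nm <- c(nm, sprintf("beta0_first[%s]", s))
    if (length(formula$occ)) {
      nm <- c(nm, sprintf("beta[%s,%s]", s, formula$occ))
    }
    if (auto) nm <- c(nm, sprintf("phi[%s]", s))
    nm <- c(nm, sprintf("alpha0[%s,%d]", s, yrs))
  }
  if (length(formula$det)) nm <- c(nm, sprintf("alpha_det[%s]", formula$det))
  if (formula$effects == "random") {
    nm <- c(nm, "mu_beta0", "sigma_beta0")
    if (sep) nm <- c(nm, "mu_beta0_first", "sigma_beta0_first")
    if (length(formula$occ)) {
      nm <- c(nm, as.vector(rbind(sprintf("mu_beta[%s]", formula$occ),
                                  sprintf("sigma_beta[%s]", formula$occ))))
    }
    if (auto) nm <- c(nm, "mu_phi", "sigma_phi")
    nm <- c(nm, as.vector(rbind(sprintf("mu_alpha[%d]", yrs),
                                sprintf("sigma_alpha[%d]", yrs))))
  }
  nm
}

#' Fit the multispecies auto-logistic occupancy model
#'
#' Runs the Metropolis-within-Gibbs sampler with latent-state data
#' augmentation: latent occupancy states are drawn from their Bernoulli
#' full conditionals each iteration, species-level effects are updated by
#' adaptive random-walk Metropolis under community normal priors (random
#' guild) or vague normal priors (fixed guild), community means by
#' conjugate normal draws, and community sds by Metropolis on the log
#' scale. Chains run under independent seeds derived from `config$seed`.
#'
#' @param detections Long detection tibble ([read_detections()] /
#'   [sim_dataset()]).
#' @param covariates A `covariate_table`; scaled internally if not already.
#' @param formula An [occu_formula()].
#' @param design Full [survey_design()]; defaults to the one attached to
#'   `detections`. The fit uses the species of `formula$guild`.
#' @param config An [mcmc_config()].
#' @param exclude Species codes to drop from the guild (e.g. granivores
#'   from the insectivore set).
#' @return An object of class `occu_fit`.
#' @export
fit_occu <- function(detections, covariates, formula,
                     design = attr(detections, "design"),
                     config = mcmc_config(), exclude = character()) {
  stopifnot(inherits(formula, "occu_formula"), inherits(config, "mcmc_config"))
  gdesign <- design_for_guild(design, formula$guild, exclude)
  if (formula$effects == "random" && gdesign$n_species < 2) {
    stop("random-effects structure needs >= 2 species; use effects = 'fixed'",
         call. = FALSE)
  }
  covariates <- scale_covariates(covariates)
  bad <- setdiff(c(formula$occ, formula$det), attr(covariates, "covariates"))
  if (length(bad)) {
    stop("formula covariate(s) not in table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  y <- detection_array(detections, gdesign)
  x <- covariate_array(covariates, formula$occ)
  # no detection covariates vary by visit in the covariate table; replicate
  # site-year values across visits when detection covariates are requested
  xdet <- NULL
  if (length(formula$det)) {
    xs <- covariate_array(covariates, formula$det)
    xdet <- array(0, c(gdesign$n_sites, gdesign$n_visits, length(formula$det),
                       gdesign$n_years))
    for (j in seq_len(gdesign$n_visits)) xdet[, j, , ] <- xs
  }
  fit_occu_arrays(y, x, xdet, formula, gdesign, config,
                  covariates = covariates)
}

# internal: fit from prepared arrays (also used for prior-only runs)
fit_occu_arrays <- function(y, x, xdet, formula, gdesign, config,
                            covariates = NULL) {
  dims <- c(gdesign$n_sites, gdesign$n_visits, gdesign$n_species,
            gdesign$n_years, length(formula$occ), length(formula$det))
  xd <- if (is.null(xdet)) numeric(0) else as.numeric(xdet)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000L * ch)
    chains[[ch]] <- .run_chain_cpp(
      as.integer(y), as.numeric(x), xd, as.integer(dims),
      formula$effects == "random", formula$autologistic,
      config$separate_first_year, config$n_iter, config$n_burnin,
      config$thin, config$mu_sd, config$fixed_sd, config$sigma_upper,
      config$init_proposal_scale, config$adapt, config$adapt_interval,
      config$target_accept, config$save_z
    )
  }
  nm <- param_names(formula, gdesign, config)
  draws <- lapply(chains, function(ch) {
    m <- ch$draws
    colnames(m) <- nm
    m
  })
  structure(
    list(
      draws = draws,
      deviance = lapply(chains, `[[`, "deviance"),
      z = if (config$save_z) lapply(chains, `[[`, "z") else NULL,
      z_sum = Reduce(`+`, lapply(chains, `[[`, "z_sum")),
      accept = lapply(chains, `[[`, "accept"),
      n_save = chains[[1]]$n_save,
      param_names = nm,
      formula = formula, design = gdesign, config = config,
      covariates = covariates, y = y, x = x, xdet = xdet
    ),
    class = "occu_fit"
  )
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf(
    "<occu_fit> %s (%s guild, %s effects): %d chains x %d draws, %d parameters\n",
    x$formula$name, x$formula$guild, x$formula$effects,
    length(x$draws), x$n_save, length(x$param_names)
  ))
  invisible(x)
}

#' All saved draws of one parameter, pooled across chains
#'
#' @param fit An `occu_fit`.
#' @param par Parameter name (see `fit$param_names`).
#' @return Numeric vector.
#' @export
draws_of <- function(fit, par) {
  if (!par %in% fit$param_names) stop("unknown parameter: ", par, call. = FALSE)
  unlist(lapply(fit$draws, function(m) m[, par]), use.names = FALSE)
}

# split-chain rank-normalized R-hat
rhat_split <- function(chains) {
  halves <- list()
  for (m in chains) {
    n <- length(m)
    if (n < 4) return(NA_real_)
    halves <- c(halves, list(m[seq_len(n %/% 2)], m[(n %/% 2 + 1):(2 * (n %/% 2))]))
  }
  pooled <- unlist(halves)
  if (stats::sd(pooled) == 0) return(1) # degenerate: constant draws
  r <- rank(pooled, ties.method = "average")
  zall <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  n <- length(halves[[1]])
  zs <- split(zall, rep(seq_along(halves), each = n))
  means <- vapply(zs, mean, numeric(1))
  vars <- vapply(zs, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summaries with credible intervals and R-hat
#'
#' Symmetric-quantile credible intervals at `level` (85% by default, the
#' reporting convention used throughout) and split-chain rank-normalized
#' R-hat per parameter.
#'
#' @param fit An `occu_fit`.
#' @param level Credible level in (0, 1).
#' @return A tibble: `term, mean, sd, lower, upper, rhat`.
#' @export
summarize_fit <- function(fit, level = 0.85) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  purrr::map_dfr(fit$param_names, function(par) {
    per_chain <- lapply(fit$draws, function(m) m[, par])
    v <- unlist(per_chain, use.names = FALSE)
    q <- unname(stats::quantile(v, c(a, 1 - a), type = 7))
    tibble::tibble(
      term = par, mean = mean(v), sd = stats::sd(v),
      lower = q[1], upper = q[2],
      rhat = rhat_split(per_chain)
    )
  })
}

#' Initialize latent occupancy states
#'
#' Maximal initialization: every cell starts occupied, which is consistent
#' with any detection history (a detection forces occupancy; absence never
#' rules it out), so the first likelihood evaluation is finite.
#'
#' @param y I x J x K x T detection array.
#' @return I x K x T 0/1 array.
#' @export
init_latent <- function(y) {
  d <- dim(y)
  array(1L, d[c(1, 3, 4)])
}

#' One Gibbs sweep over the latent occupancy states
#'
#' Reference (R) implementation of the latent-state full conditional used
#' by the sampler: cells with a detection stay occupied; other cells are
#' drawn from Bernoulli full conditionals combining the occupancy prior,
#' the probability of the observed all-zero detection history, and (for
#' years before the last) the auto-logistic term carried by the following
#' year's occupancy.
#'
#' @param y Detection array (I x J x K x T).
#' @param params A [species_params()].
#' @param x Scaled covariate array (I x C x T).
#' @param z Current latent array (I x K x T).
#' @param design A [survey_design()].
#' @return Updated latent array.
#' @export
update_z <- function(y, params, x, z, design) {
  I <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]; T <- dim(y)[4]
  C <- ncol(params$beta)
  p <- detection_probs(params, design)
  for (t in seq_len(T)) {
    for (k in seq_len(K)) {
      for (i in seq_len(I)) {
        yv <- y[i, , k, t]
        if (any(yv == 1, na.rm = TRUE)) { z[i, k, t] <- 1L; next }
        xt <- if (C) x[i, seq_len(C), t] else numeric(0)
        lp <- params$beta0[k] + (if (C) sum(params$beta[k, ] * xt) else 0)
        if (t > 1 && !is.null(params$phi)) {
          lp <- lp + params$phi[k] * z[i, k, t - 1]
        }
        psi <- clamp_prob(stats::plogis(lp))
        a <- psi * prod(1 - p[i, !is.na(yv), k, t])
        b <- 1 - psi
        if (t < T && !is.null(params$phi)) {
          lpn <- params$beta0[k] +
            (if (C) sum(params$beta[k, ] * x[i, seq_len(C), t + 1]) else 0)
          psi1 <- clamp_prob(stats::plogis(lpn + params$phi[k]))
          psi0 <- clamp_prob(stats::plogis(lpn))
          zn <- z[i, k, t + 1]
          a <- a * if (zn == 1) psi1 else 1 - psi1
          b <- b * if (zn == 1) psi0 else 1 - psi0
        }
        z[i, k, t] <- as.integer(stats::runif(1) < a / (a + b))
      }
    }
  }
  z
}
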