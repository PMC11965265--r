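#' Observation-level deviance conditional on the latent states
#'
#' `-2` times the log-likelihood of the detection data given `p * z`,
#' summed over non-missing visits -- the conditional deviance that
#' BUGS-family samplers report for occupancy models. A detection at an
#' unoccupied cell gives infinite deviance.
#'
#' @param y I x J x K x T detection array.
#' @param z I x K x T latent occupancy array.
#' @param params A [species_params()].
#' @param design A [survey_design()].
#' @param det_covars Optional detection covariate array.
#' @return Scalar deviance (0 for empty data).
#' @export
obs_deviance <- function(y, z, params, design, det_covars = NULL) {
  p <- detection_probs(params, design, det_covars)
  ll <- 0
  J <- dim(y)[2]
  for (j in seq_len(J)) {
    yj <- array(y[, j, , ], dim(z))
    pj <- array(p[, j, , ], dim(z))
    keep <- !is.na(yj)
    if (!any(keep)) next
    if (any(keep & yj == 1 & z == 0)) return(Inf)
    pr <- pj * z
    term <- ifelse(yj == 1, log(pr), log1p(-pr))
    ll <- ll + sum(term[keep & z == 1]) # z = 0 cells contribute log(1) = 0
  }
  -2 * ll
}

# posterior means of continuous parameters, as a species_params object
mean_params <- function(fit) {
  m <- colMeans(do.call(rbind, fit$draws))
  f <- fit$formula; d <- fit$design
  K <- d$n_species; T <- d$n_years
  sp <- d$species$species
  get <- function(nms) unname(m[nms])
  beta <- matrix(0, K, length(f$occ))
  for (c_idx in seq_along(f$occ)) {
    beta[, c_idx] <- get(sprintf("beta[%s,%s]", sp, f$occ[c_idx]))
  }
  alpha0 <- matrix(0, K, T)
  for (t in seq_len(T)) alpha0[, t] <- get(sprintf("alpha0[%s,%d]", sp, d$years[t]))
  species_params(
    beta0 = get(sprintf("beta0[%s]", sp)),
    beta = beta,
    phi = if (f$autologistic) get(sprintf("phi[%s]", sp)) else NULL,
    alpha0 = alpha0,
    alpha_det = if (length(f$det)) get(sprintf("alpha_det[%s]", f$det)) else numeric(0),
    beta0_first = if (fit$config$separate_first_year) {
      get(sprintf("beta0_first[%s]", sp))
    } else NULL
  )
}

# per-cell posterior mode of z (majority vote over saved draws)
z_mode <- function(fit) {
  n_tot <- fit$n_save * length(fit$draws)
  zm <- array(as.integer(fit$z_sum / n_tot > 0.5), dim(fit$y)[c(1, 3, 4)])
  # cells with a detection are occupied in every draw; mode handles them
  zm
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`: `Dbar` is the
#' posterior mean of the conditional observation-level deviance (computed
#' per saved draw inside the sampler) and `D(theta_bar)` evaluates the
#' deviance at the posterior means of the continuous parameters with the
#' latent states fixed at their per-cell posterior mode.
#'
#' @param fit An `occu_fit` (with >= 10 saved draws).
#' @return A list with `dic`, `pD`, `Dbar`, `Dhat`.
#' @export
dic <- function(fit) {
  dev <- unlist(fit$deviance, use.names = FALSE)
  if (length(dev) < 10) stop("too few saved draws for DIC (< 10)", call. = FALSE)
  Dbar <- mean(dev)
  Dhat <- obs_deviance(fit$y, z_mode(fit), mean_params(fit), fit$design,
                       fit$xdet)
  pD <- Dbar - Dhat
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Posterior predictive Bayesian p-value
#'
#' For every saved draw, detection data are replicated from the fitted
#' model at that draw (given its latent states), and a Freeman-Tukey
#' discrepancy `T = sum (sqrt(obs) - sqrt(exp))^2` over per-(site, species,
#' year) detection totals is computed for the observed and replicated data.
#' The p-value is the fraction of draws whose replicated discrepancy is at
#' least the observed one; values near 0.5 indicate adequate fit, values
#' near 0 or 1 indicate misfit.
#'
#' @param fit An `occu_fit` fitted with `save_z = TRUE`.
#' @return A list with `p_value` and the discrepancy draws
#'   (`T_obs`, `T_rep`).
#' @export
bayes_pvalue <- function(fit) {
  if (is.null(fit[["z"]])) stop("fit was run with save_z = FALSE", call. = FALSE)
  if (fit$n_save < 1) stop("no saved draws", call. = FALSE)
  y <- fit$y
  I <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]; T <- dim(y)[4]
  d <- fit$design
  # per-cell observed detection totals and visit counts
  nj <- apply(!is.na(y), c(1, 3, 4), sum)
  dsum <- apply(y, c(1, 3, 4), sum, na.rm = TRUE)
  cell_k <- rep(rep(seq_len(K), each = I), T)
  cell_t <- rep(seq_len(T), each = I * K)
  use_det_covars <- length(fit$formula$det) > 0
  T_obs <- T_rep <- numeric(0)
  for (ch in seq_along(fit$draws)) {
    m <- fit$draws[[ch]]
    zc <- fit[["z"]][[ch]]
    a0_cols <- lapply(seq_len(T), function(t) {
      m[, sprintf("alpha0[%s,%d]", d$species$species, d$years[t]), drop = FALSE]
    })
    for (s in seq_len(nrow(m))) {
      zv <- zc[s, ]
      a0 <- vapply(a0_cols, function(mm) mm[s, ], numeric(K))
      a0 <- matrix(a0, K, T)
      if (use_det_covars) {
        ad <- m[s, sprintf("alpha_det[%s]", fit$formula$det)]
        # visit-heterogeneous p: accumulate expectation and replicate per visit
        ev <- yr <- numeric(length(zv))
        for (j in seq_len(J)) {
          lp <- a0[cbind(cell_k, cell_t)]
          for (c_idx in seq_along(ad)) {
            lp <- lp + ad[c_idx] * as.numeric(fit$xdet[, j, c_idx, ])
          }
          pv <- clamp_prob(stats::plogis(lp))
          miss <- is.na(as.numeric(y[, j, , ]))
          ev <- ev + ifelse(miss, 0, pv * zv)
          yr <- yr + ifelse(miss, 0, stats::rbinom(length(zv), 1, pv * zv))
        }
      } else {
        pkt <- clamp_prob(stats::plogis(a0))
        pv <- pkt[cbind(cell_k, cell_t)]
        ev <- zv * pv * as.numeric(nj)
        yr <- stats::rbinom(length(zv), as.numeric(nj), pv * zv)
      }
      T_obs <- c(T_obs, sum((sqrt(as.numeric(dsum)) - sqrt(ev))^2))
      T_rep <- c(T_rep, sum((sqrt(yr) - sqrt(ev))^2))
    }
  }
  list(p_value = mean(T_rep >= T_obs), T_obs = T_obs, T_rep = T_rep)
}

#' Fit and score a candidate model set
#'
#' Fits every formula in `set`, scores each with DIC and the Bayesian
#' p-value, and returns the selection table sorted by DIC with `delta_dic`
#' relative to the best model. A failure in one model is recorded in its
#' row rather than aborting the table.
#'
#' @param detections,covariates,design As in [fit_occu()].
#' @param set List of [occu_formula()] (e.g. [insectivore_model_set()]).
#' @param config An [mcmc_config()].
#' @param exclude Species exclusions passed to [fit_occu()].
#' @param keep_fits Attach the fitted `occu_fit` objects (named by model)
#'   as attribute `"fits"` of the result.
#' @return A tibble: `model, dic, delta_dic, bayes_p, error`.
#' @export
run_model_set <- function(detections, covariates, set,
                          design = attr(detections, "design"),
                          config = mcmc_config(), exclude = character(),
                          keep_fits = FALSE) {
  stopifnot(length(set) >= 1)
  nms <- vapply(set, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate model names in set", call. = FALSE)
  fits <- list()
  rows <- purrr::map(set, function(f) {
    tryCatch({
      fit <- fit_occu(detections, covariates, f, design, config, exclude)
      if (keep_fits) fits[[f$name]] <<- fit
      set.seed(config$seed + 77L) # replicate-data RNG, decoupled from chains
      bp <- bayes_pvalue(fit)
      tibble::tibble(model = f$name, dic = dic(fit)$dic,
                     bayes_p = bp$p_value, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(model = f$name, dic = NA_real_, bayes_p = NA_real_,
                     error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$dic)
  out$delta_dic <- out$dic - min(out$dic, na.rm = TRUE)
  out <- dplyr::select(out, "model", "dic", "delta_dic", "bayes_p", "error")
  if (keep_fits) attr(out, "fits") <- fits
  out
}
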