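#' Species-level parameter bundle
#'
#' Collects species-level parameters of the multispecies auto-logistic
#' occupancy model on the logit scale: occupancy intercepts `beta0` (length
#' K), covariate effects `beta` (K x C), auto-logistic persistence offsets
#' `phi` (length K, or `NULL` when the persistence term is off), detection
#' intercepts `alpha0` (K x T, species by year), and optional shared
#' detection-covariate effects `alpha_det`. An optional separate first-year
#' occupancy intercept `beta0_first` can be supplied; by default the
#' intercept is shared across years.
#'
#' @param beta0 Numeric vector (K).
#' @param beta Numeric matrix (K x C); use a 0-column matrix for the null
#'   model.
#' @param phi Numeric vector (K) or `NULL`.
#' @param alpha0 Numeric matrix (K x T).
#' @param alpha_det Numeric vector (C_det), default empty.
#' @param beta0_first Numeric vector (K) or `NULL` (shared intercept).
#' @return A list of class `species_params`.
#' @export
species_params <- function(beta0, beta, phi, alpha0,
                           alpha_det = numeric(0), beta0_first = NULL) {
  beta <- as.matrix(beta)
  alpha0 <- as.matrix(alpha0)
  K <- length(beta0)
  if (nrow(beta) != K || nrow(alpha0) != K ||
      (!is.null(phi) && length(phi) != K) ||
      (!is.null(beta0_first) && length(beta0_first) != K)) {
    stop("inconsistent species_params dimensions", call. = FALSE)
  }
  vals <- c(beta0, beta, phi, alpha0, alpha_det, beta0_first)
  if (any(!is.finite(vals))) stop("non-finite parameter values", call. = FALSE)
  structure(list(beta0 = beta0, beta = beta, phi = phi, alpha0 = alpha0,
                 alpha_det = alpha_det, beta0_first = beta0_first),
            class = "species_params")
}

# probabilities are kept strictly inside (0,1) so log terms stay finite
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Occupancy probabilities for one year
#'
#' Year 1: `logit(psi) = beta0_k + sum_c beta_kc x_ic`. Later years add the
#' auto-logistic term `phi_k * z[i,k,t-1]`, so occupancy depends on whether
#' the site was occupied the previous season.
#'
#' @param params A [species_params()].
#' @param x Covariate matrix for the year (I x C, scaled); columns must
#'   align with `params$beta`.
#' @param z_prev I x K 0/1 matrix of previous-year occupancy, or `NULL` for
#'   the first year.
#' @param first_year Logical; `TRUE` selects the first-year intercept when a
#'   separate one is present.
#' @return I x K matrix of probabilities in (0, 1).
#' @export
occupancy_probs <- function(params, x, z_prev = NULL, first_year = is.null(z_prev)) {
  x <- as.matrix(x)
  K <- length(params$beta0)
  if (ncol(x) != ncol(params$beta)) {
    stop("covariate columns do not match params$beta", call. = FALSE)
  }
  b0 <- if (first_year && !is.null(params$beta0_first)) {
    params$beta0_first
  } else {
    params$beta0
  }
  lp <- matrix(b0, nrow(x), K, byrow = TRUE)
  if (ncol(x) > 0) lp <- lp + x %*% t(params$beta)
  if (!is.null(z_prev)) {
    if (is.null(params$phi)) stop("z_prev given but params$phi is NULL", call. = FALSE)
    lp <- lp + sweep(as.matrix(z_prev), 2, params$phi, `*`)
  }
  clamp_prob(stats::plogis(lp))
}

#' Detection probabilities
#'
#' `logit(p[i,j,k,t]) = alpha0[k,t] + alpha_det . x_det[i,j,t]`; constant
#' over sites and visits when there are no detection covariates.
#'
#' @param params A [species_params()].
#' @param design A [survey_design()]; `alpha0` must have one column per
#'   year.
#' @param det_covars Optional I x J x C_det x T array of detection
#'   covariates.
#' @return I x J x K x T array of probabilities.
#' @export
detection_probs <- function(params, design, det_covars = NULL) {
  if (ncol(params$alpha0) != design$n_years) {
    stop("alpha0 must have one column per year", call. = FALSE)
  }
  I <- design$n_sites; J <- design$n_visits
  K <- nrow(params$alpha0); T <- design$n_years
  lp <- array(0, c(I, J, K, T))
  for (k in seq_len(K)) for (t in seq_len(T)) {
    lp[, , k, t] <- params$alpha0[k, t]
  }
  if (length(params$alpha_det)) {
    if (is.null(det_covars)) stop("alpha_det set but det_covars missing", call. = FALSE)
    eff <- array(0, c(I, J, T))
    for (c_idx in seq_along(params$alpha_det)) {
      eff <- eff + params$alpha_det[c_idx] * det_covars[, , c_idx, ]
    }
    for (k in seq_len(K)) lp[, , k, ] <- lp[, , k, ] + eff
  }
  clamp_prob(stats::plogis(lp))
}

#' Complete-data log-likelihood
#'
#' Joint log-density of the latent occupancy states and the observations:
#' Bernoulli terms for `z` given `psi` plus, over non-missing visits,
#' Bernoulli terms for `y` given `p * z`. A detection at an unoccupied cell
#' (`y = 1`, `z = 0`) has probability zero and returns `-Inf`.
#'
#' @param y I x J x K x T detection array (`NA` = missing visit).
#' @param z I x K x T 0/1 latent occupancy array.
#' @param psi I x K x T occupancy probability array.
#' @param p I x J x K x T detection probability array.
#' @return Scalar log-likelihood.
#' @export
complete_data_loglik <- function(y, z, psi, p) {
  proc <- sum(z * log(psi) + (1 - z) * log1p(-psi))
  I <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]; T <- dim(y)[4]
  obs <- 0
  for (j in seq_len(J)) {
    yj <- array(y[, j, , ], c(I, K, T))
    pj <- array(p[, j, , ], c(I, K, T))
    keep <- !is.na(yj)
    if (!any(keep)) next
    if (any(keep & yj == 1 & z == 0)) return(-Inf)
    pr <- pj * z
    term <- ifelse(yj == 1, log(pr), log1p(-pr))
    obs <- obs + sum(term[keep])
  }
  proc + obs
}

#' Marginal log-likelihood (latent states summed out)
#'
#' For each (site, species) pair the complete-data likelihood is summed over
#' all latent occupancy sequences `z[1:T]` by a forward recursion that
#' respects the auto-logistic dependence of year t on year t-1; the result
#' is the sum over pairs of the log marginal probabilities of the observed
#' detection histories. Used for likelihood checks and the optional
#' marginal DIC, not inside the sampler (which augments `z`).
#'
#' @inheritParams complete_data_loglik
#' @param params A [species_params()].
#' @param x I x C x T scaled covariate array aligned with `params$beta`.
#' @param det_covars Optional detection covariate array.
#' @param design A [survey_design()] (for dimensions).
#' @return Scalar log marginal likelihood.
#' @export
marginal_loglik <- function(y, params, x, design, det_covars = NULL) {
  I <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]; T <- dim(y)[4]
  C <- ncol(params$beta)
  p <- detection_probs(params, design, det_covars)
  x1 <- matrix(x[, seq_len(C), 1], I, C)
  total <- 0
  for (k in seq_len(K)) {
    psi1 <- occupancy_probs(params, x1, z_prev = NULL)[, k]
    for (i in seq_len(I)) {
      # forward pass over z_t in {0,1}
      f <- c(`0` = NA_real_, `1` = NA_real_)
      obs_lik <- function(t, zval) {
        yv <- y[i, , k, t]
        keep <- !is.na(yv)
        if (!any(keep)) return(1)
        pv <- p[i, keep, k, t] * zval
        prod(ifelse(yv[keep] == 1, pv, 1 - pv))
      }
      f["1"] <- psi1[i] * obs_lik(1, 1)
      f["0"] <- (1 - psi1[i]) * obs_lik(1, 0)
      if (T > 1) {
        for (t in 2:T) {
          xt <- x[i, seq_len(ncol(params$beta)), t]
          lp <- params$beta0[k] +
            (if (length(xt)) sum(params$beta[k, ] * xt) else 0)
          psi_from0 <- clamp_prob(stats::plogis(lp))
          psi_from1 <- clamp_prob(stats::plogis(
            lp + if (!is.null(params$phi)) params$phi[k] else 0))
          o1 <- obs_lik(t, 1); o0 <- obs_lik(t, 0)
          f_new1 <- (f["0"] * psi_from0 + f["1"] * psi_from1) * o1
          f_new0 <- (f["0"] * (1 - psi_from0) + f["1"] * (1 - psi_from1)) * o0
          f <- c(`0` = unname(f_new0), `1` = unname(f_new1))
        }
      }
      total <- total + log(sum(f))
    }
  }
  total
}
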