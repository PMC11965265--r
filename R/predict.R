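#' Predicted occupancy curves over a covariate gradient
#'
#' Evaluates first-year occupancy probability over a grid of one scaled
#' covariate with all other covariates held at their mean (0 on the scaled
#' scale). Species curves average the inverse-logit over each species' own
#' posterior draws. The community (population-averaged) curve integrates
#' over the species random-effect distribution by Monte Carlo: for each
#' saved hyperparameter draw, species-level intercepts and slopes are drawn
#' from the community normals and the inverse-logit is averaged. A
#' `community_plugin` variant -- the inverse-logit evaluated at the
#' community means -- is also returned, labelled, since the two averages
#' differ (the plug-in curve ignores between-species spread).
#'
#' @param fit An `occu_fit` whose model contains `covariate`.
#' @param covariate Covariate name to sweep.
#' @param mode `"species"`, `"community"`, or `"both"` (default).
#' @param grid_n Number of grid points.
#' @param grid Optional explicit grid of scaled covariate values.
#' @param n_mc Species draws per hyperparameter draw for the community
#'   average.
#' @param level Credible level for the curve bands.
#' @return A tibble: `curve` (species code, `"community"`, or
#'   `"community_plugin"`), `covariate`, `x` (scaled), `x_natural` (original
#'   units when scaling metadata is available), `mean`, `lower`, `upper`.
#' @export
predict_occupancy <- function(fit, covariate, mode = c("both", "species", "community"),
                              grid_n = 50, grid = NULL, n_mc = 30,
                              level = 0.85) {
  mode <- match.arg(mode)
  f <- fit$formula
  if (!covariate %in% f$occ) {
    stop("covariate '", covariate, "' is not in model '", f$name, "'",
         call. = FALSE)
  }
  a <- (1 - level) / 2
  c_idx <- match(covariate, f$occ)
  if (is.null(grid)) {
    xv <- fit$x[, c_idx, ]
    grid <- seq(min(xv), max(xv), length.out = grid_n)
  }
  sc <- if (!is.null(fit$covariates)) attr(fit$covariates, "scaling") else NULL
  x_nat <- if (!is.null(sc) && covariate %in% sc$covariate) {
    r <- sc[sc$covariate == covariate, ]
    grid * r$sd + r$mean
  } else {
    rep(NA_real_, length(grid))
  }
  m <- do.call(rbind, fit$draws)
  sp <- fit$design$species$species
  out <- list()

  if (mode %in% c("both", "species")) {
    for (s in sp) {
      b0 <- m[, sprintf("beta0[%s]", s)]
      bc <- m[, sprintf("beta[%s,%s]", s, covariate)]
      curves <- vapply(grid, function(g) {
        v <- stats::plogis(b0 + bc * g)
        c(mean(v), stats::quantile(v, c(a, 1 - a), names = FALSE))
      }, numeric(3))
      out[[length(out) + 1]] <- tibble::tibble(
        curve = s, covariate = covariate, x = grid, x_natural = x_nat,
        mean = curves[1, ], lower = curves[2, ], upper = curves[3, ])
    }
  }
  if (mode %in% c("both", "community") && f$effects == "random") {
    mu0 <- m[, "mu_beta0"]; s0 <- m[, "sigma_beta0"]
    mub <- m[, sprintf("mu_beta[%s]", covariate)]
    sb <- m[, sprintf("sigma_beta[%s]", covariate)]
    nd <- length(mu0)
    # Monte Carlo over the species random-effect distribution per draw
    eps0 <- matrix(stats::rnorm(nd * n_mc), nd, n_mc)
    epsb <- matrix(stats::rnorm(nd * n_mc), nd, n_mc)
    b0s <- mu0 + s0 * eps0
    bbs <- mub + sb * epsb
    curves <- vapply(grid, function(g) {
      pg <- rowMeans(stats::plogis(b0s + bbs * g))
      c(mean(pg), stats::quantile(pg, c(a, 1 - a), names = FALSE))
    }, numeric(3))
    out[[length(out) + 1]] <- tibble::tibble(
      curve = "community", covariate = covariate, x = grid, x_natural = x_nat,
      mean = curves[1, ], lower = curves[2, ], upper = curves[3, ])
    plug <- vapply(grid, function(g) {
      pg <- stats::plogis(mu0 + mub * g)
      c(mean(pg), stats::quantile(pg, c(a, 1 - a), names = FALSE))
    }, numeric(3))
    out[[length(out) + 1]] <- tibble::tibble(
      curve = "community_plugin", covariate = covariate, x = grid,
      x_natural = x_nat,
      mean = plug[1, ], lower = plug[2, ], upper = plug[3, ])
  }
  structure(dplyr::bind_rows(out),
            class = c("occu_curves", class(tibble::tibble())))
}
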