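#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted occupancy model
#'
#' One row per parameter with posterior mean, sd, symmetric-quantile
#' credible bounds at `level` (85% by default) and split-chain R-hat.
#'
#' @param x An `occu_fit`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble (see [summarize_fit()]).
#' @export
tidy.occu_fit <- function(x, level = 0.85, ...) {
  summarize_fit(x, level = level)
}

#' One-row model summary
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A tibble with the model name, guild, chain/draw counts, maximum
#'   R-hat, DIC and effective number of parameters.
#' @export
glance.occu_fit <- function(x, ...) {
  s <- summarize_fit(x)
  d <- dic(x)
  tibble::tibble(
    model = x$formula$name, guild = x$formula$guild,
    n_species = x$design$n_species,
    n_chains = length(x$draws), n_draws = x$n_save * length(x$draws),
    max_rhat = max(s$rhat, na.rm = TRUE),
    dic = d$dic, p_d = d$pD
  )
}

#' Caterpillar plot of posterior summaries
#'
#' @param object An `occu_fit`.
#' @param pars Optional regular expression selecting parameters (default:
#'   occupancy covariate effects and community means).
#' @param level Credible level for the interval segments.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occu_fit <- function(object, pars = "^(beta\\[|mu_)", level = 0.85,
                              ...) {
  s <- summarize_fit(object, level = level)
  s <- s[grepl(pars, s$term), , drop = FALSE]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower, xend = .data$upper,
                                       yend = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("Posterior mean and %d%% CrI", round(level * 100)),
                  y = NULL, title = object$formula$name)
}

#' Plot predicted occupancy curves
#'
#' Species-specific curves dashed, the population-averaged community curve
#' solid, on the scaled covariate axis.
#'
#' @param object An `occu_curves` tibble from [predict_occupancy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occu_curves <- function(object, ...) {
  comm <- object$curve %in% c("community", "community_plugin")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$mean,
                               group = .data$curve,
                               linetype = ifelse(comm, "community", "species"))) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$curve)) +
    ggplot2::scale_linetype_manual(values = c(community = "solid",
                                              species = "dashed"),
                                   name = NULL) +
    ggplot2::labs(x = sprintf("%s (scaled)", object$covariate[1]),
                  y = "Occupancy probability") +
    ggplot2::ylim(0, 1)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
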