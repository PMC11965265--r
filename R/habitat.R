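#' Kruskal-Wallis rank test with an exact-permutation option
#'
#' The H statistic (with the standard average-rank tie correction) and its
#' chi-square p-value come from [stats::kruskal.test()]. For small samples
#' the chi-square approximation is poor, so for two groups with total n at
#' most `exact_max` an exact permutation p-value is computed by enumerating
#' every assignment of the pooled observations to the two group sizes and
#' counting assignments with H at least as large as observed.
#'
#' @param data A data frame.
#' @param value Column with the measurements (e.g. soil temperature, deg C).
#' @param group Column with the group labels (e.g. inside/outside).
#' @param exact `"auto"` (exact when feasible), `TRUE`, or `FALSE`.
#' @param exact_max Largest total n for the `"auto"` exact enumeration
#'   (default 10).
#' @return A tibble: `statistic` (H), `df`, `p_value`, `p_exact` (`NA` when
#'   not computed), `method`.
#' @export
#' @examples
#' d <- data.frame(temp = c(1, 2, 3, 4, 5, 6),
#'                 loc = rep(c("inside", "outside"), each = 3))
#' kruskal_wallis(d, temp, loc)
kruskal_wallis <- function(data, value, group, exact = "auto",
                           exact_max = 10) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (any(table(g) == 0) || nlevels(g) < 2) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (length(v) < 3) stop("need total n >= 3", call. = FALSE)
  if (length(unique(v)) == 1) {
    # fully tied data: the tie-corrected statistic carries no information
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1, p_value = 1,
                          p_exact = 1, method = "Kruskal-Wallis (degenerate)"))
  }
  kt <- stats::kruskal.test(v, g)
  H <- unname(kt$statistic)
  do_exact <- isTRUE(exact) ||
    (identical(exact, "auto") && nlevels(g) == 2 && length(v) <= exact_max)
  p_exact <- NA_real_
  if (do_exact) {
    if (nlevels(g) != 2) stop("exact enumeration implemented for 2 groups",
                              call. = FALSE)
    n <- length(v)
    n1 <- sum(g == levels(g)[1])
    splits <- utils::combn(n, n1)
    stats_all <- apply(splits, 2, function(idx) {
      gg <- factor(ifelse(seq_len(n) %in% idx, "a", "b"))
      unname(stats::kruskal.test(v, gg)$statistic)
    })
    p_exact <- mean(stats_all >= H - 1e-12)
  }
  tibble::tibble(
    statistic = H, df = unname(kt$parameter),
    p_value = unname(kt$p.value), p_exact = p_exact,
    method = if (do_exact) "Kruskal-Wallis (chi-square + exact permutation)"
             else "Kruskal-Wallis (chi-square)"
  )
}

#' Two-group linear contrast (inside vs outside)
#'
#' Ordinary least squares of the (optionally z-scored) response on a 0/1
#' group indicator, coded inside = 0 / outside = 1, so the coefficient is
#' exactly the outside-minus-inside difference in (standardized) group
#' means: responses higher inside the facility yield negative
#' coefficients. Standardizing the response puts coefficients on the
#' magnitude scale conventional for these habitat contrasts.
#'
#' @param data A data frame.
#' @param response Measurement column.
#' @param group Column distinguishing the two groups; the reference
#'   (coded 0) level is `"inside"` when present, otherwise the first
#'   factor level.
#' @param standardize Z-score the response first (default `TRUE`).
#' @return A tibble: `estimate` (the contrast), `std_error`, `statistic`
#'   (t), `p_value`, `n`.
#' @export
group_contrast <- function(data, response, group, standardize = TRUE) {
  v <- rlang::eval_tidy(rlang::enquo(response), data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  if (any(table(g) == 0)) stop("both groups must be non-empty", call. = FALSE)
  if (length(v) < 3) stop("need n >= 3", call. = FALSE)
  if ("inside" %in% levels(g)) g <- stats::relevel(g, "inside")
  if (standardize) v <- as.numeric(scale(v))
  ind <- as.integer(g == levels(g)[2])
  fit <- stats::lm(v ~ ind)
  sm <- suppressWarnings(summary(fit))$coefficients # perfect fits handled below
  if (nrow(sm) < 2 || any(!is.finite(sm["ind", ]))) {
    # zero residual variance: contrast is exactly determined
    est <- mean(v[ind == 1]) - mean(v[ind == 0])
    return(tibble::tibble(estimate = est, std_error = 0,
                          statistic = ifelse(est == 0, 0, Inf),
                          p_value = ifelse(est == 0, 1, 0), n = length(v)))
  }
  tibble::tibble(
    estimate = sm["ind", "Estimate"], std_error = sm["ind", "Std. Error"],
    statistic = sm["ind", "t value"], p_value = sm["ind", "Pr(>|t|)"],
    n = length(v)
  )
}

#' Habitat-contrast table for the study covariates
#'
#' Runs [group_contrast()] for orthopteran abundance, grass cover and forb
#' cover against inside/outside status, in both standardized and raw
#' response scalings.
#'
#' @param covariates A `covariate_table` (unscaled).
#' @param design A [survey_design()]; defaults to the attached one.
#' @return A tibble with one row per covariate x scaling.
#' @export
habitat_contrasts <- function(covariates, design = attr(covariates, "design")) {
  loc <- ifelse(design$sites$stratum[match(covariates$site,
                                           design$sites$site)] == "inside",
                "inside", "outside")
  df <- dplyr::mutate(tibble::as_tibble(covariates), location = loc)
  purrr::map_dfr(c("orthoptera", "grass", "forb"), function(v) {
    dplyr::bind_rows(
      dplyr::mutate(
        group_contrast(df, !!rlang::sym(v), location, standardize = TRUE),
        covariate = v, scaling = "standardized", .before = 1),
      dplyr::mutate(
        group_contrast(df, !!rlang::sym(v), location, standardize = FALSE),
        covariate = v, scaling = "raw", .before = 1)
    )
  })
}
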