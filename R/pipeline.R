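#' Run the full analysis pipeline
#'
#' Ties the stages together: scales covariates, fits and scores the
#' candidate model set, refits nothing (fits are reused), and writes the
#' standard report bundle to `out_dir`:
#'
#' * `selection_table.csv` -- model, DIC, delta-DIC, Bayesian p-value;
#' * `coefficients.csv` -- one row per species from the best-supported
#'   model: occupancy intercept, covariate effects and per-year detection
#'   intercepts, each with posterior mean and credible bounds;
#' * `prediction_curves.csv` -- predicted occupancy versus each covariate
#'   in the best model (species, community and plug-in community curves);
#' * `habitat.csv` -- inside/outside linear contrasts for the vegetation
#'   and arthropod covariates (plus soil-temperature Kruskal-Wallis rows
#'   when soil data are supplied);
#' * `manifest.json` -- seed, versions, config echo and per-stage errors.
#'
#' Everything downstream of the seed is deterministic: the same inputs and
#' seed give byte-identical output files.
#'
#' @param detections Long detection tibble.
#' @param covariates Unscaled `covariate_table`.
#' @param out_dir Output directory (created if needed).
#' @param design A [survey_design()].
#' @param model_set List of [occu_formula()]; default the built-in
#'   insectivore set.
#' @param exclude Species exclusions (granivores etc.).
#' @param mcmc An [mcmc_config()]; its seed is overridden by `seed`.
#' @param level Credible level for reported intervals (default 0.85).
#' @param soil Optional soil-temperature tibble with columns `temp_c`,
#'   `group` and optionally `comparison`.
#' @param seed Integer seed for every stochastic stage.
#' @return Invisibly, a list with the selection table, best fit, and paths.
#' @export
run_pipeline <- function(detections, covariates, out_dir,
                         design = attr(detections, "design"),
                         model_set = insectivore_model_set(),
                         exclude = character(), mcmc = mcmc_config(),
                         level = 0.85, soil = NULL, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mcmc$seed <- as.integer(seed)
  errors <- list()
  covariates <- scale_covariates(covariates)

  sel <- run_model_set(detections, covariates, model_set, design, mcmc,
                       exclude, keep_fits = TRUE)
  fits <- attr(sel, "fits")
  readr::write_csv(dplyr::select(sel, -"error"),
                   file.path(out_dir, "selection_table.csv"), progress = FALSE)

  best_name <- sel$model[which.min(sel$dic)]
  best <- fits[[best_name]]
  coefs <- coefficients_table(best, level = level)
  readr::write_csv(coefs, file.path(out_dir, "coefficients.csv"),
                   progress = FALSE)

  set.seed(seed + 101L)
  curves <- purrr::map_dfr(best$formula$occ, function(v) {
    predict_occupancy(best, v, mode = "both", level = level)
  })
  readr::write_csv(curves, file.path(out_dir, "prediction_curves.csv"),
                   progress = FALSE)

  hab <- tryCatch(habitat_contrasts(unscale_covariates(covariates), design),
                  error = function(e) {
                    errors$habitat <<- conditionMessage(e)
                    tibble::tibble()
                  })
  if (!is.null(soil)) {
    soil_rows <- soil_kruskal(soil)
    hab <- dplyr::bind_rows(hab, soil_rows)
  }
  readr::write_csv(hab, file.path(out_dir, "habitat.csv"), progress = FALSE)

  manifest <- list(
    seed = seed, level = level,
    package_version = as.character(utils::packageVersion("solaroccu")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    models = vapply(model_set, `[[`, character(1), "name"),
    best_model = best_name,
    mcmc = mcmc[c("n_chains", "n_iter", "n_burnin", "thin")],
    errors = c(errors, stats::setNames(as.list(sel$error[!is.na(sel$error)]),
                                       sel$model[!is.na(sel$error)]))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(selection = sel, best = best, out_dir = out_dir))
}

# Table-2-style wide coefficient table: one row per species
coefficients_table <- function(fit, level = 0.85) {
  s <- summarize_fit(fit, level = level)
  sp <- fit$design$species$species
  f <- fit$formula
  yrs <- fit$design$years
  one <- function(term) {
    r <- s[s$term == term, ]
    c(r$mean, r$lower, r$upper)
  }
  rows <- purrr::map_dfr(sp, function(k) {
    vals <- c(one(sprintf("beta0[%s]", k)))
    nmv <- c("intercept", "intercept_lower", "intercept_upper")
    for (v in f$occ) {
      vals <- c(vals, one(sprintf("beta[%s,%s]", k, v)))
      nmv <- c(nmv, v, paste0(v, "_lower"), paste0(v, "_upper"))
    }
    if (f$autologistic) {
      vals <- c(vals, one(sprintf("phi[%s]", k)))
      nmv <- c(nmv, "phi", "phi_lower", "phi_upper")
    }
    for (t in seq_along(yrs)) {
      vals <- c(vals, one(sprintf("alpha0[%s,%d]", k, yrs[t])))
      nmv <- c(nmv, sprintf("detection_%d%s", yrs[t], c("", "_lower", "_upper")))
    }
    tibble::as_tibble(stats::setNames(as.list(vals), nmv))
  })
  dplyr::bind_cols(tibble::tibble(species = sp), rows)
}

# per-comparison Kruskal-Wallis rows for soil temperature data
soil_kruskal <- function(soil) {
  stopifnot(all(c("temp_c", "group") %in% names(soil)))
  if (!"comparison" %in% names(soil)) soil$comparison <- "all"
  purrr::map_dfr(unique(soil$comparison), function(cmp) {
    d <- soil[soil$comparison == cmp, ]
    kw <- kruskal_wallis(d, temp_c, group)
    tibble::tibble(covariate = paste0("soil_temp_", cmp), scaling = "raw",
                   estimate = NA_real_, std_error = NA_real_,
                   statistic = kw$statistic, p_value = kw$p_value,
                   n = nrow(d), p_exact = kw$p_exact, method = kw$method)
  })
}

#' Read a pipeline run configuration from YAML
#'
#' Supported keys: `detections`, `covariates`, `soil` (paths), `out_dir`,
#' `guild` (`insectivore`/`synanthropic`), `exclude`, `seed`, `level`, and
#' an `mcmc` block with [mcmc_config()] fields.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$mcmc <- do.call(mcmc_config, c(cfg$mcmc))
  cfg
}
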