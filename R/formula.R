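#' Specify one candidate occupancy model
#'
#' A model formula names the occupancy covariates entering the logit of
#' occupancy probability (empty = null model), optional detection
#' covariates, the guild the model applies to, whether species-level effects
#' are drawn from community normal distributions (`"random"`) or treated as
#' fixed effects (`"fixed"`, used for the two-species synanthropic guild),
#' and whether the auto-logistic persistence term (an offset on the logit of
#' occupancy for sites occupied the previous year) is included.
#'
#' @param occ Character vector of occupancy covariate names (possibly
#'   empty).
#' @param guild `"insectivore"` or `"synanthropic"`.
#' @param name Model label; defaults to a `+`-joined covariate list using
#'   the conventional short names (Solar, Insect, Grass, Forb), or "Null".
#' @param det Detection covariate names (default none: detection is
#'   modelled with species- and year-specific intercepts only).
#' @param effects `"random"` (community hyperdistributions) or `"fixed"`.
#' @param autologistic Include the persistence offset (default `TRUE`).
#' @return An object of class `occu_formula`.
#' @export
#' @examples
#' occu_formula(c("dist_solar", "orthoptera", "forb"), guild = "insectivore")
occu_formula <- function(occ, guild, name = NULL, det = character(),
                         effects = if (guild == "synanthropic") "fixed" else "random",
                         autologistic = TRUE) {
  occ <- as.character(occ)
  guild <- match.arg(guild, c("insectivore", "synanthropic"))
  effects <- match.arg(effects, c("random", "fixed"))
  if (is.null(name)) {
    name <- if (length(occ)) {
      paste(covariate_label(occ), collapse = " + ")
    } else {
      "Null"
    }
  }
  structure(
    list(name = name, occ = occ, det = as.character(det), guild = guild,
         effects = effects, autologistic = isTRUE(autologistic)),
    class = "occu_formula"
  )
}

# conventional short labels for the study covariates
covariate_label <- function(x) {
  lab <- c(dist_solar = "Solar", orthoptera = "Insect", grass = "Grass",
           forb = "Forb")
  ifelse(x %in% names(lab), lab[x], x)
}

#' @export
print.occu_formula <- function(x, ...) {
  cat(sprintf("<occu_formula> %s [%s, %s effects%s]\n", x$name, x$guild,
              x$effects, if (x$autologistic) ", auto-logistic" else ""))
  invisible(x)
}

#' Built-in candidate model sets
#'
#' The enumerated candidate sets: 12 models for the insectivorous guild
#' (combinations of distance to the solar facility, orthopteran abundance,
#' forb cover and grass cover, plus a null model) and 8 for the synanthropic
#' guild (which excludes orthopteran abundance, since neither synanthropic
#' species feeds its nestlings arthropods).
#'
#' @return A list of [occu_formula()] objects.
#' @export
insectivore_model_set <- function() {
  combos <- list(
    c("dist_solar", "orthoptera", "forb"),
    c("dist_solar", "orthoptera"),
    c("dist_solar", "grass", "orthoptera", "forb"),
    c("dist_solar", "orthoptera", "grass"),
    c("dist_solar", "forb"),
    c("dist_solar", "grass", "forb"),
    "orthoptera",
    c("dist_solar", "grass"),
    "forb",
    "grass",
    "dist_solar",
    character()
  )
  lapply(combos, occu_formula, guild = "insectivore")
}

#' @rdname insectivore_model_set
#' @export
synanthropic_model_set <- function() {
  combos <- list(
    c("forb", "grass"),
    c("dist_solar", "forb", "grass"),
    c("dist_solar", "grass"),
    c("dist_solar", "forb"),
    "grass",
    "dist_solar",
    character(),
    "forb"
  )
  lapply(combos, occu_formula, guild = "synanthropic")
}
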