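#' Read the site-by-year occupancy covariate table
#'
#' Expects a CSV with header `site,year,dist_solar,orthoptera,grass,forb`:
#' distance from the facility edge (m; 0 inside), orthopteran pitfall
#' abundance (count), and percent grass and forb cover. Static covariates
#' (distance) may be supplied for a single year; they are replicated across
#' years internally.
#'
#' @param path CSV path.
#' @param design A [survey_design()].
#' @param covariates Covariate column names expected in the file.
#' @return A tibble of class `covariate_table` with one row per site-year.
#' @export
read_covariates <- function(path, design,
                            covariates = c("dist_solar", "orthoptera",
                                           "grass", "forb")) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  as_covariates(tbl, design, covariates)
}

#' Validate an in-memory covariate table
#'
#' @param tbl Data frame with `site`, `year` and the covariate columns.
#' @inheritParams read_covariates
#' @return A `covariate_table` tibble.
#' @export
as_covariates <- function(tbl, design,
                          covariates = c("dist_solar", "orthoptera",
                                         "grass", "forb")) {
  stopifnot(inherits(design, "survey_design"))
  miss <- setdiff(c("site", "year", covariates), names(tbl))
  if (length(miss)) {
    stop("covariate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(tbl[, c("site", "year", covariates)])
  out$site <- as.character(out$site)
  out$year <- as.integer(out$year)
  if (!all(out$site %in% design$sites$site)) {
    stop("covariate table contains sites not in the design", call. = FALSE)
  }
  # replicate static (single-year) tables across years
  if (length(unique(out$year)) == 1L && design$n_years > 1L) {
    out <- tidyr::crossing(year2 = design$years,
                           dplyr::select(out, -"year"))
    out <- dplyr::rename(out, year = "year2")
  }
  full <- tidyr::crossing(site = design$sites$site, year = design$years)
  out <- dplyr::left_join(full, out, by = c("site", "year"))
  if (anyNA(out[covariates])) {
    stop("covariate table does not cover every site-year", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$year, .data$site)
  structure(out, class = c("covariate_table", class(tibble::tibble())),
            covariates = covariates, scaling = NULL, design = design)
}

#' Center and scale occupancy covariates
#'
#' Each covariate column is centered to mean 0 and scaled to standard
#' deviation 1 (sample, n-1 convention) over all site-year cells; the means
#' and sds are stored so the transformation is invertible with
#' [unscale_covariates()]. Fitting always operates on the scaled table, so
#' regression coefficients are per-standard-deviation effects.
#'
#' @param covs A `covariate_table` from [read_covariates()] /
#'   [as_covariates()].
#' @return The scaled `covariate_table`, with attribute `"scaling"` (a
#'   tibble `covariate, mean, sd`).
#' @export
scale_covariates <- function(covs) {
  vars <- attr(covs, "covariates")
  if (!is.null(attr(covs, "scaling"))) {
    return(covs) # already scaled
  }
  mu <- vapply(covs[vars], mean, numeric(1))
  sd_ <- vapply(covs[vars], stats::sd, numeric(1))
  if (any(sd_ <= 0)) {
    stop("constant covariate column(s): ",
         paste(vars[sd_ <= 0], collapse = ", "), call. = FALSE)
  }
  out <- covs
  for (v in vars) out[[v]] <- (covs[[v]] - mu[v]) / sd_[v]
  attr(out, "scaling") <- tibble::tibble(covariate = vars, mean = unname(mu),
                                         sd = unname(sd_))
  out
}

#' Invert covariate scaling
#'
#' @param covs A scaled `covariate_table`.
#' @return The table on the original measurement scale.
#' @export
unscale_covariates <- function(covs) {
  sc <- attr(covs, "scaling")
  if (is.null(sc)) stop("table is not scaled", call. = FALSE)
  out <- covs
  for (r in seq_len(nrow(sc))) {
    v <- sc$covariate[r]
    out[[v]] <- covs[[v]] * sc$sd[r] + sc$mean[r]
  }
  attr(out, "scaling") <- NULL
  out
}

#' Convert a covariate table to the internal I x C x T array
#'
#' @param covs A `covariate_table`.
#' @param covariates Columns to include (defaults to all of them).
#' @return Numeric array `(n_sites, length(covariates), n_years)`.
#' @export
covariate_array <- function(covs, covariates = attr(covs, "covariates")) {
  design <- attr(covs, "design")
  x <- array(NA_real_,
             dim = c(design$n_sites, length(covariates), design$n_years),
             dimnames = list(design$sites$site, covariates, design$years))
  i <- match(covs$site, design$sites$site)
  t <- match(covs$year, design$years)
  for (c_idx in seq_along(covariates)) {
    x[cbind(i, c_idx, t)] <- covs[[covariates[c_idx]]]
  }
  x
}
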