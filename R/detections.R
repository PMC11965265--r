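#' Read detection/non-detection records
#'
#' Reads a long-format survey file with one row per (site, year, visit,
#' species) and a `count` (or `detected`) column, validates it against the
#' design, and collapses counts to presence/absence: any positive count is a
#' detection. Site-year-visit-species cells absent from the file are treated
#' as missing visits and contribute nothing to any likelihood downstream.
#'
#' @param path Path to a CSV/TSV file with header
#'   `site,year,visit,species,count` (`detected` accepted in place of
#'   `count`).
#' @param design A [survey_design()] the records must resolve against.
#' @return A tibble with columns `site, year, visit, species, y` (`y` in
#'   0/1), one row per observed cell, carrying the design as attribute
#'   `"design"`.
#' @export
read_detections <- function(path, design) {
  stopifnot(inherits(design, "survey_design"))
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  as_detections(tbl, design)
}

#' Validate an in-memory detection table
#'
#' @param tbl Data frame with columns `site, year, visit, species` and
#'   `count` or `detected`.
#' @inheritParams read_detections
#' @return See [read_detections()].
#' @export
as_detections <- function(tbl, design) {
  need <- c("site", "year", "visit", "species")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("detection table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"count" %in% names(tbl) && !"detected" %in% names(tbl)) {
    stop("detection table needs a `count` or `detected` column", call. = FALSE)
  }
  val <- if ("count" %in% names(tbl)) tbl$count else tbl$detected
  val <- as.numeric(val)
  if (anyNA(val)) stop("missing count values; omit the row instead", call. = FALSE)
  if (any(val < 0)) {
    bad <- which(val < 0)[1]
    stop(sprintf("negative count in record %d (site=%s, species=%s)",
                 bad, tbl$site[bad], tbl$species[bad]), call. = FALSE)
  }
  out <- tibble::tibble(
    site = as.character(tbl$site),
    year = as.integer(tbl$year),
    visit = as.integer(tbl$visit),
    species = as.character(tbl$species),
    y = as.integer(val > 0)
  )
  check_known <- function(values, known, what) {
    bad <- !values %in% known
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("unknown %s '%s' in record %d", what, values[i], i),
           call. = FALSE)
    }
  }
  check_known(out$site, design$sites$site, "site")
  check_known(out$species, design$species$species, "species")
  check_known(out$year, design$years, "year")
  if (any(out$visit < 1L | out$visit > design$n_visits)) {
    i <- which(out$visit < 1L | out$visit > design$n_visits)[1]
    stop(sprintf("visit %d out of range in record %d", out$visit[i], i),
         call. = FALSE)
  }
  key <- paste(out$site, out$year, out$visit, out$species)
  if (anyDuplicated(key)) {
    stop("duplicate (site, year, visit, species) records", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$site, .data$year, .data$visit, .data$species)
  attr(out, "design") <- design
  out
}

#' Write detection records
#'
#' Inverse of [read_detections()]: writes the long-format CSV with a `count`
#' column (0/1, since the pipeline is presence/absence only).
#'
#' @param detections Tibble from [read_detections()] or [sim_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- dplyr::transmute(detections, site = .data$site, year = .data$year,
                          visit = .data$visit, species = .data$species,
                          count = .data$y)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Convert long detections to the internal I x J x K x T array
#'
#' Cells never visited are `NA` and are skipped by every likelihood.
#'
#' @inheritParams write_detections
#' @param design A [survey_design()]; defaults to the one attached to
#'   `detections`.
#' @return Integer array with dim `(n_sites, n_visits, n_species, n_years)`
#'   and dimnames from the design.
#' @export
detection_array <- function(detections, design = attr(detections, "design")) {
  stopifnot(inherits(design, "survey_design"))
  y <- array(NA_integer_,
             dim = c(design$n_sites, design$n_visits, design$n_species,
                     design$n_years),
             dimnames = list(design$sites$site, NULL, design$species$species,
                             design$years))
  if (nrow(detections)) {
    i <- match(detections$site, design$sites$site)
    j <- detections$visit
    k <- match(detections$species, design$species$species)
    t <- match(detections$year, design$years)
    keep <- !is.na(k) # species outside the design (other guild) are dropped
    y[cbind(i, j, k, t)[keep, , drop = FALSE]] <- detections$y[keep]
  }
  y
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}
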