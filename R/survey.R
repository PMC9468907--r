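#' Survey container for quadrat-based grass community data
#'
#' A `grass_survey` bundles the three tables a grazed-grassland survey
#' produces: per-quadrat species records (`observations`), per-quadrat
#' metadata (`meta`: bare ground, dung), and per-site environment (`sites`:
#' mean annual rainfall, percent sand, CEC, pH). Construction validates
#' every field against its closed enumeration or numeric range and checks
#' referential integrity between the tables.
#'
#' @param observations Tibble with columns `site_id`, `quadrat_id`,
#'   `species`, `cover_pct` (percent, 0-100), `leaf_table_height_mm` (> 0),
#'   `culm_orientation` (one of lateral, geniculate-lateral, geniculate,
#'   decumbent, geniculate-upright, upright), `stolons` (logical), `rhizome`
#'   (none/short/long), `tufted_base` (logical).
#' @param meta Tibble with `site_id`, `quadrat_id`, `bare_ground_pct`
#'   (0-100), `dung_present` (logical); one row per quadrat.
#' @param sites Tibble with `site_id`, `map_mm` (> 0), `sand_pct` (0-100),
#'   `cec` (>= 0), `ph` (0-14); one row per site, no missing values.
#' @return An object of class `grass_survey`: a named list of the three
#'   validated tibbles.
#' @details Summed species cover within a quadrat may exceed 100% (canopies
#'   overlap); only per-species cover is bounded. Sites with fewer than 15
#'   quadrats trigger a warning, not an error.
#' @export
new_survey <- function(observations, meta, sites) {
  observations <- tibble::as_tibble(observations)
  meta <- tibble::as_tibble(meta)
  sites <- tibble::as_tibble(sites)
  check_columns(observations, c(
    "site_id", "quadrat_id", "species", "cover_pct", "leaf_table_height_mm",
    "culm_orientation", "stolons", "rhizome", "tufted_base"
  ), "observations")
  check_columns(meta, c("site_id", "quadrat_id", "bare_ground_pct", "dung_present"),
    "meta")
  check_columns(sites, c("site_id", environment_variables), "sites")

  problems <- c(
    check_range(observations, "cover_pct", 0, 100),
    check_positive(observations, "leaf_table_height_mm"),
    check_enum(observations, "culm_orientation", culm_orientation_levels),
    check_enum(observations, "rhizome", rhizome_levels),
    check_logical(observations, "stolons"),
    check_logical(observations, "tufted_base"),
    check_range(meta, "bare_ground_pct", 0, 100),
    check_logical(meta, "dung_present"),
    check_positive(sites, "map_mm"),
    check_range(sites, "sand_pct", 0, 100),
    check_range(sites, "cec", 0, Inf),
    check_range(sites, "ph", 1e-12, 14 - 1e-12)
  )
  if (anyNA(sites[environment_variables])) {
    problems <- c(problems, "sites: missing environment values are not allowed")
  }
  dup_obs <- duplicated(observations[c("site_id", "quadrat_id", "species")])
  if (any(dup_obs)) {
    problems <- c(problems, paste0(
      "observations: duplicated (site_id, quadrat_id, species) at rows ",
      paste(which(dup_obs), collapse = ", ")
    ))
  }
  dup_meta <- duplicated(meta[c("site_id", "quadrat_id")])
  if (any(dup_meta)) {
    problems <- c(problems, paste0(
      "meta: duplicated (site_id, quadrat_id) at rows ",
      paste(which(dup_meta), collapse = ", ")
    ))
  }
  if (anyDuplicated(sites$site_id)) {
    problems <- c(problems, "sites: duplicated site_id")
  }
  if (length(problems) > 0) {
    abort(c("Survey validation failed", problems),
      class = "grasslawns_validation_error")
  }

  # Referential integrity: observation quadrats need metadata, sites need
  # environment rows.
  obs_keys <- paste(observations$site_id, observations$quadrat_id, sep = "\r")
  meta_keys <- paste(meta$site_id, meta$quadrat_id, sep = "\r")
  dangling_q <- !obs_keys %in% meta_keys
  referential <- character()
  if (any(dangling_q)) {
    referential <- c(referential, paste0(
      "observations rows without a quadrat_meta row: ",
      paste(head(which(dangling_q), 5), collapse = ", ")
    ))
  }
  for (what in list(list(observations, "observations"), list(meta, "meta"))) {
    missing_site <- !what[[1]]$site_id %in% sites$site_id
    if (any(missing_site)) {
      referential <- c(referential, paste0(
        what[[2]], " rows referencing unknown site_id: ",
        paste(unique(what[[1]]$site_id[missing_site]), collapse = ", ")
      ))
    }
  }
  if (length(referential) > 0) {
    abort(c("Survey referential integrity failed", referential),
      class = "grasslawns_referential_error")
  }

  quadrat_counts <- dplyr::count(meta, .data$site_id)
  small <- quadrat_counts$site_id[quadrat_counts$n < 15]
  if (length(small) > 0) {
    warn(paste0(
      "Sites with fewer than 15 quadrats: ", paste(small, collapse = ", ")
    ), class = "grasslawns_small_site_warning")
  }

  structure(
    list(observations = observations, meta = meta, sites = sites),
    class = "grass_survey"
  )
}

check_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      paste0(table, ": missing required column(s): ",
        paste(missing, collapse = ", ")),
      class = "grasslawns_schema_error"
    )
  }
}

check_range <- function(df, field, lo, hi) {
  x <- df[[field]]
  bad <- which(is.na(x) | x < lo | x > hi)
  if (length(bad) == 0) return(character())
  paste0(field, " outside [", lo, ", ", hi, "] at row(s) ",
    paste(head(bad, 5), collapse = ", "))
}

check_positive <- function(df, field) {
  x <- df[[field]]
  bad <- which(is.na(x) | x <= 0)
  if (length(bad) == 0) return(character())
  paste0(field, " must be > 0; violated at row(s) ",
    paste(head(bad, 5), collapse = ", "))
}

check_enum <- function(df, field, levels) {
  bad <- which(is.na(df[[field]]) | !df[[field]] %in% levels)
  if (length(bad) == 0) return(character())
  paste0(field, " not in {", paste(levels, collapse = ", "), "} at row(s) ",
    paste(head(bad, 5), collapse = ", "))
}

check_logical <- function(df, field) {
  bad <- which(is.na(df[[field]]))
  if (length(bad) == 0 && is.logical(df[[field]])) return(character())
  if (!is.logical(df[[field]])) {
    return(paste0(field, " must be logical (TRUE/FALSE or 1/0)"))
  }
  paste0(field, " has unparseable value(s) at row(s) ",
    paste(head(bad, 5), collapse = ", "))
}

#' Read a survey from delimited text files
#'
#' Reads the three standard input files (comma-separated, UTF-8, `.` decimal
#' mark), decodes boolean columns given as TRUE/FALSE or 1/0, and validates
#' the result with [new_survey()].
#'
#' @param quadrats_path Path to `quadrats.csv` (one row per species-in-quadrat
#'   record).
#' @param meta_path Path to `quadrat_meta.csv` (one row per quadrat).
#' @param sites_path Path to `sites.csv` (one row per site).
#' @return A validated `grass_survey`.
#' @export
load_survey <- function(quadrats_path, meta_path, sites_path) {
  for (p in c(quadrats_path, meta_path, sites_path)) {
    if (!file.exists(p)) {
      abort(paste0("Input file does not exist: ", p),
        class = "grasslawns_io_error")
    }
  }
  obs <- readr::read_csv(quadrats_path, show_col_types = FALSE,
    col_types = readr::cols(
      site_id = "c", quadrat_id = "c", species = "c",
      .default = readr::col_guess()
    ))
  meta <- readr::read_csv(meta_path, show_col_types = FALSE,
    col_types = readr::cols(site_id = "c", quadrat_id = "c",
      .default = readr::col_guess()))
  sites <- readr::read_csv(sites_path, show_col_types = FALSE,
    col_types = readr::cols(site_id = "c", .default = readr::col_guess()))
  for (field in c("stolons", "tufted_base")) {
    if (field %in% names(obs)) obs[[field]] <- parse_flag(obs[[field]])
  }
  if ("dung_present" %in% names(meta)) {
    meta$dung_present <- parse_flag(meta$dung_present)
  }
  new_survey(obs, meta, sites)
}

#' @export
print.grass_survey <- function(x, ...) {
  cat("<grass_survey>\n")
  cat("  sites:        ", nrow(x$sites), "\n")
  cat("  quadrats:     ", nrow(x$meta), "\n")
  cat("  observations: ", nrow(x$observations), " (",
    dplyr::n_distinct(x$observations$species), " species)\n", sep = "")
  invisible(x)
}

#' Per-site summary of survey effort, bare ground and dung
#'
#' @param survey A `grass_survey`.
#' @return A tibble with one row per site: `site_id`, `n_quadrats`,
#'   `n_species`, `bare_ground_mean` (unweighted mean over quadrats) and
#'   `dung_proportion` (share of quadrats with dung). Sites present in the
#'   environment table but with no quadrats are dropped with a warning.
#' @export
summarize_survey <- function(survey) {
  stopifnot(inherits(survey, "grass_survey"))
  empty <- setdiff(survey$sites$site_id, survey$meta$site_id)
  if (length(empty) > 0) {
    warn(paste0("Sites with no quadrats excluded from summary: ",
      paste(empty, collapse = ", ")))
  }
  per_site_species <- survey$observations |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n_species = dplyr::n_distinct(.data$species))
  survey$meta |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_quadrats = dplyr::n(),
      bare_ground_mean = mean(.data$bare_ground_pct),
      dung_proportion = mean(.data$dung_present)
    ) |>
    dplyr::left_join(per_site_species, by = "site_id") |>
    dplyr::mutate(n_species = dplyr::coalesce(.data$n_species, 0L)) |>
    dplyr::select("site_id", "n_quadrats", "n_species",
      "bare_ground_mean", "dung_proportion")
}
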