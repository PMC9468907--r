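#' Encode culm orientation categories as ordinal codes
#'
#' Maps the field categories onto the 1-5 prostrate-to-upright scale used by
#' the culm orientation index: lateral = 1, geniculate-lateral = 2,
#' geniculate and decumbent = 3, geniculate-upright = 4, upright = 5.
#'
#' @param category Character vector of culm orientation categories.
#' @return Integer vector of codes in 1..5.
#' @export
encode_culm_orientation <- function(category) {
  codes <- c(
    "lateral" = 1L, "geniculate-lateral" = 2L, "geniculate" = 3L,
    "decumbent" = 3L, "geniculate-upright" = 4L, "upright" = 5L
  )
  bad <- !category %in% names(codes)
  if (any(bad)) {
    abort(paste0(
      "Unknown culm orientation ",
      paste(unique(category[bad]), collapse = ", "),
      "; legal categories: ", paste(culm_orientation_levels, collapse = ", ")
    ), class = "grasslawns_validation_error")
  }
  unname(codes[category])
}

#' Site-level median leaf table height
#'
#' The median is taken over all species-by-quadrat records at a site, each
#' record counting once (no cover weighting, no per-species aggregation
#' first); even record counts use the usual midpoint convention.
#'
#' @param survey A `grass_survey`.
#' @return Tibble `site_id`, `median_height_mm`. Sites in the environment
#'   table with no observations are excluded with a warning.
#' @export
site_median_height <- function(survey) {
  stopifnot(inherits(survey, "grass_survey"))
  empty <- setdiff(survey$sites$site_id, survey$observations$site_id)
  if (length(empty) > 0) {
    warn(paste0("Sites with no observations excluded from medians: ",
      paste(empty, collapse = ", ")))
  }
  survey$observations |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(median_height_mm = median(.data$leaf_table_height_mm))
}

#' Grazer use index from leaf table heights
#'
#' For each species-by-quadrat record, the leaf table height is divided by
#' the site-level median height; ratios above 1 are reciprocated so that
#' both much-taller and much-shorter species score low; the index is the
#' flat mean of the transformed ratios over all of the species' records
#' across quadrats and sites. Values lie in (0, 1], with 1 meaning the
#' species always sits at the site median, where grazer use is assumed
#' maximal.
#'
#' @param records Tibble with columns `species`, `site_id`,
#'   `leaf_table_height_mm`.
#' @param medians Tibble `site_id`, `median_height_mm` as returned by
#'   [site_median_height()].
#' @return Tibble `species`, `grazer_use_index`.
#' @export
grazer_use_index <- function(records, medians) {
  missing <- setdiff(unique(records$site_id), medians$site_id)
  if (length(missing) > 0) {
    abort(paste0("No site median height for site(s): ",
      paste(missing, collapse = ", ")), class = "grasslawns_validation_error")
  }
  records |>
    dplyr::inner_join(medians, by = "site_id") |>
    dplyr::mutate(
      ratio = .data$leaf_table_height_mm / .data$median_height_mm,
      use = ifelse(.data$ratio > 1, 1 / .data$ratio, .data$ratio)
    ) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(grazer_use_index = mean(.data$use))
}

#' Build the species-level trait index table
#'
#' Computes the four trait indices per species from a survey's quadrat
#' records: the culm orientation index (mean 1-5 code over records), the
#' lateral index (proportion of records with stolons or long rhizomes), the
#' tuft index (proportion of records with a tufted base) and the grazer use
#' index ([grazer_use_index()]). Species occurring in more than 10 quadrats
#' are flagged `clustered` and enter the formal growth-form classification;
#' rarer species are assigned manually via an override table.
#'
#' @param survey A `grass_survey`.
#' @return A tibble of class `trait_table` with columns `species`,
#'   `culm_orientation_index`, `lateral_index`, `tuft_index`,
#'   `grazer_use_index`, `n_quadrats`, `clustered`.
#' @export
build_trait_table <- function(survey) {
  stopifnot(inherits(survey, "grass_survey"))
  obs <- survey$observations
  gui <- grazer_use_index(
    obs[c("species", "site_id", "leaf_table_height_mm")],
    site_median_height(survey)
  )
  out <- obs |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      culm_orientation_index = mean(encode_culm_orientation(.data$culm_orientation)),
      lateral_index = mean(.data$stolons | .data$rhizome == "long"),
      tuft_index = mean(.data$tufted_base),
      n_quadrats = dplyr::n()
    ) |>
    dplyr::left_join(gui, by = "species") |>
    dplyr::mutate(clustered = .data$n_quadrats > 10L) |>
    dplyr::select("species", "culm_orientation_index", "lateral_index",
      "tuft_index", "grazer_use_index", "n_quadrats", "clustered") |>
    dplyr::arrange(.data$species)
  class(out) <- c("trait_table", class(out))
  out
}
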