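#' Site summaries for bare-ground analyses
#'
#' Joins the per-site survey summary (bare ground, dung proportion), the
#' per-site growth-form cover and the site environment into one table, and
#' classifies each site's dominance: `"lateral"` when lateral attractors
#' out-cover tufted attractors, `"tufted"` when the reverse; exact ties are
#' `NA` and flagged.
#'
#' @param survey A `grass_survey`.
#' @param assignment A `growthform_model` or `species`/`growth_form` tibble.
#' @return A tibble of class `site_summary`: one row per site with
#'   `bare_ground_mean`, `dung_proportion`, one cover column per growth
#'   form, the environment variables, and `dominance`.
#' @export
site_summaries <- function(survey, assignment) {
  base <- summarize_survey(survey)
  cover <- growthform_site_cover(survey, assignment)
  for (f in c("lateral_attractor", "tufted_attractor")) {
    if (!f %in% names(cover)) cover[[f]] <- 0
  }
  out <- base |>
    dplyr::inner_join(cover, by = "site_id") |>
    dplyr::inner_join(survey$sites, by = "site_id") |>
    dplyr::mutate(dominance = dplyr::case_when(
      .data$lateral_attractor > .data$tufted_attractor ~ "lateral",
      .data$lateral_attractor < .data$tufted_attractor ~ "tufted",
      TRUE ~ NA_character_
    ))
  if (anyNA(out$dominance)) {
    warn(paste0("Exact attractor-cover ties at site(s): ",
      paste(out$site_id[is.na(out$dominance)], collapse = ", ")))
  }
  class(out) <- c("site_summary", class(out))
  out
}

#' Split sites into lateral- vs tufted-attractor-dominated groups
#'
#' @param summaries A `site_summary` tibble from [site_summaries()].
#' @return Named list of two tibbles, `lateral` and `tufted`; tied sites
#'   are excluded with a warning.
#' @export
dominance_split <- function(summaries) {
  tied <- is.na(summaries$dominance)
  if (any(tied)) {
    warn(paste0("Excluding tied site(s) from dominance split: ",
      paste(summaries$site_id[tied], collapse = ", ")))
  }
  ok <- summaries[!tied, ]
  list(
    lateral = ok[ok$dominance == "lateral", ],
    tufted = ok[ok$dominance == "tufted", ]
  )
}

#' One-way F comparison of bare ground between dominance groups
#'
#' Standard one-way ANOVA F-test on (1, n - 2) degrees of freedom of mean
#' site bare ground between the two dominance groups.
#'
#' @param summaries A `site_summary` tibble with `dominance` set, or any
#'   data frame with the `response`/`group` columns named below.
#' @param response Column holding the per-site response (default
#'   `bare_ground_mean`).
#' @param group Grouping column (default `dominance`).
#' @return One-row tibble: `f_statistic`, `df1`, `df2`, `p_value`, and the
#'   two group means.
#' @export
compare_groups <- function(summaries, response = "bare_ground_mean",
                           group = "dominance") {
  df <- summaries[!is.na(summaries[[group]]), ]
  counts <- table(df[[group]])
  if (length(counts) != 2 || any(counts < 2)) {
    abort("Group comparison needs two groups with at least 2 sites each",
      class = "grasslawns_degenerate_error")
  }
  fit <- lm(as.formula(paste(response, "~", group)), data = df)
  a <- anova(fit)
  means <- tapply(df[[response]], df[[group]], mean)
  tibble::tibble(
    f_statistic = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
    p_value = a$`Pr(>F)`[1],
    mean_1 = means[1], group_1 = names(means)[1],
    mean_2 = means[2], group_2 = names(means)[2]
  )
}

# All marginality-respecting sub-models of a three-way factorial: every
# subset of the 7 candidate terms that contains the main effects of each of
# its interactions, plus the intercept-only model.
marginal_term_sets <- function(vars = c("map_mm", "sand_pct", "dung_proportion")) {
  terms <- c(
    as.list(vars),
    asplit(combn(vars, 2), 2),
    list(vars)
  )
  term_labels <- vapply(terms, paste, "", collapse = ":")
  parents <- lapply(terms, function(t) {
    if (length(t) == 1) character() else {
      unlist(lapply(seq_len(length(t) - 1), function(k) {
        apply(combn(t, k), 2, paste, collapse = ":")
      }))
    }
  })
  keep <- list(character()) # intercept-only
  for (mask in seq_len(2^length(terms) - 1)) {
    inc <- which(bitwAnd(mask, 2^(seq_along(terms) - 1)) > 0)
    labels <- term_labels[inc]
    respects <- all(unlist(parents[inc]) %in% labels)
    if (respects) keep[[length(keep) + 1]] <- labels
  }
  keep
}

#' All-subsets AICc regression of bare ground on rainfall, sand and dung
#'
#' Fits ordinary least squares for every sub-model of
#' `map_mm * sand_pct * dung_proportion` that respects marginality
#' (interactions only alongside their main effects), plus the
#' intercept-only model, and ranks them by Gaussian AICc (the residual
#' variance counts as a parameter). Percentage bare ground is analysed
#' untransformed.
#'
#' @param group_sites A `site_summary` tibble (typically one element of
#'   [dominance_split()]).
#' @param response Response column (default `bare_ground_mean`).
#' @return An object of class `bareground_selection`: `ladder` (tibble
#'   `terms`, `n_params`, `logLik`, `aicc`, `delta_aicc`), `best_terms`,
#'   `best_fit` (the `lm`), `best_coefs`, and `best_f` (overall F, df and p
#'   of the best model against the intercept-only model; `NA` when the
#'   intercept-only model wins).
#' @export
fit_bareground_subsets <- function(group_sites,
                                   response = "bare_ground_mean") {
  n <- nrow(group_sites)
  if (n < 5) {
    warn("Fewer than 5 sites: saturated candidates will be skipped")
  }
  sets <- marginal_term_sets()
  rows <- list()
  fits <- list()
  for (i in seq_along(sets)) {
    labels <- sets[[i]]
    key <- if (length(labels) == 0) "(intercept)" else
      paste(labels, collapse = " + ")
    rhs <- if (length(labels) == 0) "1" else paste(labels, collapse = " + ")
    fit <- lm(as.formula(paste(response, "~", rhs)), data = group_sites)
    ll <- logLik(fit)
    p <- attr(ll, "df") # coefficients + residual variance
    flagged <- anyNA(fit$coefficients)
    rows[[key]] <- tibble::tibble(
      terms = key, n_params = p, logLik = as.numeric(ll),
      aicc = if (flagged) Inf else aicc(as.numeric(ll), p, n),
      collinear = flagged
    )
    fits[[key]] <- fit
  }
  ladder <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$aicc) |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc))
  best_terms <- ladder$terms[1]
  best_fit <- fits[[best_terms]]
  best_f <- tibble::tibble(f_statistic = NA_real_, df1 = NA_real_,
    df2 = NA_real_, p_value = NA_real_)
  fs <- summary(best_fit)$fstatistic
  if (!is.null(fs)) {
    best_f <- tibble::tibble(
      f_statistic = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
      p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    )
  }
  structure(list(
    ladder = ladder, best_terms = best_terms, best_fit = best_fit,
    best_coefs = stats::coef(best_fit), best_f = best_f,
    n_sites = n, response = response
  ), class = "bareground_selection")
}

#' @export
print.bareground_selection <- function(x, ...) {
  cat("<bareground_selection> n =", x$n_sites, "sites; best:",
    x$best_terms, "\n")
  print(as.data.frame(head(x$ladder, 5)))
  invisible(x)
}
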