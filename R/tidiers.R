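#' Tidy a growth-form model
#'
#' @param x A `growthform_model`.
#' @param ... Unused.
#' @return The assignments tibble (`species`, `growth_form`, `provenance`)
#'   joined with the numeric cluster ids.
#' @method tidy growthform_model
#' @export
tidy.growthform_model <- function(x, ...) {
  dplyr::left_join(x$assignments, x$clusters, by = "species")
}

#' @rdname tidy.growthform_model
#' @return For `glance()`: a one-row tibble with `k`, `n_species`,
#'   `n_clustered`, `pc1_variance_pct`, `pc2_variance_pct`.
#' @method glance growthform_model
#' @export
glance.growthform_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_species = nrow(x$assignments),
    n_clustered = sum(x$assignments$provenance == "clustered"),
    pc1_variance_pct = x$pca$variance_pct[1],
    pc2_variance_pct = x$pca$variance_pct[2]
  )
}

#' Tidy a fourth-corner fit
#'
#' @param x A `fourthcorner_fit`.
#' @param ... Unused.
#' @return Tibble `trait`, `env_variable`, `estimate` (one row per
#'   trait-environment coefficient).
#' @method tidy fourthcorner_fit
#' @export
tidy.fourthcorner_fit <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "env_variable",
      values_to = "estimate")
}

#' @rdname tidy.fourthcorner_fit
#' @method glance fourthcorner_fit
#' @export
glance.fourthcorner_fit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, logLik = x$logLik,
    n_params = x$n_params, n_cells = x$n_cells, AICc = x$aicc,
    ridged = x$ridged)
}

#' Tidy a fourth-corner environment-subset selection
#'
#' @param x A `fourthcorner_selection`.
#' @param ... Unused.
#' @return The AICc ladder tibble, ascending.
#' @method tidy fourthcorner_selection
#' @export
tidy.fourthcorner_selection <- function(x, ...) {
  x$ladder
}

#' @rdname tidy.fourthcorner_selection
#' @method glance fourthcorner_selection
#' @export
glance.fourthcorner_selection <- function(x, ...) {
  tibble::tibble(
    best_env_subset = x$ladder$env_subset[1],
    best_aicc = x$ladder$aicc[1],
    delta_to_full = x$ladder$delta_aicc[
      x$ladder$env_subset == paste(environment_variables, collapse = "+")],
    n_models = nrow(x$ladder)
  )
}

#' Tidy a resampling ANOVA
#'
#' @param x A `fourthcorner_anova`.
#' @param ... Unused.
#' @return One-row tibble `statistic`, `n_iterations`, `p_value`, `method`.
#' @method tidy fourthcorner_anova
#' @export
tidy.fourthcorner_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, n_iterations = x$n_iterations,
    p_value = x$p, method = x$method)
}

#' Tidy a site ordination
#'
#' @param x A `site_ordination`.
#' @param ... Unused.
#' @return Loadings in long form: `variable`, `component`, `loading`.
#' @method tidy site_ordination
#' @export
tidy.site_ordination <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
      values_to = "loading")
}

#' @rdname tidy.site_ordination
#' @method glance site_ordination
#' @export
glance.site_ordination <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$scores),
    pc1_variance_pct = x$variance_pct[1],
    pc2_variance_pct = x$variance_pct[2]
  )
}

#' Tidy a bare-ground subset selection
#'
#' @param x A `bareground_selection`.
#' @param ... Unused.
#' @return The AICc ladder tibble.
#' @method tidy bareground_selection
#' @export
tidy.bareground_selection <- function(x, ...) {
  x$ladder
}

#' @rdname tidy.bareground_selection
#' @method glance bareground_selection
#' @export
glance.bareground_selection <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(best_terms = x$best_terms, n_sites = x$n_sites,
      best_aicc = x$ladder$aicc[1],
      runner_up_delta = if (nrow(x$ladder) > 1) x$ladder$delta_aicc[2]
        else NA_real_),
    x$best_f
  )
}
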