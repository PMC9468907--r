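#' Write pipeline products to deterministic files
#'
#' Generic writer for every pipeline product. File names are fixed per
#' product type (`trait_table.csv`, `assignments.csv`, `vtests.csv`,
#' `pca_traits.csv`, `fourthcorner_coefs.csv`, `aicc_ladder.csv`,
#' `models.json`, `anova.json`, `site_pca.csv`, `cover_surface_<form>.csv`,
#' `bareground_models.json`, `quadrats.csv`/`quadrat_meta.csv`/`sites.csv`,
#' `ground_truth.json`), so re-running with identical inputs reproduces
#' byte-identical content.
#'
#' @param results A pipeline product (trait table, growth-form model,
#'   fourth-corner selection/ANOVA, site ordination, cover surfaces,
#'   bare-ground comparison, survey or simulation).
#' @param out_dir Output directory (created if needed).
#' @param ... Unused.
#' @return Tibble manifest of written files (`artifact`, `file`).
#' @export
write_results <- function(results, out_dir, ...) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      abort(paste0("Cannot create output directory: ", out_dir),
        class = "grasslawns_io_error")
    }
  }
  if (file.access(out_dir, 2) != 0) {
    abort(paste0("Output directory is not writable: ", out_dir),
      class = "grasslawns_io_error")
  }
  UseMethod("write_results")
}

#' @export
write_results.default <- function(results, out_dir, ...) {
  abort(paste0("No writer for objects of class ",
    paste(class(results), collapse = "/")))
}

manifest_row <- function(artifact, file) {
  tibble::tibble(artifact = artifact, file = file)
}

write_csv_det <- function(df, path) {
  readr::write_csv(tibble::as_tibble(df), path, na = "NA")
}

write_json_det <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
}

#' @export
write_results.trait_table <- function(results, out_dir, ...) {
  write_csv_det(results, file.path(out_dir, "trait_table.csv"))
  manifest_row("trait_table", "trait_table.csv")
}

#' @export
write_results.growthform_model <- function(results, out_dir, ...) {
  write_csv_det(results$assignments, file.path(out_dir, "assignments.csv"))
  vt <- results$vtests[c("cluster", "trait", "cluster_mean", "overall_mean",
    "v", "p")]
  write_csv_det(vt, file.path(out_dir, "vtests.csv"))
  pca_df <- dplyr::bind_cols(
    tibble::tibble(component = colnames(results$pca$loadings),
      variance_pct = results$pca$variance_pct),
    tibble::as_tibble(t(results$pca$loadings))
  )
  write_csv_det(pca_df, file.path(out_dir, "pca_traits.csv"))
  dplyr::bind_rows(
    manifest_row("assignments", "assignments.csv"),
    manifest_row("vtests", "vtests.csv"),
    manifest_row("pca_traits", "pca_traits.csv")
  )
}

#' @export
write_results.fourthcorner_selection <- function(results, out_dir, ...) {
  best <- results$best
  coefs <- tibble::as_tibble(best$coefficients, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "env_variable",
      values_to = "coefficient")
  write_csv_det(coefs, file.path(out_dir, "fourthcorner_coefs.csv"))
  ladder <- results$ladder[c("env_subset", "aicc", "delta_aicc", "n_params")]
  names(ladder) <- c("env_subset", "AICc", "delta_AICc", "n_params")
  write_csv_det(ladder, file.path(out_dir, "aicc_ladder.csv"))
  write_json_det(list(
    best = list(env = best$env, aicc = best$aicc, deviance = best$deviance,
      n_params = best$n_params, n_cells = best$n_cells,
      ridged = best$ridged),
    ladder = results$ladder[c("env_subset", "logLik", "n_params", "aicc",
      "delta_aicc")],
    reference = results$reference
  ), file.path(out_dir, "models.json"))
  dplyr::bind_rows(
    manifest_row("fourthcorner_coefs", "fourthcorner_coefs.csv"),
    manifest_row("aicc_ladder", "aicc_ladder.csv"),
    manifest_row("models", "models.json")
  )
}

#' @export
write_results.fourthcorner_anova <- function(results, out_dir, ...) {
  write_json_det(list(
    statistic = results$statistic, n_iterations = results$n_iterations,
    p = results$p, method = results$method, seed = results$seed
  ), file.path(out_dir, "anova.json"))
  manifest_row("anova", "anova.json")
}

#' @export
write_results.site_ordination <- function(results, out_dir, ...) {
  scores <- tibble::tibble(
    site_id = results$scores$site_id,
    pc1 = results$scores$PC1, pc2 = results$scores$PC2
  )
  write_csv_det(scores, file.path(out_dir, "site_pca.csv"))
  loadings <- dplyr::bind_cols(
    tibble::tibble(variable = rownames(results$loadings)),
    tibble::as_tibble(results$loadings)
  )
  loadings$variance_pct_of_component <- NULL
  write_csv_det(loadings, file.path(out_dir, "site_pca_loadings.csv"))
  dplyr::bind_rows(
    manifest_row("site_pca", "site_pca.csv"),
    manifest_row("site_pca_loadings", "site_pca_loadings.csv")
  )
}

#' @export
write_results.cover_surfaces <- function(results, out_dir, ...) {
  forms <- unique(results$surfaces$form)
  purrr::map_dfr(forms, function(f) {
    df <- results$surfaces[results$surfaces$form == f,
      c("pc1", "pc2", "cover")]
    file <- paste0("cover_surface_", f, ".csv")
    write_csv_det(df, file.path(out_dir, file))
    manifest_row(paste0("cover_surface_", f), file)
  })
}

#' @export
write_results.bareground_comparison <- function(results, out_dir, ...) {
  as_group <- function(sel) {
    if (is.null(sel)) return(NULL)
    list(
      n_sites = sel$n_sites,
      ladder = sel$ladder[c("terms", "n_params", "aicc", "delta_aicc")],
      best = list(terms = sel$best_terms,
        coefficients = as.list(sel$best_coefs),
        f = as.list(sel$best_f))
    )
  }
  write_json_det(list(
    group_comparison = as.list(results$comparison),
    lateral = as_group(results$lateral),
    tufted = as_group(results$tufted)
  ), file.path(out_dir, "bareground_models.json"))
  manifest_row("bareground_models", "bareground_models.json")
}

#' @export
write_results.site_summary <- function(results, out_dir, ...) {
  write_csv_det(results, file.path(out_dir, "site_summary.csv"))
  manifest_row("site_summary", "site_summary.csv")
}

#' @export
write_results.grass_survey <- function(results, out_dir, ...) {
  write_csv_det(results$observations, file.path(out_dir, "quadrats.csv"))
  write_csv_det(results$meta, file.path(out_dir, "quadrat_meta.csv"))
  write_csv_det(results$sites, file.path(out_dir, "sites.csv"))
  dplyr::bind_rows(
    manifest_row("quadrats", "quadrats.csv"),
    manifest_row("quadrat_meta", "quadrat_meta.csv"),
    manifest_row("sites", "sites.csv")
  )
}

#' @export
write_results.grass_simulation <- function(results, out_dir, ...) {
  m <- write_results(results$survey, out_dir)
  gt <- results$ground_truth
  write_json_det(list(
    pool = gt$pool, b = as.data.frame(gt$b),
    bareground = as.list(gt$bareground),
    sites = gt$sites, expected_cover = gt$expected_cover,
    seed = results$config$seed
  ), file.path(out_dir, "ground_truth.json"))
  dplyr::bind_rows(m, manifest_row("ground_truth", "ground_truth.json"))
}
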