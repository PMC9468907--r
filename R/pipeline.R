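#' Run the full grazed-grassland analysis pipeline
#'
#' Executes every stage in order — trait indices, growth-form
#' classification, fourth-corner trait-environment modelling with AICc
#' subset selection and resampling ANOVA, environmental ordination with
#' growth-form cover surfaces, and bare-ground regressions — writing each
#' stage's artifacts plus a `manifest.json` (package version, seed, config
#' echo, per-stage wall time and status). A stage failure aborts downstream
#' stages; the manifest records the partial completion.
#'
#' @param survey A `grass_survey`, or `NULL` to load one from the three
#'   paths below.
#' @param quadrats_path,meta_path,sites_path Input CSV paths (used when
#'   `survey` is `NULL`).
#' @param out_dir Output directory.
#' @param k Number of growth-form clusters (default 4).
#' @param n_iterations Resampling ANOVA iterations (default 999; >= 99
#'   enforced).
#' @param seed Seed recorded in the manifest and driving the resampling
#'   stream.
#' @param grid_n Cover-surface grid resolution per axis.
#' @param unit_variance Correlation-matrix PCA for the trait indices?
#' @param overrides Optional tibble (`species`, `growth_form`) or path to
#'   `overrides.csv` assigning rare species.
#' @param anova_method `"permute"` (default) or `"bootstrap"` site
#'   resampling.
#' @return Invisibly, a list with `results` (one entry per stage) and
#'   `manifest` (tibble of written files).
#' @export
run_pipeline <- function(survey = NULL, quadrats_path = NULL,
                         meta_path = NULL, sites_path = NULL,
                         out_dir, k = 4, n_iterations = 999, seed = 1,
                         grid_n = 100, unit_variance = TRUE,
                         overrides = NULL,
                         anova_method = c("permute", "bootstrap")) {
  anova_method <- match.arg(anova_method)
  if (k < 2) abort("k must be >= 2")
  if (n_iterations < 99) abort("n_iterations must be >= 99")
  if (is.character(overrides)) {
    overrides <- readr::read_csv(overrides, show_col_types = FALSE)
  }
  if (is.null(survey)) {
    survey <- load_survey(quadrats_path, meta_path, sites_path)
  }
  stopifnot(inherits(survey, "grass_survey"))

  results <- list()
  manifest_files <- list()
  stages <- list()
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed) {
      stages[[name]] <<- list(status = "skipped", seconds = 0)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) e)
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(out, "error")) {
      failed <<- TRUE
      stages[[name]] <<- list(status = "error", seconds = secs,
        message = conditionMessage(out))
      warn(paste0("Stage '", name, "' failed: ", conditionMessage(out),
        "; downstream stages skipped"))
      return(invisible(NULL))
    }
    stages[[name]] <<- list(status = "ok", seconds = secs)
    results[[name]] <<- out
    invisible(out)
  }

  run_stage("indices", function() {
    tt <- build_trait_table(survey)
    manifest_files$indices <<- write_results(tt, out_dir)
    tt
  })
  run_stage("classify", function() {
    gm <- assign_growth_forms(results$indices, k = k, overrides = overrides,
      unit_variance = unit_variance)
    manifest_files$classify <<- write_results(gm, out_dir)
    gm
  })
  run_stage("fourthcorner", function() {
    triplet <- build_triplet(survey, results$indices)
    selection <- select_env_subset(triplet)
    anova <- anova_resampling(triplet, env = selection$best$env,
      n_iterations = n_iterations, seed = seed, method = anova_method)
    manifest_files$fourthcorner <<- dplyr::bind_rows(
      write_results(selection, out_dir),
      write_results(anova, out_dir)
    )
    list(triplet = triplet, selection = selection, anova = anova)
  })
  run_stage("ordination", function() {
    ord <- site_environment_pca(survey$sites)
    cover <- growthform_site_cover(survey, results$classify)
    surfaces <- interpolate_cover_surface(ord, cover, grid_n = grid_n)
    manifest_files$ordination <<- dplyr::bind_rows(
      write_results(ord, out_dir),
      write_results(surfaces, out_dir)
    )
    list(ordination = ord, cover = cover, surfaces = surfaces)
  })
  run_stage("bareground", function() {
    summaries <- site_summaries(survey, results$classify)
    comparison <- compare_groups(summaries)
    groups <- dominance_split(summaries)
    fit_group <- function(df) {
      if (nrow(df) < 3) return(NULL)
      fit_bareground_subsets(df)
    }
    bg <- structure(list(
      summaries = summaries, comparison = comparison,
      lateral = fit_group(groups$lateral), tufted = fit_group(groups$tufted)
    ), class = "bareground_comparison")
    manifest_files$bareground <<- dplyr::bind_rows(
      write_results(summaries, out_dir),
      write_results(bg, out_dir)
    )
    bg
  })

  manifest <- dplyr::bind_rows(manifest_files)
  write_json_det(list(
    package = "grasslawns",
    version = as.character(utils::packageVersion("grasslawns")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = list(k = k, n_iterations = n_iterations, grid_n = grid_n,
      unit_variance = unit_variance, anova_method = anova_method),
    stages = stages,
    files = manifest$file
  ), file.path(out_dir, "manifest.json"))
  invisible(list(results = results, manifest = manifest, stages = stages))
}
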