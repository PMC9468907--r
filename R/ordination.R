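#' Ordinate sites by their environment
#'
#' Centred, unit-variance PCA of the four site environment variables (mean
#' annual rainfall, percent sand, CEC, pH), with the deterministic sign
#' convention of [pca_ordination()]. The first two axes are the plane on
#' which growth-form cover surfaces are interpolated.
#'
#' @param sites Tibble with `site_id` and the four environment columns (at
#'   least 3 sites, no missing values).
#' @return An object of class `site_ordination`: `scores` (tibble `site_id`,
#'   `PC1`..`PC4`), `loadings` (4 variables by 4 components),
#'   `variance_pct` (length 4, sums to 100), `center`, `scale`.
#' @export
site_environment_pca <- function(sites) {
  check_columns(sites, c("site_id", environment_variables), "sites")
  if (nrow(sites) < 3) abort("Site ordination needs at least 3 sites")
  m <- as.matrix(sites[environment_variables])
  rownames(m) <- sites$site_id
  if (anyNA(m)) abort("Missing environment values are not allowed")
  const <- apply(m, 2, sd) == 0
  if (any(const)) {
    abort(paste0("Constant environment variable(s): ",
      paste(environment_variables[const], collapse = ", ")),
      class = "grasslawns_degenerate_error")
  }
  p <- pca_ordination(m, unit_variance = TRUE)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(site_id = sites$site_id),
      tibble::as_tibble(p$scores)),
    loadings = p$loadings, variance_pct = p$variance_pct,
    center = p$center, scale = p$scale
  ), class = "site_ordination")
}

#' @export
print.site_ordination <- function(x, ...) {
  cat("<site_ordination> ", nrow(x$scores), " sites; variance (%): ",
    paste(sprintf("%.2f", x$variance_pct), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-site percentage cover of each growth form
#'
#' For every site and growth form, the mean over quadrats of the summed
#' per-species aerial cover of that form's species. All species occurring
#' at a site are included (not just the dominant 90% set); species without
#' a growth-form label contribute to an `unassigned` column and are
#' reported.
#'
#' @param survey A `grass_survey`.
#' @param assignment A `growthform_model` or a tibble with `species` and
#'   `growth_form`.
#' @return Tibble, one row per site, one column per growth form (absolute
#'   percent cover; a quadrat with no grass of a form contributes 0).
#' @export
growthform_site_cover <- function(survey, assignment) {
  if (inherits(assignment, "growthform_model")) {
    assignment <- assignment$assignments
  }
  check_columns(assignment, c("species", "growth_form"), "assignment")
  cover <- site_species_cover(survey) |>
    dplyr::left_join(assignment[c("species", "growth_form")], by = "species")
  unlabelled <- unique(cover$species[is.na(cover$growth_form)])
  if (length(unlabelled) > 0) {
    warn(paste0("Species without growth-form label counted as 'unassigned': ",
      paste(unlabelled, collapse = ", ")))
    cover$growth_form[is.na(cover$growth_form)] <- "unassigned"
  }
  forms <- intersect(c(growth_form_levels, "unassigned"),
    unique(cover$growth_form))
  cover |>
    dplyr::group_by(.data$site_id, .data$growth_form) |>
    dplyr::summarise(cover = sum(.data$mean_cover), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "growth_form", values_from = "cover",
      values_fill = 0) |>
    dplyr::select(dplyr::all_of(c("site_id", forms))) |>
    dplyr::arrange(.data$site_id)
}

#' Delaunay triangulation of points in the plane
#'
#' Direct circumcircle construction: a triangle belongs to the Delaunay
#' triangulation iff no other point lies strictly inside its circumcircle.
#' O(n^4), intended for the tens of sites a survey ordination produces;
#' near-degenerate (collinear) triples are skipped.
#'
#' @param points Numeric matrix or data frame with 2 columns.
#' @return Integer matrix, one row per triangle, columns the three vertex
#'   row indices of `points`.
#' @export
delaunay_triangulation <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 3) abort("Triangulation needs at least 3 points")
  scale_len <- max(apply(pts, 2, function(z) diff(range(z))))
  if (scale_len == 0) abort("All points coincide")
  eps <- 1e-9 * scale_len
  tris <- list()
  combs <- combn(n, 3)
  for (c_i in seq_len(ncol(combs))) {
    i <- combs[1, c_i]; j <- combs[2, c_i]; k <- combs[3, c_i]
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    area2 <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(area2) < eps * scale_len) next
    # Circumcentre via perpendicular bisector solve.
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) + (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
      (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
    uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
      (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
    r2 <- (a[1] - ux)^2 + (a[2] - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2
    if (all(d2 >= r2 - eps^2 - 1e-12 * r2)) {
      tris[[length(tris) + 1]] <- c(i, j, k)
    }
  }
  if (length(tris) == 0) {
    abort("No valid triangles (points may be collinear); consider jittering",
      class = "grasslawns_degenerate_error")
  }
  do.call(rbind, tris)
}

#' Piecewise-linear barycentric interpolation
#'
#' Evaluates the linear interpolant defined by a Delaunay triangulation of
#' `points` with values `values` at arbitrary query locations. Queries
#' outside the convex hull return `NA` (no extrapolation); at a data point
#' the interpolant reproduces the observed value exactly.
#'
#' @param points Numeric matrix/data frame with 2 columns (data locations).
#' @param values Numeric vector, one value per data point.
#' @param query Numeric matrix/data frame with 2 columns (locations to
#'   evaluate).
#' @param triangles Optional precomputed [delaunay_triangulation()] result.
#' @return Numeric vector of interpolated values, `NA` outside the hull.
#' @export
interp_barycentric <- function(points, values, query, triangles = NULL) {
  pts <- as.matrix(points)
  q <- as.matrix(query)
  stopifnot(length(values) == nrow(pts))
  if (is.null(triangles)) triangles <- delaunay_triangulation(pts)
  out <- rep(NA_real_, nrow(q))
  tol <- 1e-9
  for (t_i in seq_len(nrow(triangles))) {
    v <- triangles[t_i, ]
    a <- pts[v[1], ]; b <- pts[v[2], ]; c <- pts[v[3], ]
    det <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    w1 <- ((b[2] - c[2]) * (q[, 1] - c[1]) + (c[1] - b[1]) * (q[, 2] - c[2])) / det
    w2 <- ((c[2] - a[2]) * (q[, 1] - c[1]) + (a[1] - c[1]) * (q[, 2] - c[2])) / det
    w3 <- 1 - w1 - w2
    inside <- w1 >= -tol & w2 >= -tol & w3 >= -tol
    fill <- inside & is.na(out)
    out[fill] <- w1[fill] * values[v[1]] + w2[fill] * values[v[2]] +
      w3[fill] * values[v[3]]
  }
  out
}

#' Interpolate growth-form cover across the environmental ordination plane
#'
#' Lays a `grid_n` by `grid_n` grid over the first two ordination axes and
#' evaluates, for each growth form, the piecewise-linear barycentric
#' interpolant of site-level percent cover over a Delaunay triangulation of
#' the site scores. Values are clipped at 0 and the grid is restricted to
#' the convex hull of the sites (`NA` outside); contour levels run from 0
#' in 10-percent-cover steps.
#'
#' @param ordination A `site_ordination`.
#' @param cover Sites-by-growth-forms cover tibble from
#'   [growthform_site_cover()].
#' @param grid_n Grid resolution per axis (default 100).
#' @param forms Growth-form columns to interpolate (default: all present).
#' @return An object of class `cover_surfaces`: `surfaces` (tibble `form`,
#'   `pc1`, `pc2`, `cover`), `levels` (named list of contour levels),
#'   `at_sites` (interpolated value at each site's own coordinates),
#'   `sites`, `triangles`.
#' @export
interpolate_cover_surface <- function(ordination, cover, grid_n = 100,
                                      forms = NULL) {
  stopifnot(inherits(ordination, "site_ordination"))
  scores <- ordination$scores
  joined <- dplyr::inner_join(scores, cover, by = "site_id")
  if (nrow(joined) < 3) abort("Need at least 3 sites with cover values")
  if (is.null(forms)) {
    forms <- setdiff(names(cover), "site_id")
  }
  pts <- as.matrix(joined[c("PC1", "PC2")])
  tris <- delaunay_triangulation(pts)
  grid <- expand.grid(
    pc1 = seq(min(pts[, 1]), max(pts[, 1]), length.out = grid_n),
    pc2 = seq(min(pts[, 2]), max(pts[, 2]), length.out = grid_n)
  )
  surfaces <- purrr::map_dfr(forms, function(f) {
    z <- interp_barycentric(pts, joined[[f]], grid, triangles = tris)
    tibble::tibble(form = f, pc1 = grid$pc1, pc2 = grid$pc2,
      cover = pmax(z, 0))
  })
  at_sites <- purrr::map_dfr(forms, function(f) {
    tibble::tibble(form = f, site_id = joined$site_id,
      observed = joined[[f]],
      interpolated = interp_barycentric(pts, joined[[f]], pts,
        triangles = tris))
  })
  levels <- lapply(setNames(forms, forms), function(f) {
    top <- max(joined[[f]], 0)
    seq(0, ceiling(top / 10) * 10, by = 10)
  })
  structure(list(
    surfaces = surfaces, levels = levels, at_sites = at_sites,
    sites = joined[c("site_id", "PC1", "PC2", forms)], triangles = tris,
    grid_n = grid_n
  ), class = "cover_surfaces")
}

#' @export
print.cover_surfaces <- function(x, ...) {
  cat("<cover_surfaces> forms: ",
    paste(unique(x$surfaces$form), collapse = ", "),
    "; grid ", x$grid_n, "x", x$grid_n, "\n", sep = "")
  invisible(x)
}
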