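#' Range-standardize a table of variables to \[0, 1\]
#'
#' Each variable is mapped by `(x - min) / (max - min)`. The minima and
#' maxima are recorded in the `"ranges"` attribute so the transform can be
#' replayed on new data.
#'
#' @param x A data frame or numeric matrix (items by variables).
#' @return An object of the same shape with each column in \[0, 1\] and a
#'   `ranges` attribute (tibble `variable`, `min`, `max`).
#' @export
range_standardize <- function(x) {
  m <- as.matrix(x)
  rng <- apply(m, 2, range)
  constant <- rng[2, ] - rng[1, ] <= 0
  if (any(constant)) {
    abort(paste0("Cannot range-standardize constant variable(s): ",
      paste(colnames(m)[constant], collapse = ", ")),
      class = "grasslawns_degenerate_error")
  }
  out <- sweep(sweep(m, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/")
  attr(out, "ranges") <- tibble::tibble(
    variable = colnames(m), min = unname(rng[1, ]), max = unname(rng[2, ])
  )
  out
}

#' Principal components analysis with a deterministic sign convention
#'
#' Thin wrapper around [stats::prcomp()] that centres (and optionally
#' unit-variance scales) the input and fixes the sign indeterminacy of each
#' component: the largest-magnitude loading of every component is made
#' positive, so repeated runs and cross-platform runs agree exactly.
#'
#' @param x Numeric matrix or data frame, items by variables (>= 2 of each,
#'   no missing values).
#' @param unit_variance Scale variables to unit variance (correlation-matrix
#'   PCA) before decomposition? Default `TRUE`.
#' @return An object of class `grass_pca`: list with `loadings` (variables
#'   by components), `scores` (items by components), `variance_pct` (per
#'   component, sums to 100), `center`, `scale`.
#' @export
pca_ordination <- function(x, unit_variance = TRUE) {
  m <- as.matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("PCA needs at least 2 items and 2 variables",
      class = "grasslawns_degenerate_error")
  }
  if (anyNA(m)) abort("PCA input contains missing values")
  sds <- apply(m, 2, sd)
  if (all(sds == 0)) abort("PCA input has rank 0 (all variables constant)")
  if (unit_variance && any(sds == 0)) {
    abort(paste0("Cannot unit-variance scale constant variable(s): ",
      paste(colnames(m)[sds == 0], collapse = ", ")),
      class = "grasslawns_degenerate_error")
  }
  p <- prcomp(m, center = TRUE, scale. = unit_variance)
  # Sign convention: flip components whose largest-|loading| entry is negative.
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(
    loadings = p$rotation,
    scores = p$x,
    variance_pct = 100 * p$sdev^2 / sum(p$sdev^2),
    center = p$center,
    scale = if (unit_variance) p$scale else rep(1, ncol(m))
  ), class = "grass_pca")
}

#' Agglomerative Ward clustering of points
#'
#' Builds the minimum-variance (Ward) agglomeration tree on Euclidean
#' coordinates — at each step the pair of clusters whose merger least
#' increases total within-cluster variance is joined. Heights are on the
#' distance scale (`sqrt(2 * delta SS)`).
#'
#' @param points Numeric matrix, items by coordinates (e.g. PCA scores).
#' @return An object of class `hclust`.
#' @export
ward_cluster <- function(points) {
  m <- as.matrix(points)
  if (nrow(m) < 2) abort("Clustering needs at least 2 items")
  hclust(dist(m), method = "ward.D2")
}

#' Cut an agglomeration tree into k groups
#'
#' Removes the k-1 highest merges and relabels the resulting groups
#' deterministically: label 1 is the largest cluster, ties broken by first
#' appearance in dendrogram leaf order.
#'
#' @param tree An `hclust` object.
#' @param k Number of groups, between 1 and the number of items.
#' @return Integer vector of cluster labels (named by item labels when the
#'   tree carries them).
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) {
    abort(paste0("k must be between 1 and ", n, ", got ", k))
  }
  raw <- cutree(tree, k = k)
  sizes <- table(raw)
  first_leaf <- vapply(names(sizes), function(cl) {
    min(match(which(raw == as.integer(cl)), tree$order))
  }, numeric(1))
  ord <- order(-as.vector(sizes), first_leaf)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  out <- relabel[raw]
  names(out) <- names(raw)
  out
}

#' v-test description of clusters
#'
#' For each cluster and trait, compares the cluster mean to the overall
#' mean, scaled by the variability of a random subset of the same size
#' drawn without replacement:
#' \deqn{v = (\bar x_k - \bar x) / \sqrt{(s^2/n_k)\,(N - n_k)/(N - 1)}}
#' with \eqn{s^2} the population variance of all N values. Large |v| means
#' the cluster mean is far from what a random subset of that size would
#' give; the two-sided p-value uses the standard normal reference.
#'
#' @param values Numeric vector, or data frame / matrix of trait columns.
#' @param labels Cluster label per item.
#' @return Tibble with one row per (cluster, trait): `cluster`, `trait`,
#'   `n`, `cluster_mean`, `overall_mean`, `v`, `p`, `degenerate` (TRUE when
#'   the trait is constant overall so v is reported as 0).
#' @export
vtest <- function(values, labels) {
  if (is.vector(values) && is.numeric(values)) {
    values <- tibble::tibble(value = values)
  }
  values <- as.data.frame(values)
  n_items <- nrow(values)
  if (n_items < 2) abort("v-test needs at least 2 items")
  if (length(labels) != n_items) abort("labels must match the number of items")
  purrr::map_dfr(names(values), function(trait) {
    x <- values[[trait]]
    overall <- mean(x)
    s2 <- mean((x - overall)^2) # population variance
    purrr::map_dfr(sort(unique(labels)), function(cl) {
      idx <- labels == cl
      n_k <- sum(idx)
      cl_mean <- mean(x[idx])
      degenerate <- s2 == 0
      v <- if (degenerate || n_items == n_k) {
        0
      } else {
        (cl_mean - overall) /
          sqrt(s2 / n_k * (n_items - n_k) / (n_items - 1))
      }
      tibble::tibble(
        cluster = cl, trait = trait, n = n_k,
        cluster_mean = cl_mean, overall_mean = overall,
        v = v, p = 2 * pnorm(-abs(v)), degenerate = degenerate
      )
    })
  })
}

# Map numbered clusters onto named growth forms by their v-test signature.
# Names are claimed greedily in a fixed precedence order, each by the
# remaining cluster with the highest signature score; near-ties are flagged
# ambiguous rather than silently resolved.
name_clusters <- function(vtests) {
  vw <- vtests |>
    dplyr::select("cluster", "trait", "v") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "v")
  scores <- tibble::tibble(
    cluster = vw$cluster,
    lateral_attractor = vw$lateral_index,
    resister = vw$culm_orientation_index - vw$grazer_use_index,
    tufted_attractor = vw$tuft_index + vw$grazer_use_index,
    avoider = -(vw$grazer_use_index + vw$tuft_index)
  )
  remaining <- scores$cluster
  out <- tibble::tibble(cluster = integer(), growth_form = character(),
    signature_score = numeric(), ambiguous = logical())
  for (form in c("lateral_attractor", "resister", "tufted_attractor", "avoider")) {
    s <- scores[[form]][match(remaining, scores$cluster)]
    best <- which.max(s)
    ambiguous <- sum(abs(s - s[best]) < 1e-8) > 1
    out <- dplyr::bind_rows(out, tibble::tibble(
      cluster = remaining[best], growth_form = form,
      signature_score = s[best], ambiguous = ambiguous
    ))
    remaining <- remaining[-best]
    if (length(remaining) == 0) break
  }
  dplyr::arrange(out, .data$cluster)
}

#' Classify species into growth forms by clustering on principal components
#'
#' The full classification pipeline for species occurring in more than 10
#' quadrats: range-standardize the four trait indices, PCA (all components
#' retained), Ward agglomeration on the PC scores, cut into `k` groups, and
#' v-test description of each group on the raw indices. With `k = 4` the
#' groups are mapped onto the named growth forms (lateral attractor,
#' avoider, tufted attractor, resister) by their v-test signatures; species
#' in 10 or fewer quadrats receive labels from the `overrides` table.
#'
#' @param trait_table A `trait_table` from [build_trait_table()].
#' @param k Number of clusters (default 4, the ecologically interpretable
#'   cut).
#' @param overrides Optional tibble `species`, `growth_form` assigning rare
#'   (non-clustered) species; clustered species in this table are ignored
#'   with a warning. Non-clustered species without an override are labelled
#'   `"unassigned"` with a warning.
#' @param unit_variance Use correlation-matrix PCA (default `TRUE`).
#' @return An object of class `growthform_model` with elements
#'   `assignments` (tibble `species`, `growth_form`, `provenance`),
#'   `clusters`, `pca` (`grass_pca`), `tree` (`hclust`), `vtests`,
#'   `cluster_names`, `k`.
#' @export
assign_growth_forms <- function(trait_table, k = 4, overrides = NULL,
                                unit_variance = TRUE) {
  stopifnot(is.data.frame(trait_table))
  clustered <- dplyr::filter(trait_table, .data$clustered)
  if (nrow(clustered) < k) {
    abort(paste0("Need at least k = ", k, " clustered species, have ",
      nrow(clustered)), class = "grasslawns_degenerate_error")
  }
  X <- as.matrix(clustered[trait_index_names])
  rownames(X) <- clustered$species
  pca <- pca_ordination(range_standardize(X), unit_variance = unit_variance)
  tree <- ward_cluster(pca$scores)
  labels <- cut_tree(tree, k)
  vt <- vtest(as.data.frame(X), labels)
  cluster_names <- if (k == 4) {
    name_clusters(vt)
  } else {
    tibble::tibble(cluster = sort(unique(labels)),
      growth_form = paste0("cluster_", sort(unique(labels))),
      signature_score = NA_real_, ambiguous = FALSE)
  }

  clustered_assign <- tibble::tibble(
    species = clustered$species,
    cluster = unname(labels),
    growth_form = cluster_names$growth_form[match(labels, cluster_names$cluster)],
    provenance = "clustered"
  )
  rare <- dplyr::filter(trait_table, !.data$clustered)
  if (!is.null(overrides)) {
    check_columns(overrides, c("species", "growth_form"), "overrides")
    ignored <- intersect(overrides$species, clustered$species)
    if (length(ignored) > 0) {
      warn(paste0("Overrides for clustered species ignored: ",
        paste(ignored, collapse = ", ")))
    }
  }
  rare_assign <- tibble::tibble(
    species = rare$species,
    cluster = NA_integer_,
    growth_form = if (is.null(overrides)) NA_character_ else
      overrides$growth_form[match(rare$species, overrides$species)],
    provenance = "manual_override"
  )
  unassigned <- is.na(rare_assign$growth_form)
  if (any(unassigned)) {
    warn(paste0("No override for rare species, labelled 'unassigned': ",
      paste(rare_assign$species[unassigned], collapse = ", ")))
    rare_assign$growth_form[unassigned] <- "unassigned"
    rare_assign$provenance[unassigned] <- "unassigned"
  }
  assignments <- dplyr::arrange(
    dplyr::bind_rows(clustered_assign, rare_assign), .data$species
  )
  structure(list(
    assignments = assignments[c("species", "growth_form", "provenance")],
    clusters = assignments[c("species", "cluster")],
    pca = pca, tree = tree, vtests = vt,
    cluster_names = cluster_names, k = k,
    trait_table = trait_table
  ), class = "growthform_model")
}

#' @export
print.growthform_model <- function(x, ...) {
  cat("<growthform_model> k =", x$k, "\n")
  cat("  clustered species:", sum(x$assignments$provenance == "clustered"), "\n")
  cat("  PC variance (%):",
    paste(sprintf("%.2f", x$pca$variance_pct), collapse = ", "), "\n")
  print(table(x$assignments$growth_form))
  invisible(x)
}
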