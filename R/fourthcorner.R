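#' Minimal species set comprising 90% of site cover
#'
#' Species are sorted by descending cover (ties alphabetical) and the
#' shortest prefix whose cumulative share of total site cover reaches the
#' threshold is returned. This captures the dominant species at a site while
#' discarding abundance information downstream.
#'
#' @param cover Named numeric vector of per-species cover at one site, or a
#'   tibble with columns `species` and `cover`.
#' @param threshold Cumulative share of total cover to reach (default 0.9).
#' @return Character vector of retained species, in descending-cover order.
#' @export
minimal_cover_set <- function(cover, threshold = 0.9) {
  if (is.data.frame(cover)) {
    cover <- setNames(cover$cover, cover$species)
  }
  cover <- cover[cover > 0]
  if (length(cover) == 0 || sum(cover) <= 0) {
    abort("All covers are zero; no minimal cover set exists",
      class = "grasslawns_degenerate_error")
  }
  ord <- order(-cover, names(cover))
  share <- cumsum(cover[ord]) / sum(cover)
  keep <- seq_len(which(share >= threshold - 1e-12)[1])
  names(cover)[ord][keep]
}

# Site-level mean per-species cover: summed cover over quadrats divided by
# the number of quadrats at the site (absent species count as zero cover).
site_species_cover <- function(survey) {
  n_q <- dplyr::count(survey$meta, .data$site_id, name = "n_quadrats")
  survey$observations |>
    dplyr::group_by(.data$site_id, .data$species) |>
    dplyr::summarise(total_cover = sum(.data$cover_pct), .groups = "drop") |>
    dplyr::inner_join(n_q, by = "site_id") |>
    dplyr::mutate(mean_cover = .data$total_cover / .data$n_quadrats) |>
    dplyr::select("site_id", "species", "mean_cover")
}

#' Assemble the L, R, Q matrices for fourth-corner analysis
#'
#' Builds the three linked tables of a fourth-corner analysis from a survey:
#' `L`, sites by species presence/absence restricted to each site's minimal
#' 90%-cover set; `R`, sites by the four environment variables, centred and
#' unit-variance scaled; `Q`, species by the four trait indices, likewise
#' standardized. Scaling centres and SDs are recorded.
#'
#' @param survey A `grass_survey`.
#' @param trait_table A `trait_table`; every retained species must appear.
#' @param threshold Cover share defining the minimal set (default 0.9).
#' @return An object of class `community_triplet`: list with `L`, `R`, `Q`,
#'   raw counterparts `R_raw`/`Q_raw`, `cover` (sites by species site-mean
#'   cover), `retained` (list of per-site minimal sets), and `scalers`.
#' @export
build_triplet <- function(survey, trait_table, threshold = 0.9) {
  stopifnot(inherits(survey, "grass_survey"))
  cover_long <- site_species_cover(survey)
  sites <- sort(unique(survey$sites$site_id))
  retained <- lapply(setNames(sites, sites), function(s) {
    sub <- dplyr::filter(cover_long, .data$site_id == s)
    minimal_cover_set(setNames(sub$mean_cover, sub$species), threshold)
  })
  species <- sort(unique(unlist(retained)))
  missing <- setdiff(species, trait_table$species)
  if (length(missing) > 0) {
    abort(paste0("Retained species missing from trait table: ",
      paste(missing, collapse = ", ")), class = "grasslawns_validation_error")
  }
  L <- matrix(0L, length(sites), length(species),
    dimnames = list(sites, species))
  for (s in sites) L[s, retained[[s]]] <- 1L
  cover_mat <- matrix(0, length(sites), length(species),
    dimnames = list(sites, species))
  retained_species <- species
  sub <- dplyr::filter(cover_long, .data$species %in% retained_species)
  cover_mat[cbind(sub$site_id, sub$species)] <- sub$mean_cover

  env <- as.matrix(survey$sites[match(sites, survey$sites$site_id),
    environment_variables])
  rownames(env) <- sites
  const_env <- apply(env, 2, sd) == 0
  if (any(const_env)) {
    abort(paste0("Constant environment variable(s) cannot be standardized: ",
      paste(environment_variables[const_env], collapse = ", ")),
      class = "grasslawns_degenerate_error")
  }
  R <- scale(env)
  Q_raw <- as.matrix(trait_table[match(species, trait_table$species),
    trait_index_names])
  rownames(Q_raw) <- species
  const_q <- apply(Q_raw, 2, sd) == 0
  if (any(const_q)) {
    abort(paste0("Constant trait index(es) across retained species cannot ",
      "be standardized: ", paste(trait_index_names[const_q], collapse = ", ")),
      class = "grasslawns_degenerate_error")
  }
  Q <- scale(Q_raw)
  structure(list(
    L = L, R = R[, , drop = FALSE], Q = Q[, , drop = FALSE],
    R_raw = env, Q_raw = Q_raw, cover = cover_mat, retained = retained,
    scalers = list(
      R_center = attr(R, "scaled:center"), R_scale = attr(R, "scaled:scale"),
      Q_center = attr(Q, "scaled:center"), Q_scale = attr(Q, "scaled:scale")
    )
  ), class = "community_triplet")
}

#' @export
print.community_triplet <- function(x, ...) {
  cat("<community_triplet> ", nrow(x$L), " sites x ", ncol(x$L),
    " species; retained per site: ",
    paste(range(rowSums(x$L)), collapse = "-"), "\n", sep = "")
  invisible(x)
}

# Vectorized fourth-corner design. Rows are site-major (site 1's species,
# then site 2's, ...). `site_index` re-maps environment rows to sites, which
# is how the resampling ANOVA permutes/bootstraps site blocks.
fourth_corner_design <- function(triplet, env, site_index = NULL,
                                 interactions = TRUE) {
  L <- triplet$L
  n_sites <- nrow(L)
  n_sp <- ncol(L)
  if (is.null(site_index)) site_index <- seq_len(n_sites)
  y <- as.vector(t(L))
  X_sp <- kronecker(matrix(1, n_sites, 1), diag(n_sp))
  colnames(X_sp) <- paste0("sp_", colnames(L))
  E <- triplet$R[site_index, env, drop = FALSE]
  E_rows <- E[rep(seq_len(n_sites), each = n_sp), , drop = FALSE]
  colnames(E_rows) <- env
  X <- cbind(X_sp, E_rows)
  if (interactions) {
    Q_rows <- triplet$Q[rep(seq_len(n_sp), times = n_sites), , drop = FALSE]
    X_int <- do.call(cbind, lapply(env, function(e) {
      m <- Q_rows * E_rows[, e]
      colnames(m) <- paste0(trait_index_names, ":", e)
      m
    }))
    X <- cbind(X, X_int)
  }
  list(X = X, y = y)
}

# Binomial IRLS with an optional ridge penalty; used as the stabilised
# fallback when plain ML separates.
ridge_irls <- function(X, y, lambda = 1e-2, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X + diag(lambda, p), XtW %*% z))
    mu <- plogis(drop(X %*% beta))
    mu <- clip(mu, 1e-12, 1 - 1e-12)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  list(coefficients = setNames(beta, colnames(X)), deviance = dev,
    converged = TRUE)
}

fit_binomial <- function(X, y, ridge_fallback = TRUE) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), control = list(maxit = 100))
  )
  coefs <- fit$coefficients
  free <- grep("^sp_", names(coefs), invert = TRUE)
  separated <- !fit$converged ||
    anyNA(coefs) ||
    (length(free) > 0 && max(abs(coefs[free])) > 15)
  ridged <- FALSE
  if (separated && ridge_fallback) {
    warn("Separation detected in binomial fit; using ridge-stabilised fit",
      class = "grasslawns_separation_warning")
    fit <- ridge_irls(X, y)
    ridged <- TRUE
  } else if (separated) {
    abort("Binomial fit did not converge (possible complete separation)",
      class = "grasslawns_fit_error")
  }
  list(coefficients = fit$coefficients, deviance = fit$deviance,
    converged = TRUE, ridged = ridged)
}

#' Fit the fourth-corner binomial GLM
#'
#' Fits one logistic regression to the vectorized presence/absence matrix
#' `L`, with a linear predictor of species intercepts, environment main
#' effects, and one interaction coefficient per (trait, environment
#' variable) pair — the fourth-corner terms. Traits being species-constant,
#' their main effects are absorbed by the species intercepts. Maximum
#' likelihood via IRLS; on complete separation the fit falls back to a
#' lightly ridge-penalised IRLS with a warning.
#'
#' @param triplet A `community_triplet`.
#' @param env Non-empty character subset of
#'   `c("map_mm", "sand_pct", "cec", "ph")`; default all four.
#' @return An object of class `fourthcorner_fit`: `coefficients` (4 traits
#'   by |env| matrix), `species_intercepts`, `env_main`, `env`, `deviance`,
#'   `logLik`, `n_params`, `n_cells`, `aicc`, `ridged`.
#' @export
fit_fourth_corner <- function(triplet, env = environment_variables) {
  stopifnot(inherits(triplet, "community_triplet"))
  env <- match.arg(env, environment_variables, several.ok = TRUE)
  if (length(env) == 0) abort("env subset must be non-empty")
  d <- fourth_corner_design(triplet, env)
  fit <- fit_binomial(d$X, d$y)
  coefs <- fit$coefficients
  B <- matrix(NA_real_, length(trait_index_names), length(env),
    dimnames = list(trait_index_names, env))
  for (q in trait_index_names) {
    for (e in env) B[q, e] <- coefs[paste0(q, ":", e)]
  }
  loglik <- -fit$deviance / 2
  n_cells <- length(d$y)
  n_params <- ncol(d$X)
  structure(list(
    coefficients = B,
    species_intercepts = coefs[grep("^sp_", names(coefs))],
    env_main = coefs[env],
    env = env, deviance = fit$deviance, logLik = loglik,
    n_params = n_params, n_cells = n_cells,
    aicc = aicc(loglik, n_params, n_cells), ridged = fit$ridged
  ), class = "fourthcorner_fit")
}

#' @export
print.fourthcorner_fit <- function(x, ...) {
  cat("<fourthcorner_fit> env: ", paste(x$env, collapse = " + "),
    "; AICc = ", format(x$aicc), if (x$ridged) " (ridge-stabilised)", "\n",
    sep = "")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Select the environment subset by AICc
#'
#' Fits the fourth-corner GLM for every non-empty subset of the four
#' environment variables (15 models) and ranks them by small-sample
#' corrected AICc. A species-intercepts-only reference model (no
#' environment, hence no trait-environment terms) is fitted separately as a
#' null anchor; it does not compete in the ladder.
#'
#' @param triplet A `community_triplet`.
#' @return An object of class `fourthcorner_selection`: `ladder` (tibble
#'   `env_subset`, `logLik`, `n_params`, `aicc`, `delta_aicc`, `ridged`,
#'   sorted ascending), `best` (the minimum-AICc `fourthcorner_fit`),
#'   `fits` (all 15), and `reference` (intercept-only AICc).
#' @export
select_env_subset <- function(triplet) {
  subsets <- unlist(lapply(seq_along(environment_variables), function(k) {
    asplit(combn(environment_variables, k), 2)
  }), recursive = FALSE)
  fits <- list()
  rows <- list()
  for (s in subsets) {
    key <- paste(s, collapse = "+")
    fit <- tryCatch(fit_fourth_corner(triplet, env = as.character(s)),
      error = function(e) e)
    fits[[key]] <- fit
    rows[[key]] <- if (inherits(fit, "error")) {
      tibble::tibble(env_subset = key, logLik = NA_real_,
        n_params = NA_integer_, aicc = Inf, ridged = NA,
        error = conditionMessage(fit))
    } else {
      tibble::tibble(env_subset = key, logLik = fit$logLik,
        n_params = fit$n_params, aicc = fit$aicc, ridged = fit$ridged,
        error = NA_character_)
    }
  }
  ladder <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$aicc) |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc))
  # Null anchor: species intercepts only.
  d0 <- fourth_corner_design(triplet, environment_variables,
    interactions = FALSE)
  X0 <- d0$X[, grep("^sp_", colnames(d0$X)), drop = FALSE]
  ref_fit <- fit_binomial(X0, d0$y)
  reference <- tibble::tibble(
    env_subset = "(none)", logLik = -ref_fit$deviance / 2,
    n_params = ncol(X0),
    aicc = aicc(-ref_fit$deviance / 2, ncol(X0), length(d0$y))
  )
  structure(list(
    ladder = ladder[c("env_subset", "logLik", "n_params", "aicc",
      "delta_aicc", "ridged", "error")],
    best = fits[[ladder$env_subset[1]]],
    fits = fits, reference = reference
  ), class = "fourthcorner_selection")
}

#' @export
print.fourthcorner_selection <- function(x, ...) {
  cat("<fourthcorner_selection> best:", x$ladder$env_subset[1], "\n")
  print(as.data.frame(head(x$ladder, 5)))
  invisible(x)
}

#' Resampling ANOVA for the overall trait-environment interaction
#'
#' Tests whether the trait-environment terms jointly improve on a model
#' with species intercepts and environment main effects only. The observed
#' statistic is the likelihood-ratio deviance between the two models. The
#' null distribution resamples whole sites: each site's species block keeps
#' its responses while the site-to-environment pairing is permuted
#' (`method = "permute"`, default) or drawn with replacement
#' (`method = "bootstrap"`); both models are refitted each iteration, which
#' preserves within-site species correlation.
#'
#' @param triplet A `community_triplet`.
#' @param env Environment subset to test (default all four variables).
#' @param n_iterations Number of resampling iterations (default 999; below
#'   99 a warning flags the coarse p resolution).
#' @param seed Optional integer seed for the resampling stream.
#' @param method `"permute"` or `"bootstrap"`.
#' @return An object of class `fourthcorner_anova`: `statistic`,
#'   `null_statistics`, `n_iterations`, `p` (computed as
#'   `(1 + #\{null >= observed\}) / (1 + n_iterations)`), `method`, `seed`.
#' @export
anova_resampling <- function(triplet, env = environment_variables,
                             n_iterations = 999, seed = NULL,
                             method = c("permute", "bootstrap")) {
  stopifnot(inherits(triplet, "community_triplet"))
  method <- match.arg(method)
  if (n_iterations < 99) {
    warn("Fewer than 99 iterations gives a coarse p-value resolution")
  }
  if (!is.null(seed)) set.seed(seed)
  n_sites <- nrow(triplet$L)
  n_sp <- ncol(triplet$L)
  # The species block and trait rows never change across iterations; only
  # the environment-dependent columns are rebuilt from the resampled site
  # index.
  y <- as.vector(t(triplet$L))
  X_sp <- kronecker(matrix(1, n_sites, 1), diag(n_sp))
  Q_rows <- triplet$Q[rep(seq_len(n_sp), times = n_sites), , drop = FALSE]
  E_base <- triplet$R[, env, drop = FALSE]
  site_rows <- rep(seq_len(n_sites), each = n_sp)
  n_env <- length(env)
  n_int <- length(trait_index_names) * n_env
  fam <- binomial()
  lr_stat <- function(site_index) {
    E_rows <- E_base[site_index[site_rows], , drop = FALSE]
    X_int <- matrix(0, length(y), n_int)
    k <- 0
    for (e in seq_len(n_env)) {
      X_int[, k + seq_len(ncol(Q_rows))] <- Q_rows * E_rows[, e]
      k <- k + ncol(Q_rows)
    }
    X_null <- cbind(X_sp, E_rows)
    f_null <- suppressWarnings(glm.fit(X_null, y, family = fam,
      control = list(maxit = 100)))
    f_full <- suppressWarnings(glm.fit(cbind(X_null, X_int), y, family = fam,
      control = list(maxit = 100)))
    f_null$deviance - f_full$deviance
  }
  observed <- lr_stat(seq_len(n_sites))
  null_stats <- vapply(seq_len(n_iterations), function(i) {
    idx <- if (method == "permute") {
      sample.int(n_sites)
    } else {
      sample.int(n_sites, replace = TRUE)
    }
    lr_stat(idx)
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (1 + n_iterations)
  structure(list(
    statistic = observed, null_statistics = null_stats,
    n_iterations = n_iterations, p = p, method = method, seed = seed
  ), class = "fourthcorner_anova")
}

#' @export
print.fourthcorner_anova <- function(x, ...) {
  cat("<fourthcorner_anova> LR deviance = ", format(x$statistic),
    ", p = ", format(x$p), " (", x$n_iterations, " ", x$method,
    " iterations)\n", sep = "")
  invisible(x)
}
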