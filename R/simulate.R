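#' Default growth-form archetype parameters
#'
#' Four archetypes whose latent trait-index distributions qualitatively
#' mirror the field growth forms: lateral attractors (high lateral, low
#' tuft, prostrate culms, high grazer use), tufted attractors (high tuft,
#' high grazer use), resisters (upright, tufted, low grazer use) and
#' avoiders (low tuft, low grazer use, variable architecture).
#' `height_habit` governs whether a species' leaf table sits above
#' (`tall`), below (`short`) or alternately on either side (`tall_mixed` /
#' `short_mixed`, split by within-archetype parity) of the site median —
#' the mechanism through which the grazer use index is induced.
#'
#' @return Tibble of archetype means and SDs for the four latent indices.
#' @export
default_archetypes <- function() {
  tibble::tribble(
    ~growth_form, ~proportion, ~culm_mean, ~culm_sd, ~lateral_mean,
    ~lateral_sd, ~tuft_mean, ~tuft_sd, ~grazer_mean, ~grazer_sd,
    ~height_habit,
    "lateral_attractor", 0.25, 1.8, 0.40, 0.85, 0.07, 0.15, 0.07, 0.75,
    0.06, "tall_mixed",
    "tufted_attractor", 0.25, 3.3, 0.40, 0.15, 0.07, 0.85, 0.07, 0.75,
    0.06, "short_mixed",
    "resister", 0.25, 4.4, 0.35, 0.10, 0.05, 0.88, 0.06, 0.38, 0.06, "tall",
    "avoider", 0.25, 2.6, 0.50, 0.55, 0.12, 0.18, 0.08, 0.38, 0.06, "short"
  )
}

#' Default fourth-corner coefficient matrix for the generator
#'
#' Trait-by-environment coefficients (on standardized scales) governing
#' species occurrence in simulated surveys. Defaults encode the qualitative
#' field pattern: tuft, lateral and culm orientation increase with
#' rainfall; culm orientation decreases with sand and CEC and increases
#' with pH; tuft decreases with pH; grazer use increases weakly with CEC.
#'
#' @return 4 x 4 numeric matrix, rows the trait indices, columns the
#'   environment variables.
#' @export
default_fourthcorner_b <- function() {
  B <- matrix(0, 4, 4, dimnames = list(trait_index_names,
    environment_variables))
  B["culm_orientation_index", "map_mm"] <- 0.5
  B["culm_orientation_index", "sand_pct"] <- -0.5
  B["culm_orientation_index", "cec"] <- -0.4
  B["culm_orientation_index", "ph"] <- 0.4
  B["lateral_index", "map_mm"] <- 0.5
  B["tuft_index", "map_mm"] <- 0.5
  B["tuft_index", "ph"] <- -0.3
  B["grazer_use_index", "cec"] <- 0.2
  B
}

#' Configuration for the synthetic survey generator
#'
#' Bundles every generative parameter with study-scale defaults: 33 sites
#' of 30 quadrats (0.25 m^2 in the emulated protocol), a 60-species pool in
#' four archetypes, rainfall 336-987 mm/yr and sand 44-93% gradients, an
#' occurrence model `logit P(species s at site i) = alpha_s + t_s' B e_i`,
#' Dirichlet quadrat covers, lognormal leaf table heights, and a
#' quadrat-level bare-ground model linear in the site's dung proportion.
#'
#' @param seed Master seed; each generation stage derives its own stream
#'   from it.
#' @param n_sites,quadrats_per_site,n_species Survey dimensions
#'   (`quadrats_per_site` >= 15, the study-protocol minimum).
#' @param archetypes Archetype parameter tibble (see
#'   [default_archetypes()]).
#' @param env_ranges Named list of `c(min, max)` for the four environment
#'   variables.
#' @param b Fourth-corner coefficient matrix for occurrence (default
#'   [default_fourthcorner_b()]).
#' @param base_occupancy,alpha_sd Mean occurrence probability at average
#'   environment and SD of species-level logit intercepts.
#' @param quadrat_occupancy Probability a site-present species occurs in a
#'   given quadrat.
#' @param cover_concentration Gamma/Dirichlet concentration for quadrat
#'   cover shares.
#' @param total_cover_range `c(min, max)` summed grass cover per quadrat.
#' @param height_baseline_mm,height_site_sdlog,height_record_sdlog Leaf
#'   table height model: site baselines are lognormal around the overall
#'   baseline; records are lognormal around `baseline * rho_species`.
#' @param bareground_intercept,bareground_dung_slope,bareground_sd
#'   Quadrat bare ground = intercept + slope * site dung proportion +
#'   Gaussian noise, clipped to \[0, 100\]. Defaults give ~32.5% mean bare
#'   ground at average grazing pressure.
#' @param dung_beta_shape1,dung_beta_shape2 Beta distribution of site
#'   grazing pressure; dung per quadrat is Bernoulli(pressure).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_sites = 33,
                              quadrats_per_site = 30,
                              n_species = 60,
                              archetypes = default_archetypes(),
                              env_ranges = list(
                                map_mm = c(336, 987), sand_pct = c(44, 93),
                                cec = c(1, 30), ph = c(4.5, 8.5)
                              ),
                              b = default_fourthcorner_b(),
                              base_occupancy = 0.35,
                              alpha_sd = 0.4,
                              quadrat_occupancy = 0.55,
                              cover_concentration = 0.3,
                              total_cover_range = c(55, 95),
                              height_baseline_mm = 100,
                              height_site_sdlog = 0.15,
                              height_record_sdlog = 0.1,
                              bareground_intercept = 25,
                              bareground_dung_slope = 15,
                              bareground_sd = 8,
                              dung_beta_shape1 = 2,
                              dung_beta_shape2 = 2) {
  cfg <- list(
    seed = seed, n_sites = n_sites, quadrats_per_site = quadrats_per_site,
    n_species = n_species, archetypes = archetypes, env_ranges = env_ranges,
    b = b, base_occupancy = base_occupancy, alpha_sd = alpha_sd,
    quadrat_occupancy = quadrat_occupancy,
    cover_concentration = cover_concentration,
    total_cover_range = total_cover_range,
    height_baseline_mm = height_baseline_mm,
    height_site_sdlog = height_site_sdlog,
    height_record_sdlog = height_record_sdlog,
    bareground_intercept = bareground_intercept,
    bareground_dung_slope = bareground_dung_slope,
    bareground_sd = bareground_sd,
    dung_beta_shape1 = dung_beta_shape1,
    dung_beta_shape2 = dung_beta_shape2
  )
  sd_cols <- grep("_sd$", names(archetypes), value = TRUE)
  if (any(as.matrix(archetypes[sd_cols]) < 0)) {
    abort("Archetype SDs must be >= 0")
  }
  if (quadrats_per_site < 15) {
    abort("quadrats_per_site must be >= 15 (study-protocol minimum)")
  }
  if (base_occupancy <= 0 || base_occupancy >= 1 ||
    quadrat_occupancy <= 0 || quadrat_occupancy > 1) {
    abort("Occupancy probabilities must lie in (0, 1)")
  }
  structure(cfg, class = "simulation_config")
}

# Truncated-normal draw by rejection (SDs are small relative to the legal
# ranges, so acceptance is high; degenerate configs are rejected upstream).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(clip(mean, lo, hi), n))
  out <- rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- out < lo | out > hi
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  clip(out, lo, hi)
}

latent_ranges <- list(
  culm = c(1, 5), lateral = c(0.02, 0.98), tuft = c(0.02, 0.98),
  grazer = c(0.05, 0.98)
)

#' Simulate a species pool from growth-form archetypes
#'
#' Draws each species' latent trait indices from its archetype's truncated
#' normal distributions and derives its field-level generative parameters:
#' the probability of stolons/long rhizomes per record equals the latent
#' lateral index, the probability of a tufted base equals the latent tuft
#' index, the per-record culm code is `floor(c) + Bernoulli(frac(c))` so
#' its mean equals the latent code, and the species' height multiplier
#' `rho` relative to the site baseline is `1/grazer` (tall habit) or
#' `grazer` (short habit), so the grazer use index recovers the latent
#' value when the site median sits at the baseline.
#'
#' @param config A `simulation_config`.
#' @return Tibble of class `species_pool`: `species`, `archetype`, latent
#'   `culm`, `lateral`, `tuft`, `grazer`, height habit (`tall`), `rho`,
#'   and occurrence intercept `alpha`.
#' @export
simulate_species_pool <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seeds(config$seed, c("pool"))[["pool"]])
  arch <- config$archetypes
  # >50% truncation mass means the archetype cannot honestly represent its
  # nominal distribution.
  for (i in seq_len(nrow(arch))) {
    for (idx in names(latent_ranges)) {
      m <- arch[[paste0(idx, "_mean")]][i]
      s <- arch[[paste0(idx, "_sd")]][i]
      if (s > 0) {
        r <- latent_ranges[[idx]]
        outside <- pnorm(r[1], m, s) + pnorm(r[2], m, s, lower.tail = FALSE)
        if (outside > 0.5) {
          abort(paste0("Archetype '", arch$growth_form[i], "' truncates >50% ",
            "of its '", idx, "' distribution; degenerate config"),
            class = "grasslawns_degenerate_error")
        }
      }
    }
  }
  n <- config$n_species
  counts <- floor(n * arch$proportion)
  while (sum(counts) < n) {
    counts[which.max(n * arch$proportion - counts)] <-
      counts[which.max(n * arch$proportion - counts)] + 1
  }
  pool <- purrr::map_dfr(seq_len(nrow(arch)), function(i) {
    k <- counts[i]
    if (k == 0) return(NULL)
    habit <- arch$height_habit[i]
    tall <- switch(habit,
      tall = rep(TRUE, k),
      short = rep(FALSE, k),
      tall_mixed = seq_len(k) %% 2 == 1,
      short_mixed = seq_len(k) %% 2 == 0,
      abort(paste0("Unknown height habit: ", habit))
    )
    tibble::tibble(
      archetype = arch$growth_form[i],
      culm = rtrunc_norm(k, arch$culm_mean[i], arch$culm_sd[i], 1, 5),
      lateral = rtrunc_norm(k, arch$lateral_mean[i], arch$lateral_sd[i],
        latent_ranges$lateral[1], latent_ranges$lateral[2]),
      tuft = rtrunc_norm(k, arch$tuft_mean[i], arch$tuft_sd[i],
        latent_ranges$tuft[1], latent_ranges$tuft[2]),
      grazer = rtrunc_norm(k, arch$grazer_mean[i], arch$grazer_sd[i],
        latent_ranges$grazer[1], latent_ranges$grazer[2]),
      tall = tall
    )
  })
  pool <- pool[sample.int(nrow(pool)), ]
  pool$species <- sprintf("species_%03d", seq_len(nrow(pool)))
  pool$rho <- ifelse(pool$tall, 1 / pool$grazer, pool$grazer)
  pool$alpha <- qlogis(config$base_occupancy) +
    rnorm(nrow(pool), 0, config$alpha_sd)
  out <- pool[c("species", "archetype", "culm", "lateral", "tuft",
    "grazer", "tall", "rho", "alpha")]
  class(out) <- c("species_pool", class(out))
  out
}

# Draw site environments along two latent gradients with noise, clipped to
# the configured ranges.
simulate_site_environment <- function(config) {
  n <- config$n_sites
  g1 <- runif(n, -1, 1)
  g2 <- runif(n, -1, 1)
  rng <- config$env_ranges
  mid <- function(v) mean(rng[[v]])
  half <- function(v) diff(rng[[v]]) / 2
  env <- tibble::tibble(
    site_id = sprintf("site_%02d", seq_len(n)),
    map_mm = clip(mid("map_mm") + 0.9 * half("map_mm") * g1 +
      rnorm(n, 0, 0.15 * half("map_mm")), rng$map_mm[1], rng$map_mm[2]),
    sand_pct = clip(mid("sand_pct") +
      half("sand_pct") * (0.6 * g1 + 0.6 * g2) +
      rnorm(n, 0, 0.15 * half("sand_pct")), rng$sand_pct[1], rng$sand_pct[2]),
    cec = clip(mid("cec") - half("cec") * (0.7 * g1 - 0.4 * g2) +
      rnorm(n, 0, 0.2 * half("cec")), rng$cec[1], rng$cec[2]),
    ph = clip(mid("ph") - half("ph") * (0.5 * g1 - 0.5 * g2) +
      rnorm(n, 0, 0.2 * half("ph")), rng$ph[1], rng$ph[2])
  )
  list(env = env, g1 = g1, g2 = g2)
}

#' Simulate a full quadrat survey with ground truth
#'
#' Generates a seeded synthetic survey with the statistical structure the
#' analysis pipeline assumes: sites placed along correlated environment
#' gradients; species presence per site drawn from the fourth-corner logit
#' model `alpha_s + t_s' B e_i`; per-quadrat covers from a Dirichlet over
#' occurring species scaled by a total-cover draw; lognormal leaf table
#' heights induced by each species' tall/short height multiplier; dung
#' Bernoulli per quadrat from a Beta-distributed site grazing pressure; and
#' quadrat bare ground linear in the site's realized dung proportion plus
#' noise, clipped to \[0, 100\].
#'
#' @param config A `simulation_config`.
#' @return A list of class `grass_simulation`: `survey` (a validated
#'   `grass_survey`), `ground_truth` (species pool with latent values, the
#'   coefficient matrix `b`, bare-ground coefficients, per-site latent
#'   gradients, grazing pressure and approximate expected growth-form
#'   cover), and `config`.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- stage_seeds(config$seed,
    c("pool", "sites", "presence", "quadrats", "meta"))
  pool <- simulate_species_pool(config)

  set.seed(seeds[["sites"]])
  site_env <- simulate_site_environment(config)
  env <- site_env$env
  baselines <- config$height_baseline_mm *
    exp(rnorm(config$n_sites, 0, config$height_site_sdlog))

  set.seed(seeds[["presence"]])
  # Degenerate columns (single site, constant latent trait) standardize to
  # zero rather than NaN so the occurrence model stays defined.
  safe_scale <- function(m) {
    s <- apply(m, 2, sd)
    s[is.na(s) | s == 0] <- Inf
    sweep(sweep(m, 2, colMeans(m), "-"), 2, s, "/")
  }
  E_std <- safe_scale(as.matrix(env[environment_variables]))
  T_std <- safe_scale(as.matrix(
    setNames(pool[c("culm", "lateral", "tuft", "grazer")], trait_index_names)
  ))
  eta <- sweep(T_std %*% config$b %*% t(E_std), 1, pool$alpha, "+")
  prob <- plogis(eta) # species x sites
  presence <- matrix(FALSE, nrow(pool), config$n_sites)
  for (i in seq_len(config$n_sites)) {
    for (try in 1:50) {
      draw <- runif(nrow(pool)) < prob[, i]
      if (sum(draw) >= 2) break
    }
    if (sum(draw) < 2) {
      abort(paste0("Could not draw >= 2 species at site ", env$site_id[i],
        " after 50 retries; occupancy too low"),
        class = "grasslawns_degenerate_error")
    }
    presence[, i] <- draw
  }

  set.seed(seeds[["quadrats"]])
  obs <- purrr::map_dfr(seq_len(config$n_sites), function(i) {
    present <- which(presence[, i])
    m <- length(present)
    nq <- config$quadrats_per_site
    occ <- matrix(runif(nq * m) < config$quadrat_occupancy, nq, m)
    for (q in which(rowSums(occ) == 0)) {
      occ[q, sample.int(m, 1)] <- TRUE
    }
    gam <- matrix(stats::rgamma(nq * m, shape = config$cover_concentration),
      nq, m) * occ
    total <- runif(nq, config$total_cover_range[1], config$total_cover_range[2])
    cover <- gam / rowSums(gam) * total
    idx <- which(occ, arr.ind = TRUE)
    sp <- present[idx[, 2]]
    heights <- baselines[i] * pool$rho[sp] *
      exp(rnorm(nrow(idx), 0, config$height_record_sdlog))
    code <- floor(pool$culm[sp]) +
      (runif(nrow(idx)) < pool$culm[sp] - floor(pool$culm[sp]))
    code <- clip(code, 1, 5)
    culm_cat <- dplyr::case_when(
      code == 1 ~ "lateral",
      code == 2 ~ "geniculate-lateral",
      code == 3 & runif(nrow(idx)) < 0.5 ~ "decumbent",
      code == 3 ~ "geniculate",
      code == 4 ~ "geniculate-upright",
      TRUE ~ "upright"
    )
    spreading <- runif(nrow(idx)) < pool$lateral[sp]
    stolons <- spreading & runif(nrow(idx)) < 0.7
    rhizome <- ifelse(spreading & (!stolons | runif(nrow(idx)) < 0.35),
      "long",
      ifelse(runif(nrow(idx)) < pool$tuft[sp] * 0.6, "short", "none"))
    tibble::tibble(
      site_id = env$site_id[i],
      quadrat_id = sprintf("q%02d", idx[, 1]),
      species = pool$species[sp],
      cover_pct = clip(cover[idx], 0.01, 100),
      leaf_table_height_mm = heights,
      culm_orientation = culm_cat,
      stolons = stolons,
      rhizome = rhizome,
      tufted_base = runif(nrow(idx)) < pool$tuft[sp]
    )
  })

  set.seed(seeds[["meta"]])
  pressure <- rbeta(config$n_sites, config$dung_beta_shape1,
    config$dung_beta_shape2)
  meta <- purrr::map_dfr(seq_len(config$n_sites), function(i) {
    nq <- config$quadrats_per_site
    dung <- runif(nq) < pressure[i]
    dung_prop <- mean(dung)
    tibble::tibble(
      site_id = env$site_id[i],
      quadrat_id = sprintf("q%02d", seq_len(nq)),
      bare_ground_pct = clip(config$bareground_intercept +
        config$bareground_dung_slope * dung_prop +
        rnorm(nq, 0, config$bareground_sd), 0, 100),
      dung_present = dung
    )
  })

  survey <- new_survey(obs, meta, env)

  # Approximate expected per-site growth-form cover share: presence
  # probability mass of each form, normalized, times mean total cover.
  mean_total <- mean(config$total_cover_range)
  expected_cover <- purrr::map_dfr(seq_len(config$n_sites), function(i) {
    w <- tapply(prob[, i], pool$archetype, sum)
    share <- w / sum(w)
    dplyr::bind_cols(tibble::tibble(site_id = env$site_id[i]),
      tibble::as_tibble(as.list(share * mean_total)))
  })
  ground_truth <- list(
    pool = pool,
    b = config$b,
    bareground = c(intercept = config$bareground_intercept,
      dung_slope = config$bareground_dung_slope, sd = config$bareground_sd),
    sites = dplyr::bind_cols(env,
      tibble::tibble(g1 = site_env$g1, g2 = site_env$g2,
        grazing_pressure = pressure, height_baseline_mm = baselines)),
    expected_cover = expected_cover
  )
  structure(list(survey = survey, ground_truth = ground_truth,
    config = config), class = "grass_simulation")
}

#' Packaged small synthetic surveys for tests and examples
#'
#' Deterministic presets (fixed internal seeds) with documented ground
#' truth:
#' * `tiny` — 2 sites x 15 quadrats, 4 species (one per archetype).
#' * `null` — 10 sites with no trait-environment association (`B = 0`).
#' * `planted_clusters` — 4 archetypes x 12 species each, well separated.
#' * `planted_fourthcorner` — 40 sites, single planted tuft-by-rainfall
#'   coefficient of +1, all other entries 0.
#' * `planted_bareground` — 20 sites, bare ground = 20 + 15 x dung
#'   proportion + N(0, 2).
#'
#' @param name Preset identifier.
#' @return A `grass_simulation` (see [simulate_survey()]).
#' @export
make_fixture <- function(name = c("tiny", "null", "planted_clusters",
                                  "planted_fourthcorner",
                                  "planted_bareground")) {
  presets <- c("tiny", "null", "planted_clusters", "planted_fourthcorner",
    "planted_bareground")
  if (!is.character(name) || length(name) != 1 || !name %in% presets) {
    abort(paste0("Unknown fixture preset; available: ",
      paste(presets, collapse = ", ")))
  }
  cfg <- switch(name,
    tiny = simulation_config(seed = 101, n_sites = 2, quadrats_per_site = 15,
      n_species = 4, quadrat_occupancy = 0.9, base_occupancy = 0.95,
      alpha_sd = 0.1, b = default_fourthcorner_b() * 0),
    null = simulation_config(seed = 102, n_sites = 10,
      b = default_fourthcorner_b() * 0, n_species = 30),
    planted_clusters = simulation_config(seed = 103, n_sites = 10,
      n_species = 48, quadrat_occupancy = 0.6, base_occupancy = 0.5),
    planted_fourthcorner = {
      B <- default_fourthcorner_b() * 0
      B["tuft_index", "map_mm"] <- 1
      simulation_config(seed = 104, n_sites = 40, n_species = 40, b = B)
    },
    planted_bareground = simulation_config(seed = 105, n_sites = 20,
      n_species = 30, bareground_intercept = 20,
      bareground_dung_slope = 15, bareground_sd = 2)
  )
  simulate_survey(cfg)
}

#' @export
print.grass_simulation <- function(x, ...) {
  cat("<grass_simulation> seed", x$config$seed, "\n")
  print(x$survey)
  invisible(x)
}
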