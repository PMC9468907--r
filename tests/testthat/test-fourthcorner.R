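test_that("the minimal 90%-cover set takes the shortest dominant prefix", {
  expect_equal(
    minimal_cover_set(c(a = 50, b = 30, c = 15, d = 5)),
    c("a", "b", "c") # 50 + 30 = 80 < 90, third species needed
  )
  expect_equal(minimal_cover_set(c(only = 12)), "only")
  ten <- setNames(rep(10, 10), letters[1:10])
  expect_equal(length(minimal_cover_set(ten)), 9)
  expect_error(minimal_cover_set(c(a = 0, b = 0)),
    class = "grasslawns_degenerate_error")
  # ties broken alphabetically
  expect_equal(minimal_cover_set(c(b = 40, a = 40, c = 20))[1:2], c("a", "b"))
})

test_that("the minimal cover set is minimal on random covers", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(2:15, 1)
    cover <- setNames(runif(n, 0.01, 50), paste0("s", sprintf("%02d", 1:n)))
    keep <- minimal_cover_set(cover)
    share <- sum(cover[keep]) / sum(cover)
    expect_gte(share, 0.9 - 1e-9)
    if (length(keep) > 1) {
      without_last <- sum(cover[keep[-length(keep)]]) / sum(cover)
      expect_lt(without_last, 0.9)
    }
  }
})

test_that("the community triplet matches a hand-built toy example", {
  survey <- hand_survey()
  tt <- build_trait_table(survey)
  # site A covers: sp_short (40+30+20)/3 = 30, sp_tall 25/3;
  # sp_short alone holds 30/38.33 = 78% < 90%, so both species retained.
  # site B: sp_short 50, sp_tall 25; 50/75 = 67% < 90%, both retained.
  tri <- build_triplet(survey, tt)
  expect_equal(dim(tri$L), c(2, 2))
  expect_true(all(tri$L == 1))
  expect_equal(tri$cover["A", "sp_short"], 30)
  expect_equal(tri$cover["A", "sp_tall"], 25 / 3)
  expect_equal(unname(colMeans(tri$R)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(tri$R, 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_error(build_triplet(survey, tt[tt$species != "sp_short", ]),
    "sp_short", class = "grasslawns_validation_error")
})

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-10, 3, 20), 27.5)
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(-5, 9, 10), Inf) # saturated: correction undefined
  # delta is invariant to a constant shift of both log-likelihoods
  d1 <- aicc(-10, 3, 50) - aicc(-12, 4, 50)
  d2 <- aicc(-10 + 7, 3, 50) - aicc(-12 + 7, 4, 50)
  expect_equal(d1, d2)
})

test_that("richer environment subsets never lose likelihood and the ladder is coherent", {
  sim <- simulate_survey(simulation_config(seed = 19, n_sites = 15,
    n_species = 20))
  tt <- build_trait_table(sim$survey)
  tri <- build_triplet(sim$survey, tt)
  sel <- suppressWarnings(select_env_subset(tri))
  lad <- sel$ladder
  expect_equal(nrow(lad), 15)
  expect_equal(sum(lad$delta_aicc == 0), 1)
  expect_true(all(diff(lad$aicc) >= -1e-9))
  full_ll <- lad$logLik[lad$env_subset == "map_mm+sand_pct+cec+ph"]
  for (v in c("map_mm", "sand_pct", "cec", "ph")) {
    expect_lte(lad$logLik[lad$env_subset == v], full_ll + 1e-6)
  }
  expect_lte(lad$aicc[1],
    lad$aicc[lad$env_subset == "map_mm+sand_pct+cec+ph"])
  # the species-only reference anchors but does not compete
  expect_false("(none)" %in% lad$env_subset)
  expect_equal(nrow(sel$reference), 1)
})

test_that("the deviance statistic is invariant to species and site relabeling", {
  sim <- simulate_survey(simulation_config(seed = 23, n_sites = 12,
    n_species = 15))
  tt <- build_trait_table(sim$survey)
  tri <- build_triplet(sim$survey, tt)
  fit <- suppressWarnings(fit_fourth_corner(tri, env = c("map_mm", "ph")))
  permute_triplet <- function(tri, sp_perm, site_perm) {
    tri$L <- tri$L[site_perm, sp_perm]
    tri$R <- tri$R[site_perm, , drop = FALSE]
    tri$Q <- tri$Q[sp_perm, , drop = FALSE]
    tri
  }
  set.seed(1)
  tri2 <- permute_triplet(tri, sample.int(ncol(tri$L)),
    sample.int(nrow(tri$L)))
  fit2 <- suppressWarnings(fit_fourth_corner(tri2, env = c("map_mm", "ph")))
  expect_equal(fit2$deviance, fit$deviance, tolerance = 1e-6)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-4)
})

test_that("resampling ANOVA respects its p-value bound and warns on few iterations", {
  sim <- simulate_survey(simulation_config(seed = 29, n_sites = 10,
    n_species = 12, quadrats_per_site = 15))
  tt <- build_trait_table(sim$survey)
  tri <- build_triplet(sim$survey, tt)
  expect_warning(
    an <- anova_resampling(tri, env = c("map_mm", "sand_pct"),
      n_iterations = 49, seed = 2),
    "resolution"
  )
  expect_gte(an$p, 1 / 50)
  expect_lte(an$p, 1)
  expect_length(an$null_statistics, 49)
  # same seed reproduces the same p
  an2 <- suppressWarnings(anova_resampling(tri,
    env = c("map_mm", "sand_pct"), n_iterations = 49, seed = 2))
  expect_equal(an2$p, an$p)
})
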