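test_that("culm orientation categories map onto the 1-5 ordinal scale", {
  expect_identical(encode_culm_orientation("lateral"), 1L)
  expect_identical(encode_culm_orientation("geniculate-lateral"), 2L)
  expect_identical(encode_culm_orientation(c("decumbent", "geniculate")),
    c(3L, 3L))
  expect_identical(encode_culm_orientation("geniculate-upright"), 4L)
  expect_identical(encode_culm_orientation("upright"), 5L)
  expect_error(encode_culm_orientation("erect"), "legal categories")
})

test_that("site median height uses flat records with midpoint convention", {
  survey <- hand_survey()
  med <- site_median_height(survey)
  # site A records: 40, 60, 80, 120, 60 -> median 60
  expect_equal(med$median_height_mm[med$site_id == "A"], 60)
  # site B records: 50, 100 -> midpoint 75
  expect_equal(med$median_height_mm[med$site_id == "B"], 75)
  med3 <- site_median_height(local({
    s <- hand_survey()
    s$observations <- s$observations[s$observations$site_id == "A", ][1:3, ]
    s$meta <- s$meta[s$meta$site_id == "A", ]
    s$sites <- s$sites[s$sites$site_id == "A", ]
    suppressWarnings(new_survey(s$observations, s$meta, s$sites))
  }))
  expect_equal(med3$median_height_mm, 60) # {40, 60, 80}
})

test_that("grazer use index reciprocates ratios above one", {
  medians <- tibble::tibble(site_id = "A", median_height_mm = 100)
  at_median <- tibble::tibble(species = "x", site_id = "A",
    leaf_table_height_mm = c(100, 100, 100))
  expect_equal(grazer_use_index(at_median, medians)$grazer_use_index, 1)
  twice <- tibble::tibble(species = "x", site_id = "A",
    leaf_table_height_mm = 200)
  expect_equal(grazer_use_index(twice, medians)$grazer_use_index, 0.5)
  both <- tibble::tibble(species = "x", site_id = "A",
    leaf_table_height_mm = c(50, 200)) # ratios 0.5 and 2.0
  expect_equal(grazer_use_index(both, medians)$grazer_use_index, 0.5)
  expect_error(
    grazer_use_index(tibble::tibble(species = "x", site_id = "Z",
      leaf_table_height_mm = 10), medians),
    "site median"
  )
})

test_that("trait table proportions, counts and clustering flag are exact", {
  survey <- hand_survey()
  tt <- build_trait_table(survey)
  short <- tt[tt$species == "sp_short", ]
  # stolons or long rhizome in 3 of 4 records
  expect_equal(short$lateral_index, 0.75)
  expect_equal(short$tuft_index, 0.25)
  expect_equal(short$n_quadrats, 4L)
  expect_false(short$clustered)
  tall <- tt[tt$species == "sp_tall", ]
  expect_equal(tall$tuft_index, 1)
  expect_equal(tall$lateral_index, 0)
  # culm codes: upright 5, upright 5, geniculate-upright 4 -> mean 14/3
  expect_equal(tall$culm_orientation_index, 14 / 3)
})

test_that("the clustered flag flips strictly above 10 quadrat records", {
  make_n <- function(n) {
    obs <- tibble::tibble(
      site_id = "A", quadrat_id = sprintf("q%02d", 1:n), species = "sp",
      cover_pct = 10, leaf_table_height_mm = 50,
      culm_orientation = "upright", stolons = FALSE, rhizome = "none",
      tufted_base = TRUE
    )
    meta <- tibble::tibble(site_id = "A", quadrat_id = sprintf("q%02d", 1:n),
      bare_ground_pct = 5, dung_present = FALSE)
    sites <- tibble::tibble(site_id = "A", map_mm = 500, sand_pct = 50,
      cec = 5, ph = 6)
    build_trait_table(suppressWarnings(new_survey(obs, meta, sites)))
  }
  expect_false(make_n(10)$clustered)
  expect_true(make_n(11)$clustered)
})

test_that("grazer use index is scale invariant per site", {
  survey <- hand_survey()
  base <- build_trait_table(survey)
  for (c_mult in c(0.1, 3.7, 250)) {
    scaled <- survey
    is_a <- scaled$observations$site_id == "A"
    scaled$observations$leaf_table_height_mm[is_a] <-
      scaled$observations$leaf_table_height_mm[is_a] * c_mult
    scaled <- suppressWarnings(new_survey(scaled$observations, scaled$meta,
      scaled$sites))
    expect_equal(build_trait_table(scaled)$grazer_use_index,
      base$grazer_use_index, tolerance = 1e-12)
  }
})

test_that("records at ratio r and 1/r contribute identically", {
  medians <- tibble::tibble(site_id = "A", median_height_mm = 100)
  set.seed(42)
  for (i in 1:20) {
    r <- exp(runif(1, -3, 3))
    g_r <- grazer_use_index(tibble::tibble(species = "x", site_id = "A",
      leaf_table_height_mm = 100 * r), medians)$grazer_use_index
    g_inv <- grazer_use_index(tibble::tibble(species = "x", site_id = "A",
      leaf_table_height_mm = 100 / r), medians)$grazer_use_index
    expect_equal(g_r, g_inv, tolerance = 1e-12)
  }
})

test_that("trait indices are permutation invariant and rational proportions", {
  sim <- make_fixture("null")
  tt <- build_trait_table(sim$survey)
  set.seed(7)
  shuffled <- sim$survey
  shuffled$observations <-
    shuffled$observations[sample.int(nrow(shuffled$observations)), ]
  shuffled <- new_survey(shuffled$observations, shuffled$meta,
    shuffled$sites)
  expect_equal(build_trait_table(shuffled), tt)
  # lateral and tuft indices are exact k/n fractions of the record count
  expect_true(all(abs(tt$lateral_index * tt$n_quadrats -
    round(tt$lateral_index * tt$n_quadrats)) < 1e-9))
  expect_true(all(abs(tt$tuft_index * tt$n_quadrats -
    round(tt$tuft_index * tt$n_quadrats)) < 1e-9))
  expect_true(all(tt$grazer_use_index > 0 & tt$grazer_use_index <= 1))
  expect_true(all(tt$culm_orientation_index >= 1 &
    tt$culm_orientation_index <= 5))
})
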