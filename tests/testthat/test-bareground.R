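fake_summaries <- function(bare, group) {
  tibble::tibble(
    site_id = sprintf("s%02d", seq_along(bare)),
    bare_ground_mean = bare,
    dominance = group
  )
}

test_that("dominance assignment follows attractor cover with ties flagged", {
  survey <- hand_survey()
  assignment <- tibble::tibble(
    species = c("sp_short", "sp_tall"),
    growth_form = c("lateral_attractor", "tufted_attractor")
  )
  summaries <- site_summaries(survey, assignment)
  # site A: lateral 30 vs tufted 25/3 -> lateral; site B: 50 vs 25 -> lateral
  expect_equal(summaries$dominance, c("lateral", "lateral"))
  split <- dominance_split(summaries)
  expect_equal(nrow(split$lateral), 2)
  expect_equal(nrow(split$tufted), 0)
  tied <- summaries
  tied$lateral_attractor <- c(20, 20)
  tied$tufted_attractor <- c(20, 5)
  tied$dominance <- c(NA, "lateral")
  expect_warning(split2 <- dominance_split(tied), "tied")
  expect_equal(split2$lateral$site_id, tied$site_id[2])
})

test_that("group F comparison matches hand ANOVA and a brute-force oracle", {
  s <- fake_summaries(c(1, 2, 3, 4, 5, 6),
    rep(c("lateral", "tufted"), each = 3))
  out <- compare_groups(s)
  expect_equal(out$f_statistic, 13.5)
  expect_equal(out$df1, 1)
  expect_equal(out$df2, 4)
  # identical group means give F = 0
  s0 <- fake_summaries(c(5, 7, 5, 7), rep(c("lateral", "tufted"), each = 2))
  expect_equal(compare_groups(s0)$f_statistic, 0)
  # brute-force sums of squares on random inputs
  set.seed(17)
  for (rep in 1:20) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    y <- rnorm(n1 + n2, sd = 3)
    g <- rep(c("a", "b"), c(n1, n2))
    got <- compare_groups(fake_summaries(y, g))$f_statistic
    grand <- mean(y)
    ssb <- n1 * (mean(y[1:n1]) - grand)^2 + n2 * (mean(y[-(1:n1)]) - grand)^2
    ssw <- sum((y[1:n1] - mean(y[1:n1]))^2) +
      sum((y[-(1:n1)] - mean(y[-(1:n1)]))^2)
    expect_equal(got, (ssb / 1) / (ssw / (n1 + n2 - 2)), tolerance = 1e-10)
  }
  # permuting sites within groups changes nothing
  perm <- sample.int(6)
  s_perm <- fake_summaries(s$bare_ground_mean[perm], s$dominance[perm])
  expect_equal(compare_groups(s_perm)$f_statistic, out$f_statistic)
  expect_error(compare_groups(fake_summaries(1:3, c("a", "a", "b"))),
    class = "grasslawns_degenerate_error")
})

test_that("subset enumeration respects marginality and includes the null model", {
  sets <- grasslawns:::marginal_term_sets()
  labels <- vapply(sets, paste, "", collapse = " + ")
  expect_true("" %in% labels) # intercept-only
  for (s in sets) {
    for (term in s) {
      parts <- strsplit(term, ":")[[1]]
      if (length(parts) > 1) {
        for (k in seq_len(length(parts) - 1)) {
          subints <- apply(combn(parts, k), 2, paste, collapse = ":")
          expect_true(all(subints %in% s))
        }
      }
    }
  }
  # three-way interaction only appears in the full model's closure
  with_three <- sets[vapply(sets, function(s)
    "map_mm:sand_pct:dung_proportion" %in% s, TRUE)]
  expect_true(all(vapply(with_three, length, 1L) == 7))
})

test_that("a planted dung effect is selected with a positive slope", {
  set.seed(8)
  n <- 20
  df <- tibble::tibble(
    site_id = sprintf("s%02d", 1:n),
    map_mm = runif(n, 336, 987), sand_pct = runif(n, 44, 93),
    dung_proportion = runif(n, 0, 1)
  )
  df$bare_ground_mean <- 20 + 15 * df$dung_proportion + rnorm(n, 0, 2)
  sel <- fit_bareground_subsets(df)
  expect_match(sel$best_terms, "dung_proportion")
  expect_gt(sel$best_coefs[["dung_proportion"]], 0)
  expect_equal(sum(sel$ladder$delta_aicc == 0), 1)
  expect_true(all(sel$ladder$delta_aicc >= 0))
})

test_that("pure-noise responses prefer the intercept-only model most often", {
  # With 18 competing sub-models each able to beat the null by chance
  # (single-term models win when a chi-square(1) draw exceeds the ~2.8 AICc
  # penalty gap, ~9.5% each), the null wins roughly two thirds of the time
  # at n = 20 — it should be the clear modal choice, never the minority.
  set.seed(12)
  n <- 20
  reps <- 100
  choices <- character(reps)
  for (r in 1:reps) {
    df <- tibble::tibble(
      site_id = sprintf("s%02d", 1:n),
      map_mm = runif(n, 336, 987), sand_pct = runif(n, 44, 93),
      dung_proportion = runif(n, 0, 1),
      bare_ground_mean = rnorm(n, 30, 5)
    )
    sel <- fit_bareground_subsets(df)
    choices[r] <- sel$best_terms
  }
  wins <- mean(choices == "(intercept)")
  expect_gte(wins, 0.5)
  expect_equal(names(which.max(table(choices))), "(intercept)")
})

test_that("planted slopes are recovered within two standard errors", {
  set.seed(27)
  n <- 30
  hits <- 0
  reps <- 50
  for (r in 1:reps) {
    dung <- runif(n, 0, 1)
    bare <- 20 + 15 * dung + rnorm(n, 0, 2)
    fit <- lm(bare ~ dung)
    est <- coef(summary(fit))["dung", ]
    if (abs(est["Estimate"] - 15) <= 2 * est["Std. Error"]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("fewer than five sites warns about saturated candidates", {
  df <- tibble::tibble(
    site_id = c("a", "b", "c", "d"),
    map_mm = c(400, 600, 800, 500), sand_pct = c(50, 60, 70, 80),
    dung_proportion = c(0.1, 0.4, 0.8, 0.5),
    bare_ground_mean = c(20, 25, 35, 28)
  )
  expect_warning(sel <- fit_bareground_subsets(df), "saturated")
  expect_true(is.finite(sel$ladder$aicc[1]))
})
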