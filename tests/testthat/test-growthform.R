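test_that("range standardization maps each variable onto [0, 1]", {
  m <- cbind(a = c(1, 3, 5), b = c(0, 0.25, 1))
  out <- range_standardize(m)
  expect_equal(out[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(out[, "b"], c(0, 0.25, 1), ignore_attr = TRUE)
  ranges <- attr(out, "ranges")
  expect_equal(ranges$min, c(1, 0))
  expect_equal(ranges$max, c(5, 1))
  expect_error(range_standardize(cbind(a = c(2, 2, 2), b = 1:3)), "a",
    class = "grasslawns_degenerate_error")
})

test_that("PCA conserves variance, reconstructs input, and has fixed signs", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rnorm(30 * 4), 30, 4,
      dimnames = list(NULL, paste0("v", 1:4)))
    p <- pca_ordination(m, unit_variance = TRUE)
    expect_equal(sum(p$variance_pct), 100, tolerance = 1e-9)
    expect_true(all(p$variance_pct >= 0))
    # reconstruction of the centred/scaled input from all components
    scaled <- scale(m)
    recon <- p$scores %*% t(p$loadings)
    expect_lt(max(abs(recon - scaled)), 1e-8)
    # orthogonality of components
    g <- crossprod(p$loadings)
    expect_lt(max(abs(g - diag(ncol(m)))), 1e-8)
    # sign convention: dominant loading of every component is positive
    for (j in seq_len(ncol(p$loadings))) {
      expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
    }
  }
})

test_that("two perfectly correlated variables put 100% of variance on PC1", {
  x <- rnorm(20)
  p <- pca_ordination(cbind(a = x, b = 3 * x + 1), unit_variance = TRUE)
  expect_equal(p$variance_pct[1], 100, tolerance = 1e-9)
})

test_that("degenerate PCA inputs are rejected", {
  expect_error(pca_ordination(matrix(1, 5, 1)), "2 items and 2 variables")
  expect_error(pca_ordination(matrix(1, 4, 3)), "rank 0")
})

test_that("ward clustering merges identical points at height zero and keeps monotone heights", {
  two <- rbind(c(1, 2), c(1, 2))
  tree <- ward_cluster(two)
  expect_equal(tree$height, 0)
  set.seed(5)
  for (rep in 1:10) {
    pts <- matrix(rnorm(16 * 3), 16, 3)
    h <- ward_cluster(pts)$height
    expect_true(all(diff(h) >= -1e-12))
  }
})

test_that("ward clustering joins well-separated triplets last", {
  set.seed(9)
  pts <- rbind(
    matrix(rnorm(6, mean = 0, sd = 0.1), 3, 2),
    matrix(rnorm(6, mean = 10, sd = 0.1), 3, 2)
  )
  tree <- ward_cluster(pts)
  labels <- cut_tree(tree, 2)
  expect_equal(length(unique(labels[1:3])), 1)
  expect_equal(length(unique(labels[4:6])), 1)
  expect_false(labels[1] == labels[4])
  # merge sequence agrees with the exhaustive greedy Ward oracle
  oracle <- ward_oracle(pts)
  expect_equal(hclust_partitions(tree), oracle$partitions)
  expect_equal(sort(tree$height), sort(oracle$heights), tolerance = 1e-10)
})

test_that("tree cuts relabel clusters by decreasing size", {
  set.seed(21)
  pts <- rbind(
    matrix(rnorm(10, 0, 0.05), 5, 2),
    matrix(rnorm(4, 8, 0.05), 2, 2)
  )
  tree <- ward_cluster(pts)
  labels <- cut_tree(tree, 2)
  expect_equal(unname(labels[1:5]), rep(1L, 5)) # larger cluster is label 1
  expect_equal(unname(labels[6:7]), rep(2L, 2))
  expect_equal(length(unique(cut_tree(tree, 1))), 1)
  expect_equal(length(unique(cut_tree(tree, 7))), 7)
  expect_error(cut_tree(tree, 0), "between 1 and")
  expect_error(cut_tree(tree, 8), "between 1 and")
})

test_that("v-test matches hand evaluation and handles degenerate cases", {
  # values {0,0,1,1}, cluster = last two items
  vt <- vtest(c(0, 0, 1, 1), c(1, 1, 2, 2))
  v2 <- vt$v[vt$cluster == 2]
  expect_equal(v2, 0.5 / sqrt((0.25 / 2) * (2 / 3)), tolerance = 1e-12)
  expect_equal(v2, sqrt(3), tolerance = 1e-4)
  # a cluster containing every item has v = 0
  all_in <- vtest(rnorm(6), rep(1, 6))
  expect_equal(all_in$v, 0)
  # constant trait: flagged, v reported as 0
  const <- vtest(rep(2, 6), c(1, 1, 1, 2, 2, 2))
  expect_true(all(const$degenerate))
  expect_equal(const$v, c(0, 0))
  # antisymmetry under reflecting the trait about its mean
  x <- c(0.2, 0.9, 0.4, 0.7, 0.1, 0.6)
  lab <- c(1, 2, 1, 2, 1, 2)
  up <- vtest(x, lab)
  down <- vtest(2 * mean(x) - x, lab)
  expect_equal(up$v, -down$v, tolerance = 1e-12)
})

test_that("v-test agrees with a brute-force oracle on random instances", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    labels <- sample(1:3, n, replace = TRUE)
    labels[1:3] <- 1:3 # ensure all clusters non-empty
    vt <- vtest(x, labels)
    for (cl in 1:3) {
      expect_equal(vt$v[vt$cluster == cl], vtest_oracle(x, labels, cl),
        tolerance = 1e-10)
    }
  }
})

test_that("growth-form assignment recovers planted archetypes and is deterministic", {
  sim <- make_fixture("planted_clusters")
  tt <- build_trait_table(sim$survey)
  gm1 <- suppressWarnings(assign_growth_forms(tt))
  gm2 <- suppressWarnings(assign_growth_forms(tt))
  expect_identical(gm1$assignments, gm2$assignments)
  joined <- dplyr::inner_join(gm1$assignments, sim$ground_truth$pool,
    by = "species")
  clustered <- joined[joined$provenance == "clustered", ]
  expect_gte(adjusted_rand_index(clustered$growth_form, clustered$archetype),
    0.9)
  expect_false(any(gm1$cluster_names$ambiguous))
  # byte-identical assignments.csv on re-run
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_results(gm1, d1)
  write_results(gm2, d2)
  expect_identical(readLines(file.path(d1, "assignments.csv")),
    readLines(file.path(d2, "assignments.csv")))
})

test_that("rare species take overrides and missing overrides warn", {
  sim <- make_fixture("planted_clusters")
  tt <- build_trait_table(sim$survey)
  tt <- tt[tt$clustered, ]
  rare <- tibble::tibble(
    species = c("rare_with_override", "rare_without_override"),
    culm_orientation_index = c(2, 4), lateral_index = c(0.6, 0.1),
    tuft_index = c(0.2, 0.8), grazer_use_index = c(0.4, 0.5),
    n_quadrats = c(3L, 7L), clustered = FALSE
  )
  tt <- dplyr::bind_rows(tt, rare)
  overrides <- tibble::tibble(species = "rare_with_override",
    growth_form = "avoider")
  expect_warning(
    gm <- assign_growth_forms(tt, overrides = overrides),
    "unassigned"
  )
  row <- gm$assignments[gm$assignments$species == "rare_with_override", ]
  expect_equal(row$growth_form, "avoider")
  expect_equal(row$provenance, "manual_override")
  missing_row <- gm$assignments[
    gm$assignments$species == "rare_without_override", ]
  expect_equal(missing_row$growth_form, "unassigned")
})

test_that("classification refuses fewer clustered species than k", {
  tt <- tibble::tibble(
    species = c("a", "b", "c"),
    culm_orientation_index = c(1, 2, 3), lateral_index = c(0.1, 0.5, 0.9),
    tuft_index = c(0.9, 0.5, 0.1), grazer_use_index = c(0.3, 0.6, 0.9),
    n_quadrats = c(20L, 20L, 5L), clustered = c(TRUE, TRUE, FALSE)
  )
  expect_error(assign_growth_forms(tt, k = 4), "clustered species",
    class = "grasslawns_degenerate_error")
})
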