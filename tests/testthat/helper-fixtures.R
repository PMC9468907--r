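# Hand-built two-site survey used across the IO and trait-index tests.
# Site A: heights 40/60/80 across three quadrats; site B: single quadrat.
hand_survey <- function() {
  observations <- tibble::tribble(
    ~site_id, ~quadrat_id, ~species, ~cover_pct, ~leaf_table_height_mm,
    ~culm_orientation, ~stolons, ~rhizome, ~tufted_base,
    "A", "q1", "sp_short", 40, 40, "lateral", TRUE, "none", FALSE,
    "A", "q2", "sp_short", 30, 60, "lateral", TRUE, "long", FALSE,
    "A", "q3", "sp_short", 20, 80, "geniculate", FALSE, "short", TRUE,
    "A", "q1", "sp_tall", 10, 120, "upright", FALSE, "none", TRUE,
    "A", "q2", "sp_tall", 15, 60, "upright", FALSE, "short", TRUE,
    "B", "q1", "sp_short", 50, 50, "decumbent", FALSE, "long", FALSE,
    "B", "q1", "sp_tall", 25, 100, "geniculate-upright", FALSE, "none", TRUE
  )
  meta <- tibble::tribble(
    ~site_id, ~quadrat_id, ~bare_ground_pct, ~dung_present,
    "A", "q1", 10, TRUE,
    "A", "q2", 30, FALSE,
    "A", "q3", 20, TRUE,
    "B", "q1", 40, FALSE
  )
  sites <- tibble::tribble(
    ~site_id, ~map_mm, ~sand_pct, ~cec, ~ph,
    "A", 500, 60, 10, 6.5,
    "B", 900, 80, 5, 5.5
  )
  suppressWarnings(new_survey(observations, meta, sites))
}

# Independent greedy Ward oracle: recomputes the minimum-variance merge
# cost from the raw coordinates at every step (no Lance-Williams
# recursion). Returns the sequence of partitions and merge heights on the
# ward.D2 distance scale.
ward_oracle <- function(points) {
  pts <- as.matrix(points)
  clusters <- lapply(seq_len(nrow(pts)), identity)
  partitions <- list()
  heights <- numeric()
  delta_ss <- function(a, b) {
    na <- length(a); nb <- length(b)
    ca <- colMeans(pts[a, , drop = FALSE])
    cb <- colMeans(pts[b, , drop = FALSE])
    na * nb / (na + nb) * sum((ca - cb)^2)
  }
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- delta_ss(clusters[[i]], clusters[[j]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    clusters[[best[2]]] <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    clusters[[best[3]]] <- NULL
    heights <- c(heights, sqrt(2 * best[1]))
    partitions[[length(partitions) + 1]] <- canonical_partition(clusters)
  }
  list(partitions = partitions, heights = heights)
}

# Canonical string form of a partition (sorted members, sorted blocks) so
# two partitions can be compared irrespective of labels.
canonical_partition <- function(clusters) {
  blocks <- sort(vapply(clusters, function(cl) {
    paste(sort(cl), collapse = ",")
  }, ""))
  paste(blocks, collapse = "|")
}

# Partition sequence induced by an hclust tree, bottom merge upward.
hclust_partitions <- function(tree) {
  n <- length(tree$order)
  lapply(seq_len(n - 1), function(step) {
    labels <- cutree(tree, k = n - step)
    canonical_partition(split(seq_len(n), labels))
  })
}

# Literal transliteration of the v-test formula, one value at a time.
vtest_oracle <- function(x, labels, cluster) {
  n <- length(x)
  overall <- sum(x) / n
  s2 <- sum((x - overall)^2) / n
  idx <- which(labels == cluster)
  nk <- length(idx)
  ck <- sum(x[idx]) / nk
  (ck - overall) / sqrt(s2 / nk * (n - nk) / (n - 1))
}

write_survey_csvs <- function(survey, dir) {
  suppressWarnings(write_results(survey, dir))
  list(
    quadrats = file.path(dir, "quadrats.csv"),
    meta = file.path(dir, "quadrat_meta.csv"),
    sites = file.path(dir, "sites.csv")
  )
}
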