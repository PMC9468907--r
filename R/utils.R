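# Closed enumerations shared across the package.
culm_orientation_levels <- c(
  "lateral", "geniculate-lateral", "geniculate", "decumbent",
  "geniculate-upright", "upright"
)
rhizome_levels <- c("none", "short", "long")
growth_form_levels <- c(
  "lateral_attractor", "avoider", "tufted_attractor", "resister"
)
trait_index_names <- c(
  "culm_orientation_index", "lateral_index", "tuft_index", "grazer_use_index"
)
environment_variables <- c("map_mm", "sand_pct", "cec", "ph")

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\log L + 2p + 2p(p+1)/(n-p-1)}. Returns `Inf` (with no
#' error) when `n - p - 1 <= 0`, i.e. the correction is undefined because the
#' model is saturated relative to the sample size.
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Number of estimated parameters `p` (for least-squares
#'   models this counts the residual variance).
#' @param n Sample size.
#' @return A single numeric AICc value.
#' @examples
#' aicc(-10, 3, 20) # 27.5
#' @export
aicc <- function(loglik, n_params, n) {
  if (n - n_params - 1 <= 0) {
    return(Inf)
  }
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) / (n - n_params - 1)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' to score recovery of planted archetypes by the clustering stage.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single numeric in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

# Parse assorted truthy/falsy encodings (TRUE/FALSE, T/F, 1/0, yes/no) into
# logical; anything else becomes NA so validation can report it.
parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Derive per-stage RNG seeds (< 2^31) from one master seed so pipeline
# stages can be regenerated independently.
stage_seeds <- function(seed, stages) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
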