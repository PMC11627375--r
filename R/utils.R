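#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct bind_rows bind_cols rename n
#'   row_number
#' @importFrom stats runif sd cor fisher.test phyper ks.test
NULL

# Single source of truth for the four hormone-dependent cancer labels.
HDC_CANCERS <- c("breast", "endometrial", "ovarian", "prostate")

#' Default hormone-dependent cancer labels
#'
#' The four trait labels used throughout the pipeline: breast, endometrial,
#' ovarian and prostate cancer.
#'
#' @return Character vector of length four.
#' @export
hdc_cancers <- function() HDC_CANCERS

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= 0
}

#' Construct a permutation-test result
#'
#' Container shared by the variant-clustering and the TAD-enrichment
#' permutation tests. The empirical p-value follows the resampling convention
#' `#\{null >= observed\} / n_perms`; when no null value reaches the observed
#' statistic the p-value is reported as the upper bound `1 / n_perms` with
#' `p_is_upper_bound = TRUE`. The z-score standardises the observed statistic
#' against the null mean and standard deviation and is `NA` (with
#' `z_defined = FALSE`) when the null is degenerate (zero spread).
#'
#' @param observed Observed value of the statistic.
#' @param null_values Numeric vector of the statistic under the null.
#' @param seed Integer seed used for the permutations (recorded, not consumed).
#' @param smoothed Logical; if `TRUE` use the add-one smoothed estimator
#'   `(k + 1) / (n + 1)` instead of the raw `k / n`.
#'
#' @return An object of class `perm_test`: a list with elements `observed`,
#'   `null_values`, `z`, `z_defined`, `p_empirical`, `p_is_upper_bound`,
#'   `n_perms`, `seed`, `smoothed`.
#' @export
perm_test_result <- function(observed, null_values, seed = NA_integer_,
                             smoothed = FALSE) {
  stopifnot(is.numeric(null_values), length(null_values) >= 1L)
  n <- length(null_values)
  k <- sum(null_values >= observed)
  if (smoothed) {
    p <- (k + 1) / (n + 1)
    upper <- FALSE
  } else if (k == 0L) {
    p <- 1 / n
    upper <- TRUE
  } else {
    p <- k / n
    upper <- FALSE
  }
  mu <- mean(null_values)
  s <- stats::sd(null_values)
  z_defined <- is.finite(s) && s > 0
  structure(
    list(
      observed = observed,
      null_values = null_values,
      z = if (z_defined) (observed - mu) / s else NA_real_,
      z_defined = z_defined,
      p_empirical = p,
      p_is_upper_bound = upper,
      n_perms = n,
      seed = seed,
      smoothed = smoothed
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$n_perms, " permutations)\n", sep = "")
  cat("  observed statistic: ", x$observed, "\n", sep = "")
  cat("  null mean (sd): ", signif(mean(x$null_values), 4), " (",
      signif(stats::sd(x$null_values), 4), ")\n", sep = "")
  if (x$z_defined) {
    cat("  z: ", signif(x$z, 4), "\n", sep = "")
  } else {
    cat("  z: undefined (degenerate null)\n")
  }
  cat("  empirical p: ", if (x$p_is_upper_bound) "< " else "",
      signif(x$p_empirical, 4), "\n", sep = "")
  invisible(x)
}

# Set the RNG locally when a seed is supplied, restoring the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Uniform integer positions in [0, len) for possibly long chromosomes.
runif_pos <- function(n, len) {
  p <- floor(stats::runif(n, 0, len))
  pmin(p, len - 1)
}
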