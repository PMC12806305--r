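## Scenario 1: permutation test for the between-arm difference in mean
## percent cholesterol change.
##
## The statistic is t = |mean(diet changes) - mean(control changes)| and
## the empirical p-value is the fraction of relabelled statistics at least
## as large as the observed one (no +1 continuity correction, so p = 0 is
## attainable; the analysis this reproduces reports a bound, not an exact
## value).

#' Observed two-sample statistic: absolute difference in mean change
#'
#' @param diet_changes numeric vector of percent cholesterol changes in the
#'   intervention arm.
#' @param control_changes numeric vector of percent cholesterol changes in
#'   the control arm.
#' @return non-negative scalar, percentage points.
#' @examples
#' observed_statistic(c(-10, -20), c(0, -2))  # 14
#' @export
observed_statistic <- function(diet_changes, control_changes) {
  if (!length(diet_changes) || !length(control_changes))
    stop_input("both arms must be non-empty")
  if (anyNA(diet_changes) || anyNA(control_changes))
    stop_input("percent changes must not contain missing values")
  abs(mean(diet_changes) - mean(control_changes))
}

#' Monte-Carlo permutation null distribution of the statistic
#'
#' Each round relabels the pooled changes uniformly at random into
#' pseudo-arms of the original sizes and recomputes
#' [observed_statistic()]. Label assignments are sampled with replacement
#' from the assignment space (standard Monte-Carlo permutation).
#'
#' @param all_changes pooled numeric vector of length
#'   `n_diet + n_control`.
#' @param n_diet,n_control pseudo-arm sizes.
#' @param n_perm number of permutation rounds.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return numeric vector of `n_perm` simulated statistics.
#' @export
permutation_null <- function(all_changes, n_diet, n_control, n_perm = 2500,
                             seed = NULL) {
  n_diet <- check_count(n_diet, "n_diet")
  n_control <- check_count(n_control, "n_control")
  n_perm <- check_count(n_perm, "n_perm")
  n <- length(all_changes)
  if (n != n_diet + n_control)
    stop_input(sprintf("pooled sample has %d values but n_diet + n_control = %d",
                       n, n_diet + n_control))
  total <- sum(all_changes)
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, n_diet)
      m1 <- sum(all_changes[idx]) / n_diet
      abs(m1 - (total - m1 * n_diet) / n_control)
    }, numeric(1))
  })
}

#' Exhaustive permutation null distribution
#'
#' Enumerates every one of the `choose(n, n_diet)` label assignments of the
#' pooled values and returns the statistic for each. Used automatically by
#' [run_scenario1()] when the assignment space is small, and as the exact
#' reference for the Monte-Carlo sampler.
#'
#' @inheritParams permutation_null
#' @return numeric vector of length `choose(length(all_changes), n_diet)`.
#' @export
permutation_null_exact <- function(all_changes, n_diet, n_control) {
  n_diet <- check_count(n_diet, "n_diet")
  n_control <- check_count(n_control, "n_control")
  n <- length(all_changes)
  if (n != n_diet + n_control)
    stop_input(sprintf("pooled sample has %d values but n_diet + n_control = %d",
                       n, n_diet + n_control))
  total <- sum(all_changes)
  sums <- utils::combn(all_changes, n_diet, FUN = sum)
  abs(sums / n_diet - (total - sums) / n_control)
}

#' Empirical permutation p-value
#'
#' The fraction of simulated statistics at least as extreme as the observed
#' one: `mean(t_sim >= t_obs)`.
#'
#' @param t_obs observed statistic (non-negative).
#' @param t_sim numeric vector of simulated statistics.
#' @return probability in `[0, 1]`.
#' @examples
#' permutation_p_value(5, c(1, 2, 6, 7))  # 0.5
#' @export
permutation_p_value <- function(t_obs, t_sim) {
  if (!length(t_sim)) stop_input("t_sim must be non-empty")
  if (!is.numeric(t_obs) || length(t_obs) != 1 || !is.finite(t_obs))
    stop_input("t_obs must be a single finite number")
  mean(t_sim >= t_obs)
}

#' Run Scenario 1: permutation test on an MCE-style cohort
#'
#' Composes [observed_statistic()], [permutation_null()] (or
#' [permutation_null_exact()]) and [permutation_p_value()] on the
#' `pct_chol_change` column of a two-arm cohort.
#'
#' @param cohort MCE-style cohort `data.frame` with columns `arm` and
#'   `pct_chol_change`; both arms must be present.
#' @param n_perm number of permutation rounds (ignored under exhaustive
#'   enumeration).
#' @param seed integer seed for the relabelling stream.
#' @param exact `"auto"` enumerates exhaustively when the assignment space
#'   has at most `max_exact` elements, `"always"` forces enumeration,
#'   `"never"` forces Monte-Carlo sampling.
#' @param max_exact assignment-space bound for auto-enumeration.
#' @return an object of class `permutation_result` with fields `t_obs`,
#'   `t_sim`, `n_perm`, `p_value`, `exact`, `n_diet`, `n_control`, `seed`.
#' @examples
#' coh <- generate_mce(mce_config(n_diet = 30, n_control = 30, seed = 1))
#' run_scenario1(coh, n_perm = 200, seed = 2)
#' @export
run_scenario1 <- function(cohort, n_perm = 2500, seed = NULL,
                          exact = c("auto", "never", "always"),
                          max_exact = 10000) {
  exact <- match.arg(exact)
  if (!all(c("arm", "pct_chol_change") %in% names(cohort)))
    stop_input("cohort must have columns `arm` and `pct_chol_change`")
  diet <- cohort$pct_chol_change[cohort$arm == "diet"]
  control <- cohort$pct_chol_change[cohort$arm == "control"]
  if (!length(diet) || !length(control))
    stop_input("cohort must contain both a diet arm and a control arm")
  t_obs <- observed_statistic(diet, control)
  pooled <- c(diet, control)
  space <- choose(length(pooled), length(diet))
  use_exact <- exact == "always" || (exact == "auto" && space <= max_exact)
  t_sim <- if (use_exact) {
    permutation_null_exact(pooled, length(diet), length(control))
  } else {
    permutation_null(pooled, length(diet), length(control), n_perm, seed)
  }
  structure(list(
    t_obs = t_obs,
    t_sim = t_sim,
    n_perm = length(t_sim),
    p_value = permutation_p_value(t_obs, t_sim),
    exact = use_exact,
    n_diet = length(diet),
    n_control = length(control),
    seed = seed
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test of mean percent cholesterol change\n")
  cat(sprintf("  arms: diet n=%d, control n=%d\n", x$n_diet, x$n_control))
  cat(sprintf("  observed |mean difference|: %.3f percentage points\n", x$t_obs))
  cat(sprintf("  null rounds: %d (%s)\n", x$n_perm,
              if (x$exact) "exhaustive enumeration" else "Monte-Carlo"))
  cat(sprintf("  empirical p-value: %.4g\n", x$p_value))
  invisible(x)
}
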