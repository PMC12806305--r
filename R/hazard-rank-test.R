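## Scenario 2: bootstrap rank test on cause-specific CVD-death hazards.
##
## Hazards are summarized by the time-averaged Nelson-Aalen cumulative
## hazard H(tau)/tau, a per-year rate, with other-cause deaths and
## administrative end-of-study both treated as right censoring
## (cause-specific convention). The null distribution of the
## decrease-minus-increase subgroup difference is built by resampling the
## pooled arm with replacement and assigning pseudo-subgroups of the
## observed sizes, which imposes the null of no subgroup effect.

#' Build survival records from times and CVD-death indicators
#'
#' @param time positive event/censoring times, years.
#' @param is_cvd_death logical; `TRUE` for a CVD death, `FALSE` for any
#'   censoring (other-cause death or administrative).
#' @return a `data.frame` with columns `time`, `is_cvd_death`.
#' @export
survival_records <- function(time, is_cvd_death) {
  if (length(time) != length(is_cvd_death))
    stop_input("time and is_cvd_death must have equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop_input("times must be positive and finite")
  data.frame(time = as.numeric(time), is_cvd_death = as.logical(is_cvd_death))
}

## Nelson-Aalen cumulative hazard at tau. Ties: deaths at an event time are
## summed before the risk set is decremented, and subjects censored at that
## same time are still at risk (deaths-first convention).
na_cumulative_hazard <- function(time, dead, tau) {
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]
  ds <- dead[ord]
  new_grp <- c(TRUE, ts[-1] != ts[-n])
  first_idx <- which(new_grp)
  ut <- ts[first_idx]
  grp <- cumsum(new_grp)
  d_cnt <- tabulate(grp[ds], nbins = length(ut))
  at_risk <- n - first_idx + 1
  keep <- d_cnt > 0 & ut <= tau
  sum(d_cnt[keep] / at_risk[keep])
}

#' Time-averaged Nelson-Aalen hazard estimate
#'
#' Estimates the cumulative cause-specific hazard
#' `H(tau) = sum over CVD-death times s <= tau of dN(s)/Y(s)` (dN = CVD
#' deaths at s, Y = number at risk just before s) and returns the per-year
#' summary `H(tau)/tau`.
#'
#' @param records a `data.frame` from [survival_records()] (columns `time`,
#'   `is_cvd_death`).
#' @param tau evaluation horizon, years (> 0).
#' @return per-year hazard rate (non-negative).
#' @examples
#' r <- survival_records(c(1, 2, 3), c(TRUE, FALSE, TRUE))
#' estimate_hazard(r, tau = 3)  # (1/3 + 1/1) / 3 = 4/9
#' @export
estimate_hazard <- function(records, tau) {
  if (!nrow(records)) stop_input("records must be non-empty")
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop_input("tau must be a single positive number")
  na_cumulative_hazard(records$time, records$is_cvd_death, tau) / tau
}

#' Split an arm into cholesterol-decrease and -increase subgroups
#'
#' Participants with `pct_chol_change < 0` form the decrease subgroup;
#' `>= 0` (including exactly 0) the increase subgroup. Each participant is
#' mapped to a survival record in which only `event == "cvd_death"` counts
#' as an event.
#'
#' @param arm_cohort rows of an MCE-style cohort belonging to one arm
#'   (columns `pct_chol_change`, `time`, `event`).
#' @return a list with elements `decrease` and `increase`, each a
#'   [survival_records()] `data.frame`.
#' @export
split_subgroups <- function(arm_cohort) {
  if (!nrow(arm_cohort)) stop_input("arm cohort must be non-empty")
  need <- c("pct_chol_change", "time", "event")
  if (!all(need %in% names(arm_cohort)))
    stop_input("arm cohort must have columns pct_chol_change, time, event")
  dec <- arm_cohort$pct_chol_change < 0
  rec <- function(rows) {
    data.frame(time = as.numeric(rows$time),
               is_cvd_death = rows$event == "cvd_death")
  }
  list(decrease = rec(arm_cohort[dec, , drop = FALSE]),
       increase = rec(arm_cohort[!dec, , drop = FALSE]))
}

#' Hazard difference between two subgroups
#'
#' `estimate_hazard(decrease, tau) - estimate_hazard(increase, tau)`. When
#' `tau` is `NULL` it defaults to the maximum observed time across both
#' subgroups (the pooled arm horizon).
#'
#' @param decrease,increase [survival_records()] `data.frame`s.
#' @param tau evaluation horizon, years; `NULL` for the pooled maximum.
#' @return per-year hazard-rate difference (decrease minus increase).
#' @export
hazard_difference <- function(decrease, increase, tau = NULL) {
  if (!nrow(decrease) || !nrow(increase))
    stop_input("both subgroups must be non-empty")
  if (is.null(tau)) tau <- max(decrease$time, increase$time)
  estimate_hazard(decrease, tau) - estimate_hazard(increase, tau)
}

#' Bootstrap null distribution of the subgroup hazard difference
#'
#' Each iteration draws `n_dec + n_inc` records with replacement from the
#' pooled arm, assigns the first `n_dec` to a pseudo-decrease subgroup and
#' the remainder to a pseudo-increase subgroup, and records their hazard
#' difference. Because both pseudo-subgroups are drawn from the same pool,
#' the subgroup labels carry no effect under this scheme. A permutation
#' variant (resampling without replacement, i.e. relabelling) is available
#' via `method`.
#'
#' @param pooled [survival_records()] `data.frame` for the whole arm.
#' @param n_dec,n_inc pseudo-subgroup sizes.
#' @param n_boot number of resampling iterations.
#' @param tau evaluation horizon, years.
#' @param seed integer seed, or `NULL`.
#' @param method `"bootstrap"` (with replacement, default) or
#'   `"permutation"` (label shuffling; requires
#'   `n_dec + n_inc == nrow(pooled)`).
#' @return numeric vector of `n_boot` simulated differences.
#' @export
bootstrap_null <- function(pooled, n_dec, n_inc, n_boot = 5000, tau = NULL,
                           seed = NULL, method = c("bootstrap", "permutation")) {
  method <- match.arg(method)
  if (!nrow(pooled)) stop_input("pooled records must be non-empty")
  n_dec <- check_count(n_dec, "n_dec")
  n_inc <- check_count(n_inc, "n_inc")
  n_boot <- check_count(n_boot, "n_boot")
  if (is.null(tau)) tau <- max(pooled$time)
  n <- nrow(pooled)
  k <- n_dec + n_inc
  if (method == "permutation" && k != n)
    stop_input("permutation null requires n_dec + n_inc == nrow(pooled)")
  time <- pooled$time
  dead <- pooled$is_cvd_death
  with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- if (method == "bootstrap") sample.int(n, k, replace = TRUE)
             else sample.int(n, k)
      d_idx <- idx[seq_len(n_dec)]
      i_idx <- idx[-seq_len(n_dec)]
      na_cumulative_hazard(time[d_idx], dead[d_idx], tau) / tau -
        na_cumulative_hazard(time[i_idx], dead[i_idx], tau) / tau
    }, numeric(1))
  })
}

#' Two-tailed resampling p-value for the hazard difference
#'
#' `mean(abs(h_sim) >= abs(h_obs))`.
#'
#' @param h_obs observed hazard difference.
#' @param h_sim numeric vector of simulated null differences.
#' @return probability in `[0, 1]`.
#' @examples
#' rank_test_p_value(0.1, c(-0.2, 0.05, 0.15, -0.01))  # 0.5
#' @export
rank_test_p_value <- function(h_obs, h_sim) {
  if (!length(h_sim)) stop_input("h_sim must be non-empty")
  if (!is.numeric(h_obs) || length(h_obs) != 1 || !is.finite(h_obs))
    stop_input("h_obs must be a single finite number")
  mean(abs(h_sim) >= abs(h_obs))
}

#' Run Scenario 2: bootstrap rank test on one arm of an MCE-style cohort
#'
#' Splits the arm into cholesterol-decrease/increase subgroups, computes
#' the observed time-averaged Nelson-Aalen hazard difference at
#' `tau = ` maximum observed time in the arm, builds the pooled bootstrap
#' null, and evaluates the two-tailed resampling p-value.
#'
#' @param cohort MCE-style cohort `data.frame`.
#' @param arm `"diet"` or `"control"`.
#' @param n_boot number of bootstrap iterations.
#' @param seed integer seed for the resampling stream.
#' @param tau evaluation horizon, years; `NULL` for the arm maximum.
#' @param method null scheme passed to [bootstrap_null()].
#' @return an object of class `rank_test_result` with fields `h_obs`,
#'   `h_sim`, `n_boot`, `p_value`, `subgroup_sizes`, `tau`, `arm`, `seed`.
#' @examples
#' coh <- generate_mce(mce_config(n_diet = 80, n_control = 80, seed = 1))
#' run_scenario2(coh, arm = "control", n_boot = 200, seed = 2)
#' @export
run_scenario2 <- function(cohort, arm = c("diet", "control"), n_boot = 5000,
                          seed = NULL, tau = NULL,
                          method = c("bootstrap", "permutation")) {
  arm <- match.arg(arm)
  method <- match.arg(method)
  rows <- cohort[cohort$arm == arm, , drop = FALSE]
  if (!nrow(rows)) stop_input(sprintf("cohort has no rows in the %s arm", arm))
  sub <- split_subgroups(rows)
  if (!nrow(sub$decrease))
    stop_input("decrease subgroup is empty: no participant with negative cholesterol change")
  if (!nrow(sub$increase))
    stop_input("increase subgroup is empty: no participant with non-negative cholesterol change")
  if (is.null(tau)) tau <- max(rows$time)
  h_obs <- hazard_difference(sub$decrease, sub$increase, tau)
  pooled <- rbind(sub$decrease, sub$increase)
  h_sim <- bootstrap_null(pooled, nrow(sub$decrease), nrow(sub$increase),
                          n_boot = n_boot, tau = tau, seed = seed,
                          method = method)
  structure(list(
    h_obs = h_obs,
    h_sim = h_sim,
    n_boot = length(h_sim),
    p_value = rank_test_p_value(h_obs, h_sim),
    subgroup_sizes = c(decrease = nrow(sub$decrease), increase = nrow(sub$increase)),
    tau = tau,
    arm = arm,
    method = method,
    seed = seed
  ), class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Bootstrap rank test of CVD hazards (%s arm)\n", x$arm))
  cat(sprintf("  subgroups: decrease n=%d, increase n=%d; tau = %.3f y\n",
              x$subgroup_sizes["decrease"], x$subgroup_sizes["increase"], x$tau))
  cat(sprintf("  observed hazard difference: %.4f per year\n", x$h_obs))
  cat(sprintf("  null iterations: %d (%s)\n", x$n_boot, x$method))
  cat(sprintf("  two-tailed p-value: %.4g\n", x$p_value))
  invisible(x)
}
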