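## Scenario 3: correlation screen + binned A/B comparison.
##
## A Pearson-correlation screen decides whether diastolic blood pressure
## (DBP) may confound the cholesterol-CVD link; if so, the cohort is
## stratified into DBP bins and, per bin, the mean cholesterol of CVD
## cases (a point) is compared against a percentile-bootstrap confidence
## interval of the whole-bin mean cholesterol. A case mean outside the
## interval flags the bin as one where cholesterol associates with CVD.

#' Pearson correlation coefficient
#'
#' Computed as `(1/(n-1)) * sum(((x - mean(x))/s_x) * ((y - mean(y))/s_y))`
#' with `s` the sample standard deviation (n-1 denominator), and clamped to
#' `[-1, 1]` against floating-point overshoot.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return correlation in `[-1, 1]`.
#' @examples
#' pearson_corr(c(1, 2, 4), c(2, 2, 5))
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 2) stop_input("need at least two paired observations")
  if (anyNA(x) || anyNA(y)) stop_input("inputs must not contain missing values")
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop_input("degenerate input: zero sample standard deviation")
  r <- sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (length(x) - 1)
  min(1, max(-1, r))
}

#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples `values` with replacement `n_boot` times and returns the
#' `(1-level)/2` and `1-(1-level)/2` empirical quantiles of the resampled
#' means.
#'
#' @param values non-empty numeric vector.
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level in (0, 1).
#' @param seed integer seed, or `NULL`.
#' @return named numeric vector `c(low, high)`.
#' @examples
#' bootstrap_mean_ci(rnorm(50), n_boot = 500, seed = 1)
#' @export
bootstrap_mean_ci <- function(values, n_boot = 5000, level = 0.95, seed = NULL) {
  if (!length(values)) stop_input("values must be non-empty")
  if (anyNA(values)) stop_input("values must not contain missing values")
  n_boot <- check_count(n_boot, "n_boot")
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop_input("level must lie strictly inside (0, 1)")
  n <- length(values)
  means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = ci[1], high = ci[2])
}

#' Diastolic-blood-pressure bin specification
#'
#' Finite bins are left-closed, right-open `[e_i, e_{i+1})` except the
#' final finite bin, which is closed; open tails below the first and above
#' the last edge catch the remainder, so every DBP value maps to exactly
#' one bin. The default edges make the 60 and 100 mmHg decision
#' thresholds expressible as bin boundaries.
#'
#' @param edges strictly increasing numeric cut-points, mmHg.
#' @return an object of class `bin_spec` with fields `edges` and `labels`.
#' @examples
#' bin_spec()$labels
#' @export
bin_spec <- function(edges = seq(40, 120, by = 10)) {
  if (!is.numeric(edges) || length(edges) < 2 || any(!is.finite(edges)) ||
      any(diff(edges) <= 0))
    stop_input("edges must be at least two strictly increasing finite numbers")
  k <- length(edges)
  inner <- paste0("[", edges[-k], ",", edges[-1],
                  c(rep(")", k - 2), "]"))
  labels <- c(paste0("<", edges[1]), inner, paste0(">", edges[k]))
  structure(list(edges = as.numeric(edges), labels = labels),
            class = "bin_spec")
}

#' Assign DBP values to bins
#'
#' @param dbp numeric vector of diastolic blood pressures, mmHg.
#' @param spec a [bin_spec()].
#' @return factor of bin labels (levels in bin order), one per value.
#' @export
assign_bins <- function(dbp, spec = bin_spec()) {
  if (!inherits(spec, "bin_spec")) stop_input("spec must be a bin_spec")
  e <- spec$edges
  k <- length(e)
  ## findInterval over (-Inf, e1, ..., ek, Inf): index 0 -> low tail.
  idx <- findInterval(dbp, e)                # 0..k
  idx[dbp == e[k]] <- k - 1                  # closed right end of last finite bin
  factor(spec$labels[idx + 1], levels = spec$labels)
}

#' Run Scenario 3: binned bootstrap-CI A/B test on an FHS-style cohort
#'
#' Computes the cholesterol-DBP [pearson_corr()] screen, then for every
#' DBP bin the percentile-bootstrap CI of the bin's mean cholesterol
#' (all members, CVD cases included) and the plain mean cholesterol of the
#' bin's CVD cases. A bin is flagged `associated` when the case mean falls
#' outside the CI. Bins with no CVD case or fewer than `min_bin_n` members
#' are reported but marked `insufficient` (their `associated` flag is `NA`
#' when undefined).
#'
#' @param cohort FHS-style cohort `data.frame` (columns
#'   `total_cholesterol`, `dbp`, `cvd`).
#' @param bins a [bin_spec()].
#' @param n_boot bootstrap resamples per bin.
#' @param level CI level in (0, 1).
#' @param seed integer seed; fans out one sub-seed per bin.
#' @param corr_threshold screening threshold on `|corr|`.
#' @param min_bin_n minimum bin size for a usable comparison.
#' @return an object of class `ab_test_result` with fields `corr`,
#'   `corr_screen_passed`, and `bins`, a `data.frame` with one row per bin:
#'   `bin`, `n_all`, `n_cvd`, `mean_all`, `ci_low`, `ci_high`, `mean_cvd`,
#'   `associated`, `insufficient`.
#' @examples
#' coh <- generate_fhs(fhs_config(n = 800, seed = 1))
#' run_scenario3(coh, n_boot = 300, seed = 2)
#' @export
run_scenario3 <- function(cohort, bins = bin_spec(), n_boot = 5000,
                          level = 0.95, seed = NULL, corr_threshold = 0.1,
                          min_bin_n = 20) {
  if (!nrow(cohort)) stop_input("cohort must be non-empty")
  need <- c("total_cholesterol", "dbp", "cvd")
  if (!all(need %in% names(cohort)))
    stop_input("cohort must have columns total_cholesterol, dbp, cvd")
  corr <- pearson_corr(cohort$total_cholesterol, cohort$dbp)
  bin_of <- assign_bins(cohort$dbp, bins)
  labels <- levels(bin_of)
  bin_seeds <- if (is.null(seed)) rep(list(NULL), length(labels))
               else as.list(derive_seeds(seed, length(labels)))
  rows <- lapply(seq_along(labels), function(i) {
    members <- cohort[bin_of == labels[i], , drop = FALSE]
    n_all <- nrow(members)
    n_cvd <- sum(members$cvd)
    if (n_all == 0) {
      return(data.frame(bin = labels[i], n_all = 0L, n_cvd = 0L,
                        mean_all = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, mean_cvd = NA_real_,
                        associated = NA, insufficient = TRUE))
    }
    ci <- bootstrap_mean_ci(members$total_cholesterol, n_boot = n_boot,
                            level = level, seed = bin_seeds[[i]])
    mean_cvd <- if (n_cvd > 0) mean(members$total_cholesterol[members$cvd]) else NA_real_
    associated <- if (n_cvd > 0) (mean_cvd < ci["low"] | mean_cvd > ci["high"]) else NA
    data.frame(bin = labels[i], n_all = n_all, n_cvd = as.integer(n_cvd),
               mean_all = mean(members$total_cholesterol),
               ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
               mean_cvd = mean_cvd, associated = unname(associated),
               insufficient = n_cvd == 0 | n_all < min_bin_n)
  })
  bins_df <- do.call(rbind, rows)
  rownames(bins_df) <- NULL
  structure(list(
    corr = corr,
    corr_screen_passed = abs(corr) >= corr_threshold,
    bins = bins_df,
    level = level,
    n_boot = n_boot,
    min_bin_n = min_bin_n,
    seed = seed
  ), class = "ab_test_result")
}

#' @export
print.ab_test_result <- function(x, ...) {
  cat("Binned bootstrap-CI A/B test (cholesterol vs CVD across DBP strata)\n")
  cat(sprintf("  cholesterol-DBP correlation: %.3f (screen %s)\n", x$corr,
              if (x$corr_screen_passed) "passed" else "not passed"))
  cat(sprintf("  %d%% population-mean CIs from %d bootstrap resamples per bin\n",
              round(100 * x$level), x$n_boot))
  print(x$bins, digits = 4)
  invisible(x)
}
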