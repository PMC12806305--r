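## Synthetic cohort generators.
##
## The original MCE trial and FHS first-wave micro-data are not
## redistributable, so the package generates cohorts that reproduce the
## published summary structure: arm sizes and percent-cholesterol-change
## dispersions for the trial, and the cholesterol / diastolic-blood-pressure
## / CVD dependence pattern for the observational cohort.

MCE_EVENT_LEVELS <- c("cvd_death", "other_death", "censored")

#' Configuration for the synthetic MCE-style trial cohort
#'
#' Defaults encode the published trial structure: 1179 diet-arm and 1176
#' control-arm participants whose percent change in serum total cholesterol
#' has standard deviation 13 (diet) and 16 (control) percentage points, an
#' arm-mean gap of 13 points, and a 4.5-year administrative follow-up
#' horizon. CVD-death times are exponential with a per-year hazard selected
#' by arm and by the sign of the participant's own cholesterol change
#' (decrease vs increase subgroups); other-cause deaths are exponential
#' with a shared hazard; censoring is administrative at the horizon only.
#'
#' The four subgroup hazards were calibrated once by simulation so the
#' time-averaged Nelson-Aalen hazard differences land near 0.12/yr
#' (control arm) and 0.04/yr (diet arm) and the diet-arm bootstrap test is
#' borderline non-significant, then frozen; see the methods vignette.
#'
#' @param n_diet,n_control arm sizes (participants).
#' @param mean_pct_change_diet,mean_pct_change_control arm means of percent
#'   cholesterol change (signed percentage points).
#' @param sd_pct_change_diet,sd_pct_change_control arm standard deviations
#'   of percent cholesterol change (percentage points, > 0 unless exactly 0
#'   for a degenerate arm).
#' @param followup_horizon administrative censoring time, years.
#' @param cvd_hazard_control_decrease,cvd_hazard_control_increase,cvd_hazard_diet_decrease,cvd_hazard_diet_increase
#'   per-year cause-specific CVD-death hazards by arm and cholesterol
#'   subgroup (change < 0 is "decrease", change >= 0 is "increase").
#' @param other_death_hazard per-year hazard of death from other causes.
#' @param seed integer seed; all generator randomness flows through it.
#' @return an object of class `mce_config` (a validated named list).
#' @seealso [generate_mce()]
#' @examples
#' cfg <- mce_config(seed = 1)
#' cfg$n_diet
#' @export
mce_config <- function(n_diet = 1179,
                       n_control = 1176,
                       mean_pct_change_diet = -14,
                       mean_pct_change_control = -1,
                       sd_pct_change_diet = 13,
                       sd_pct_change_control = 16,
                       followup_horizon = 4.5,
                       cvd_hazard_control_decrease = 0.18,
                       cvd_hazard_control_increase = 0.06,
                       cvd_hazard_diet_decrease = 0.185,
                       cvd_hazard_diet_increase = 0.145,
                       other_death_hazard = 0.04,
                       seed = 1L) {
  cfg <- list(
    n_diet = check_count(n_diet, "n_diet"),
    n_control = check_count(n_control, "n_control"),
    mean_pct_change_diet = check_number(mean_pct_change_diet, "mean_pct_change_diet"),
    mean_pct_change_control = check_number(mean_pct_change_control, "mean_pct_change_control"),
    sd_pct_change_diet = check_nonneg(sd_pct_change_diet, "sd_pct_change_diet"),
    sd_pct_change_control = check_nonneg(sd_pct_change_control, "sd_pct_change_control"),
    followup_horizon = check_positive(followup_horizon, "followup_horizon"),
    cvd_hazard_control_decrease = check_nonneg(cvd_hazard_control_decrease, "cvd_hazard_control_decrease"),
    cvd_hazard_control_increase = check_nonneg(cvd_hazard_control_increase, "cvd_hazard_control_increase"),
    cvd_hazard_diet_decrease = check_nonneg(cvd_hazard_diet_decrease, "cvd_hazard_diet_decrease"),
    cvd_hazard_diet_increase = check_nonneg(cvd_hazard_diet_increase, "cvd_hazard_diet_increase"),
    other_death_hazard = check_nonneg(other_death_hazard, "other_death_hazard"),
    seed = check_count(seed, "seed")
  )
  structure(cfg, class = "mce_config")
}

#' Configuration for the synthetic FHS-style observational cohort
#'
#' Defaults encode the published cohort structure: 3840 participants whose
#' serum total cholesterol and diastolic blood pressure (DBP) are bivariate
#' normal with correlation 0.33, and a CVD flag whose log-odds depend on
#' standardized cholesterol only while DBP lies in the 60-100 mmHg band
#' (outside that band CVD is independent of cholesterol). Means/SDs for
#' cholesterol (235 +/- 45 mg/dL) and DBP (83 +/- 12 mmHg) are typical
#' mid-century adult cohort values; see the methods vignette.
#'
#' @param n cohort size.
#' @param chol_mean,chol_sd mean and SD of total cholesterol, mg/dL.
#' @param dbp_mean,dbp_sd mean and SD of diastolic blood pressure, mmHg.
#' @param chol_dbp_corr cholesterol-DBP correlation, in (-1, 1).
#' @param cvd_base_rate baseline CVD probability, in (0, 1).
#' @param chol_effect_logodds_per_sd log-odds increment of CVD per SD of
#'   cholesterol, applied only when `dbp_gate[1] <= dbp <= dbp_gate[2]`.
#' @param dbp_gate two DBP cut-points (mmHg) bounding the band in which
#'   cholesterol is associated with CVD.
#' @param seed integer seed.
#' @return an object of class `fhs_config`.
#' @seealso [generate_fhs()]
#' @examples
#' fhs_config(seed = 3)$chol_dbp_corr
#' @export
fhs_config <- function(n = 3840,
                       chol_mean = 235,
                       chol_sd = 45,
                       dbp_mean = 83,
                       dbp_sd = 12,
                       chol_dbp_corr = 0.33,
                       cvd_base_rate = 0.25,
                       chol_effect_logodds_per_sd = 0.8,
                       dbp_gate = c(60, 100),
                       seed = 1L) {
  corr <- check_number(chol_dbp_corr, "chol_dbp_corr")
  if (abs(corr) >= 1) stop_config("chol_dbp_corr", "must lie strictly inside (-1, 1)")
  rate <- check_number(cvd_base_rate, "cvd_base_rate")
  if (rate <= 0 || rate >= 1) stop_config("cvd_base_rate", "must lie strictly inside (0, 1)")
  if (!is.numeric(dbp_gate) || length(dbp_gate) != 2 || any(!is.finite(dbp_gate)) ||
      dbp_gate[1] >= dbp_gate[2])
    stop_config("dbp_gate", "must be two increasing finite cut-points")
  cfg <- list(
    n = check_count(n, "n"),
    chol_mean = check_positive(chol_mean, "chol_mean"),
    chol_sd = check_positive(chol_sd, "chol_sd"),
    dbp_mean = check_positive(dbp_mean, "dbp_mean"),
    dbp_sd = check_positive(dbp_sd, "dbp_sd"),
    chol_dbp_corr = corr,
    cvd_base_rate = rate,
    chol_effect_logodds_per_sd = check_number(chol_effect_logodds_per_sd,
                                              "chol_effect_logodds_per_sd"),
    dbp_gate = as.numeric(dbp_gate),
    seed = check_count(seed, "seed")
  )
  structure(cfg, class = "fhs_config")
}

## Exponential event time that tolerates a zero hazard (rate 0 => never).
rexp_or_inf <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

#' Generate a synthetic MCE-style trial cohort
#'
#' Draws one participant table: percent cholesterol change is normal per
#' arm; the CVD-death hazard of each participant is selected by arm and by
#' the sign of their own change (change < 0 -> decrease subgroup, change
#' >= 0 -> increase subgroup); observed time is the minimum of the
#' exponential CVD-death time, the exponential other-cause death time and
#' the administrative horizon, with the matching event code.
#'
#' @param config an [mce_config()].
#' @return a `data.frame` with columns `id` (character), `arm`
#'   (`"control"`/`"diet"`), `pct_chol_change` (percent, signed), `time`
#'   (years, in (0, horizon]) and `event` (one of `"cvd_death"`,
#'   `"other_death"`, `"censored"`). Rows at the horizon are censored.
#' @examples
#' coh <- generate_mce(mce_config(n_diet = 20, n_control = 20, seed = 1))
#' table(coh$arm, coh$event)
#' @export
generate_mce <- function(config = mce_config()) {
  if (!inherits(config, "mce_config")) config <- do.call(mce_config, as.list(config))
  with_seed(config$seed, {
    arm <- rep(c("diet", "control"), c(config$n_diet, config$n_control))
    n <- length(arm)
    pct <- numeric(n)
    is_diet <- arm == "diet"
    pct[is_diet] <- stats::rnorm(config$n_diet, config$mean_pct_change_diet,
                                 config$sd_pct_change_diet)
    pct[!is_diet] <- stats::rnorm(config$n_control, config$mean_pct_change_control,
                                  config$sd_pct_change_control)
    decrease <- pct < 0  # exactly 0 counts as "increase"
    lam <- ifelse(is_diet,
                  ifelse(decrease, config$cvd_hazard_diet_decrease,
                         config$cvd_hazard_diet_increase),
                  ifelse(decrease, config$cvd_hazard_control_decrease,
                         config$cvd_hazard_control_increase))
    t_cvd <- numeric(n)
    for (l in unique(lam)) {
      idx <- which(lam == l)
      t_cvd[idx] <- rexp_or_inf(length(idx), l)
    }
    t_oth <- rexp_or_inf(n, config$other_death_hazard)
    time <- pmin(t_cvd, t_oth, config$followup_horizon)
    event <- rep("censored", n)
    event[time == t_cvd & time < config$followup_horizon] <- "cvd_death"
    event[time == t_oth & time < config$followup_horizon] <- "other_death"
    data.frame(
      id = sprintf("mce_%04d", seq_len(n)),
      arm = arm,
      pct_chol_change = pct,
      time = time,
      event = event,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic FHS-style observational cohort
#'
#' Cholesterol and diastolic blood pressure are drawn bivariate normal at
#' the configured means, SDs and correlation; the CVD flag is Bernoulli
#' with log-odds `logit(base rate) + effect * (chol - mean)/sd` inside the
#' DBP gate and `logit(base rate)` outside it. Standardization uses the
#' configured population mean/SD, not the sample moments, so the gate is a
#' property of the generating process rather than of one draw.
#'
#' @param config an [fhs_config()].
#' @return a `data.frame` with columns `id` (character),
#'   `total_cholesterol` (mg/dL), `dbp` (mmHg) and `cvd` (logical).
#' @examples
#' coh <- generate_fhs(fhs_config(n = 200, seed = 1))
#' mean(coh$cvd)
#' @export
generate_fhs <- function(config = fhs_config()) {
  if (!inherits(config, "fhs_config")) config <- do.call(fhs_config, as.list(config))
  with_seed(config$seed, {
    n <- config$n
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    rho <- config$chol_dbp_corr
    chol <- config$chol_mean + config$chol_sd * z1
    dbp <- config$dbp_mean + config$dbp_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    gate <- dbp >= config$dbp_gate[1] & dbp <= config$dbp_gate[2]
    eta <- stats::qlogis(config$cvd_base_rate) +
      config$chol_effect_logodds_per_sd * z1 * as.numeric(gate)
    cvd <- stats::runif(n) < stats::plogis(eta)
    data.frame(
      id = sprintf("fhs_%04d", seq_len(n)),
      total_cholesterol = chol,
      dbp = dbp,
      cvd = cvd,
      stringsAsFactors = FALSE
    )
  })
}

COHORT_COLUMNS <- list(
  mce = c("id", "arm", "pct_chol_change", "time", "event"),
  fhs = c("id", "total_cholesterol", "dbp", "cvd")
)

#' Write a cohort table to CSV
#'
#' Comma-separated, UTF-8, with a mandatory header row; event codes and
#' arms are written lowercase, logicals as `TRUE`/`FALSE`, numerics at full
#' double precision (so a write-read round trip reproduces them exactly).
#'
#' @param cohort a cohort `data.frame` (from [generate_mce()],
#'   [generate_fhs()] or [read_cohort()]).
#' @param path file path to write.
#' @param schema `"mce"` or `"fhs"`.
#' @return `path`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, path, schema = c("mce", "fhs")) {
  schema <- match.arg(schema)
  cols <- COHORT_COLUMNS[[schema]]
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop_input(sprintf("cohort is missing column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  df <- cohort[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the header and every row: numeric fields must parse, MCE event
#' codes must be one of `cvd_death`/`other_death`/`censored`, arms one of
#' `control`/`diet`, and the FHS `cvd` flag `TRUE`/`FALSE` (or 0/1).
#' Violations raise a parse error naming the first offending data row.
#'
#' @param path CSV file path.
#' @param schema `"mce"` or `"fhs"`.
#' @return a cohort `data.frame` in the schema's column order.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, schema = c("mce", "fhs")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_input(sprintf("cohort file not found: %s", path))
  cols <- COHORT_COLUMNS[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop_parse(sprintf("%s: missing column(s): %s", path,
                       paste(missing_cols, collapse = ", ")))
  df <- df[, cols, drop = FALSE]

  parse_num <- function(x, field) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stop_parse(sprintf("%s: row %d: non-numeric value '%s' in column %s",
                         path, bad[1], x[bad[1]], field))
    v
  }
  check_levels <- function(x, levels, field) {
    bad <- which(!(x %in% levels))
    if (length(bad))
      stop_parse(sprintf("%s: row %d: unknown %s code '%s' (expected one of %s)",
                         path, bad[1], field, x[bad[1]],
                         paste(levels, collapse = ", ")))
    x
  }

  if (schema == "mce") {
    df$arm <- check_levels(df$arm, c("control", "diet"), "arm")
    df$event <- check_levels(df$event, MCE_EVENT_LEVELS, "event")
    df$pct_chol_change <- parse_num(df$pct_chol_change, "pct_chol_change")
    df$time <- parse_num(df$time, "time")
  } else {
    df$total_cholesterol <- parse_num(df$total_cholesterol, "total_cholesterol")
    df$dbp <- parse_num(df$dbp, "dbp")
    cvd <- check_levels(toupper(df$cvd), c("TRUE", "FALSE", "1", "0"), "cvd")
    df$cvd <- cvd %in% c("TRUE", "1")
    if (any(df$total_cholesterol <= 0, na.rm = TRUE) || any(df$dbp <= 0, na.rm = TRUE))
      stop_parse(sprintf("%s: non-positive cholesterol or blood pressure", path))
  }
  rownames(df) <- NULL
  df
}
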