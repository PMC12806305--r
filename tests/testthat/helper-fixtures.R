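# Fixture builders shared across test files. All cohorts are built in code;
# nothing is read from disk except explicit round-trip tests.

options(dietheart.verbose = FALSE)

# Hand-rolled two-arm cohort with explicit values (no randomness).
mce_fixture <- function(diet_changes, control_changes,
                        time = NULL, event = NULL) {
  n <- length(diet_changes) + length(control_changes)
  data.frame(
    id = sprintf("p%03d", seq_len(n)),
    arm = rep(c("diet", "control"),
              c(length(diet_changes), length(control_changes))),
    pct_chol_change = c(diet_changes, control_changes),
    time = if (is.null(time)) rep(1, n) else time,
    event = if (is.null(event)) rep("censored", n) else event,
    stringsAsFactors = FALSE
  )
}

# Total-variation distance between two empirical distributions on the
# union of their support points (tolerating tiny float jitter via rounding).
tv_distance <- function(a, b, digits = 10) {
  a <- round(a, digits); b <- round(b, digits)
  pts <- sort(unique(c(a, b)))
  pa <- tabulate(match(a, pts), length(pts)) / length(a)
  pb <- tabulate(match(b, pts), length(pts)) / length(b)
  sum(abs(pa - pb)) / 2
}
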