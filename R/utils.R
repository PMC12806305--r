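## Internal helpers: seeded evaluation, seed fan-out, error classes, logging.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded generators do not perturb unrelated
#' randomness. A `NULL` seed evaluates `expr` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a stream so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive per-stage seeds from one master seed
#'
#' Fans a single master seed out into `n` independent stage seeds by
#' seeding R's RNG with the master and drawing `n` integers uniformly from
#' `1:(2^31 - 2)`. The derivation is deterministic, so `--seed S` pins an
#' entire multi-stage run while stages stay decoupled.
#'
#' @param master integer master seed.
#' @param n number of stage seeds required.
#' @return integer vector of length `n`.
#' @examples
#' derive_seeds(1, 3)
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master),
            is.numeric(n), length(n) == 1, n >= 1)
  with_seed(as.integer(master), sample.int(2147483646L, as.integer(n)))
}

## Condition constructors: configuration vs input vs parse errors, so
## callers (and the CLI) can branch on class rather than message text.
stop_config <- function(field, msg) {
  stop(structure(
    class = c("dietheart_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field `%s`: %s", field, msg),
         call = sys.call(-1))))
}

stop_input <- function(msg) {
  stop(structure(
    class = c("dietheart_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

stop_parse <- function(msg) {
  stop(structure(
    class = c("dietheart_parse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

## Info-level logger; silenced via options(dietheart.verbose = FALSE).
log_info <- function(fmt, ...) {
  if (isFALSE(getOption("dietheart.verbose", TRUE))) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...)))
  invisible()
}

## Scalar checks used by config validators.
check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x != round(x))
    stop_config(field, "must be a single positive integer")
  as.integer(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop_config(field, "must be a single positive number")
  as.numeric(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
    stop_config(field, "must be a single non-negative number")
  as.numeric(x)
}

check_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_config(field, "must be a single finite number")
  as.numeric(x)
}
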