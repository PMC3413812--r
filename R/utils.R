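#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so that library internals never disturb a user's
#' random stream and every generated object is reproducible in isolation.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a class so callers can distinguish validation failures
abort_validation <- function(msg, class = "smcdeform_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort_validation(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  if (nonnegative && x < 0) {
    abort_validation(sprintf("`%s` must be >= 0 (got %g)", name, x))
  }
  invisible(x)
}
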