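# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' If `seed` is `NULL` the expression runs against the current RNG stream;
#' otherwise the global RNG state is saved, `set.seed(seed)` applied, and the
#' state restored afterwards, so seeded calls never perturb the caller's
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    stats::runif(1L)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a bounded child seed from a base seed and a stream index, so a single
# user-facing seed can drive many independent generator calls reproducibly.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) stop_input("`%s` must be > %g", name, min)
  if (!strict_min && x < min) stop_input("`%s` must be >= %g", name, min)
  invisible(x)
}
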