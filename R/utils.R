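`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_input(name, " must be a single non-missing number")
  if (!allow_inf && !is.finite(x)) stop_input(name, " must be finite")
  if (strict && x <= lower) stop_input(name, " must be > ", lower)
  if (!strict && x < lower) stop_input(name, " must be >= ", lower)
  invisible(x)
}

#' Convert between lognormal CV and log-scale SD
#'
#' Between-subject variability on PK parameters is modelled on the log scale
#' (an "exponential" model, \eqn{P_i = \theta e^{\eta}}, \eqn{\eta \sim
#' N(0,\omega^2)}). Reported variability is often a coefficient of variation;
#' the exact lognormal relation is \eqn{CV = \sqrt{e^{\omega^2}-1}}.
#'
#' @param cv coefficient of variation as a fraction (0.689 for 68.9%)
#' @param omega log-scale standard deviation
#' @return `cv_to_omega` returns omega; `omega_to_cv` returns the CV fraction.
#' @examples
#' cv_to_omega(0.689)
#' omega_to_cv(cv_to_omega(0.689))
#' @export
cv_to_omega <- function(cv) {
  stopifnot(all(cv >= 0))
  sqrt(log(1 + cv^2))
}

#' @rdname cv_to_omega
#' @export
omega_to_cv <- function(omega) {
  stopifnot(all(omega >= 0))
  sqrt(exp(omega^2) - 1)
}

# Evaluate a function under a temporary, restored RNG state seeded with `seed`.
# Keeps package randomness reproducible without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

utils::globalVariables(c("time", "p5", "p95", "dv"))
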