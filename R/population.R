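#' Residual unexplained variability model
#'
#' Observation model \eqn{y = f (1 + \epsilon_p) + \epsilon_a} with
#' \eqn{\epsilon_p \sim N(0, \sigma_{prop}^2)} and
#' \eqn{\epsilon_a \sim N(0, \sigma_{add}^2)}, so
#' \eqn{Var(y \mid f) = f^2\sigma_{prop}^2 + \sigma_{add}^2}.
#'
#' @param kind "additive", "proportional" or "combined"
#' @param sigma_add additive SD, mg/L
#' @param sigma_prop proportional SD, fraction (0.26 means 26%)
#' @return an object of class `residual_error`
#' @export
residual_error <- function(kind = c("combined", "additive", "proportional"),
                           sigma_add = 0, sigma_prop = 0) {
  kind <- match.arg(kind)
  check_number(sigma_add, "sigma_add", 0)
  check_number(sigma_prop, "sigma_prop", 0)
  if (kind == "additive" && sigma_prop != 0)
    stop_input("additive error model must have sigma_prop = 0")
  if (kind == "proportional" && sigma_add != 0)
    stop_input("proportional error model must have sigma_add = 0")
  structure(list(kind = kind, sigma_add = sigma_add, sigma_prop = sigma_prop),
            class = "residual_error")
}

error_sd <- function(error_model, f) {
  sqrt(f^2 * error_model$sigma_prop^2 + error_model$sigma_add^2)
}

#' Apply the residual-error model to true concentrations
#'
#' Draws one measured value per true concentration using the current RNG
#' stream. Negative measured values can arise from the additive component and
#' are retained (assay noise), not truncated.
#'
#' @param true_conc vector of model-predicted concentrations, mg/L (>= 0)
#' @param error_model a [residual_error()] object
#' @return measured concentrations, mg/L
#' @export
observe_conc <- function(true_conc, error_model) {
  stopifnot(inherits(error_model, "residual_error"))
  if (any(true_conc < 0)) stop_input("true_conc must be >= 0")
  n <- length(true_conc)
  eps_p <- if (error_model$sigma_prop > 0) stats::rnorm(n, 0, error_model$sigma_prop) else 0
  eps_a <- if (error_model$sigma_add > 0) stats::rnorm(n, 0, error_model$sigma_add) else 0
  true_conc * (1 + eps_p) + eps_a
}

#' Covariate effect on a structural parameter
#'
#' Continuous covariates (age, body weight) enter as a power model centred on
#' the population median, \eqn{(x/\mathrm{ref})^\beta}; binary covariates
#' (sex, concurrent csDMARD) as a proportional shift \eqn{e^{\beta x}}. Both
#' keep parameters strictly positive.
#'
#' @param parameter structural parameter name ("CL", "VD", "ka", "Q", "VP")
#' @param covariate one of "age", "body_weight", "sex", "csDMARD"
#' @param coefficient dimensionless exponent/log-shift
#' @param reference centring value for continuous covariates (population
#'   median); ignored for binary covariates
#' @return an object of class `covariate_effect`
#' @export
covariate_effect <- function(parameter, covariate, coefficient, reference = NULL) {
  covariate <- match.arg(covariate, c("age", "body_weight", "sex", "csDMARD"))
  parameter <- match.arg(parameter, c("CL", "VD", "ka", "Q", "VP"))
  check_number(coefficient, "coefficient")
  form <- if (covariate %in% c("age", "body_weight")) "power" else "shift"
  if (form == "power") {
    if (is.null(reference)) stop_input("continuous covariate effects need a reference (median)")
    check_number(reference, "reference", 0, strict = TRUE)
  }
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 coefficient = coefficient, reference = reference),
            class = "covariate_effect")
}

#' Subject covariates
#'
#' @param age years (> 0)
#' @param body_weight kg (> 0)
#' @param sex 0/1 indicator (1 = female by package convention)
#' @param csDMARD 0/1 indicator of concurrent csDMARD therapy
#' @return an object of class `subject_covariates`
#' @export
subject_covariates <- function(age, body_weight, sex = 0, csDMARD = 0) {
  check_number(age, "age", 0, strict = TRUE)
  check_number(body_weight, "body_weight", 0, strict = TRUE)
  stopifnot(sex %in% c(0, 1), csDMARD %in% c(0, 1))
  structure(list(age = age, body_weight = body_weight, sex = sex,
                 csDMARD = csDMARD), class = "subject_covariates")
}

# multiplicative covariate factor on each structural parameter
# covs: list/data.frame-row with age, body_weight, sex, csDMARD; vectorised
# over covs rows when given a data.frame
covariate_factors <- function(effects, covs) {
  covs <- as.data.frame(unclass(covs), stringsAsFactors = FALSE)
  fac <- matrix(1, nrow(covs), 5,
                dimnames = list(NULL, c("CL", "VD", "ka", "Q", "VP")))
  for (ef in effects) {
    x <- covs[[cov_column(ef$covariate)]]
    if (is.null(x)) stop_input("covariate ", ef$covariate, " missing from data")
    g <- if (ef$form == "power") (x / ef$reference)^ef$coefficient
         else exp(ef$coefficient * x)
    fac[, ef$parameter] <- fac[, ef$parameter] * g
  }
  fac
}

cov_column <- function(name) {
  c(age = "age", body_weight = "body_weight", sex = "sex", csDMARD = "csDMARD")[[name]]
}

#' Population pharmacokinetic model
#'
#' The full hierarchical model: typical values \eqn{\theta}, lognormal
#' between-subject variability (BSV) \eqn{P_i = \theta\, g(cov_i)\,
#' e^{\eta_i}} with \eqn{\eta_i \sim N(0, \Omega)}, covariate effects
#' \eqn{g(\cdot)}, and a residual-error model.
#'
#' @param typical a [pk_params()] object of typical values
#' @param bsv named numeric vector of log-scale SDs (omega), e.g.
#'   `c(CL = 0.62, VD = 0.155)`; parameters absent carry no BSV
#' @param bsv_corr optional correlation matrix between the random effects,
#'   with dimnames matching `names(bsv)`
#' @param covariate_effects list of [covariate_effect()] objects
#' @param error_model a [residual_error()] object
#' @param fixed character vector of parameters not estimated ("ka",
#'   "sigma_add", ...); fixed parameters carry no standard error
#' @param name optional label (e.g. drug name)
#' @return an object of class `population_model`
#' @seealso [model_adalimumab()], [model_etanercept()]
#' @export
population_model <- function(typical, bsv = numeric(0), bsv_corr = NULL,
                             covariate_effects = list(),
                             error_model = residual_error("additive", sigma_add = 0.1),
                             fixed = character(0), name = NULL) {
  stopifnot(inherits(typical, "pk_params"), inherits(error_model, "residual_error"))
  if (length(bsv)) {
    if (is.null(names(bsv)) || !all(names(bsv) %in% c("CL", "VD", "ka", "Q", "VP")))
      stop_input("bsv must be named with structural parameter names")
    if (any(bsv < 0)) stop_input("omega values must be >= 0")
  }
  if (!is.null(bsv_corr)) {
    if (!isSymmetric(unname(bsv_corr)) || any(abs(diag(bsv_corr) - 1) > 1e-12))
      stop_input("bsv_corr must be symmetric with unit diagonal")
    if (any(eigen(bsv_corr, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop_input("bsv_corr must be positive definite")
    if (!identical(sort(colnames(bsv_corr)), sort(names(bsv))))
      stop_input("bsv_corr dimnames must match names(bsv)")
    bsv_corr <- bsv_corr[names(bsv), names(bsv)]
  }
  for (ef in covariate_effects) stopifnot(inherits(ef, "covariate_effect"))
  structure(list(typical = typical, bsv = bsv, bsv_corr = bsv_corr,
                 covariate_effects = covariate_effects,
                 error_model = error_model, fixed = fixed, name = name),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model", if (!is.null(x$name)) paste0("(", x$name, ")"), "\n")
  print(x$typical)
  if (length(x$bsv))
    cat("  BSV (omega, log-SD):",
        paste(sprintf("%s = %.4g (CV %.1f%%)", names(x$bsv), x$bsv,
                      100 * omega_to_cv(x$bsv)), collapse = ", "), "\n")
  cat(sprintf("  Residual error: %s (sigma_add = %g mg/L, sigma_prop = %g)\n",
              x$error_model$kind, x$error_model$sigma_add, x$error_model$sigma_prop))
  if (length(x$fixed)) cat("  Fixed:", paste(x$fixed, collapse = ", "), "\n")
  if (length(x$covariate_effects))
    for (ef in x$covariate_effects)
      cat(sprintf("  Covariate: %s on %s (%s), beta = %.4g\n",
                  ef$covariate, ef$parameter, ef$form, ef$coefficient))
  invisible(x)
}

#' Built-in study models
#'
#' Final one-compartment models for the two biosimilars. Adalimumab: typical
#' CL 0.00283 L/h, VD 9.19 L, ka fixed at 0.01167 /h (literature value; no
#' BSV on ka), BSV reported as lognormal CV% (68.9% on CL, 15.6% on VD)
#' and converted to log-scale SD, combined error with sigma_prop 0.26 and
#' sigma_add 10.8 mg/L. Etanercept: CL 0.0404 L/h, VD 7.76 L (no BSV), ka
#' fixed at 0.0396 /h, BSV on CL as log-scale SD 0.173 (~17.3% CV),
#' combined error with sigma_prop 0.46 and sigma_add fixed at 0.0001 mg/L
#' for stability. Reported-variability unit readings are overridable through
#' the arguments.
#'
#' @param ka absorption rate constant, 1/h (fixed, not estimated)
#' @param cv_CL,cv_VD BSV as lognormal CV fractions (adalimumab)
#' @param omega_CL BSV on CL as log-scale SD (etanercept)
#' @param sigma_add,sigma_prop residual error components
#' @return a [population_model()]
#' @export
model_adalimumab <- function(ka = 0.01167, cv_CL = 0.689, cv_VD = 0.156,
                             sigma_prop = 0.26, sigma_add = 10.8) {
  population_model(
    typical = pk_params(CL = 0.00283, VD = 9.19, ka = ka),
    bsv = c(CL = cv_to_omega(cv_CL), VD = cv_to_omega(cv_VD)),
    error_model = residual_error("combined", sigma_add = sigma_add,
                                 sigma_prop = sigma_prop),
    fixed = "ka", name = "adalimumab biosimilar")
}

#' @rdname model_adalimumab
#' @export
model_etanercept <- function(ka = 0.0396, omega_CL = 0.173,
                             sigma_prop = 0.46, sigma_add = 1e-4) {
  population_model(
    typical = pk_params(CL = 0.0404, VD = 7.76, ka = ka),
    bsv = c(CL = omega_CL),
    error_model = residual_error("combined", sigma_add = sigma_add,
                                 sigma_prop = sigma_prop),
    fixed = c("ka", "sigma_add"), name = "etanercept biosimilar")
}

#' Individual parameters from typicals, covariates and random effects
#'
#' \eqn{P_i = \theta \, g(cov_i) \, e^{\eta_i}}; with all \eqn{\eta = 0} and
#' no covariate effects this returns the typical values exactly.
#'
#' @param model a [population_model()]
#' @param cov a [subject_covariates()] object, or `NULL` when the model has
#'   no covariate effects
#' @param eta named vector of random effects for exactly the BSV-carrying
#'   parameters (default: all zero)
#' @return a [pk_params()] object
#' @export
individual_parameters <- function(model, cov = NULL,
                                  eta = stats::setNames(numeric(length(model$bsv)),
                                                        names(model$bsv))) {
  stopifnot(inherits(model, "population_model"))
  bn <- names(model$bsv)
  if (!setequal(names(eta) %||% character(0), bn))
    stop_input("eta must be supplied for exactly the BSV-carrying parameters (",
               paste(bn, collapse = ", "), ")")
  if (length(model$covariate_effects) && is.null(cov))
    stop_input("model has covariate effects; cov is required")
  th <- model$typical
  fac <- if (is.null(cov)) rep(1, 5) else
    covariate_factors(model$covariate_effects, cov)[1, ]
  names(fac) <- c("CL", "VD", "ka", "Q", "VP")
  mult <- stats::setNames(rep(1, 5), names(fac))
  if (length(bn)) mult[bn] <- exp(eta[bn])
  v <- unname(c(th$CL, th$VD, th$ka, th$Q %||% NA, th$VP %||% NA) *
                unname(fac) * unname(mult))
  pk_params(CL = v[1], VD = v[2], ka = v[3],
            Q = if (is_twocpt(th)) v[4], VP = if (is_twocpt(th)) v[5])
}

# draw an n x k matrix of random effects from N(0, Omega); zero omegas are
# legal (degenerate components), so scale after any correlation transform
draw_etas <- function(model, n) {
  k <- length(model$bsv)
  if (k == 0) return(matrix(0, n, 0))
  z <- matrix(stats::rnorm(n * k), n, k)
  if (!is.null(model$bsv_corr)) z <- z %*% chol(model$bsv_corr)
  etas <- sweep(z, 2, model$bsv, `*`)
  colnames(etas) <- names(model$bsv)
  etas
}

# n x 5 matrix of individual parameter values (columns CL, VD, ka, Q, VP)
individual_parameter_matrix <- function(model, covs, etas) {
  n <- nrow(etas)
  th <- model$typical
  base <- c(CL = th$CL, VD = th$VD, ka = th$ka,
            Q = th$Q %||% NA_real_, VP = th$VP %||% NA_real_)
  P <- matrix(rep(base, each = n), n, 5, dimnames = list(NULL, names(base)))
  if (length(model$covariate_effects)) {
    if (is.null(covs)) stop_input("model has covariate effects; covariates required")
    P <- P * covariate_factors(model$covariate_effects, covs)
  }
  for (nm in colnames(etas)) P[, nm] <- P[, nm] * exp(etas[, nm])
  P
}

#' Sample individual parameter sets from the population model
#'
#' @param model a [population_model()]
#' @param covariates optional data.frame with one row per subject (columns
#'   `age`, `body_weight`, `sex`, `csDMARD`); required when the model carries
#'   covariate effects
#' @param n number of individuals
#' @param seed optional integer seed (RNG state is restored afterwards)
#' @return a list of [pk_params()] objects with the drawn `eta` matrix as
#'   attribute `"etas"`
#' @export
sample_individuals <- function(model, n, covariates = NULL, seed = NULL) {
  stopifnot(inherits(model, "population_model"), n >= 1)
  with_seed(seed, {
    etas <- draw_etas(model, n)
    P <- individual_parameter_matrix(model, covariates, etas)
    out <- lapply(seq_len(n), function(i)
      pk_params(CL = P[i, "CL"], VD = P[i, "VD"], ka = P[i, "ka"],
                Q = if (is_twocpt(model$typical)) P[i, "Q"],
                VP = if (is_twocpt(model$typical)) P[i, "VP"]))
    attr(out, "etas") <- etas
    out
  })
}
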