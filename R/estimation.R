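#' Estimation settings
#'
#' @param max_iterations outer optimiser iteration cap (default 500)
#' @param agq_nodes adaptive Gauss-Hermite nodes per random-effect dimension;
#'   `NULL` selects 9 (one dimension), 5 (two) or Laplace (more)
#' @param rel_tol outer relative convergence tolerance
#' @return a list of settings for [fit_poppk()]
#' @export
fit_settings <- function(max_iterations = 500, agq_nodes = NULL,
                         rel_tol = 1e-8) {
  list(max_iterations = max_iterations, agq_nodes = agq_nodes,
       rel_tol = rel_tol)
}

#' Fit the population PK model by maximum likelihood
#'
#' Maximises the marginal likelihood of the hierarchical model (random
#' effects integrated out by adaptive Gauss-Hermite quadrature centred on the
#' per-subject conditional modes; the one-node case is the Laplace
#' approximation). Structural parameters, BSV magnitudes and residual SDs are
#' estimated on the log scale to enforce positivity; covariate coefficients
#' are unconstrained. Parameters named in `model$fixed` are honoured exactly
#' and returned bit-identical. The procedure is deterministic: no simulation
#' enters the objective.
#'
#' @param dataset a [study_dataset()] with at least one likelihood
#'   observation (`mdv = 0`)
#' @param model a [population_model()] providing initial values, BSV
#'   configuration, error-model kind and fixed flags
#' @param settings a [fit_settings()] list
#' @param se compute standard errors from the observed Fisher information
#'   (numerical Hessian of the marginal log-likelihood); skip for speed in
#'   large model scans
#' @return an object of class `fit_result` with components `estimates` (the
#'   fitted [population_model()]), `parameters` (data.frame of estimates, SEs
#'   and RSE%), `minus2LL`, `aic`, `n_estimated`, `individual_estimates`
#'   (empirical-Bayes subject parameters), `eta` (conditional modes), and
#'   `convergence`
#' @examples
#' \donttest{
#' ds <- generate_dataset(model_etanercept(), design_recovery("etanercept"),
#'                        dosing_regimen(50, 168), n_subjects = 40, seed = 7)
#' fit <- fit_poppk(ds, model_etanercept())
#' fit$parameters
#' }
#' @export
fit_poppk <- function(dataset, model, settings = fit_settings(), se = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(model, "population_model"))
  prep <- prep_nlme(dataset, model)
  pspec <- build_pspec(model)
  state <- new.env(parent = emptyenv())
  objective <- function(x) {
    m <- apply_pspec(model, pspec, x)
    val <- tryCatch(model_nll(m, prep, settings$agq_nodes, state)$nll,
                    error = function(e) NA_real_)
    if (!is.finite(val)) return(1e10)
    val
  }
  gradient <- function(x) {
    h <- 1e-4
    vapply(seq_along(x), function(j) {
      xp <- xm <- x
      xp[j] <- x[j] + h
      xm[j] <- x[j] - h
      (objective(xp) - objective(xm)) / (2 * h)
    }, 0)
  }
  opt <- stats::nlminb(pspec$start, objective, gradient = gradient,
                       control = list(iter.max = settings$max_iterations,
                                      eval.max = 8 * settings$max_iterations,
                                      rel.tol = settings$rel_tol))
  est_model <- apply_pspec(model, pspec, opt$par)
  final <- tryCatch(model_nll(est_model, prep, settings$agq_nodes, state),
                    error = function(e)
                      model_nll(est_model, prep, settings$agq_nodes, NULL))
  p <- length(pspec$free)
  converged <- opt$convergence == 0 && opt$iterations <= settings$max_iterations
  par_tab <- parameter_table(pspec, opt$par, vcov_x = NULL)
  fit <- structure(list(
    estimates = est_model, parameters = par_tab,
    minus2LL = 2 * final$nll, aic = 2 * final$nll + 2 * p,
    n_estimated = p,
    individual_estimates = ebe_table(dataset, final),
    eta = final$etas,
    convergence = list(status = if (converged) "converged" else "not_converged",
                       iterations = opt$iterations, message = opt$message),
    .objective = objective, .par = opt$par, .pspec = pspec,
    .model0 = model, .settings = settings, dataset = dataset),
    class = "fit_result")
  if (!converged)
    warning("optimiser did not report convergence (", opt$message,
            "); partial result returned", call. = FALSE)
  if (se) fit <- compute_standard_errors(fit)
  fit
}

ebe_table <- function(dataset, final) {
  ids <- dataset$subjects$id
  out <- data.frame(id = ids, CL = final$ipar[, "CL"], VD = final$ipar[, "VD"],
                    ka = final$ipar[, "ka"])
  if (!all(is.na(final$ipar[, "Q"]))) {
    out$Q <- final$ipar[, "Q"]; out$VP <- final$ipar[, "VP"]
  }
  out
}

parameter_table <- function(pspec, x, vcov_x) {
  nat <- se_nat <- numeric(length(pspec$free))
  for (i in seq_along(pspec$free)) {
    e <- pspec$free[[i]]
    nat[i] <- if (e$trans == "log") exp(x[i]) else x[i]
    se_nat[i] <- if (is.null(vcov_x)) NA_real_ else {
      sx <- sqrt(pmax(vcov_x[i, i], 0))
      if (e$trans == "log") nat[i] * sx else sx
    }
  }
  data.frame(parameter = pspec$free_names,
             block = vapply(pspec$free, `[[`, "", "block"),
             estimate = nat, se = se_nat,
             rse_percent = 100 * se_nat / abs(nat))
}

#' Standard errors and RSE from the observed Fisher information
#'
#' Numerically differentiates the marginal log-likelihood at the optimum,
#' inverts the observed information, and propagates to the natural scale by
#' the delta method. RSE% is `100 * SE / |estimate|`; fixed parameters carry
#' no SE/RSE entry.
#'
#' @param fit a [fit_poppk()] result
#' @return the fit with its `parameters` table populated with `se` and
#'   `rse_percent`
#' @export
compute_standard_errors <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  Hx <- tryCatch(stats::optimHess(fit$.par, fit$.objective),
                 error = function(e) NULL)
  vcov_x <- if (!is.null(Hx))
    tryCatch(solve(Hx), error = function(e) NULL)
  if (is.null(vcov_x) || any(!is.finite(diag(vcov_x)))) {
    warning("singular information matrix; standard errors unavailable",
            call. = FALSE)
    vcov_x <- NULL
  }
  fit$parameters <- parameter_table(fit$.pspec, fit$.par, vcov_x)
  fit$vcov <- vcov_x
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Population PK fit (", x$convergence$status, ", ",
      x$convergence$iterations, " iterations)\n", sep = "")
  cat(sprintf("  -2LL = %.3f, AIC = %.3f, %d estimated parameters\n",
              x$minus2LL, x$aic, x$n_estimated))
  tab <- x$parameters
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$rse_percent <- signif(tab$rse_percent, 3)
  print(tab, row.names = FALSE)
  fx <- x$estimates$fixed
  if (length(fx)) cat("  Fixed:", paste(fx, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.fit_result <- function(object, ...) {
  structure(-object$minus2LL / 2, df = object$n_estimated, class = "logLik")
}

#' Compare two fitted models by AIC and likelihood-ratio test
#'
#' The LRT requires nesting, checked by inclusion of the estimated-parameter
#' name sets; the statistic is `-2LL(reduced) - (-2LL(full))` referred to a
#' chi-squared distribution with df equal to the difference in
#' estimated-parameter counts. Non-nested models can still be compared by AIC
#' with `lrt = FALSE`.
#'
#' @param fit_a,fit_b [fit_poppk()] results on the same dataset
#' @param lrt perform the likelihood-ratio test
#' @return a list with `delta_aic` (`aic_b - aic_a`), and when `lrt` is
#'   `TRUE`: `lrt_stat`, `df`, `p_value`
#' @export
compare_models <- function(fit_a, fit_b, lrt = TRUE) {
  stopifnot(inherits(fit_a, "fit_result"), inherits(fit_b, "fit_result"))
  out <- list(aic_a = fit_a$aic, aic_b = fit_b$aic,
              delta_aic = fit_b$aic - fit_a$aic)
  if (!lrt) return(out)
  pa <- fit_a$.pspec$free_names
  pb <- fit_b$.pspec$free_names
  if (all(pa %in% pb)) { red <- fit_a; full <- fit_b }
  else if (all(pb %in% pa)) { red <- fit_b; full <- fit_a }
  else stop_input("models are not nested (parameter-set inclusion fails); ",
                  "use lrt = FALSE for an AIC-only comparison")
  stat <- red$minus2LL - full$minus2LL
  df <- full$n_estimated - red$n_estimated
  p <- if (df == 0) {
    if (abs(stat) < 1e-6) 1 else NA_real_
  } else stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
  c(out, list(lrt_stat = stat, df = df, p_value = p))
}

#' Default covariate candidates for the selection scan
#'
#' Age and body weight (power models centred on the dataset medians) and sex
#' and concurrent csDMARD (proportional shifts), each on CL and on VD.
#'
#' @param dataset a [study_dataset()] (for centring medians)
#' @return list of single-effect candidates for [covariate_scan()]
#' @export
default_candidates <- function(dataset) {
  meds <- list(age = stats::median(dataset$subjects$age),
               body_weight = stats::median(dataset$subjects$body_weight))
  out <- list()
  for (param in c("CL", "VD"))
    for (cv in c("age", "body_weight", "sex", "csDMARD"))
      out[[paste(cv, param, sep = "_on_")]] <-
        covariate_effect(param, cv, coefficient = 0,
                         reference = meds[[cv]])
  out
}

#' Covariate selection scan
#'
#' Fits the base model plus each single candidate effect, annotates each with
#' its LRT p-value against the base fit, and ranks by AIC. The selection rule
#' keeps the candidate with the lowest AIC among those with LRT p < `alpha`,
#' preferring the simpler (base) model on ties: an AIC improvement of less
#' than `aic_tie` over the base counts as a tie.
#'
#' @param dataset a [study_dataset()]
#' @param base_model a [population_model()] without the candidate effects
#' @param candidates named list of [covariate_effect()] objects (default:
#'   [default_candidates()]); empty list returns the base fit unchanged
#' @param alpha LRT significance level (default 0.05)
#' @param aic_tie AIC margin treated as a tie (default 2)
#' @param settings,se passed to [fit_poppk()]
#' @return a list with `table` (one row per candidate: deviance, AIC, LRT
#'   p-value, convergence status), `selected` (name of the chosen model,
#'   `"base"` if none qualifies), `base_fit`, and `fits`
#' @export
covariate_scan <- function(dataset, base_model,
                           candidates = default_candidates(dataset),
                           alpha = 0.05, aic_tie = 2,
                           settings = fit_settings(), se = FALSE) {
  base_fit <- fit_poppk(dataset, base_model, settings = settings, se = se)
  if (!length(candidates))
    return(list(table = NULL, selected = "base", base_fit = base_fit,
                fits = list()))
  rows <- list()
  fits <- list()
  for (nm in names(candidates)) {
    m <- base_model
    m$covariate_effects <- c(m$covariate_effects, list(candidates[[nm]]))
    f <- tryCatch(
      suppressWarnings(fit_poppk(dataset, m, settings = settings, se = se)),
      error = function(e) NULL)
    if (is.null(f)) {
      rows[[nm]] <- data.frame(candidate = nm, beta = NA, minus2LL = NA,
                               aic = NA, lrt_stat = NA, p_value = NA,
                               status = "failed")
      next
    }
    cmp <- compare_models(base_fit, f)
    bnm <- sprintf("beta_%s_%s", candidates[[nm]]$covariate,
                   candidates[[nm]]$parameter)
    rows[[nm]] <- data.frame(
      candidate = nm,
      beta = f$parameters$estimate[f$parameters$parameter == bnm],
      minus2LL = f$minus2LL, aic = f$aic,
      lrt_stat = cmp$lrt_stat, p_value = cmp$p_value,
      status = f$convergence$status)
    fits[[nm]] <- f
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic), ]
  ok <- !is.na(tab$p_value) & tab$p_value < alpha &
    tab$aic <= base_fit$aic - aic_tie & tab$status == "converged"
  selected <- if (any(ok)) tab$candidate[which(ok)[1]] else "base"
  list(table = tab, selected = selected, base_fit = base_fit, fits = fits)
}

#' Empirical-Bayes evaluation of a model on a dataset without refitting
#'
#' Computes the marginal deviance, conditional-mode random effects and
#' individual parameters for a fully specified model. Useful for diagnostics
#' under a known (e.g. simulation-true) model.
#'
#' @inheritParams minus2ll
#' @return a `fit_result` with `convergence$status = "evaluated"`
#' @export
evaluate_model <- function(model, dataset, agq_nodes = NULL) {
  prep <- prep_nlme(dataset, model)
  final <- model_nll(model, prep, agq_nodes)
  pspec <- build_pspec(model)
  p <- length(pspec$free)
  structure(list(
    estimates = model,
    parameters = parameter_table(pspec, pspec$start, NULL),
    minus2LL = 2 * final$nll, aic = 2 * final$nll + 2 * p, n_estimated = p,
    individual_estimates = ebe_table(dataset, final), eta = final$etas,
    convergence = list(status = "evaluated", iterations = 0, message = ""),
    .pspec = pspec, .model0 = model, dataset = dataset),
    class = "fit_result")
}
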