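# Simulation-based goodness-of-fit diagnostics. PWRES and NPDE use
# Monte-Carlo simulation from the population model rather than first-order
# linearisation: exact under the nonlinear model at desk-scale cost.

fit_model_of <- function(fit) fit$estimates

check_fit_covers <- function(fit, dataset) {
  missing_ids <- setdiff(dataset$subjects$id, fit$individual_estimates$id)
  if (length(missing_ids))
    stop_input("subject(s) in dataset absent from fit: ",
               paste(missing_ids, collapse = ", "))
}

#' Population and individual predictions
#'
#' PRED is the prediction for the covariate-adjusted typical subject
#' (\eqn{\eta = 0}); IPRED uses the empirical-Bayes individual parameters.
#'
#' @param fit a [fit_poppk()] or [evaluate_model()] result
#' @param dataset a [study_dataset()]; defaults to the one the model was
#'   fitted to
#' @return data.frame with one row per likelihood observation: `id`, `time`,
#'   `DV`, `PRED`, `IPRED`
#' @export
predictions <- function(fit, dataset = fit$dataset) {
  stopifnot(inherits(fit, "fit_result"))
  check_fit_covers(fit, dataset)
  model <- fit_model_of(fit)
  prep <- prep_nlme(dataset, model)
  n <- prep$n_subj
  P_typ <- individual_parameter_matrix(model, prep$covs,
                                       matrix(0, n, length(model$bsv),
                                              dimnames = list(NULL, names(model$bsv))))
  ie <- fit$individual_estimates[match(dataset$subjects$id,
                                       fit$individual_estimates$id), ]
  P_ind <- cbind(CL = ie$CL, VD = ie$VD, ka = ie$ka,
                 Q = ie$Q %||% NA_real_, VP = ie$VP %||% NA_real_)
  data.frame(id = prep$obs$id, time = prep$obs$time, DV = prep$obs$dv,
             PRED = conc_for_obs(prep, P_typ),
             IPRED = conc_for_obs(prep, P_ind))
}

#' Individual weighted residuals
#'
#' `IWRES = (DV - IPRED) / sqrt(IPRED^2 sigma_prop^2 + sigma_add^2)`; under
#' the true model these have mean ~0 and SD ~1.
#'
#' @inheritParams predictions
#' @return numeric vector, one value per likelihood observation
#' @export
iwres <- function(fit, dataset = fit$dataset) {
  em <- fit_model_of(fit)$error_model
  if (em$sigma_add == 0 && em$sigma_prop == 0)
    stop_input("all residual SDs are zero; IWRES undefined")
  pr <- predictions(fit, dataset)
  (pr$DV - pr$IPRED) / error_sd(em, pr$IPRED)
}

# simulate the population-model observation matrix (n_obs x n_sim),
# including residual error
simulate_obs_matrix <- function(model, prep, n_sim) {
  n <- prep$n_subj
  Y <- matrix(NA_real_, nrow(prep$obs), n_sim)
  for (s in seq_len(n_sim)) {
    etas <- draw_etas(model, n)
    P <- individual_parameter_matrix(model, prep$covs, etas)
    f <- conc_for_obs(prep, P)
    Y[, s] <- observe_conc(pmax(f, 0), model$error_model)
  }
  Y
}

#' Population weighted residuals by Monte-Carlo
#'
#' The mean and SD of each observation under the population model (random
#' effects and residual error) are estimated by simulation;
#' `PWRES = (DV - E[y]) / SD[y]`.
#'
#' @inheritParams predictions
#' @param n_sim number of simulation replicates (>= 500)
#' @param seed integer seed for the simulation stream
#' @return numeric vector, one value per likelihood observation
#' @export
pwres <- function(fit, dataset = fit$dataset, n_sim = 1000, seed = 1) {
  if (n_sim < 500) stop_input("n_sim must be >= 500")
  check_fit_covers(fit, dataset)
  model <- fit_model_of(fit)
  prep <- prep_nlme(dataset, model)
  with_seed(seed, {
    Y <- simulate_obs_matrix(model, prep, n_sim)
    m <- rowMeans(Y)
    s <- sqrt(rowMeans((Y - m)^2) * n_sim / (n_sim - 1))
    (prep$obs$dv - m) / s
  })
}

#' Normalised prediction distribution errors
#'
#' Simulates `n_sim` replicate datasets under the model, decorrelates the
#' observed and simulated vectors within each subject by the Cholesky factor
#' of the empirical simulation covariance (with a 1e-10 diagonal jitter for
#' near-singular sparse designs), and maps the rank of each decorrelated
#' observation among its simulations through the standard-normal quantile:
#' `pde = (rank + 0.5) / (n_sim + 1)`, `NPDE = qnorm(pde)`. The offset
#' convention keeps every pde strictly inside (0, 1), so NPDE is always
#' finite. Under a correct model NPDE is approximately standard normal.
#'
#' @inheritParams pwres
#' @param seed integer seed (required: NPDE is a pure function of
#'   fit, dataset and seed)
#' @return numeric vector, one value per likelihood observation
#' @export
npde <- function(fit, dataset = fit$dataset, n_sim = 1000, seed) {
  if (n_sim < 100) stop_input("n_sim must be >= 100 to resolve ranks")
  if (missing(seed)) stop_input("seed is required")
  check_fit_covers(fit, dataset)
  model <- fit_model_of(fit)
  prep <- prep_nlme(dataset, model)
  with_seed(seed, {
    Y <- simulate_obs_matrix(model, prep, n_sim)
    out <- numeric(nrow(prep$obs))
    for (i in unique(prep$subj_idx)) {
      rows <- which(prep$subj_idx == i)
      Yi <- Y[rows, , drop = FALSE]
      yi <- prep$obs$dv[rows]
      m <- rowMeans(Yi)
      S <- stats::cov(t(Yi)) + diag(1e-10, length(rows))
      R <- chol(S)  # S = R'R
      ystar <- backsolve(R, yi - m, transpose = TRUE)
      Sstar <- backsolve(R, Yi - m, transpose = TRUE)
      rank_below <- rowSums(Sstar < ystar)
      out[rows] <- stats::qnorm((rank_below + 0.5) / (n_sim + 1))
    }
    out
  })
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper with the diagnostic conventions used here: valid for
#' 3 <= n <= 5000 and rejecting degenerate (zero-variance) input.
#'
#' @param values numeric sample
#' @return list with `W` and `p`
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop_input("n must be within [3, 5000]")
  if (stats::sd(values) == 0) stop_input("zero variance: test undefined")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}

#' Full goodness-of-fit diagnostics table
#'
#' One row per likelihood observation with PRED, IPRED, DV, PWRES, IWRES and
#' NPDE, plus the Shapiro-Wilk test of the NPDE distribution as attribute
#' `"npde_test"` (with its alpha = 0.05 verdict).
#'
#' @inheritParams npde
#' @return a data.frame of class `diagnostics_table`
#' @export
diagnostics_table <- function(fit, dataset = fit$dataset, n_sim = 1000, seed = 1) {
  pr <- predictions(fit, dataset)
  pr$PWRES <- pwres(fit, dataset, n_sim = max(n_sim, 500), seed = seed)
  pr$IWRES <- iwres(fit, dataset)
  pr$NPDE <- npde(fit, dataset, n_sim = n_sim, seed = seed + 1L)
  sw <- shapiro_wilk(pr$NPDE)
  sw$reject_at_0.05 <- sw$p < 0.05
  attr(pr, "npde_test") <- sw
  class(pr) <- c("diagnostics_table", class(pr))
  pr
}
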