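# Forward simulation of dosing regimens: virtual populations with percentile
# bands, and deterministic typical-individual regimen comparison against a
# therapeutic window.

#' Simulate a virtual population under a dosing regimen
#'
#' Draws `n` individuals from the population model (between-subject
#' variability and, when the model carries covariate effects, covariates),
#' computes each residual-error-free concentration profile on an hourly grid,
#' and summarises the pointwise median and 5th/95th percentiles by direct
#' order statistics. Percentile bands reflect BSV only unless
#' `include_residual = TRUE` adds assay noise.
#'
#' @param model a [population_model()]
#' @param regimen a [dosing_regimen()]
#' @param horizon_h simulation horizon in hours (>= one interval; default
#'   2016 h = 12 weeks, the study follow-up)
#' @param n number of virtual individuals (default 10000)
#' @param seed integer seed
#' @param include_residual add residual (assay) error to individual profiles
#' @param resolution_h time-grid spacing, h
#' @param covariates optional [covariate_distribution()] when the model has
#'   covariate effects
#' @return an object of class `simulation_summary`: `time`, `median`, `p5`,
#'   `p95`, `typical` (eta = 0 profile), `n_individuals`, `seed`
#' @export
simulate_population_profile <- function(model, regimen, horizon_h = 2016,
                                        n = 10000, seed = 1,
                                        include_residual = FALSE,
                                        resolution_h = 1, covariates = NULL) {
  stopifnot(inherits(model, "population_model"),
            inherits(regimen, "dosing_regimen"))
  if (horizon_h < regimen$interval)
    stop_input("horizon must cover at least one dosing interval")
  if (n < 100) warning("n < 100 gives unstable percentiles", call. = FALSE)
  times <- seq(0, horizon_h, by = resolution_h)
  typ <- conc_profile(individual_parameters(model), regimen, times)
  with_seed(seed, {
    etas <- draw_etas(model, n)
    covs <- if (length(model$covariate_effects)) {
      draw_covariates(covariates %||% builtin_covariates(), n)
    } else NULL
    P <- individual_parameter_matrix(model, covs, etas)
    td <- dose_times(regimen, horizon_h)
    D <- regimen$dose_amount
    qs <- matrix(NA_real_, length(times), 3)
    chunk <- 256L
    for (lo in seq(1, length(times), by = chunk)) {
      hi <- min(lo + chunk - 1L, length(times))
      tt <- times[lo:hi]
      C <- matrix(0, n, length(tt))
      if (is_twocpt(model$typical)) {
        reg_chunk <- regimen
        for (i in seq_len(n)) {
          p_i <- pk_params(CL = P[i, "CL"], VD = P[i, "VD"], ka = P[i, "ka"],
                           Q = P[i, "Q"], VP = P[i, "VP"])
          C[i, ] <- conc_profile(p_i, reg_chunk, tt)
        }
      } else {
        ke <- P[, "CL"] / P[, "VD"]
        ka <- P[, "ka"]
        close <- abs(ka - ke) / ke < 1e-7
        if (any(close)) ke[close] <- ke[close] * (1 + 1e-6)
        coef <- D * ka / (P[, "VD"] * (ka - ke))
        for (d in td) {
          lag <- tt - d
          lag[lag < 0] <- Inf
          C <- C + coef * (exp(-outer(ke, lag)) - exp(-outer(ka, lag)))
        }
      }
      if (include_residual) {
        em <- model$error_model
        C <- C * (1 + stats::rnorm(length(C), 0, em$sigma_prop)) +
          stats::rnorm(length(C), 0, em$sigma_add)
      }
      qs[lo:hi, ] <- t(apply(C, 2, stats::quantile,
                             probs = c(0.05, 0.5, 0.95), names = FALSE))
    }
    structure(list(time = times, p5 = qs[, 1], median = qs[, 2],
                   p95 = qs[, 3], typical = typ, n_individuals = n,
                   seed = seed, include_residual = include_residual),
              class = "simulation_summary")
  })
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("Population simulation: %d individuals over %g h (seed %d)\n",
              x$n_individuals, max(x$time), x$seed))
  cat(sprintf("  final point: median %.3g [p5 %.3g, p95 %.3g] mg/L\n",
              x$median[length(x$median)], x$p5[length(x$p5)],
              x$p95[length(x$p95)]))
  invisible(x)
}

#' Compare dosing regimens for the typical individual
#'
#' Deterministic comparison based on the typical (eta = 0) individual:
#' analytic steady-state metrics, position of the steady-state trough
#' relative to the therapeutic window, time to reach 90% of the asymptotic
#' trough, and the finite-horizon trough (concentration at `horizon_h`). The
#' window position is judged on the asymptotic steady-state trough; the
#' finite-horizon value is reported separately because a long effective
#' half-life can leave the study window far from steady state.
#'
#' @param model a [population_model()]
#' @param regimens list of [dosing_regimen()] objects
#' @param window a [therapeutic_window()]
#' @param horizon_h finite reporting horizon, h
#' @return a data.frame, one row per regimen: dose, interval, `C_avg`,
#'   `C_trough_ss`, `C_max_ss`, `C_at_horizon`, `accumulation_ratio`,
#'   `time_to_90pct_ss_h`, `window_position`
#' @examples
#' compare_regimens(model_etanercept(),
#'                  list(dosing_regimen(50, 120), dosing_regimen(50, 168),
#'                       dosing_regimen(50, 240)),
#'                  therapeutic_window(2.1, 4.7))
#' @export
compare_regimens <- function(model, regimens, window, horizon_h = 2016) {
  stopifnot(inherits(model, "population_model"),
            inherits(window, "therapeutic_window"))
  typ <- individual_parameters(model)
  rows <- lapply(regimens, function(reg) {
    stopifnot(inherits(reg, "dosing_regimen"))
    if (reg$dose_amount == 0) {
      return(data.frame(dose_mg = 0, interval_h = reg$interval, C_avg = 0,
                        C_trough_ss = 0, C_max_ss = 0, C_at_horizon = 0,
                        accumulation_ratio = 1 / (1 - exp(-elimination_rate(typ) * reg$interval)),
                        time_to_90pct_ss_h = reg$interval,
                        window_position = "below"))
    }
    ss <- steady_state_metrics(typ, reg)
    pos <- if (ss$C_trough < window$lower) "below"
           else if (ss$C_trough > window$upper) "above" else "within"
    data.frame(dose_mg = reg$dose_amount, interval_h = reg$interval,
               C_avg = ss$C_avg, C_trough_ss = ss$C_trough,
               C_max_ss = ss$C_max,
               C_at_horizon = conc_profile(typ, reg, horizon_h),
               accumulation_ratio = ss$accumulation_ratio,
               time_to_90pct_ss_h = ss$time_to_90pct_steady_state,
               window_position = pos)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coverage of observed data by simulated percentile bands
#'
#' Fraction of likelihood observations falling within the simulated
#' [p5, p95] band at their sampling times (band interpolated on the grid).
#' Observations beyond the simulation horizon are excluded and counted.
#'
#' @param summary a [simulate_population_profile()] result
#' @param dataset a [study_dataset()]
#' @return list with `coverage` (fraction in-band, `NA` if no usable
#'   observations), `n_used`, `n_excluded`
#' @export
overlay_observations <- function(summary, dataset) {
  stopifnot(inherits(summary, "simulation_summary"),
            inherits(dataset, "study_dataset"))
  ob <- dataset$obs[dataset$obs$mdv == 0, , drop = FALSE]
  beyond <- ob$time > max(summary$time)
  use <- ob[!beyond, , drop = FALSE]
  if (nrow(use) == 0)
    return(list(coverage = NA_real_, n_used = 0L, n_excluded = sum(beyond)))
  lo <- stats::approx(summary$time, summary$p5, use$time)$y
  hi <- stats::approx(summary$time, summary$p95, use$time)$y
  list(coverage = mean(use$dv >= lo & use$dv <= hi),
       n_used = nrow(use), n_excluded = sum(beyond))
}

#' Plot a population simulation with its therapeutic window
#'
#' @param summary a [simulate_population_profile()] result
#' @param window optional [therapeutic_window()]
#' @param dataset optional [study_dataset()] whose observations are overlaid
#'   (values clipped at 0 for display)
#' @return a ggplot object
#' @export
plot_simulation <- function(summary, window = NULL, dataset = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_input("ggplot2 is required for plotting")
  df <- data.frame(time = summary$time / 24, median = summary$median,
                   p5 = summary$p5, p95 = summary$p95)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = p5, ymax = p95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = median), colour = "steelblue4") +
    ggplot2::labs(x = "Time (days)", y = "Concentration (mg/L)")
  if (!is.null(window))
    p <- p + ggplot2::geom_hline(yintercept = c(window$lower, window$upper),
                                 colour = "grey40", linetype = "dashed")
  if (!is.null(dataset)) {
    ob <- dataset$obs[dataset$obs$mdv == 0, ]
    p <- p + ggplot2::geom_point(
      data = data.frame(time = ob$time / 24, dv = pmax(ob$dv, 0)),
      ggplot2::aes(x = time, y = dv), size = 0.8)
  }
  p
}
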