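# Shared fixtures: study models, regimens, and ODE oracles built in code.

etn_params <- function() pk_params(CL = 0.0404, VD = 7.76, ka = 0.0396)
etn_regimen <- function() dosing_regimen(50, 168)
ada_regimen <- function() dosing_regimen(40, 336)

# Independent ODE oracle for the depot + central (+ peripheral) system;
# integrates the full multi-dose problem with deSolve.
ode_conc <- function(params, dose_times, dose_amt, times) {
  ka <- params$ka
  ke <- params$CL / params$VD
  if (is.null(params$Q)) {
    rhs <- function(t, y, p) list(c(-ka * y[1], ka * y[1] - ke * y[2]))
    y0 <- c(A = 0, C = 0)
  } else {
    k12 <- params$Q / params$VD
    k21 <- params$Q / params$VP
    rhs <- function(t, y, p) list(c(
      -ka * y[1],
      ka * y[1] - (ke + k12) * y[2] + k21 * y[3],
      k12 * y[2] - k21 * y[3]))
    y0 <- c(A = 0, C = 0, P = 0)
  }
  ev <- data.frame(var = "A", time = dose_times, value = dose_amt,
                   method = "add")
  grid <- sort(unique(c(0, dose_times, times)))
  out <- deSolve::ode(y0, grid, rhs, NULL, events = list(data = ev),
                      rtol = 1e-11, atol = 1e-13)
  out[match(times, out[, "time"]), "C"] / params$VD
}

# noiseless single-subject dataset with a rich schedule (for exact-recovery
# and prediction tests)
rich_noiseless_dataset <- function(params, regimen = etn_regimen(),
                                   times = c(6, 12, 24, 48, 96, 168, 240,
                                             336, 504, 672, 1008, 2016)) {
  truth <- conc_profile(params, regimen, times)
  study_dataset(
    subjects = data.frame(id = 1, age = 55, body_weight = 70, sex = 1,
                          csDMARD = 1),
    doses = data.frame(id = 1, time = dose_times(regimen, max(times)),
                       amt = regimen$dose_amount),
    obs = data.frame(id = 1, time = times, dv = truth, mdv = 0))
}

dose_times <- biosimpk:::dose_times

# 31-node adaptive Gauss-Hermite oracle for the marginal -2LL of a
# one-random-effect model, written independently of the package's engine:
# Bateman superposition, lognormal eta on CL, combined error.
agq_oracle_m2ll <- function(model, dataset, n_nodes = 31) {
  gh <- pracma::gaussHermite(n_nodes)
  omega <- model$bsv[["CL"]]
  em <- model$error_model
  th <- model$typical
  total <- 0
  for (id in dataset$subjects$id) {
    ob <- dataset$obs[dataset$obs$id == id & dataset$obs$mdv == 0, ]
    dl <- dataset$doses[dataset$doses$id == id, ]
    cond_ll <- function(eta) {
      CL <- th$CL * exp(eta)
      ke <- CL / th$VD
      f <- vapply(ob$time, function(t) {
        past <- dl[dl$time <= t, ]
        sum(past$amt * th$ka / (th$VD * (th$ka - ke)) *
              (exp(-ke * (t - past$time)) - exp(-th$ka * (t - past$time))))
      }, 0)
      sum(dnorm(ob$dv, f, sqrt(f^2 * em$sigma_prop^2 + em$sigma_add^2),
                log = TRUE))
    }
    joint <- function(eta) cond_ll(eta) + dnorm(eta, 0, omega, log = TRUE)
    opt <- optimize(function(e) -joint(e), c(-8 * omega, 8 * omega))
    mode <- opt$minimum
    h <- 1e-4
    hess <- -(joint(mode + h) + joint(mode - h) - 2 * joint(mode)) / h^2
    s <- 1 / sqrt(hess)
    lw <- log(gh$w) + gh$x^2 +
      vapply(mode + sqrt(2) * s * gh$x, joint, 0)
    mx <- max(lw)
    total <- total + 0.5 * log(2) + log(s) + mx + log(sum(exp(lw - mx)))
  }
  -2 * total
}

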