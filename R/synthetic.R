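#' Sparse sampling design
#'
#' Sample times are hours relative to the first dose; times are normalised to
#' sorted unique order. `trough_times` marks samples drawn immediately
#' pre-dose (true troughs): in the exported dataset the observation row
#' precedes the dose row at the same nominal time.
#'
#' @param times non-negative sample times, h
#' @param trough_times subset of `times` drawn immediately before a dose
#' @param name design label
#' @return an object of class `sampling_design`
#' @export
sampling_design <- function(times, trough_times = numeric(0), name = "custom") {
  if (any(times < 0)) stop_input("sample times must be >= 0")
  times <- sort(unique(times))
  if (!all(trough_times %in% times))
    stop_input("trough_times must be a subset of times")
  structure(list(name = name, times = times,
                 trough = times %in% trough_times), class = "sampling_design")
}

#' Built-in study sampling designs
#'
#' The optimised trough-oriented schedules used for the two arms: baseline
#' (pre-treatment), 1 h post-first dose, then pre-dose troughs at 2, 4, 6 and
#' 12 weeks; the etanercept arm adds a sample at day 6 (144 h). All
#' post-baseline samples after the 1 h sample are true troughs taken directly
#' before the next dose.
#'
#' @param drug "adalimumab" or "etanercept"
#' @return a [sampling_design()]
#' @examples
#' builtin_design("adalimumab")$times  # 0, 1, 336, 672, 1008, 2016
#' @export
builtin_design <- function(drug = c("adalimumab", "etanercept")) {
  drug <- match.arg(drug)
  troughs <- c(336, 672, 1008, 2016)
  times <- switch(drug,
    adalimumab = c(0, 1, troughs),
    etanercept = c(0, 1, 144, troughs))
  sampling_design(times, trough_times = troughs, name = drug)
}

#' Parameter-recovery sampling design
#'
#' A rich 12-sample per-subject schedule used by the package's simulation
#' protocols for parameter recovery. The etanercept schedule spans the
#' 12-week study window with absorption-phase and trough samples. The
#' adalimumab schedule uses six pairs of troughs 24 h apart between weeks 16
#' and 48: the drug's long effective half-life (VD/CL of roughly 94 days)
#' leaves early samples weakly informative, late troughs carry most of the
#' between-subject signal, and the near-replicate pairs (the profile is
#' essentially flat over 24 h at this half-life) separate residual error
#' from between-subject variability.
#'
#' @inheritParams builtin_design
#' @return a [sampling_design()]
#' @export
design_recovery <- function(drug = c("adalimumab", "etanercept")) {
  drug <- match.arg(drug)
  times <- switch(drug,
    etanercept = c(2, 24, 72, 144, 167, 336, 504, 672, 1008, 1344, 1680, 2016),
    adalimumab = c(2688, 2712, 4032, 4056, 5376, 5400, 6384, 6408, 7056,
                   7080, 8040, 8064))
  sampling_design(times, name = paste0(drug, "-recovery"))
}

#' Cohort covariate distributions
#'
#' Lognormal age and body-weight distributions matched to the reported cohort
#' medians and interquartile ranges, plus Bernoulli sex (female = 1) and
#' concurrent-csDMARD indicators. Adalimumab arm: weight median 85.5 kg
#' [66--111], age 50.5 y [46--61], 90% female, 80% csDMARD. Etanercept arm:
#' weight 70.5 kg [69--84], age 57.5 y [56--59], 67% female, csDMARD in all
#' with known status.
#'
#' @param drug "adalimumab" or "etanercept"
#' @return an object of class `covariate_distribution` with a
#'   `draw(n)`-style sampler used by [generate_dataset()]
#' @export
builtin_covariates <- function(drug = c("adalimumab", "etanercept")) {
  drug <- match.arg(drug)
  spec <- switch(drug,
    adalimumab = list(weight = c(85.5, 66, 111), age = c(50.5, 46, 61),
                      p_female = 0.9, p_csdmard = 0.8),
    etanercept = list(weight = c(70.5, 69, 84), age = c(57.5, 56, 59),
                      p_female = 2 / 3, p_csdmard = 1))
  covariate_distribution(weight_median = spec$weight[1],
                         weight_iqr = spec$weight[2:3],
                         age_median = spec$age[1], age_iqr = spec$age[2:3],
                         p_female = spec$p_female, p_csdmard = spec$p_csdmard)
}

#' @rdname builtin_covariates
#' @param weight_median,weight_iqr,age_median,age_iqr medians and IQRs
#'   (length-2, 25th and 75th percentiles) of body weight (kg) and age (years)
#' @param p_female,p_csdmard Bernoulli probabilities for the binary covariates
#' @export
covariate_distribution <- function(weight_median, weight_iqr, age_median,
                                   age_iqr, p_female = 0.5, p_csdmard = 0.5) {
  iqr_sdlog <- function(iqr) (log(iqr[2]) - log(iqr[1])) / (2 * stats::qnorm(0.75))
  structure(list(weight_meanlog = log(weight_median),
                 weight_sdlog = iqr_sdlog(weight_iqr),
                 age_meanlog = log(age_median), age_sdlog = iqr_sdlog(age_iqr),
                 p_female = p_female, p_csdmard = p_csdmard),
            class = "covariate_distribution")
}

draw_covariates <- function(dist, n) {
  data.frame(
    age = stats::rlnorm(n, dist$age_meanlog, dist$age_sdlog),
    body_weight = stats::rlnorm(n, dist$weight_meanlog, dist$weight_sdlog),
    sex = stats::rbinom(n, 1, dist$p_female),
    csDMARD = stats::rbinom(n, 1, dist$p_csdmard))
}

#' Longitudinal popPK study dataset
#'
#' Container for per-subject dose events, concentration observations and
#' covariates; the unit of estimation. Observations with `mdv = 1` (missing
#' dependent variable, including drug-naive baseline samples) are recorded
#' but excluded from the likelihood.
#'
#' @param subjects data.frame: `id`, `age`, `body_weight`, `sex`, `csDMARD`
#' @param doses data.frame: `id`, `time` (h), `amt` (mg)
#' @param obs data.frame: `id`, `time` (h), `dv` (mg/L), `mdv` (0/1)
#' @return an object of class `study_dataset`
#' @export
study_dataset <- function(subjects, doses, obs) {
  need <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      stop_input(what, " must have columns ", paste(cols, collapse = ", "))
  need(subjects, c("id", "age", "body_weight", "sex", "csDMARD"), "subjects")
  need(doses, c("id", "time", "amt"), "doses")
  need(obs, c("id", "time", "dv", "mdv"), "obs")
  if (anyDuplicated(subjects$id)) stop_input("subject ids must be unique")
  if (nrow(doses) && any(doses$amt <= 0)) stop_input("dose amounts must be > 0")
  if (any(c(doses$time, obs$time) < 0)) stop_input("event times must be >= 0")
  if (!all(c(doses$id, obs$id) %in% subjects$id))
    stop_input("dose/observation ids must appear in subjects")
  structure(list(subjects = subjects, doses = doses, obs = obs),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Study dataset: %d subjects, %d dose events, %d observations (%d in likelihood)\n",
              nrow(x$subjects), nrow(x$doses), nrow(x$obs), sum(x$obs$mdv == 0)))
  invisible(x)
}

#' Generate a study-like synthetic dataset
#'
#' Forward-simulates the hierarchical model through the sampling design:
#' individual parameters are drawn from the population model, noiseless
#' profiles computed by superposition, and the residual-error model applied.
#' Baseline (t = 0, pre-treatment) samples have true concentration 0 and are
#' recorded with `mdv = 1` (excluded from the likelihood by default, as they
#' carry no PK information for a drug-naive cohort).
#'
#' @param model a [population_model()]
#' @param design a [sampling_design()]
#' @param regimen a [dosing_regimen()]
#' @param n_subjects number of subjects
#' @param covariates a [covariate_distribution()], a data.frame with one row
#'   per subject, or `NULL` to reuse the built-in distribution matching
#'   `model$name` (falling back to the adalimumab arm)
#' @param n_dropout number of scheduled post-baseline samples dropped
#'   uniformly at random across the dataset (emulates missed samples)
#' @param seed optional integer seed
#' @return a [study_dataset()]; the drawn random effects are attached as
#'   attribute `"etas"` and the noiseless truths as column `true` of `obs`
#' @examples
#' ds <- generate_dataset(model_etanercept(), builtin_design("etanercept"),
#'                        dosing_regimen(50, 168), n_subjects = 6,
#'                        n_dropout = 2, seed = 1)
#' ds
#' @export
generate_dataset <- function(model, design, regimen, n_subjects,
                             covariates = NULL, n_dropout = 0, seed = NULL) {
  stopifnot(inherits(model, "population_model"),
            inherits(design, "sampling_design"),
            inherits(regimen, "dosing_regimen"), n_subjects >= 1)
  horizon <- regimen$start_time +
    (min(regimen$n_doses, .Machine$double.xmax)) * regimen$interval
  if (is.finite(regimen$n_doses) && max(design$times) > horizon)
    warning("design requires samples beyond the dosing horizon", call. = FALSE)
  with_seed(seed, {
    covs <- if (is.null(covariates)) {
      arm <- if (identical(model$name, "etanercept biosimilar")) "etanercept" else "adalimumab"
      draw_covariates(builtin_covariates(arm), n_subjects)
    } else if (inherits(covariates, "covariate_distribution")) {
      draw_covariates(covariates, n_subjects)
    } else {
      stopifnot(nrow(covariates) == n_subjects)
      covariates
    }
    etas <- draw_etas(model, n_subjects)
    P <- individual_parameter_matrix(model, covs, etas)
    subjects <- cbind(id = seq_len(n_subjects), covs)
    tobs <- design$times
    obs <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      p <- pk_params(CL = P[i, "CL"], VD = P[i, "VD"], ka = P[i, "ka"],
                     Q = if (is_twocpt(model$typical)) P[i, "Q"],
                     VP = if (is_twocpt(model$typical)) P[i, "VP"])
      truth <- conc_profile(p, regimen, tobs)
      truth[tobs == 0] <- 0  # pre-treatment baseline
      data.frame(id = i, time = tobs, true = truth,
                 mdv = as.integer(tobs == 0))
    }))
    obs$dv <- observe_conc(obs$true, model$error_model)
    obs$dv[obs$time == 0] <- 0  # drug-naive baseline reads blank
    if (n_dropout > 0) {
      cand <- which(obs$time > 0)
      if (n_dropout > length(cand)) stop_input("n_dropout exceeds scheduled samples")
      obs <- obs[-sample(cand, n_dropout), , drop = FALSE]
    }
    td <- dose_times(regimen, max(tobs))
    doses <- data.frame(id = rep(seq_len(n_subjects), each = length(td)),
                        time = rep(td, n_subjects),
                        amt = regimen$dose_amount)
    ds <- study_dataset(subjects, doses,
                        obs[, c("id", "time", "dv", "mdv", "true")])
    attr(ds, "etas") <- etas
    ds
  })
}

NM_COLS <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "AGE", "WT", "SEX", "CSDMARD")

#' Read and write datasets in a NONMEM-style CSV dialect
#'
#' Columns, in order: `ID`, `TIME` (h), `AMT` (mg; empty for observations),
#' `DV` (mg/L; empty for doses), `EVID` (1 dose, 0 observation), `MDV`,
#' `AGE`, `WT`, `SEX`, `CSDMARD`. At a shared nominal time the observation
#' row precedes the dose row (trough convention). `write_dataset` followed by
#' `read_dataset` is the identity on valid datasets (up to the `true` column,
#' which only generated datasets carry).
#'
#' @param dataset a [study_dataset()]
#' @param path file path
#' @return `read_dataset` returns a [study_dataset()]
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  ob <- dataset$obs
  do <- dataset$doses
  rows <- rbind(
    data.frame(ID = ob$id, TIME = ob$time, AMT = rep(NA_real_, nrow(ob)),
               DV = ob$dv, EVID = rep(0L, nrow(ob)), MDV = ob$mdv,
               ord = rep(0, nrow(ob))),
    data.frame(ID = do$id, TIME = do$time, AMT = do$amt,
               DV = rep(NA_real_, nrow(do)), EVID = rep(1L, nrow(do)),
               MDV = rep(1L, nrow(do)), ord = rep(1, nrow(do))))
  rows <- rows[order(rows$ID, rows$TIME, rows$ord), ]
  sub <- dataset$subjects[match(rows$ID, dataset$subjects$id), ]
  rows$AGE <- sub$age; rows$WT <- sub$body_weight
  rows$SEX <- sub$sex; rows$CSDMARD <- sub$csDMARD
  utils::write.csv(rows[, NM_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(NM_COLS, names(raw))
  if (length(missing_cols))
    stop_input("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  bad_evid <- which(!raw$EVID %in% c(0L, 1L))
  if (length(bad_evid))
    stop_input("unknown EVID code at row ", bad_evid[1])
  bad_amt <- which(raw$EVID == 1L & (is.na(raw$AMT) | raw$AMT <= 0))
  if (length(bad_amt))
    stop_input("dose row with missing or non-positive AMT at row ", bad_amt[1])
  for (id in unique(raw$ID)) {
    tt <- raw$TIME[raw$ID == id]
    if (is.unsorted(tt))
      stop_input("non-monotone times within subject ", id, " at row ",
                 which(raw$ID == id)[which(diff(tt) < 0)[1] + 1])
  }
  first <- !duplicated(raw$ID)
  subjects <- data.frame(id = raw$ID[first], age = raw$AGE[first],
                         body_weight = raw$WT[first], sex = raw$SEX[first],
                         csDMARD = raw$CSDMARD[first])
  is_obs <- raw$EVID == 0L
  obs <- data.frame(id = raw$ID[is_obs], time = raw$TIME[is_obs],
                    dv = raw$DV[is_obs], mdv = raw$MDV[is_obs])
  doses <- data.frame(id = raw$ID[!is_obs], time = raw$TIME[!is_obs],
                      amt = raw$AMT[!is_obs])
  study_dataset(subjects, doses, obs)
}
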