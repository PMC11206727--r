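test_that("marginal deviance matches a 31-node quadrature oracle", {
  m <- model_etanercept()
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 2,
                         seed = 61)
  expect_lt(abs(minus2ll(m, ds) - agq_oracle_m2ll(m, ds)), 0.1)
  # and at a second, perturbed parameter point
  m2 <- m
  m2$typical <- pk_params(CL = 0.05, VD = 7, ka = 0.0396)
  m2$bsv <- c(CL = 0.3)
  expect_lt(abs(minus2ll(m2, ds) - agq_oracle_m2ll(m2, ds)), 0.1)
})

test_that("rich noiseless data identify CL and VD to < 0.1%", {
  truth <- pk_params(CL = 0.05, VD = 9, ka = 0.0396)
  ds <- rich_noiseless_dataset(truth)
  spec <- population_model(
    typical = pk_params(CL = 0.03, VD = 6, ka = 0.0396),
    error_model = residual_error("additive", sigma_add = 1e-4),
    fixed = c("ka", "sigma_add"))
  fit <- suppressWarnings(fit_poppk(ds, spec, se = FALSE))
  expect_equal(fit$estimates$typical$CL, truth$CL, tolerance = 1e-3)
  expect_equal(fit$estimates$typical$VD, truth$VD, tolerance = 1e-3)
  expect_identical(fit$estimates$typical$ka, 0.0396)  # fixed, bit-identical
})

test_that("the noiseless objective is minimised at the generating values", {
  truth <- pk_params(CL = 0.05, VD = 9, ka = 0.0396)
  ds <- rich_noiseless_dataset(truth)
  spec0 <- population_model(truth,
                            error_model = residual_error("additive",
                                                         sigma_add = 1e-4),
                            fixed = c("ka", "sigma_add"))
  base <- minus2ll(spec0, ds)
  set.seed(62)
  for (i in 1:20) {
    sp <- spec0
    sp$typical <- pk_params(CL = truth$CL * exp(runif(1, -0.3, 0.3)),
                            VD = truth$VD * exp(runif(1, -0.3, 0.3)),
                            ka = truth$ka)
    expect_gte(minus2ll(sp, ds), base - 1e-6)
  }
})

test_that("parameter recovery works on a moderate synthetic cohort", {
  m <- model_etanercept()
  ds <- generate_dataset(m, design_recovery("etanercept"), etn_regimen(), 60,
                         seed = 63)
  fit <- suppressWarnings(fit_poppk(ds, m))
  tab <- fit$parameters
  cl <- tab[tab$parameter == "CL", ]
  expect_lt(abs(cl$estimate - 0.0404), 3 * cl$se)
  expect_equal(tab$rse_percent, 100 * tab$se / abs(tab$estimate))
  expect_false("ka" %in% tab$parameter)        # fixed: no SE/RSE row
  expect_false("sigma_add" %in% tab$parameter)
  expect_identical(fit$estimates$typical$ka, 0.0396)
  expect_identical(fit$estimates$error_model$sigma_add, 1e-4)
  expect_equal(fit$aic, fit$minus2LL + 2 * fit$n_estimated)
  expect_lte(fit$convergence$iterations, 500)
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  m <- model_etanercept()
  ses <- vapply(c(25, 100, 400), function(n) {
    ds <- generate_dataset(m, design_recovery("etanercept"), etn_regimen(),
                           n, seed = 64)
    fit <- suppressWarnings(fit_poppk(ds, m))
    fit$parameters$se[fit$parameters$parameter == "CL"]
  }, 0)
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.25)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.25)
})

test_that("fits are invariant to subject ordering and row shuffles", {
  m <- model_etanercept()
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 8,
                         seed = 65)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  ds2 <- study_dataset(
    subjects = ds$subjects[perm, ],
    doses = ds$doses[sample(nrow(ds$doses)), ],
    obs = ds$obs[order(ds$obs$id, ds$obs$time), c("id", "time", "dv", "mdv")])
  set.seed(66)
  expect_equal(minus2ll(m, ds2), minus2ll(m, ds), tolerance = 1e-8)
  f1 <- suppressWarnings(fit_poppk(ds, m, se = FALSE))
  f2 <- suppressWarnings(fit_poppk(ds2, m, se = FALSE))
  expect_equal(f2$estimates$typical$CL, f1$estimates$typical$CL,
               tolerance = 1e-5)
  expect_equal(f2$minus2LL, f1$minus2LL, tolerance = 1e-6)
})

test_that("model comparison implements the LRT contract", {
  m <- model_etanercept()
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 12,
                         seed = 67)
  base <- suppressWarnings(fit_poppk(ds, m, se = FALSE))
  self <- compare_models(base, base)
  expect_equal(self$delta_aic, 0)
  expect_equal(self$lrt_stat, 0, tolerance = 1e-8)
  expect_equal(self$p_value, 1)
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05004352,
               tolerance = 1e-6)
  m_cov <- m
  m_cov$covariate_effects <- list(
    covariate_effect("CL", "body_weight", 0,
                     reference = median(ds$subjects$body_weight)))
  full <- suppressWarnings(fit_poppk(ds, m_cov, se = FALSE))
  cmp <- compare_models(base, full)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$lrt_stat, -1e-6)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  # non-nested pair: different covariates
  m_cov2 <- m
  m_cov2$covariate_effects <- list(covariate_effect("CL", "sex", 0))
  alt <- suppressWarnings(fit_poppk(ds, m_cov2, se = FALSE))
  expect_error(compare_models(full, alt), "not nested")
  expect_named(compare_models(full, alt, lrt = FALSE),
               c("aic_a", "aic_b", "delta_aic"))
})

test_that("an uninformative extra parameter costs about 2 AIC on average", {
  m <- model_etanercept()
  deltas <- vapply(1:25, function(b) {
    ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(),
                           10, seed = 700 + b)
    base <- suppressWarnings(fit_poppk(ds, m, se = FALSE))
    m_cov <- m
    m_cov$covariate_effects <- list(
      covariate_effect("CL", "age", 0,
                       reference = median(ds$subjects$age)))
    full <- suppressWarnings(fit_poppk(ds, m_cov, se = FALSE))
    full$aic - base$aic
  }, 0)
  expect_gt(mean(deltas), 0)
  expect_lt(mean(deltas), 4)
})

test_that("degenerate configurations are rejected", {
  m <- model_etanercept()
  m$fixed <- c("CL", "VD", "ka", "omega_CL", "sigma_add", "sigma_prop")
  ds <- generate_dataset(model_etanercept(), builtin_design("etanercept"),
                         etn_regimen(), 2, seed = 68)
  expect_error(fit_poppk(ds, m), "all parameters fixed")
  empty <- ds
  empty$obs$mdv <- 1
  expect_error(fit_poppk(empty, model_etanercept()),
               "no likelihood observations")
})

test_that("an empty candidate list returns the base model unchanged", {
  m <- model_etanercept()
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 6,
                         seed = 69)
  sc <- covariate_scan(ds, m, candidates = list())
  expect_equal(sc$selected, "base")
  expect_null(sc$table)
})
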