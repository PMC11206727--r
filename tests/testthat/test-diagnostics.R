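test_that("PRED equals IPRED when the model has no random effects", {
  m <- population_model(pk_params(CL = 0.04, VD = 8, ka = 0.04),
                        error_model = residual_error("additive",
                                                     sigma_add = 0.5),
                        fixed = "ka")
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 5,
                         seed = 81)
  ev <- evaluate_model(m, ds)
  pr <- predictions(ev)
  expect_equal(pr$PRED, pr$IPRED)
})

test_that("a noiseless single-subject fit reproduces the data", {
  truth <- pk_params(CL = 0.05, VD = 9, ka = 0.0396)
  ds <- rich_noiseless_dataset(truth)
  spec <- population_model(pk_params(CL = 0.03, VD = 6, ka = 0.0396),
                           error_model = residual_error("additive",
                                                        sigma_add = 1e-4),
                           fixed = c("ka", "sigma_add"))
  fit <- suppressWarnings(fit_poppk(ds, spec, se = FALSE))
  pr <- predictions(fit)
  expect_equal(pr$IPRED, pr$DV, tolerance = 1e-3)
})

test_that("IWRES reduces to its defining formula", {
  m <- model_etanercept()
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 6,
                         seed = 82)
  ev <- evaluate_model(m, ds)
  pr <- predictions(ev)
  iw <- iwres(ev)
  em <- m$error_model
  expect_equal(iw, (pr$DV - pr$IPRED) /
                 sqrt(pr$IPRED^2 * em$sigma_prop^2 + em$sigma_add^2))
  # additive-only model: IWRES = (DV - IPRED) / sigma_add
  m_add <- population_model(m$typical, bsv = m$bsv,
                            error_model = residual_error("additive",
                                                         sigma_add = 0.7),
                            fixed = "ka")
  ds2 <- generate_dataset(m_add, builtin_design("etanercept"), etn_regimen(),
                          4, seed = 83)
  ev2 <- evaluate_model(m_add, ds2)
  pr2 <- predictions(ev2)
  expect_equal(iwres(ev2), (pr2$DV - pr2$IPRED) / 0.7)
  m_zero <- population_model(m$typical,
                             error_model = residual_error("combined", 0, 0),
                             fixed = "ka")
  ev2$estimates <- m_zero
  expect_error(iwres(ev2), "zero")
})

test_that("IWRES and PWRES are calibrated under the true model", {
  m <- model_etanercept()
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 100,
                         seed = 84)
  ev <- evaluate_model(m, ds)
  iw <- iwres(ev)
  expect_gt(length(iw), 500)
  expect_gt(mean(iw), -0.1); expect_lt(mean(iw), 0.1)
  expect_gt(sd(iw), 0.9); expect_lt(sd(iw), 1.1)
  pw <- pwres(ev, n_sim = 1000, seed = 85)
  expect_gt(mean(pw), -0.1); expect_lt(mean(pw), 0.1)
  expect_gt(sd(pw), 0.9); expect_lt(sd(pw), 1.1)
})

test_that("PWRES degenerates to the additive z-score without BSV", {
  m <- population_model(pk_params(CL = 0.04, VD = 8, ka = 0.04),
                        error_model = residual_error("additive",
                                                     sigma_add = 0.5),
                        fixed = "ka")
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 10,
                         seed = 86)
  ev <- evaluate_model(m, ds)
  pr <- predictions(ev)
  pw <- pwres(ev, n_sim = 2000, seed = 87)
  expect_lt(max(abs(pw - (pr$DV - pr$PRED) / 0.5)), 0.12)
  # Monte-Carlo stability: an independent replication moves each residual
  # by at most a few percent of a unit
  pw2 <- pwres(ev, n_sim = 2000, seed = 88)
  expect_lt(max(abs(pw2 - pw)), 0.15)
  expect_lt(median(abs(pw2 - pw)), 0.05)
  expect_error(pwres(ev, n_sim = 100, seed = 1), ">= 500")
})

test_that("NPDE is finite, deterministic in its seed, and rank-based", {
  m <- model_etanercept()
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 8,
                         seed = 89)
  ev <- evaluate_model(m, ds)
  np <- npde(ev, n_sim = 500, seed = 90)
  expect_true(all(is.finite(np)))
  expect_equal(npde(ev, n_sim = 500, seed = 90), np)
  expect_error(npde(ev, n_sim = 50, seed = 1), "resolve ranks")
  expect_error(npde(ev, n_sim = 500), "seed is required")
  # single observation per subject, additive-only: NPDE is the normal
  # quantile of the rank-based percentile, no decorrelation involved
  m1 <- population_model(pk_params(CL = 0.04, VD = 8, ka = 0.04),
                         bsv = c(CL = 0.3),
                         error_model = residual_error("additive",
                                                      sigma_add = 0.4),
                         fixed = "ka")
  d1 <- generate_dataset(m1, sampling_design(336), etn_regimen(), 12,
                         seed = 91)
  e1 <- evaluate_model(m1, d1)
  n_sim <- 500
  np1 <- npde(e1, n_sim = n_sim, seed = 92)
  Y <- withr::with_seed(92, {
    prep <- biosimpk:::prep_nlme(d1, m1)
    biosimpk:::simulate_obs_matrix(m1, prep, n_sim)
  })
  dv <- d1$obs$dv[d1$obs$mdv == 0]
  manual <- qnorm((rowSums((Y - rowMeans(Y)) / apply(Y, 1, sd) <
                             (dv - rowMeans(Y)) / apply(Y, 1, sd)) + 0.5) /
                    (n_sim + 1))
  expect_equal(np1, manual)
})

test_that("Shapiro-Wilk wrapper enforces its domain", {
  qs <- qnorm((seq_len(50) - 0.5) / 50)
  sw <- shapiro_wilk(qs)
  expect_gt(sw$p, 0.99)
  expect_true(sw$W > 0 && sw$W <= 1)
  set.seed(93)
  heavy <- rt(200, df = 1)
  expect_lt(shapiro_wilk(heavy)$p, 0.01)
  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
  expect_error(shapiro_wilk(c(1, 2)), "within")
  expect_error(shapiro_wilk(rnorm(5001)), "within")
})

test_that("NPDE detects a misspecified model", {
  m <- model_etanercept()
  wrong <- m
  wrong$typical <- pk_params(CL = m$typical$CL / 2, VD = m$typical$VD,
                             ka = m$typical$ka)
  rejections <- vapply(1:20, function(b) {
    ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(),
                           16, seed = 9300 + b)
    ev <- evaluate_model(wrong, ds)
    shapiro_wilk(npde(ev, n_sim = 400, seed = 9400 + b))$p < 0.05
  }, TRUE)
  expect_gt(mean(rejections), 0.5)
})

test_that("the assembled diagnostics table carries its normality verdict", {
  m <- model_etanercept()
  ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 10,
                         seed = 94)
  tab <- diagnostics_table(evaluate_model(m, ds), n_sim = 600, seed = 95)
  expect_true(all(c("PRED", "IPRED", "DV", "PWRES", "IWRES", "NPDE") %in%
                    names(tab)))
  expect_equal(nrow(tab), sum(ds$obs$mdv == 0))
  sw <- attr(tab, "npde_test")
  expect_true(is.logical(sw$reject_at_0.05))
})
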