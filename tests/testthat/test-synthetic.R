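test_that("built-in sampling designs match the study schedules", {
  ada <- builtin_design("adalimumab")
  expect_equal(ada$times, c(0, 1, 336, 672, 1008, 2016))
  etn <- builtin_design("etanercept")
  expect_length(etn$times, 7)
  expect_true(144 %in% etn$times)
  expect_error(builtin_design("infliximab"), "arg")
  d <- sampling_design(c(100, 5, 50))
  expect_equal(d$times, c(5, 50, 100))
  expect_error(sampling_design(c(-1, 5)), ">= 0")
})

test_that("generated datasets reproduce the study sample counts", {
  m <- model_adalimumab()
  ds <- generate_dataset(m, builtin_design("adalimumab"), ada_regimen(),
                         n_subjects = 10, seed = 21)
  expect_equal(nrow(ds$obs), 60)
  ds58 <- generate_dataset(m, builtin_design("adalimumab"), ada_regimen(),
                           n_subjects = 10, n_dropout = 2, seed = 21)
  expect_equal(nrow(ds58$obs), 58)
  base <- ds$obs[ds$obs$time == 0, ]
  expect_true(all(base$true == 0))
  expect_true(all(base$mdv == 1))
})

test_that("generation is seed-reproducible and degenerates correctly", {
  m <- model_etanercept()
  a <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 5,
                        seed = 9)
  b <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 5,
                        seed = 9)
  expect_equal(a$obs, b$obs)
  expect_equal(a$subjects, b$subjects)
  m0 <- m
  m0$bsv <- c(CL = 0)
  m0$error_model <- residual_error("combined", 0, 0)
  d0 <- generate_dataset(m0, builtin_design("etanercept"), etn_regimen(), 4,
                         seed = 2)
  profs <- split(d0$obs$dv, d0$obs$id)
  for (i in 2:4) expect_equal(profs[[i]], profs[[1]])
  expect_warning(
    generate_dataset(m, sampling_design(c(0, 5000)),
                     dosing_regimen(50, 168, n_doses = 2), 2, seed = 1),
    "beyond the dosing horizon")
})

test_that("cohort covariate draws match the configured medians", {
  cd <- builtin_covariates("adalimumab")
  set.seed(77)
  cv <- biosimpk:::draw_covariates(cd, 1e4)
  expect_equal(median(cv$body_weight), 85.5, tolerance = 0.02)
  expect_equal(median(cv$age), 50.5, tolerance = 0.02)
  expect_equal(mean(cv$sex), 0.9, tolerance = 0.02)
  expect_equal(mean(cv$csDMARD), 0.8, tolerance = 0.03)
})

test_that("dataset invariants hold across a seed sweep", {
  m <- model_etanercept()
  for (s in 1:100) {
    ds <- generate_dataset(m, builtin_design("etanercept"), etn_regimen(), 3,
                           n_dropout = 1, seed = s)
    expect_false(anyDuplicated(ds$subjects$id) > 0)
    expect_true(all(ds$doses$amt > 0))
    expect_true(all(ds$obs$time >= 0))
    expect_true(all(ds$obs$id %in% ds$subjects$id))
  }
})

test_that("simulated trough distribution brackets the typical trough", {
  m <- model_etanercept()
  draws <- sample_individuals(m, 1e4, seed = 55)
  troughs <- vapply(draws, function(p) conc_profile(p, etn_regimen(), 2016), 0)
  typ <- conc_profile(m$typical, etn_regimen(), 2016)
  qq <- quantile(troughs, c(0.05, 0.95))
  expect_gt(typ, qq[[1]])
  expect_lt(typ, qq[[2]])
})

test_that("NONMEM-style CSV round-trips a generated dataset", {
  m <- model_adalimumab()
  ds <- generate_dataset(m, builtin_design("adalimumab"), ada_regimen(), 16,
                         seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f)
  ds2 <- read_dataset(f)
  expect_equal(ds2$subjects, ds$subjects, ignore_attr = TRUE)
  expect_equal(ds2$doses[order(ds2$doses$id, ds2$doses$time), ],
               ds$doses[order(ds$doses$id, ds$doses$time), ],
               ignore_attr = TRUE)
  o1 <- ds$obs[order(ds$obs$id, ds$obs$time), c("id", "time", "dv", "mdv")]
  o2 <- ds2$obs[order(ds2$obs$id, ds2$obs$time), ]
  expect_equal(o2, o1, ignore_attr = TRUE)
})

test_that("the CSV parser reports malformed input with row positions", {
  ds <- study_dataset(
    subjects = data.frame(id = 1, age = 50, body_weight = 80, sex = 1,
                          csDMARD = 0),
    doses = data.frame(id = 1, time = 0, amt = 40),
    obs = data.frame(id = numeric(0), time = numeric(0), dv = numeric(0),
                     mdv = integer(0)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f)
  expect_s3_class(read_dataset(f), "study_dataset")
  raw <- read.csv(f)
  raw$AMT[1] <- -40
  write.csv(raw, f, row.names = FALSE, na = "")
  expect_error(read_dataset(f), "row 1")
  raw$AMT[1] <- 40
  raw$EVID[1] <- 3
  write.csv(raw, f, row.names = FALSE, na = "")
  expect_error(read_dataset(f), "EVID")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(ID = 1, TIME = 0), f2, row.names = FALSE)
  expect_error(read_dataset(f2), "missing mandatory column")
  raw2 <- data.frame(ID = c(1, 1), TIME = c(100, 50), AMT = c(NA, NA),
                     DV = c(1, 2), EVID = c(0, 0), MDV = c(0, 0),
                     AGE = 50, WT = 70, SEX = 1, CSDMARD = 0)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw2, f3, row.names = FALSE, na = "")
  expect_error(read_dataset(f3), "non-monotone times within subject 1 at row 2")
})
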