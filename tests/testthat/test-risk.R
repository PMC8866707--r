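make_coef_file <- function(intercepts = c(male = 0, female = 0),
                           age_coef = 0) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  blk <- function(sx) list(
    intercept = unname(intercepts[[sx]]),
    terms = list(list(covariate = "age", transform = "identity",
                      coefficient = age_coef)))
  yaml::write_yaml(list(label = "test", model_form = "revised-logistic",
                        clinical_use = FALSE,
                        sexes = list(male = blk("male"),
                                     female = blk("female"))),
                   path)
  path
}

risk_profiles <- function(n = 10, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    age = runif(n, 30, 70), sex = sample(c("male", "female"), n, TRUE),
    systolic_bp = runif(n, 100, 170), bp_treated = rbinom(n, 1, 0.3),
    diabetes = rbinom(n, 1, 0.1), smoker = rbinom(n, 1, 0.2),
    tc = runif(n, 150, 260), hdl = runif(n, 35, 80)))
}

test_that("the logistic link reproduces closed-form risks", {
  prof <- risk_profiles(5)
  zero <- read_pce_coefficients(make_coef_file(c(male = 0, female = 0)))
  expect_equal(pce_risk(prof, zero)$pce_risk, rep(0.5, 5))

  neg10 <- read_pce_coefficients(make_coef_file(c(male = -10, female = -10)))
  expect_equal(pce_risk(prof, neg10)$pce_risk,
               rep(plogis(-10), 5), tolerance = 1e-12)
  expect_equal(plogis(-10), 4.539787e-5, tolerance = 1e-6)
})

test_that("risk increases strictly with systolic pressure under a positive coefficient", {
  coefs <- read_pce_coefficients(default_pce_path())
  base <- tibble::tibble(age = 55, sex = "male", systolic_bp = seq(100, 180, 5),
                         bp_treated = 1, diabetes = 0, smoker = 0,
                         tc = 200, hdl = 50)
  r <- pce_risk(base, coefs)$pce_risk
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("the shipped synthetic coefficient file validates and is flagged non-clinical", {
  coefs <- read_pce_coefficients(default_pce_path())
  expect_s3_class(coefs, "pce_coefficients")
  expect_false(coefs$clinical_use)
  cohort <- generate_cohort(cohort_params(n = 2000, seed = 17))
  r <- pce_risk(cohort, coefs)
  expect_true(all(r$pce_risk >= 0 & r$pce_risk <= 1))
  # plausible population spread, increasing with age on average
  expect_gt(cor(r$age, r$pce_risk), 0.3)
})

test_that("risk is record-order invariant and blind to estimated LDL", {
  coefs <- read_pce_coefficients(default_pce_path())
  prof <- risk_profiles(200, seed = 3)
  perm <- withr::with_seed(4, sample.int(200))
  expect_equal(pce_risk(prof[perm, ], coefs)$pce_risk,
               pce_risk(prof, coefs)$pce_risk[perm])
  # adding/garbling LDL estimate columns cannot change the risk
  prof2 <- dplyr::mutate(prof, ldl_measured = 1, ldl_friedewald = -99)
  expect_identical(pce_risk(prof2, coefs)$pce_risk,
                   pce_risk(prof, coefs)$pce_risk)
})

test_that("malformed coefficient files are rejected with explicit errors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(model_form = "revised-logistic",
                        sexes = list(male = list(intercept = 0,
                                                 terms = list(list(
                                                   covariate = "age",
                                                   transform = "cubic",
                                                   coefficient = 1))),
                                     female = list(intercept = 0,
                                                   terms = list(list(
                                                     covariate = "age",
                                                     transform = "log",
                                                     coefficient = 1))))),
                   path)
  expect_error(read_pce_coefficients(path), "transform",
               class = "ldlbench_config_error")
  expect_error(read_pce_coefficients(withr::local_tempfile()),
               "not found", class = "ldlbench_config_error")

  coefs <- read_pce_coefficients(default_pce_path())
  prof <- risk_profiles(5)
  expect_error(pce_risk(prof[, -1], coefs), "age",
               class = "ldlbench_validation_error")
})

test_that("equal-frequency bins are balanced with stable tie handling", {
  withr::with_seed(10, x100 <- runif(100))
  b100 <- quantile_bins(x100, 20)
  expect_equal(as.integer(table(b100)), rep(5L, 20))

  withr::with_seed(11, x101 <- runif(101))
  b101 <- quantile_bins(x101, 20)
  sizes <- as.integer(table(b101))
  expect_true(all(sizes %in% c(5L, 6L)))
  expect_equal(sum(sizes == 6L), 1L)

  # all-identical risks: stable record-order assignment, sizes differ <= 1
  bt <- quantile_bins(rep(0.2, 47), 20)
  expect_true(max(table(bt)) - min(table(bt)) <= 1)
  expect_equal(bt[1:7], c(1L, 1L, 1L, 2L, 2L, 2L, 3L))

  # bin boundaries non-decreasing; concatenating bins recovers the cohort
  expect_true(all(diff(tapply(x101, b101, max)) >= 0))
  expect_equal(sort(unlist(split(x101, b101))), sort(x101), ignore_attr = TRUE)

  expect_error(quantile_bins(runif(10), 20), "fewer bins",
               class = "ldlbench_validation_error")
})

test_that("risk-vigintile grouped RMSE pools back to the global RMSE", {
  coefs <- read_pce_coefficients(default_pce_path())
  cohort <- generate_cohort(cohort_params(n = 4000, seed = 23))
  cohort <- estimate_friedewald(cohort)
  cohort <- add_risk_bins(pce_risk(cohort, coefs))
  tbl <- grouped_rmse(cohort$ldl_friedewald, cohort$ldl_measured,
                      cohort$risk_bin)
  expect_equal(nrow(tbl), 20)
  expect_true(max(tbl$n) - min(tbl$n) <= 1)
  pooled <- sqrt(sum(tbl$n * tbl$rmse^2) / sum(tbl$n))
  expect_equal(pooled, ldl_rmse(cohort$ldl_friedewald, cohort$ldl_measured),
               tolerance = 1e-12)
})
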