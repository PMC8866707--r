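test_that("cohort generation is a pure function of parameters and seed", {
  p <- cohort_params(n = 2000, seed = 101)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  attr(a, "params") <- NULL; attr(b, "params") <- NULL
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_params(n = 2000, seed = 102))
  expect_false(identical(a$tc, c2$tc))
})

test_that("generated cohorts reproduce the configured population summaries", {
  cohort <- generate_cohort(cohort_params(n = 50000, seed = 107))
  expect_equal(mean(cohort$tc), 198.3, tolerance = 0.5 / 198.3)
  expect_lt(abs(median(cohort$tg) - 105), 2)
  expect_lt(abs(mean(cohort$ldl_measured) - 124.8), 2)
  expect_lt(abs(sd(cohort$ldl_measured) - 32.4), 2)
  # structural validity
  expect_true(all(cohort$hdl < cohort$tc))
  expect_true(all(cohort$ldl_true > 0))
  expect_identical(cohort$non_hdl, cohort$tc - cohort$hdl)
  expect_true(all(cohort$vldl_factor >= 3 & cohort$vldl_factor <= 12))
  expect_true(all(cohort$age >= 20 & cohort$age <= 79))
})

test_that("a constant factor of 5 with zero noise makes Friedewald the generative inverse", {
  cohort <- generate_cohort(cohort_params(n = 1000, seed = 109,
                                          factor_model = factor_model_constant(5),
                                          assay_noise_sd = 0))
  est <- estimate_friedewald(cohort)
  expect_equal(est$ldl_friedewald, cohort$ldl_measured, tolerance = 1e-12)
})

test_that("the VLDL divisor models evaluate and clamp as documented", {
  expect_equal(eval_vldl_factor(factor_model_constant(5), c(50, 300), c(100, 100)),
               c(5, 5))
  expect_equal(eval_vldl_factor(factor_model_step(150, 4, 8),
                                c(100, 150, 200), rep(130, 3)),
               c(4, 8, 8))
  f <- eval_vldl_factor(factor_model_logistic(), seq(10, 1000, 10), rep(140, 100))
  expect_true(all(f >= 3 & f <= 12))
  expect_true(all(diff(f) >= 0))  # ramps upward in TG
  # plain functions are accepted and clamped
  expect_equal(eval_vldl_factor(function(tg, nh) tg * 0 + 99, 1:3, 1:3),
               rep(12, 3))
})

test_that("sequential exclusions remove blocks in the printed order and sum correctly", {
  man <- exclusion_manifest(1000, demographics = 50, lifestyle = 10,
                            laboratory = 30, seed = 3)
  res <- apply_exclusions(man)
  expect_equal(res$counts$n, c(50, 10, 30, 910))
  expect_equal(sum(res$counts$n[1:3]) + nrow(res$cohort), res$n_input)

  # no missingness -> identity with zero exclusions
  clean <- generate_cohort(cohort_params(n = 500, seed = 5))
  res2 <- apply_exclusions(clean)
  expect_equal(res2$counts$n, c(0, 0, 0, 500))
  expect_identical(res2$cohort, clean)

  # a record missing two blocks is counted at the first step only
  multi <- tibble::tibble(miss_demographics = c(TRUE, FALSE),
                          miss_lifestyle = c(TRUE, FALSE),
                          miss_laboratory = c(FALSE, FALSE))
  res3 <- apply_exclusions(multi)
  expect_equal(res3$counts$n, c(1, 0, 0, 1))

  expect_equal(tidy(res), res$counts)
})

test_that("missingness rates drive the generated flags", {
  cohort <- generate_cohort(cohort_params(
    n = 20000, seed = 11,
    missingness = c(demographics = 0.06, lifestyle = 0.001,
                    laboratory = 0.04)))
  expect_equal(mean(cohort$miss_demographics), 0.06, tolerance = 0.2)
  res <- apply_exclusions(cohort)
  expect_equal(sum(res$counts$n[1:3]) + nrow(res$cohort), 20000)
})

test_that("cohort splitting follows the rounded-fraction size rule", {
  big <- tibble::tibble(id = seq_len(129930))
  sp <- split_cohort(big, c(0.7, 0.3), seed = 1)
  expect_equal(sum(sp$partition == "derivation"), 90951)
  expect_equal(sum(sp$partition == "internal"), 38979)
  # disjoint and exhaustive by construction; same seed -> same membership
  sp2 <- split_cohort(big, c(0.7, 0.3), seed = 1)
  expect_identical(sp$partition, sp2$partition)
  expect_false(identical(split_cohort(big, c(0.7, 0.3), seed = 2)$partition,
                         sp$partition))
  # identity partition
  one <- split_cohort(tibble::tibble(x = 1:10), 1.0)
  expect_equal(as.character(unique(one$partition)), "partition1")
  expect_error(split_cohort(big, c(0.7, 0.2)),
               class = "ldlbench_validation_error")
  expect_error(split_cohort(big, c(1.2, -0.2)),
               class = "ldlbench_validation_error")
})

test_that("KOICA-flavoured preset shifts the population as configured", {
  ext <- generate_cohort(koica_params(n = 30000, seed = 13))
  expect_equal(mean(ext$age), 54.0, tolerance = 0.02)
  expect_equal(mean(ext$sex == "male"), 0.762, tolerance = 0.02)
  expect_lt(abs(median(ext$tg) - 113), 2)
})

test_that("Friedewald error grows with TG while the derived table stays flat", {
  cohort <- generate_cohort(cohort_params(n = 20000, seed = 119))
  holdout <- generate_cohort(cohort_params(n = 20000, seed = 120))
  tab <- suppressMessages(derive_strata_table(cohort))
  est <- estimate_martin(estimate_friedewald(holdout), tab)
  labels <- categorize(est$tg, tg_scheme())
  fw <- grouped_rmse(est$ldl_friedewald, est$ldl_measured, labels)
  ma <- grouped_rmse(est$ldl_martin, est$ldl_measured, labels)
  # Friedewald RMSE rises steeply across TG strata; the adjustable-factor
  # table keeps the profile nearly flat
  expect_gt(max(fw$rmse) / min(fw$rmse), 3)
  expect_lt(max(ma$rmse) / min(ma$rmse), 2)
  high <- as.integer(fw$group) >= 4
  expect_true(all(fw$rmse[high] > ma$rmse[high]))
})

test_that("cohort files round-trip through the delimited format", {
  cohort <- generate_cohort(cohort_params(n = 300, seed = 15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$tc, cohort$tc, tolerance = 1e-12)
  expect_equal(back$ldl_measured, cohort$ldl_measured, tolerance = 1e-12)
  expect_equal(nrow(back), 300)
})
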