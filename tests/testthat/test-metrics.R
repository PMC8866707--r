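test_that("bias statistics match hand calculations", {
  m <- rep(100, 4)
  b <- ldl_bias(m + c(2, -2, 2, -2), m)
  expect_equal(b$bias_mean, 0)
  expect_equal(b$bias_t, 0)

  b2 <- ldl_bias(rep(0, 5) + 1:5, rep(0, 5))
  expect_equal(b2$bias_mean, 3)
  expect_equal(b2$bias_t, 4.2426, tolerance = 0.001 / 4.2426)
  expect_equal(b2$bias_p, 2 * pt(-4.242640687, df = 4))

  ident <- ldl_bias(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$bias_mean, 0)
  expect_equal(ident$bias_t, 0)
  expect_equal(ident$bias_p, 1)

  expect_error(ldl_bias(1, 1), class = "ldlbench_validation_error")
})

test_that("rmse matches its closed forms", {
  expect_equal(ldl_rmse(c(103, 104), c(100, 100)), sqrt(12.5))
  expect_equal(ldl_rmse(c(103, 104), c(100, 100)), 3.5355, tolerance = 1e-3)
  expect_equal(ldl_rmse(1:10, 1:10), 0)
  expect_equal(ldl_rmse(100 - 7, 100), 7)  # single record: |e|
  expect_error(ldl_rmse(numeric(0), numeric(0)),
               class = "ldlbench_validation_error")
})

test_that("Pn accuracy counts tolerance bands with closed boundaries", {
  measured <- c(100, 100, 100, 100)
  est <- c(105, 95, 112, 88)
  expect_equal(pn_accuracy(est, measured, 10), 0.5)
  expect_equal(pn_accuracy(est, measured, 15), 1.0)
  # boundary counts as inside
  expect_equal(pn_accuracy(110, 100, 10), 1)
  expect_error(pn_accuracy(c(1, 2), c(100, 0), 10),
               class = "ldlbench_validation_error")

  # brute-force per-record loop oracle on random pairs
  withr::with_seed(5, {
    m <- runif(10000, 40, 250)
    e <- m + rnorm(10000, 0, 20)
  })
  for (np in c(10, 15, 20)) {
    oracle <- mean(vapply(seq_along(m), function(i) {
      abs(e[i] - m[i]) <= np / 100 * m[i]
    }, logical(1)))
    expect_equal(pn_accuracy(e, m, np), oracle)
  }
})

test_that("Pn is monotone in the band width on random data", {
  for (s in 1:25) {
    withr::with_seed(s, {
      m <- runif(200, 30, 260)
      e <- m + rnorm(200, 0, 25)
    })
    p <- c(pn_accuracy(e, m, 10), pn_accuracy(e, m, 15), pn_accuracy(e, m, 20))
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("concordance counts category agreement, leaving empty bins undefined", {
  out <- concordance(c(108, 95, 125), c(105, 110, 120))
  row <- out[out$category == "[100,130)", ]
  expect_equal(row$n_measured, 3)
  expect_equal(row$concordance, 2 / 3)
  # empty measured categories are NA, not zero
  expect_true(is.na(out$concordance[out$category == ">=190"]))

  # identity -> concordance 1 in every occupied category
  withr::with_seed(2, x <- runif(500, 20, 260))
  ident <- concordance(x, x)
  expect_true(all(ident$concordance[ident$n_measured > 0] == 1))
  expect_equal(attr(ident, "overall"), 1)
})

test_that("concordance equals a set-intersection oracle on random data", {
  withr::with_seed(13, {
    m <- runif(2000, 30, 250)
    e <- m + rnorm(2000, 0, 25)
  })
  for (scheme in list(ldl_scheme(), tg_scheme(), nonhdl_scheme())) {
    got <- concordance(e, m, scheme)
    breaks <- scheme$breaks
    upper <- c(breaks[-1], Inf)
    lower <- c(-Inf, breaks[-1])  # lowest bin absorbs anything below it
    for (b in seq_along(breaks)) {
      A <- which(m >= lower[b] & m < upper[b])
      B <- which(e >= lower[b] & e < upper[b])
      expected <- if (length(A) == 0) NA_real_ else
        length(intersect(A, B)) / length(A)
      expect_equal(got$concordance[b], expected)
    }
  }
  # invariant to record order
  perm <- withr::with_seed(3, sample.int(2000))
  expect_equal(concordance(e[perm], m[perm])$concordance,
               concordance(e, m)$concordance)
})

test_that("grouped RMSE matches per-group closed forms and pools to the global value", {
  est <- c(103, 104, 50, 50)
  meas <- c(100, 100, 50, 50)
  g <- c("a", "a", "b", "b")
  out <- grouped_rmse(est, meas, g)
  expect_equal(out$rmse, c(sqrt(12.5), 0))
  expect_equal(out$n, c(2L, 2L))

  # single group equals the global rmse
  one <- grouped_rmse(est, meas, rep("x", 4))
  expect_equal(one$rmse, ldl_rmse(est, meas))

  # random labels: per-group loop oracle + pooled identity
  withr::with_seed(7, {
    m <- runif(3000, 50, 200)
    e <- m + rnorm(3000, 0, 15)
    lab <- sample(letters[1:6], 3000, replace = TRUE)
  })
  tbl <- grouped_rmse(e, m, lab)
  for (i in seq_len(nrow(tbl))) {
    idx <- lab == tbl$group[i]
    expect_equal(tbl$rmse[i], sqrt(mean((e[idx] - m[idx])^2)))
  }
  pooled <- sqrt(sum(tbl$n * tbl$rmse^2) / sum(tbl$n))
  expect_equal(pooled, ldl_rmse(e, m), tolerance = 1e-12)

  # empty factor levels are omitted with a log line
  laf <- factor(lab, levels = c(letters[1:6], "zz"))
  expect_message(grouped_rmse(e, m, laf), "empty")
})

test_that("rmse^2 decomposes into squared bias plus population error variance", {
  for (s in 1:10) {
    withr::with_seed(s, {
      m <- runif(400, 50, 220)
      e <- m + rnorm(400, 3, 12)
    })
    err <- e - m
    rmse2 <- ldl_rmse(e, m)^2
    decomp <- mean(err)^2 + mean((err - mean(err))^2)
    expect_equal(rmse2, decomp, tolerance = 1e-9)
  }
})

test_that("metric_report assembles the full index set per method", {
  cohort <- generate_cohort(cohort_params(n = 3000, seed = 91))
  cohort <- estimate_friedewald(estimate_sampson_nih(cohort))
  rep <- metric_report(cohort, c(Friedewald = "ldl_friedewald",
                                 NIH = "ldl_sampson"))
  expect_equal(rep$method, c("Friedewald", "NIH"))
  expect_true(all(rep$p10 <= rep$p15 & rep$p15 <= rep$p20))
  expect_true(all(rep$rmse >= 0))
  expect_true(all(rep$p10 >= 0 & rep$p20 <= 1))
  expect_equal(rep$n, rep(3000L, 2))
  # nested concordance agrees with the standalone computation
  conc <- concordance(cohort$ldl_friedewald, cohort$ldl_measured)
  expect_equal(rep$concordance[[1]]$concordance, conc$concordance)
  # serialisation keeps one row per method
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, path)
  flat <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(flat), 2)
  expect_true(any(grepl("^concordance_", names(flat))))
})

test_that("category schemes validate their breakpoints", {
  expect_error(category_scheme("x", c(1, 1, 2)),
               class = "ldlbench_config_error")
  expect_error(category_scheme("x", c(3, 2)),
               class = "ldlbench_config_error")
  sch <- ldl_scheme()
  expect_equal(length(sch$labels), 5)
  expect_equal(as.character(categorize(c(0, 99.9, 100, 189.9, 190, 400), sch)),
               c("[0,100)", "[0,100)", "[100,130)", "[160,190)",
                 ">=190", ">=190"))
})
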