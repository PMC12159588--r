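test_that("ROM-PT regression matches the closed-form normal equations", {
  # exact line
  pt <- c(-5, 0, 5, 10, 20)
  fit <- fit_linear_rom_pt(pt, 2 * pt + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)

  # constant response
  flat <- fit_linear_rom_pt(pt, rep(90, 5))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)

  # random data: agreement with the normal-equation solution to 1e-10
  set.seed(5)
  for (i in 1:20) {
    x <- stats::rnorm(30, 10, 8)
    y <- -1.1 * x + 100 + stats::rnorm(30, 0, 9)
    f <- fit_linear_rom_pt(x, y)
    xm <- cbind(1, x)
    beta <- solve(crossprod(xm), crossprod(xm, y))
    expect_equal(f$intercept, beta[1], tolerance = 1e-10)
    expect_equal(f$slope, beta[2], tolerance = 1e-10)
    resid <- y - xm %*% beta
    expect_equal(f$rmse, sqrt(mean(resid^2)), tolerance = 1e-10)
    expect_equal(f$r_squared, 1 - sum(resid^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }

  # R^2 is invariant under affine rescaling of either variable
  x <- stats::rnorm(40, 15, 9)
  y <- -x + stats::rnorm(40, 0, 5)
  r2 <- fit_linear_rom_pt(x, y)$r_squared
  expect_equal(fit_linear_rom_pt(3 * x - 7, y)$r_squared, r2, tolerance = 1e-12)
  expect_equal(fit_linear_rom_pt(x, -0.5 * y + 40)$r_squared, r2,
               tolerance = 1e-12)

  expect_error(fit_linear_rom_pt(rep(3, 5), 1:5), "constant")
  expect_error(fit_linear_rom_pt(1:2, 1:2), "at least 3")
})

test_that("simulated cohort regression recovers the generating slope", {
  set.seed(77)
  pt <- stats::rnorm(56, 18.9, 8.8)
  rom <- 118 - 1 * pt + stats::rnorm(56, 0, 9)
  fit <- fit_linear_rom_pt(pt, rom)
  expect_lt(abs(fit$slope - (-1)), 0.15)
  expect_gt(fit$rmse, 7)
  expect_lt(fit$rmse, 11)
  expect_equal(fit$n, 56L)
})

test_that("benchmark crossings solve the fitted line", {
  expect_equal(benchmark_crossing_pt(list(slope = -1.0, intercept = 118.1), 110),
               8.1, tolerance = 1e-9)
  expect_equal(benchmark_crossing_pt(list(slope = -1.07, intercept = 42.6), 30),
               11.8, tolerance = 0.1)
  expect_equal(benchmark_crossing_pt(list(slope = -2, intercept = 50), 50), 0)
  expect_error(benchmark_crossing_pt(list(slope = 0, intercept = 1), 0),
               "never crosses")
})

test_that("clinical-relevance categories partition ROM changes", {
  expect_equal(as.character(delta_rom_category(c(9.5, -9.9, 0))),
               rep("low", 3))
  expect_equal(as.character(delta_rom_category(c(10, 15, -20, 20))),
               rep("medium", 4))
  expect_equal(as.character(delta_rom_category(c(20.5, -31))), rep("high", 2))
  # every finite delta falls in exactly one category
  set.seed(3)
  d <- stats::runif(200, -50, 50)
  expect_false(any(is.na(delta_rom_category(d))))
  expect_error(delta_rom_category(Inf))
})

test_that("impingement shift tables count patients in percentage points", {
  ids <- sprintf("P%02d", 1:56)
  a <- data.frame(patient_id = ids, motion = "IR@90Flex",
                  impingement_type = c(rep("BTBI", 20), rep("ITII", 30),
                                       rep("ITBI", 6)))
  expect_true(all(impingement_shift(a, a)$shift_pp == 0))

  b <- a
  b$impingement_type[1:9] <- "ITII"  # 9 of 56 patients flip BTBI -> ITII
  tab <- impingement_shift(a, b)
  expect_equal(tab$shift_pp[tab$impingement_type == "ITII"], 100 * 9 / 56,
               tolerance = 1e-9)
  expect_equal(tab$shift_pp[tab$impingement_type == "BTBI"], -100 * 9 / 56,
               tolerance = 1e-9)
  # shares sum to 100 within each condition
  expect_equal(sum(tab$share_a), 100, tolerance = 1e-9)
  expect_equal(sum(tab$share_b), 100, tolerance = 1e-9)

  expect_error(impingement_shift(a, b[-1, ]), "different patient sets")
})

test_that("paired t test reports n-1 degrees of freedom and known statistics", {
  x <- stats::rnorm(56, 10, 3)
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(paired_t(x, x + stats::rnorm(56))$df, 55)

  y <- c(10, 20, 30, 40)
  res <- paired_t(y + c(1, 2, 3, 4), y)
  expect_equal(res$t, 2.5 / (stats::sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-9)
  expect_equal(res$t, 3.873, tolerance = 1e-3)
  expect_equal(res$df, 3)

  expect_error(paired_t(y, y + 2), "no variance")
})

test_that("Welch test has fractional df reducing to 2n-2 for equal variances", {
  x <- stats::rnorm(20, 0, 2)
  expect_equal(welch_t(x, x)$t, 0)
  # identical sample variances: Welch-Satterthwaite collapses to 2n - 2
  expect_equal(welch_t(x, x + 5)$df, 2 * 20 - 2, tolerance = 1e-9)

  # groups with the offset-cohort moments: Welch df is fractional and sits
  # near its population value (~27); check the median over repeated draws
  set.seed(99)
  dfs <- replicate(20, {
    g1 <- stats::rnorm(19, 46.07, 4.85)
    g2 <- stats::rnorm(37, 48.89, 3.38)
    welch_t(g1, g2)$df
  })
  expect_gt(stats::median(dfs), 25)
  expect_lt(stats::median(dfs), 45)
  expect_false(any(dfs == round(dfs)))  # genuinely fractional

  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("pelvic tilt summaries recover generator moments and are antisymmetric", {
  exact <- generate_cohort_pt(cohort_gen_config(pt0_sd = 0, delta6_sd = 0,
                                                delta12_sd = 0))
  expect_equal(unique(exact$StPT_0), 18.9)
  expect_equal(unique(exact$StPT_6), 14.1)
  expect_equal(unique(exact$StPT_12), 14.7)
  sm <- summarize_pt(exact)
  expect_equal(unname(sm$means), c(18.9, 14.1, 14.7))
  expect_true(all(is.na(sm$comparisons$t)))  # no variance to test against

  cohort <- generate_cohort_pt(cohort_gen_config(seed = 4))
  sm2 <- summarize_pt(cohort)
  se <- 8.8 / sqrt(56)
  expect_lt(abs(sm2$means["StPT_0"] - 18.9), 2 * se * 1.5)
  d1 <- sm2$comparisons$mean_diff[sm2$comparisons$pair == "StPT_0 - StPT_6"]
  expect_lt(abs(d1 - 4.8), 3 * 6 / sqrt(56))
  expect_equal(sm2$comparisons$df[1], 55)

  rev <- summarize_pt(cohort[, c("patient_id", "StPT_0", "StPT_6", "StPT_12")])
  expect_equal(mean(cohort$StPT_0 - cohort$StPT_6),
               -mean(cohort$StPT_6 - cohort$StPT_0))

  expect_error(summarize_pt(cohort[, c("patient_id", "StPT_0")]), "missing")
})
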