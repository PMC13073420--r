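test_that("age bands follow the half-open convention with 70 included", {
  expect_equal(assign_age_band(c(20, 29.9, 30, 39.9, 40, 50, 70)),
               c("20-30", "20-30", "30-40", "30-40", "40-50", "50-70",
                 "50-70"))
  expect_error(assign_age_band(19), "20-70")
  expect_error(assign_age_band(70.5), "20-70")
  g <- assign_group(70, "alcohol", "1-2y")
  expect_equal(g$age_band, "50-70")
  expect_equal(g$abstinence_stratum, "1-2y")
  expect_true(is.na(assign_group(30, "control")$abstinence_stratum))
})

test_that("group summaries use sample SD and CV = SD/mean", {
  profiles <- rbind(
    subject_profile(2, 2, 2, "a", age = 25, exposure = "control"),
    subject_profile(4, 4, 4, "b", age = 26, exposure = "control"))
  s <- summarize_groups(profiles)
  whole <- s[s$measure == "whole" & s$age_band == "20-30", ]
  expect_equal(whole$mean, 3)
  expect_equal(whole$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(whole$cv, sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(whole$n, 2L)
  # 20-50 aggregate row present and pooled
  expect_true("20-50" %in% s$age_band)
  # CV is scale invariant
  profiles10 <- profiles
  for (col in c("ff_caput", "ff_corpus", "ff_cauda", "ff_whole", "delta_ff"))
    profiles10[[col]] <- profiles10[[col]] * 10
  s10 <- summarize_groups(profiles10)
  expect_equal(s10$cv, s$cv, tolerance = 1e-12)
})

test_that("reported group means and SDs reproduce the reference CV table", {
  d <- default_cohort_design()
  ref <- reference_cv_table()
  for (i in seq_len(nrow(d))) {
    row <- ref[ref$age_band == d$age_band[i] & ref$exposure == d$exposure[i], ]
    expect_lte(abs(d$sd_caput[i] / d$mean_caput[i] - row$caput), 0.005)
    expect_lte(abs(d$sd_corpus[i] / d$mean_corpus[i] - row$corpus), 0.005)
    expect_lte(abs(d$sd_cauda[i] / d$mean_cauda[i] - row$cauda), 0.005)
  }
  # the corpus control 20-30 cell is exact at 3 decimals: 0.66/2.91 = 0.227
  expect_equal(round(0.66 / 2.91, 3), 0.227)
})

test_that("one-way ANOVA matches the brute-force decomposition", {
  # identical groups: no between-group variance
  r0 <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  # frozen hand-computed example
  r <- anova_oneway(1:6, rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, 13.5, tolerance = 1e-10)
  expect_equal(r$p_value, 0.0213116411, tolerance = 1e-8)
  # random instances against the SS oracle
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    g <- rep(seq_len(k), times = sample(3:8, k, replace = TRUE))
    v <- rnorm(length(g), mean = g)
    r <- anova_oneway(v, g)
    o <- anova_oracle(v, g)
    expect_equal(r$statistic, unname(o["f"]), tolerance = 1e-10)
    expect_equal(r$p_value, unname(o["p"]), tolerance = 1e-10)
  }
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "at least 2")
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(sample(5:15, 1), 3, 1)
    y <- rnorm(sample(5:15, 1), 4, 1)
    f <- anova_oneway(c(x, y), rep(c("x", "y"), c(length(x), length(y))))
    t <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(f$statistic, unname(t$statistic)^2, tolerance = 1e-9)
    expect_equal(f$p_value, t$p.value, tolerance = 1e-9)
  }
})

test_that("the CV u-test is antisymmetric, null at equality, and detects the
           reference corpus difference", {
  eq <- cv_u_test(0.25, 30, 0.25, 40)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  a <- cv_u_test(0.342, 39, 0.238, 37)
  b <- cv_u_test(0.238, 37, 0.342, 39)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  # frozen from a scalar evaluation of Miller's formula
  expect_equal(a$statistic, 2.006392, tolerance = 1e-5)
  expect_lt(a$p_value, 0.05)
  expect_error(cv_u_test(0.3, 1, 0.2, 10), "n >= 2")
  expect_error(cv_u_test(-0.1, 10, 0.2, 10), "positive")
})

test_that("the bootstrap CV test agrees with the u-test on a clear difference", {
  set.seed(23)
  x1 <- rnorm(60, 10, 4)    # cv ~ 0.4
  x2 <- rnorm(60, 10, 1)    # cv ~ 0.1
  r <- cv_bootstrap_test(x1, x2, n_boot = 500)
  expect_lt(r$p_value, 0.05)
  same <- cv_bootstrap_test(rnorm(40, 10, 2), rnorm(40, 10, 2), n_boot = 500)
  expect_gt(same$p_value, 0.01)
})

test_that("intra-observer ICC behaves at its anchor points", {
  set.seed(3)
  truth <- rnorm(40, 6, 1.5)
  # identical repeats agree perfectly
  expect_equal(icc_intraobserver(cbind(truth, truth)), 1, tolerance = 1e-12)
  # unrelated readings share no variance
  noise <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc_intraobserver(noise)), 0.15)
  # small re-reading error: reliability above 0.90
  # population ICC = var_b / (var_b + var_e) = 1 / (1 + 0.05^2) ~ 0.9975
  repeats <- cbind(truth + rnorm(40, 0, 0.05 * 1.5),
                   truth + rnorm(40, 0, 0.05 * 1.5))
  expect_gt(icc_intraobserver(repeats), 0.90)
  expect_error(icc_intraobserver(cbind(1:4, 1:4)), "at least 5")
  expect_error(icc_intraobserver(matrix(1:10, ncol = 1)), "occasions")
})

test_that("ICC matches a mean-squares oracle computed from scratch", {
  set.seed(8)
  x <- matrix(rnorm(30, 5, 2), ncol = 2)
  n <- nrow(x); k <- 2
  # two-way ANOVA mean squares via explicit model sums of squares
  fit <- stats::aov(value ~ occ + Error(subj),
                    data = data.frame(value = as.vector(x),
                                      subj = factor(rep(1:n, k)),
                                      occ = factor(rep(1:k, each = n))))
  ms <- c(msr = summary(fit)[[1]][[1]]["Residuals", "Mean Sq"],
          msc = summary(fit)[[2]][[1]]["occ", "Mean Sq"],
          mse = summary(fit)[[2]][[1]]["Residuals", "Mean Sq"])
  icc_oracle <- (ms[["msr"]] - ms[["mse"]]) /
    (ms[["msr"]] + (k - 1) * ms[["mse"]] +
       k / n * (ms[["msc"]] - ms[["mse"]]))
  expect_equal(icc_intraobserver(x), icc_oracle, tolerance = 1e-10)
})

test_that("normality checks calibrate on Gaussian and reject heavy tails", {
  ps <- vapply(1:100, function(s) {
    set.seed(s)
    check_normality(rnorm(100, 5, 1))$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.90)
  set.seed(4)
  expect_lt(check_normality(rcauchy(100))$p_value, 0.05)
  expect_error(check_normality(rep(3, 10)), "identical")
  expect_error(check_normality(1:2), "3 <= n")
})

test_that("drinking-status comparison lays out strata and tests the null", {
  cohort <- gen_cohort(seed = 12)
  res <- compare_abstinence(cohort)
  expect_setequal(unique(res$summary$stratum),
                  c("current", "all abstainers", "<1y", "1-2y"))
  expect_setequal(unique(res$summary$age_band), c("20-50", "50-70"))
  n2050 <- res$summary[res$summary$age_band == "20-50", ]
  expect_equal(n2050$n[n2050$stratum == "current"], 60L)
  expect_equal(sum(n2050$n[n2050$stratum %in% c("<1y", "1-2y")]), 46L)
  expect_true(all(vapply(res$tests, function(t) t$p_value >= 0 &&
                           t$p_value <= 1, logical(1))))
  # a single populated stratum yields a summary but no test
  solo <- cohort[cohort$exposure == "alcohol" &
                   cohort$abstinence == "current", ]
  res1 <- suppressWarnings(compare_abstinence(solo))
  expect_length(res1$tests, 0)
  expect_setequal(unique(res1$summary$stratum), "current")
  expect_error(compare_abstinence(cohort[cohort$exposure == "control", ]),
               "no alcohol")
})

test_that("rendered tables carry one row per group and formatted cells", {
  s <- summarize_groups(gen_cohort(seed = 13))
  ff <- render_ff_table(s)
  cv <- render_cv_table(s)
  expect_equal(nrow(ff), 10L)  # 8 primary groups + two 20-50 aggregates
  expect_match(ff$whole[1], "^[0-9.]+ \\+/- [0-9.]+$")
  expect_match(cv$whole[1], "^0\\.[0-9]{3}$")
  expect_false("delta_ff" %in% names(cv))
})
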