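test_that("HWE chi-square matches hand-computed cases and label-swap symmetry", {
  perfect <- hwe_chi_square(c(25, 50, 25))
  expect_equal(perfect$chi_square, 0, tolerance = 1e-12)
  expect_equal(perfect$df, 1L)

  split <- hwe_chi_square(c(50, 0, 50))
  expect_equal(split$allele_freq, 0.5)
  expect_equal(split$expected, c(25, 50, 25))
  expect_equal(split$chi_square, 25 + 50 + 25)

  a <- hwe_chi_square(c(30, 44, 26))
  b <- hwe_chi_square(c(26, 44, 30))
  expect_equal(a$chi_square, b$chi_square, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  expect_error(hwe_chi_square(c(0, 0, 0)), "zero total")
})

test_that("genetic-model codings reproduce the 0/0.5/1 and dominance schemes", {
  g <- c("II", "ID", "DD")
  expect_equal(code_genetic_model(g, genetic_model_coding("additive", "ace")),
               c(0, 0.5, 1))
  expect_equal(code_genetic_model(g, genetic_model_coding("I_dominant", "ace")),
               c(0, 0, 1))
  expect_equal(code_genetic_model(g, genetic_model_coding("D_dominant", "ace")),
               c(0, 1, 1))
  expect_equal(code_genetic_model(c("RR", "RX", "XX"),
                                  genetic_model_coding("additive", "actn3")),
               c(0, 0.5, 1))
  expect_error(code_genetic_model(c("II", "ZZ"),
                                  genetic_model_coding("additive", "ace")),
               "unknown genotype")
})

test_that("genotype ANOVA agrees with a from-scratch sums-of-squares oracle", {
  y <- withr::with_seed(16, rnorm(60))
  g <- rep(c("II", "ID", "DD"), each = 20)
  an <- genotype_anova(y, g)
  gm <- tapply(y, g, mean)
  ssb <- sum(20 * (gm - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  f_oracle <- (ssb / 2) / ((sst - ssb) / 57)
  expect_equal(an$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(an$eta_squared, ssb / sst, tolerance = 1e-10)
  expect_equal(nrow(an$tukey), 3L)
  expect_equal(sort(an$groups$n), c(20L, 20L, 20L))

  # degenerate variance structures
  flat <- genotype_anova(rep(5, 30), rep(c("II", "ID", "DD"), 10))
  expect_equal(flat$eta_squared, 0)
  sep <- genotype_anova(rep(c(1, 2, 3), each = 10), rep(c("II", "ID", "DD"), each = 10))
  expect_equal(sep$eta_squared, 1)

  expect_error(genotype_anova(1:5, c("II", "II", "II", "ID", "DD")), "at least 2")
})

test_that("eta-squared equals additive r-squared for exactly additive data", {
  y <- rep(c(0, 0.5, 1), each = 12)
  g <- rep(c("II", "ID", "DD"), each = 12)
  an <- genotype_anova(y, g)
  code <- code_genetic_model(g, genetic_model_coding("additive", "ace"))
  expect_equal(an$eta_squared, cor(code, y)^2, tolerance = 1e-12)
})

test_that("dominant-grouping t test behaves at the null and under separation", {
  same <- withr::with_seed(21, rnorm(40))
  res <- dominant_group_ttest(c(same, same), rep(c("a", "b"), each = 40))
  expect_equal(res$t_statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_length(res$ks_p, 2L)
  expect_true(all(res$ks_p > 0.05))

  # power at a one-sd shift, n = 30 per group
  set.seed(22)
  hits <- mean(replicate(500, {
    dominant_group_ttest(c(rnorm(30), rnorm(30, 1)),
                         rep(c("g1", "g2"), each = 30))$p_value < 0.05
  }))
  expect_gte(hits, 0.95)

  expect_error(dominant_group_ttest(1:4, c("a", "a", "a", "b")), "at least 2")
})

test_that("model variance shares identify the generating architecture", {
  # constructed purely additive data: additive r2 equals eta2, share = 100%
  y <- rep(c(0, 0.5, 1), each = 10)
  g <- rep(c("II", "ID", "DD"), each = 10)
  mv <- model_variance_percent(y, g, "ace")
  add_row <- mv$table[mv$table$model == "additive", ]
  expect_equal(add_row$r_squared, mv$eta_squared, tolerance = 1e-12)
  expect_equal(add_row$percent_of_anova, 100, tolerance = 1e-9)
  expect_identical(mv$best_model, "additive")

  expect_equal(100 * 0.04 / 0.08, 50)   # the share is plain arithmetic

  expect_error(model_variance_percent(rep(1, 30), rep(c("II", "ID", "DD"), 10), "ace"),
               "undefined percentage")

  # simulated D-dominant cohorts pick D_dominant nearly always at n = 1000
  set.seed(23)
  best <- replicate(50, {
    coh <- simulate_cohort(cohort_sim_config(
      n = 1000, effect_locus = "ace", model = "D_dominant", effect_size = 0.5,
      outcome_sd = 1, seed = sample.int(1e6, 1)))
    model_variance_percent(coh$outcomes[[2]], coh$genotypes$ace, "ace")$best_model
  })
  expect_gte(mean(best == "D_dominant"), 0.9)
})

test_that("likelihood-ratio covariate test matches the Gaussian RSS identity", {
  d <- withr::with_seed(24, data.frame(y = rnorm(40), x = rnorm(40), w = rnorm(40)))
  lr <- lrt_covariate(d, "y", c("x", "w"), "w")
  rss_full <- sum(resid(lm(y ~ x + w, d))^2)
  rss_null <- sum(resid(lm(y ~ x, d))^2)
  expect_equal(lr$lr_statistic, nrow(d) * log(rss_null / rss_full),
               tolerance = 1e-8)
  expect_equal(lr$df, 1)

  same <- lrt_covariate(d, "y", c("x", "w"), character(0))
  expect_equal(same$lr_statistic, 0)

  expect_error(lrt_covariate(d, "y", c("x"), "w"), "non-nested")
})

test_that("attrition arithmetic and its guards", {
  expect_identical(attrition_adjusted_n(269, 0.05), 283L)
  expect_identical(attrition_adjusted_n(100, 0), 100L)
  expect_identical(attrition_adjusted_n(100, 0.05), 105L)
  expect_error(attrition_adjusted_n(100, 1), "dropout_rate")
  expect_error(attrition_adjusted_n(-3, 0.05), "positive integer")
})

test_that("Monte-Carlo ANOVA power matches the noncentral-F closed form", {
  # null effect: rejection rate is alpha
  p0 <- empirical_power_oneway(3, 90, 0, reps = 2000, seed = 31)
  expect_lt(abs(p0$power - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  # underpowered design agrees with the analytic benchmark
  pw <- empirical_power_oneway(3, 30, 0.25, reps = 2000, seed = 32)
  ncp <- 30 * 0.25^2
  closed <- 1 - pf(qf(0.95, 2, 27), 2, 27, ncp = ncp)
  expect_lt(closed, 0.5)
  expect_lt(abs(pw$power - closed), 3 * pw$mc_se + 3 * sqrt(closed * (1 - closed) / 2000))

  # determinism under a fixed seed
  expect_identical(empirical_power_oneway(3, 60, 0.3, reps = 200, seed = 5)$power,
                   empirical_power_oneway(3, 60, 0.3, reps = 200, seed = 5)$power)

  expect_error(empirical_power_oneway(1, 30, 0.2), "invalid")
})
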