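test_that("growth and assay formulas match their definitions", {
  expect_equal(specific_growth_rate(37, 37, 60), 0)
  expect_equal(specific_growth_rate(1, exp(0.9), 90), 1.0)
  expect_error(specific_growth_rate(0, 5, 30), "positive")
  # log additivity over consecutive intervals
  expect_equal(
    specific_growth_rate(10, 10 * 1.7, 30) +
      specific_growth_rate(10 * 1.7, 10 * 1.7^2, 30),
    2 * specific_growth_rate(10, 10 * 1.7, 30))

  expect_equal(survival_rate(400, 400), 100)
  expect_equal(survival_rate(200, 400), 50)
  expect_error(survival_rate(401, 400), "\\[0, initial")

  expect_equal(specific_activity(10, 2), 5)
  expect_equal(specific_activity(0, 2), 0)
  expect_error(specific_activity(10, 0), "positive")

  expect_equal(villus_density(20, 4), 5)
  expect_equal(villus_density(0, 4), 0)
  expect_error(villus_density(20, 0), "positive")

  expect_equal(fold_crypt_ratio(100, 25), 4)
  expect_equal(fold_crypt_ratio(33, 33), 1)
  expect_error(fold_crypt_ratio(100, 0), "positive")
})

test_that("2^-ddCt identities hold", {
  expect_equal(relative_expression_ddct(20, 18, 21, 19), 1.0)
  # ddCt = 1
  expect_equal(relative_expression_ddct(21, 18, 20, 18), 0.5)
  # ddCt = -2
  expect_equal(relative_expression_ddct(18, 18, 20, 18), 4.0)
  expect_error(relative_expression_ddct(NA, 1, 1, 1), "finite")
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  r <- anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  expect_equal(r$F, 1.5)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 4)
  expect_equal(r$p, pf(1.5, 1, 4, lower.tail = FALSE))

  # degenerate: all observations identical
  r0 <- anova_oneway(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(61)
  x <- rnorm(6); y <- rnorm(7, 1)
  r2 <- anova_oneway(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)

  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("ANOVA F is shift- and scale-invariant", {
  set.seed(62)
  g <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(5, 2))
  f0 <- anova_oneway(g)$F
  expect_equal(anova_oneway(lapply(g, `+`, 100))$F, f0, tolerance = 1e-9)
  expect_equal(anova_oneway(lapply(g, `*`, 7))$F, f0, tolerance = 1e-9)
})

test_that("Tukey HSD: identities, letters, and a published critical value", {
  # identical groups: all ties, one shared letter
  r <- tukey_hsd(list(a = c(5, 5, 6, 6), b = c(5, 6, 5, 6),
                      c = c(6, 5, 6, 5)))
  expect_true(all(r$table$p_adj == max(r$table$p_adj)))
  expect_identical(unname(r$letters), rep("a", 3))

  # two groups: adjusted p equals the pooled t-test p, q = sqrt(2)|t|
  set.seed(63)
  x <- rnorm(8); y <- rnorm(8, 0.8)
  r2 <- tukey_hsd(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r2$table$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(r2$table$q_stat, sqrt(2) * abs(unname(tt$statistic)),
               tolerance = 1e-9)

  # three balanced groups, n = 5, within-pattern variance 2.5 (df2 = 12):
  # a mean gap of q_{0.05}(3,12) * sqrt(MSE/n) = 3.773 * 0.7071 must land
  # at adjusted p = 0.05 (published studentized-range critical value)
  v <- c(-2, -1, 0, 1, 2)
  gap <- 3.773 * sqrt(2.5 / 5)
  r3 <- tukey_hsd(list(a = v, b = v + gap, c = v + 40))
  p_ab <- r3$table$p_adj[(r3$table$group_a == "a" & r3$table$group_b == "b") |
                           (r3$table$group_a == "b" & r3$table$group_b == "a")]
  expect_equal(p_ab, 0.05, tolerance = 1e-3)

  # one shifted group earns its own letter
  set.seed(64)
  g4 <- list(g1 = rnorm(6), g2 = rnorm(6), g3 = rnorm(6), g4 = rnorm(6, 8))
  r4 <- tukey_hsd(g4)
  expect_identical(unname(r4$letters["g4"]), "a")   # highest mean, alone
  expect_false(any(grepl("a", r4$letters[c("g1", "g2", "g3")])))

  # Tukey-adjusted p never undercuts the unadjusted pairwise comparison
  # built on the same pooled error (the q statistic is sqrt(2) t)
  df2 <- length(unlist(g4)) - length(g4)
  pooled_t_p <- 2 * pt(-r4$table$q_stat / sqrt(2), df = df2)
  expect_true(all(r4$table$p_adj >= pooled_t_p - 1e-9))
})

test_that("growth summaries and the simulated cohort behave", {
  # cv = 0 reproduces the trajectory exactly
  rec0 <- simulate_growth_cohort(n_fish = 5, cv = 0, seed = 65)
  s0 <- growth_summary(rec0)
  lt90 <- s0[s0$group == "LT" & s0$timepoint_days == 90, ]
  expect_equal(lt90$length_mean, default_growth_means()$LT$length_mm[3])
  expect_equal(lt90$length_sd, 0)

  # same seed, same records; different seed differs
  expect_identical(simulate_growth_cohort(seed = 66),
                   simulate_growth_cohort(seed = 66))
  expect_false(identical(simulate_growth_cohort(seed = 66),
                         simulate_growth_cohort(seed = 67)))
  expect_error(simulate_growth_cohort(cv = -0.1, seed = 1), "cv")

  # planted 3-SD group separation is detected by ANOVA at p < 0.01
  rec <- simulate_growth_cohort(n_fish = 30, cv = 0.1, seed = 68)
  final <- rec[rec$timepoint_days == 90, ]
  groups <- split(final$weight_g, final$group)
  expect_lt(anova_oneway(groups)$p, 0.01)
  # and the hybrids outrank the purebreds in the letter display
  r <- tukey_hsd(groups)
  expect_true(which(names(r$letters) == "LT") <
                which(names(r$letters) == "TJ"))
})
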