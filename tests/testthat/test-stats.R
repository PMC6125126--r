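test_that("the two-SD outlier screen follows the direct arithmetic", {
  r <- outlier_filter(c(1, 1, 1, 1))
  expect_true(all(r$keep))
  # mean 16.67, sample SD 40.82: |100 - 16.67| = 83.3 exceeds 2 SD = 81.6,
  # so the extreme value is flagged
  x <- c(0, 0, 0, 0, 0, 100)
  r2 <- outlier_filter(x)
  expect_equal(r2$mean, mean(x))
  expect_equal(r2$sd, sd(x))
  expect_equal(r2$keep, abs(x - mean(x)) <= 2 * sd(x))
  expect_equal(r2$flagged, 6L)
  expect_error(outlier_filter(c(1, 2)), "at least 3")
})

test_that("outlier removal rate on normal samples matches the rule's tail mass", {
  set.seed(91)
  n <- 30
  rates <- vapply(1:2000, function(i) {
    x <- rnorm(n)
    mean(!outlier_filter(x)$keep)
  }, numeric(1))
  # the empirical 2-SD rule removes a bit under the Gaussian 2-sigma tail
  # (4.55%) because mean/SD are estimated from the same sample
  expect_gt(mean(rates), 0.025)
  expect_lt(mean(rates), 0.0555)
})

test_that("one-way RM ANOVA matches the closed-form SS oracle", {
  d <- expand.grid(subject = paste0("s", 1:3), level = paste0("l", 1:3),
                   KEEP.OUT.ATTRS = FALSE)
  set.seed(92)
  d$y <- rnorm(9, mean = as.integer(factor(d$level)))
  fit <- rm_anova_1way(data.frame(value = d$y, subject = d$subject,
                                  level = d$level))
  orc <- rm1_oracle(d)
  expect_equal(fit$table$F, orc$F, tolerance = 1e-10)
  expect_equal(fit$table$df1, orc$df1)
  expect_equal(fit$table$df2, orc$df2)
  expect_equal(fit$table$p, orc$p, tolerance = 1e-10)
  # equal level means (with genuine residual spread) -> F collapses to 0
  d0 <- expand.grid(subject = paste0("s", 1:4), level = paste0("l", 1:3),
                    KEEP.OUT.ATTRS = FALSE)
  set.seed(921)
  e <- rnorm(12)
  e <- e - ave(e, d0$level)  # centre residuals within each level
  d0$y <- rep(c(1, 5, 9, 2), times = 3) + e
  fit0 <- rm_anova_1way(data.frame(value = d0$y, subject = d0$subject,
                                   level = d0$level))
  expect_lt(fit0$table$F, 1e-10)
  expect_error(rm_anova_1way(data.frame(value = 1:5,
                                        subject = c(1, 1, 2, 2, 3),
                                        level = c(1, 2, 1, 2, 1))),
               "complete")
})

test_that("mixed ANOVA matches the SS oracle and degenerates correctly", {
  d <- random_rm2(93)
  fit <- rm_anova_mixed(data.frame(value = d$y, subject = d$subject,
                                   group = d$group, level = d$level))
  orc <- rm2_oracle(d)
  expect_equal(fit$table$F, c(orc$F_group, orc$F_level, orc$F_int),
               tolerance = 1e-10)
  expect_equal(fit$table$df1, c(orc$df$group[1], orc$df$level[1],
                                orc$df$int[1]))
  expect_equal(fit$table$df2, c(orc$df$group[2], orc$df$level[2],
                                orc$df$int[2]))
  # identical data in both groups: group and interaction F collapse to 0
  base <- expand.grid(subject = paste0("s", 1:3), level = paste0("l", 1:3),
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(94)
  base$y <- rnorm(9)
  two <- rbind(transform(base, group = "a"),
               transform(base, group = "b",
                         subject = paste0("t", base$subject)))
  fit0 <- rm_anova_mixed(data.frame(value = two$y, subject = two$subject,
                                    group = two$group, level = two$level))
  expect_lt(max(fit0$table$F[c(1, 3)]), 1e-10)
  expect_error(rm_anova_mixed(data.frame(value = 1:6,
                                         subject = c("a", "a", "a", "b", "b", "b"),
                                         group = c("g1", "g1", "g1", "g2", "g2", "g2"),
                                         level = rep(1:3, 2))),
               "two subjects")
})

test_that("ANOVA F is invariant to shifts and positive rescaling", {
  d <- random_rm1(95)
  base <- rm_anova_1way(data.frame(value = d$y, subject = d$subject,
                                   level = d$level))$table$F
  sh <- rm_anova_1way(data.frame(value = d$y + 100, subject = d$subject,
                                 level = d$level))$table$F
  sc <- rm_anova_1way(data.frame(value = d$y * 3.7, subject = d$subject,
                                 level = d$level))$table$F
  expect_equal(sh, base, tolerance = 1e-9)
  expect_equal(sc, base, tolerance = 1e-9)
})

test_that("sums of squares decompose the total", {
  for (seed in 96:99) {
    d <- random_rm1(seed)
    ss <- rm1_oracle(d)$ss
    expect_equal(ss[["total"]],
                 ss[["level"]] + ss[["subject"]] + ss[["error"]],
                 tolerance = 1e-8 * max(1, ss[["total"]]))
    d2 <- random_rm2(seed)
    s2 <- rm2_oracle(d2)$ss
    expect_equal(s2[["total"]],
                 s2[["group"]] + s2[["sw"]] + s2[["level"]] + s2[["int"]] +
                   s2[["error"]],
                 tolerance = 1e-8 * max(1, s2[["total"]]))
  }
})

test_that("Holm-Sidak adjustment is monotone and conservative", {
  set.seed(100)
  p <- runif(8, 0, 0.2)
  adj <- holm_sidak_adjust(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_equal(holm_sidak_adjust(0.04), 0.04)
  # smallest p gets the full-family Sidak correction
  expect_equal(min(adj), 1 - (1 - min(p))^length(p), tolerance = 1e-12)
})

test_that("Tukey and Holm-Sidak post hoc tables flag the separated level", {
  set.seed(101)
  d <- expand.grid(subject = paste0("s", 1:8), level = c("a", "b", "c"),
                   KEEP.OUT.ATTRS = FALSE)
  d$y <- rnorm(24, sd = 0.3) + ifelse(d$level == "c", 4, 0)
  fit <- rm_anova_1way(data.frame(value = d$y, subject = d$subject,
                                  level = d$level))
  ph <- fit$posthoc
  involving_c <- grepl("c", ph$comparison)
  expect_true(all(ph$p_adj[involving_c] < 0.01))
  expect_true(all(ph$p_adj[!involving_c] > 0.05))
})

test_that("lead/lag chance tests behave on degenerate and toy inputs", {
  same <- c(0.01, 0.02, 0.03)
  r <- lag_vs_chance(same, same)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  # textbook pooled-variance t for a toy pair of samples
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  r2 <- lag_vs_chance(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(unname(r2$statistic), t_hand, tolerance = 1e-12)
  # a clearly shifted sample is significant
  set.seed(102)
  r3 <- lag_vs_chance(rnorm(8, 0.02, 0.002), rnorm(8, 0, 0.002))
  expect_lt(r3$p.value, 0.05)
  r4 <- lag_vs_chance(rnorm(8, 0.02, 0.002), mode = "one_sample")
  expect_lt(r4$p.value, 0.05)
  expect_error(lag_vs_chance(0.01), "at least two")
})
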