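test_that("ROI summaries report mean, sample SD and CoV over valid voxels only", {
  set.seed(2)
  v <- array(0, c(10, 10, 4))
  labs <- array(0L, c(10, 10, 4))
  labs[2:5, 2:5, ] <- 1L
  labs[6:9, 6:9, ] <- 2L
  v[labs == 1L] <- rnorm(sum(labs == 1L), 0.5, 0.02)
  v[labs == 2L] <- 1.2
  valid <- array(TRUE, dim(v))
  valid[2, 2, 1] <- FALSE              # one rejected voxel must be excluded
  sig <- conductivity_map(v, valid)
  lm_ <- label_map(labs)
  s1 <- roi_summary(sig, lm_, 1L)
  sel <- labs == 1L & valid
  expect_equal(s1$n_voxels, sum(sel))
  expect_equal(s1$mean, mean(v[sel]))
  expect_equal(s1$sd, sd(v[sel]))
  expect_equal(s1$cov_percent, 100 * sd(v[sel]) / mean(v[sel]))
  # constant ROI: zero SD, zero CoV
  s2 <- roi_summary(sig, lm_, 2L)
  expect_equal(s2$sd, 0)
  expect_equal(s2$cov_percent, 0)
  expect_error(roi_summary(sig, lm_, 9L), "valid voxels")
})

test_that("relative error reproduces the l2-norm ratio and its properties", {
  I1 <- array(c(3, 4, 0, 0), c(2, 2, 1))
  I2 <- array(c(3, 0, 0, 0), c(2, 2, 1))
  expect_equal(relative_error(I1, I2), 0.8)     # 4/5
  expect_equal(relative_error(I1, I1), 0)
  expect_equal(relative_error(I1, I1 * 0), 1)
  expect_error(relative_error(I1 * 0, I1), "zero norm")
  # scale consistency
  set.seed(4)
  A <- array(rnorm(27), c(3, 3, 3))
  B <- array(rnorm(27), c(3, 3, 3))
  expect_equal(relative_error(2.7 * A, 2.7 * B), relative_error(A, B))
})

test_that("Bland-Altman bias and limits of agreement follow mean +/- 1.96 SD", {
  ident <- bland_altman(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))

  two <- bland_altman(c(1, 0), c(0, 1))         # differences +1, -1
  expect_equal(two$bias, 0)
  expect_equal(two$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)

  three <- bland_altman(c(0.01, 0.02, 0.03), c(0, 0, 0))
  expect_equal(three$bias, 0.02)
  expect_equal(three$loa_low, 0.02 - 1.96 * 0.01, tolerance = 1e-12)
  expect_equal(three$loa_high, 0.02 + 1.96 * 0.01, tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "2 pairs")
})

test_that("paired TOST matches a composition of two one-sided t-tests", {
  set.seed(6)
  for (i in 1:20) {
    x1 <- rnorm(5, 0.5, 0.03)
    x2 <- rnorm(5, 0.5, 0.03)
    res <- tost_equivalence(x1, x2, margin = 0.025)
    d <- x1 - x2
    p1 <- t.test(d, mu = -0.025, alternative = "greater")$p.value
    p2 <- t.test(d, mu = 0.025, alternative = "less")$p.value
    expect_equal(res$p_value, max(p1, p2), tolerance = 1e-9)
    ci <- t.test(d, conf.level = 0.90)$conf.int
    expect_equal(res$ci, as.vector(ci), tolerance = 1e-9)
    expect_equal(res$ci_bound, res$ci[which.max(abs(res$ci))])
    expect_identical(res$equivalent, res$p_value <= 0.05)
  }
})

test_that("TOST degenerate and boundary behaviour", {
  x <- c(0.5, 0.51, 0.49, 0.5, 0.5)
  same <- tost_equivalence(x, x, margin = 0.025)
  expect_equal(same$p_value, 0)
  expect_true(same$equivalent)
  # mean difference exactly at the margin: equivalence cannot be concluded
  d <- c(0.02, 0.03, 0.025, 0.02, 0.03)   # mean 0.025
  at_margin <- tost_equivalence(d, rep(0, 5), margin = 0.025)
  expect_gte(at_margin$p_value, 0.5)
  expect_error(tost_equivalence(1:4, 1:5, margin = 0.1), "paired")
})

test_that("TOST power: Monte-Carlo agrees with exact integration", {
  p_mc <- tost_power(5, 0.045, 0.95, 0.025, reps = 1e5, seed = 2L)
  p_int <- tost_power(5, 0.045, 0.95, 0.025, method = "integration")
  mcse <- sqrt(p_int * (1 - p_int) / 1e5)
  expect_lt(abs(p_mc - p_int), 4 * mcse)
})

test_that("TOST power is monotone in margin and in per-arm SD", {
  margins <- c(0.01, 0.02, 0.04, 0.08)
  p_m <- vapply(margins, function(m)
    tost_power(5, 0.045, 0.95, m, method = "integration"), numeric(1))
  expect_true(all(diff(p_m) > 0))
  sds <- c(0.02, 0.045, 0.09, 0.18)
  p_s <- vapply(sds, function(s)
    tost_power(5, s, 0.95, 0.025, method = "integration"), numeric(1))
  expect_true(all(diff(p_s) < 0))
  # limits
  expect_gt(tost_power(5, 0.045, 0.95, 10, reps = 2e4, seed = 3L), 0.999)
  expect_lt(tost_power(5, 0.045, 0.95, 1e-7, reps = 2e4, seed = 3L), 0.001)
  expect_error(tost_power(5, 0.045, 1.2, 0.025), "correlation")
})

test_that("repeated-measures ANOVA matches the textbook decomposition", {
  # 2 conditions x 3 units toy table, F computed from explicit sums of squares
  df <- data.frame(subject = rep(1:3, 2),
                   condition = rep(c("A", "B"), each = 3),
                   value = c(1, 2, 3, 2, 3, 5))
  res <- session_anova(df)
  y <- df$value
  grand <- mean(y)
  ss_cond <- 3 * sum((tapply(y, df$condition, mean) - grand)^2)
  ss_unit <- 2 * sum((tapply(y, df$subject, mean) - grand)^2)
  ss_err <- sum((y - grand)^2) - ss_cond - ss_unit
  f_expected <- (ss_cond / 1) / (ss_err / 2)
  expect_equal(res$F, f_expected, tolerance = 1e-12)
  expect_equal(res$p_value, pf(f_expected, 1, 2, lower.tail = FALSE))
  # and against the aov() machinery as an independent implementation
  fit <- summary(aov(value ~ condition + Error(factor(subject)),
                     data = df))
  p_aov <- fit[["Error: Within"]][[1]][["Pr(>F)"]][1]
  expect_equal(res$p_value, p_aov, tolerance = 1e-9)
})

test_that("ANOVA degenerate and error behaviour", {
  df <- data.frame(subject = rep(1:4, 2),
                   condition = rep(c("s1", "s2"), each = 4),
                   value = rep(c(0.4, 0.5, 0.6, 0.45), 2))
  res <- session_anova(df)                     # identical sessions
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)

  set.seed(10)
  df2 <- data.frame(subject = rep(1:5, 2),
                    condition = rep(c("a", "b"), each = 5),
                    value = c(rnorm(5, 0.5, 0.01), rnorm(5, 1.5, 0.01)))
  expect_lt(session_anova(df2)$p_value, 1e-3)

  bad <- df2[-1, ]
  expect_error(session_anova(bad), "unbalanced|exactly one")
})

test_that("Bonferroni adjustment is applied across comparisons", {
  set.seed(11)
  df <- data.frame(subject = rep(1:5, 3),
                   condition = rep(c("a", "b", "c"), each = 5),
                   value = rnorm(15, 0.5, 0.05))
  res <- session_anova(df, comparisons = list(c("a", "b"), c("a", "c")))
  expect_equal(nrow(res), 2L)
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 2))
})
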