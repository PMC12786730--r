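test_that("rm_anova matches the hand SS oracle on the toy matrix", {
  m <- rbind(c(10, 9, 7), c(12, 11, 8), c(11, 10, 9), c(13, 11, 7))
  colnames(m) <- c(0, 3, 7)
  r <- rm_anova(m)
  o <- oracle_rm_anova(m)
  expect_equal(r$f_stat, o$f, tolerance = 1e-10)
  expect_equal(r$epsilon_gg, o$eps_gg, tolerance = 1e-10)
  expect_equal(r$epsilon_hf, o$eps_hf, tolerance = 1e-10)
  expect_equal(r$eta_p2, o$eta_p2, tolerance = 1e-10)
  expect_equal(r$df_time, 2)
  expect_equal(r$df_error, 6)
})

test_that("rm_anova agrees with base R mlm/aov machinery", {
  set.seed(19)
  m <- matrix(rnorm(48, rep(c(10, 9, 7, 5), each = 12), 1.5), 12, 4)
  colnames(m) <- c(0, 3, 7, 10)
  r <- rm_anova(m)
  # F from aov with an Error(subject/time) stratum
  df <- data.frame(y = as.vector(m), s = factor(rep(1:12, 4)),
                   t = factor(rep(1:4, each = 12)))
  tab <- summary(aov(y ~ t + Error(s / t), data = df))[[2]][[1]]
  expect_equal(r$f_stat, tab["t", "F value"], tolerance = 1e-10)
  expect_equal(r$p_uncorrected, tab["t", "Pr(>F)"], tolerance = 1e-10)
  # Mauchly W from stats::mauchly.test (chi-square p approximate)
  fit <- lm(m ~ 1)
  mt <- mauchly.test(fit, X = ~1, idata = data.frame(time = factor(1:4)))
  expect_equal(r$mauchly_w, unname(mt$statistic), tolerance = 1e-10)
  # stats:: adds a second-order term to the chi-square approximation
  expect_lt(abs(r$mauchly_p - mt$p.value), 0.01)
})

test_that("rm_anova equals the SS oracle on random small matrices", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(3:6, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 10, 2), n, k)
    r <- rm_anova(m)
    o <- oracle_rm_anova(m)
    expect_equal(r$f_stat, o$f, tolerance = 1e-8)
    expect_equal(r$epsilon_gg, o$eps_gg, tolerance = 1e-8)
    expect_equal(r$epsilon_hf, o$eps_hf, tolerance = 1e-8)
    expect_equal(r$eta_p2, o$eta_p2, tolerance = 1e-8)
    # epsilon bounds
    expect_gte(r$epsilon_gg, 1 / (k - 1) - 1e-12)
    expect_lte(r$epsilon_gg, 1 + 1e-12)
    expect_gte(r$epsilon_hf, r$epsilon_gg - 1e-12)
  }
})

test_that("k = 2 reduces to the paired t test with trivial sphericity", {
  set.seed(29)
  m <- matrix(rnorm(20, c(10, 8), 1), 10, 2, byrow = TRUE)
  r <- rm_anova(m)
  tt <- t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(r$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p_uncorrected, tt$p.value, tolerance = 1e-10)
  expect_identical(r$mauchly_w, 1)
  expect_identical(r$epsilon_hf, 1)
})

test_that("degenerate matrices are flagged, not silently NaN", {
  m <- matrix(rep(c(5, 5, 5), 4), 4, 3, byrow = TRUE)
  r <- rm_anova(m)  # identical columns: no time effect
  expect_equal(r$f_stat, 0)
  expect_equal(r$eta_p2, 0)
  # perfect time effect with zero error variance: infinite F, flagged
  m2 <- outer(c(1, 2, 3, 4), c(10, 8, 6)) / c(1, 2, 3, 4)  # identical rows
  r2 <- rm_anova(m2)
  expect_true(r2$degenerate)
  expect_true(is.infinite(r2$f_stat))
  expect_equal(r2$p_uncorrected, 0)
})

test_that("normality screen calibrates under H0 and catches skew", {
  p_norm <- vapply(1:100, function(s) {
    set.seed(s); normality_check(matrix(rnorm(36), 12, 3))$p[1]
  }, 0)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_skew <- vapply(1:100, function(s) {
    set.seed(s); normality_check(matrix(rlnorm(36, 0, 1.5), 12, 3))$p[1]
  }, 0)
  expect_gte(mean(p_skew < 0.05), 0.80)
  deg <- normality_check(cbind(rnorm(12), rep(1, 12)))
  expect_true(deg$degenerate[2] && is.na(deg$W[2]))
  expect_error(normality_check(matrix(1:4, 2, 2)), "3 <= n")
})

test_that("posthoc pairwise: dz, pair count, Bonferroni cap, CI", {
  # differences (1,2,3): dz = mean/sd = 2/1 = 2
  m <- cbind(c(5, 7, 9), c(4, 5, 6))
  ph <- posthoc_pairwise(m)
  expect_equal(ph$cohen_dz, 2)
  # k = 4 -> 6 pairs; Bonferroni multiplies by 6 and caps at 1
  set.seed(31)
  m4 <- matrix(rnorm(48), 12, 4)
  ph4 <- posthoc_pairwise(m4)
  expect_identical(nrow(ph4), 6L)
  raw <- t.test(m4[, 1], m4[, 2], paired = TRUE)
  expect_equal(ph4$p_adjusted[1], min(1, raw$p.value * 6), tolerance = 1e-10)
  expect_equal(ph4$ci_low[1], raw$conf.int[1], tolerance = 1e-10)
  expect_equal(ph4$ci_high[1], raw$conf.int[2], tolerance = 1e-10)
  expect_true(all(ph4$p_adjusted <= 1))
  # tukey variant returns studentized-range ps in [0, 1] for all pairs
  pht <- posthoc_pairwise(m4, method = "tukey_hsd")
  expect_identical(nrow(pht), 6L)
  expect_true(all(pht$p_adjusted >= 0 & pht$p_adjusted <= 1))
  # zero-variance differences flagged
  ph0 <- posthoc_pairwise(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_false(ph0$dz_defined)
  expect_true(is.na(ph0$cohen_dz))
})

test_that("friedman: hand-ranked example, ties, oracle agreement", {
  # every subject strictly decreasing: rank sums 9, 6, 3 -> chi2 = 6
  m <- rbind(c(10, 8, 5), c(9, 7, 3), c(12, 10, 6))
  fr <- friedman_test(m)
  expect_equal(fr$chi2, 6)
  expect_equal(fr$df, 2)
  expect_equal(friedman_test(matrix(5, 4, 3))$chi2, 0)  # all tied
  set.seed(37)
  m2 <- matrix(rnorm(48), 12, 4)  # tie-free: equals stats::friedman.test
  fr2 <- friedman_test(m2)
  ref <- friedman.test(m2)
  expect_equal(fr2$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fr2$p, ref$p.value, tolerance = 1e-12)
  expect_error(friedman_test(matrix(1, 5, 2)), "k >= 3")
})

test_that("stats_battery assembles all blocks", {
  set.seed(41)
  m <- matrix(rnorm(48, rep(c(90, 88, 68, 44), each = 12), 6), 12, 4)
  colnames(m) <- c(0, 3, 7, 10)
  b <- stats_battery(m, "PI")
  expect_identical(nrow(b$normality), 4L)
  expect_s3_class(b$anova, "rm_anova_result")
  expect_identical(nrow(b$posthoc), 6L)
  expect_false(is.null(b$friedman))
  expect_output(print(b), "partial eta")
})
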