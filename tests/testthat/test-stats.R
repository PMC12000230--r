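test_that("normality check enforces its preconditions and detects skew", {
  expect_error(shapiro_normality(c(1, 2)), "between 3 and 5000")
  expect_error(shapiro_normality(rep(1, 10)), "constant")
  set.seed(14)
  norm_p <- vapply(1:20, function(i) shapiro_normality(rnorm(50))$p, numeric(1))
  expo_p <- vapply(1:20, function(i) shapiro_normality(rexp(50))$p, numeric(1))
  expect_gte(mean(norm_p > 0.05), 0.9)
  expect_gte(mean(expo_p < 0.05), 0.9)
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  # fixed worked table: 4 subjects x 3 stages
  m <- matrix(c(30, 28, 16, 34,
                14, 18, 10, 22,
                24, 20, 18, 30), nrow = 4,
              dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  an <- rm_anova(m)
  expect_lt(abs(an$F - oracle_rm_anova_F(m)), 1e-10)
  expect_identical(c(an$df1, an$df2), c(2, 6))
  # and agrees with aov's stage F in the within-subject stratum
  long <- data.frame(y = as.vector(m),
                     subject = factor(rep(rownames(m), 3)),
                     stage = factor(rep(colnames(m), each = 4)))
  ref <- summary(stats::aov(y ~ stage + Error(subject), long))
  F_aov <- ref[["Error: Within"]][[1]]["stage", "F value"]
  expect_equal(an$F, F_aov, tolerance = 1e-10)
})

test_that("ANOVA F is invariant to constant shifts and subject relabeling", {
  set.seed(3)
  m <- matrix(rnorm(30), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("P", c(0, 2, 4, 6, 8))))
  a1 <- rm_anova(m)
  a2 <- rm_anova(m + 100)
  a3 <- rm_anova(m[sample(6), ])
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_equal(a1$F, a3$F, tolerance = 1e-12)
})

test_that("degenerate ANOVA tables follow the documented rules", {
  m <- matrix(rep(c(3, 5, 9), each = 4), nrow = 4)  # no residual, no...
  # identical values within each stage: stage effect with zero residual
  an <- rm_anova(m)
  expect_identical(an$F, Inf)
  expect_identical(an$p, 0)
  m2 <- matrix(5, nrow = 4, ncol = 3)                # everything identical
  an2 <- rm_anova(m2)
  expect_identical(an2$F, 0)
  expect_identical(an2$p, 1)
  expect_error(rm_anova(matrix(1:4, nrow = 2, ncol = 2)), "3 complete-case")
  # subjects with missing stages are dropped, retained n reported
  m3 <- matrix(rnorm(20), nrow = 5)
  m3[1, 2] <- NA
  expect_identical(rm_anova(m3)$n, 4L)
})

test_that("a programmed stage effect is detected with high power", {
  set.seed(8)
  hits <- vapply(1:30, function(i) {
    # stage means spanning ~3 residual SDs across the range
    m <- matrix(rnorm(30, sd = 0.6), nrow = 6) +
      matrix(rep(seq(0, 2, length.out = 5), each = 6), nrow = 6)
    rm_anova(m)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("post-hoc contrasts vs the reference are Holm-corrected", {
  set.seed(21)
  base <- rnorm(6, 100, 5)
  m <- cbind(P0 = base, P2 = base - 3 + rnorm(6, 0, 1),
             P4 = base - 6 + rnorm(6, 0, 1), P8 = base)
  ph <- posthoc_vs_reference(m, "P0")
  expect_identical(attr(ph, "correction"), "holm")
  expect_equal(ph$p_adj, stats::p.adjust(ph$p_raw, "holm"))
  expect_true(all(ph$p_adj >= ph$p_raw))
  bon <- posthoc_vs_reference(m, "P0", correction = "bonferroni")
  expect_true(all(ph$p_adj <= bon$p_adj + 1e-15))   # Holm dominates Bonferroni
  # Holm's step-down rule applied by hand to {0.01, 0.02, 0.04}
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "holm"),
               c(0.03, 0.04, 0.04))
  # a stage identical to the reference: zero difference, p = 1
  self <- ph[ph$stage == "P8", ]
  expect_equal(self$estimate, 0)
  expect_identical(self$t, 0)
  expect_identical(self$p_raw, 1)
  expect_error(posthoc_vs_reference(m, "P9"), "not in table")
})

test_that("t-test wrapper reproduces hand computations and edge rules", {
  a <- c(12.1, 13.4, 11.9, 14.2, 12.8)
  b <- c(11.0, 12.9, 12.1, 13.0, 11.8)
  tt <- t_tests(a, b, paired = TRUE)
  expect_equal(tt$t, oracle_paired_t(a, b), tolerance = 1e-12)
  expect_equal(tt$estimate, mean(a) - mean(b))
  # paired against a constant shift: difference is exactly the shift
  tc <- t_tests(a, a + 2.5, paired = TRUE)
  expect_equal(tc$estimate, -2.5)
  expect_identical(t_tests(a, a, paired = TRUE)$t, 0)
  expect_identical(t_tests(a, a, paired = TRUE)$p, 1)
  expect_error(t_tests(a, b[1:3], paired = TRUE), "equal lengths")
  expect_error(t_tests(a, 1), "n >= 2")
  # Welch vs pooled differ under unequal variances
  set.seed(2)
  x <- rnorm(8); y <- rnorm(20, sd = 5)
  expect_false(isTRUE(all.equal(t_tests(x, y)$df,
                                t_tests(x, y, var_equal = TRUE)$df)))
  # power: clearly separated arms are detected nearly always
  hits <- vapply(1:40, function(i)
    t_tests(rnorm(8), rnorm(8, 2))$p < 0.05, logical(1))
  expect_gte(mean(hits), 0.9)
})
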