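# explicit sum-of-squares oracle for the one-way repeated-measures design
ss_oneway <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_level <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_level - ss_subj
  F <- (ss_level / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = F, eta = ss_level / (ss_level + ss_err))
}

test_that("one-way repeated-measures ANOVA matches the SS decomposition", {
  m <- matrix(c(30, 28, 16, 34,
                14, 18, 10, 22,
                24, 20, 18, 30), nrow = 4)  # 4 subjects x 3 levels
  r <- rm_anova_oneway(m)
  o <- ss_oneway(m)
  expect_equal(r$statistic, o$F, tolerance = 1e-10)
  expect_equal(r$effect_size, o$eta, tolerance = 1e-10)
  expect_equal(r$df, c(2, 6))
  expect_true(r$p_value > 0 && r$p_value < 1)
})

test_that("degenerate and invalid ANOVA tables are handled", {
  expect_equal(rm_anova_oneway(matrix(5, 4, 3))$statistic, 0)
  expect_error(rm_anova_oneway(matrix(c(1, NA, 3, 4), 2)), "complete")
  expect_error(rm_anova_oneway(matrix(1:3, 3, 1)), "at least 2")
})

test_that("two-level repeated ANOVA equals the squared paired t", {
  set.seed(23)
  m <- matrix(rnorm(20), 10, 2)
  a <- rm_anova_oneway(m)
  t2 <- t_tests(m[, 1], m[, 2], "paired")$statistic^2
  expect_equal(a$statistic, t2, tolerance = 1e-10)
})

test_that("ANOVA F is invariant to per-subject offsets", {
  set.seed(24)
  m <- matrix(rnorm(30), 10, 3)
  shifted <- m + rnorm(10) %o% rep(1, 3)
  expect_equal(rm_anova_oneway(shifted)$statistic,
               rm_anova_oneway(m)$statistic, tolerance = 1e-10)
})

test_that("two-way repeated ANOVA matches a projection oracle and the margins", {
  set.seed(25)
  n <- 8
  arr <- array(rnorm(n * 3 * 2), c(n, 3, 2))
  r <- rm_anova_twoway(arr)

  # oracle for factor A: one-way rm ANOVA on the B-averaged margin,
  # a classical identity for balanced within-subject designs
  margin <- apply(arr, c(1, 2), mean)
  expect_equal(r$A$statistic, rm_anova_oneway(margin)$statistic,
               tolerance = 1e-10)
  expect_equal(r$A$df, c(2, 14))
  expect_equal(r$B$df, c(1, 7))
  expect_equal(r$interaction$df, c(2, 14))

  # projection oracle for the interaction: SS_AB from cell means, error SS
  # as the residual of the saturated-minus-three-way linear model
  grand <- mean(arr)
  cellm <- apply(arr, c(2, 3), mean)
  am <- rowMeans(cellm); bm <- colMeans(cellm)
  ss_int <- n * sum((cellm - outer(am, rep(1, 2)) -
                       outer(rep(1, 3), bm) + grand)^2)
  df <- data.frame(y = as.vector(arr),
                   s = factor(rep(1:n, 6)),
                   A = factor(rep(rep(1:3, each = n), 2)),
                   B = factor(rep(1:2, each = 3 * n)))
  res <- residuals(lm(y ~ s * A + s * B + A * B, data = df))
  ss_err <- sum(res^2)
  F_int <- (ss_int / 2) / (ss_err / (2 * (n - 1)))
  expect_equal(r$interaction$statistic, F_int, tolerance = 1e-8)
})

test_that("additive two-factor data show no interaction", {
  n <- 10
  subj <- rnorm(n)
  A <- c(0, 1, 2); B <- c(0, 5)
  arr <- array(0, c(n, 3, 2))
  for (i in 1:3) for (j in 1:2) arr[, i, j] <- subj + A[i] + B[j]
  r <- rm_anova_twoway(arr)
  expect_equal(r$interaction$statistic, 0, tolerance = 1e-9)
  expect_gt(r$A$statistic, 1e6)  # deterministic effects, near-zero error
})

test_that("t-tests match the textbook formula and handle edge cases", {
  x <- c(5.1, 4.8, 6.2, 5.6, 5.0, 5.9)
  r <- t_tests(x, 5, "one_sample")
  t_manual <- (mean(x) - 5) / (sd(x) / sqrt(6))
  expect_equal(r$statistic, t_manual, tolerance = 1e-12)
  expect_equal(r$df, 5)
  expect_equal(r$effect_size, (mean(x) - 5) / sd(x), tolerance = 1e-12)

  y <- c(4.9, 5.0, 5.8, 5.1, 4.7, 5.5)
  rp <- t_tests(x, y, "paired")
  d <- x - y
  expect_equal(rp$statistic, mean(d) / (sd(d) / sqrt(6)), tolerance = 1e-12)

  expect_error(t_tests(c(1, 1, 1), 0, "one_sample"), "zero variance")
  expect_equal(t_tests(x, x, "paired")$statistic, 0)   # identical pairs
  expect_error(t_tests(1:3, 1:4, "paired"), "equal length")

  r1 <- t_tests(x, 5, "one_sample", tails = "greater")
  expect_lt(r1$p_value, r$p_value)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2.5, 3, 4.2, 7)
  expect_equal(pearson_r(x, 2 * x + 1)$effect_size, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$effect_size, -1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(2, 5)), "constant")
  expect_error(pearson_r(x, x[-1]), "equal length")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")

  # null simulation: independent normals, n = 1000
  set.seed(26)
  rs <- vapply(1:50, function(i)
    pearson_r(rnorm(1000), rnorm(1000))$effect_size, numeric(1))
  expect_gt(mean(abs(rs) < 0.1), 0.98)
})
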