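# Regression, Kruskal-Wallis and two-way ANOVA wrappers, checked against
# hand arithmetic.

test_that("ordinary least squares recovers closed-form coefficients", {
  r <- suppressWarnings(linear_regression(0:2, 0:2))  # exact fit
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  # by hand: Sxy = 1, Sxx = 2 -> slope .5, intercept .5;
  # SS_res = 1.5, SS_tot = 2 -> R^2 = 0.25
  r2 <- linear_regression(0:2, c(0, 2, 1))
  expect_equal(r2$slope, 0.5)
  expect_equal(r2$intercept, 0.5)
  expect_equal(r2$r_squared, 0.25)
  expect_equal(r2$n, 3)
  # flat response
  r3 <- linear_regression(1:5, rep(2, 5))
  expect_equal(r3$slope, 0)
  expect_equal(r3$r_squared, 0)
  expect_error(linear_regression(rep(1, 4), 1:4), "degenerate design")
  expect_error(linear_regression(1:3, 1:4), "equal length")
})

test_that("regression R^2 is invariant under affine rescaling of x and y", {
  set.seed(17)
  x <- runif(20); y <- 2 * x + rnorm(20, 0, 0.3)
  base <- linear_regression(x, y)$r_squared
  expect_equal(linear_regression(3 * x - 5, y)$r_squared, base, tolerance = 1e-12)
  expect_equal(linear_regression(x, -0.2 * y + 11)$r_squared, base, tolerance = 1e-12)
})

test_that("Kruskal-Wallis reproduces hand-ranked statistics", {
  # two well-separated groups of 3: rank sums 6 and 15,
  # H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  kt <- kruskal_wallis(list(c(1, 2, 3), c(101, 102, 103)))
  expect_equal(kt$statistic, 27 / 7, tolerance = 1e-9)
  expect_equal(kt$dof, 1)
  expect_lt(kt$p_value, 0.05)
  # two identical groups: H = 0, p = 1
  kt2 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kt2$statistic, 0, tolerance = 1e-12)
  expect_equal(kt2$p_value, 1)
  # all values identical: degenerate
  kt3 <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(kt3$statistic, 0)
  expect_equal(kt3$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")

  # independent oracle: tie-corrected H computed from first principles
  set.seed(4)
  for (k in 1:5) {
    g1 <- sample(1:6, 5, replace = TRUE)
    g2 <- sample(1:6, 7, replace = TRUE)
    g3 <- sample(1:6, 4, replace = TRUE)
    pooled <- c(g1, g2, g3)
    rk <- rank(pooled)
    sizes <- c(5, 7, 4); nn <- sum(sizes)
    rs <- tapply(rk, rep(1:3, sizes), sum)
    h <- 12 / (nn * (nn + 1)) * sum(rs^2 / sizes) - 3 * (nn + 1)
    ties <- table(pooled)
    h <- h / (1 - sum(ties^3 - ties) / (nn^3 - nn))
    expect_equal(kruskal_wallis(list(g1, g2, g3))$statistic, h, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(8)
  groups <- list(rnorm(9), rnorm(7, 1), rnorm(8, 0.5))
  h0 <- kruskal_wallis(groups)$statistic
  for (f in list(exp, function(x) x^3, function(x) atan(x) * 10)) {
    expect_equal(kruskal_wallis(lapply(groups, f))$statistic, h0,
                 tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis p approximates the exact permutation null", {
  # small two-group dataset: enumerate all label assignments
  x <- c(3.1, 4.2, 5.4, 2.2, 1.8, 0.7, 3.9, 2.9)
  h_obs <- kruskal_wallis(list(x[1:4], x[5:8]))$statistic
  combos <- combn(8, 4)
  h_perm <- apply(combos, 2, function(ix)
    kruskal_wallis(list(x[ix], x[-ix]))$statistic)
  p_perm <- mean(h_perm >= h_obs - 1e-12)
  p_chisq <- kruskal_wallis(list(x[1:4], x[5:8]))$p_value
  expect_lt(abs(p_perm - p_chisq), 0.15)
})

test_that("balanced two-way ANOVA matches textbook sums of squares", {
  # 2x2 with 3 replicates per cell, known cell means, small fixed noise
  a <- rep(c("a1", "a2"), each = 6)
  b <- rep(rep(c("b1", "b2"), each = 3), 2)
  mu <- c(10, 12, 14, 20)[as.integer(interaction(a, b))]
  eps <- c(0.1, -0.2, 0.1, 0, 0.2, -0.1, -0.1, 0.1, 0, 0.2, -0.2, 0)
  y <- mu + eps
  res <- two_way_anova(y, a, b)
  # oracle: model-comparison sums of squares via explicit least squares
  d <- data.frame(y = y, a = factor(a), b = factor(b))
  rss <- function(f) sum(residuals(lm(f, data = d))^2)
  df_res <- 12 - 4
  ms_res <- rss(y ~ a * b) / df_res
  f_a <- ((rss(y ~ b) - rss(y ~ a + b)) / 1) / ms_res
  f_b <- ((rss(y ~ a) - rss(y ~ a + b)) / 1) / ms_res
  f_ab <- ((rss(y ~ a + b) - rss(y ~ a * b)) / 1) / ms_res
  expect_equal(unname(res$factor_a["F"]), f_a, tolerance = 1e-9)
  expect_equal(unname(res$factor_b["F"]), f_b, tolerance = 1e-9)
  expect_equal(unname(res$interaction["F"]), f_ab, tolerance = 1e-9)
  expect_equal(res$residual_dof, df_res)
})

test_that("pure main effects leave other terms near zero", {
  set.seed(5)
  a <- rep(c("x", "y"), each = 8)
  b <- rep(rep(c("u", "v"), each = 4), 2)
  y <- ifelse(a == "y", 3, 0) + rnorm(16, 0, 1e-3)
  res <- two_way_anova(y, a, b)
  expect_gt(res$factor_a["F"], 1e4)
  expect_lt(res$factor_b["F"], 10)
  expect_lt(res$interaction["F"], 10)
})

test_that("unbalanced designs use Type II decomposition; empty cells error", {
  set.seed(12)
  a <- c(rep("a1", 7), rep("a2", 5))
  b <- c(rep("b1", 4), rep("b2", 3), rep("b1", 2), rep("b2", 3))
  y <- rnorm(12) + (a == "a2") * 2 + (b == "b2") * 1
  res <- two_way_anova(y, a, b)
  d <- data.frame(y = y, a = factor(a), b = factor(b))
  rss <- function(f) sum(residuals(lm(f, data = d))^2)
  ms_res <- rss(y ~ a * b) / (12 - 4)
  expect_equal(unname(res$factor_a["F"]),
               (rss(y ~ b) - rss(y ~ a + b)) / ms_res, tolerance = 1e-9)
  expect_equal(unname(res$factor_b["F"]),
               (rss(y ~ a) - rss(y ~ a + b)) / ms_res, tolerance = 1e-9)
  # empty cell is reported by name
  a2 <- c("a1", "a1", "a2", "a2")
  b2 <- c("b1", "b1", "b1", "b1")
  expect_error(two_way_anova(rnorm(4), a2, b2), ">= 2 levels")
  a3 <- c("a1", "a1", "a2", "a2", "a2")
  b3 <- c("b1", "b2", "b1", "b1", "b1")
  expect_error(two_way_anova(rnorm(5), a3, b3), "empty cell")
})

test_that("pairwise rank comparisons cover all group pairs", {
  g <- list(low = c(1, 2, 3), mid = c(2, 3, 4), high = c(10, 11, 12))
  pw <- pairwise_kruskal(g)
  expect_equal(nrow(pw), 3)
  expect_setequal(paste(pw$group1, pw$group2),
                  c("low mid", "low high", "mid high"))
  expect_lt(pw$p_value[pw$group1 == "low" & pw$group2 == "high"], 0.05)
})
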