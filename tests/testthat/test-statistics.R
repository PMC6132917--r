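test_that("Mann-Whitney U uses the first-sample convention and exact enumeration", {
  # complete separation: U of the first (smaller-valued) sample is 0
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")
  # fully tied samples sit at the null centre n1*n2/2
  mwt <- mann_whitney(c(1, 2, 3), c(1, 2, 3), mode = "normal")
  expect_equal(mwt$U, 4.5)
  # reversing the samples mirrors U around n1*n2/2
  expect_equal(mann_whitney(c(3, 4), c(1, 2))$U, 4)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
  expect_error(mann_whitney(c(1, 1), c(1, 2), mode = "exact"), "ties")
})

test_that("exact Mann-Whitney p matches full enumeration on random samples", {
  set.seed(91)
  for (k in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    mw <- mann_whitney(x, y, mode = "exact")
    expect_equal(mw$p.value, mw_exact_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("2x2 chi-square reproduces hand values and is symmetric", {
  tab <- matrix(c(18, 6, 11, 16), 2, byrow = TRUE)
  ct <- chi2_2x2(tab)
  expect_equal(round(ct$statistic, 3), 6.080)
  expect_equal(ct$df, 1L)
  expect_lt(ct$p.value, 0.05)
  # identical row proportions: statistic 0
  expect_equal(chi2_2x2(matrix(c(10, 20, 5, 10), 2, byrow = TRUE))$statistic,
               0, tolerance = 1e-12)
  # perfect association with margins 10: every expected cell 5
  expect_equal(chi2_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  # invariance to transposition and to swapping both row and column order
  expect_equal(chi2_2x2(t(tab))$statistic, ct$statistic)
  expect_equal(chi2_2x2(tab[2:1, 2:1])$statistic, ct$statistic)
  expect_error(chi2_2x2(matrix(c(5, 0, 7, 0), 2)), "margins")
  expect_error(chi2_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("covariate-adjusted group F has the study df structure and matches the oracle", {
  set.seed(101)
  n1 <- 27; n2 <- 24
  group <- factor(rep(c("control", "patient"), c(n1, n2)))
  covariate <- runif(n1 + n2, 0, 0.2)
  dvs <- data.frame(ge = rnorm(n1 + n2) + 0.5 * (group == "patient"),
                    bc = rnorm(n1 + n2))
  res <- ancova_group(dvs, group, covariate)
  expect_equal(res$per_dv$df1, c(1, 1))
  expect_equal(res$per_dv$df2, c(48, 48))   # n - groups - covariate - 1
  for (i in 1:2)
    expect_equal(res$per_dv$F[i],
                 ancova_F_oracle(dvs[[i]], group, covariate),
                 tolerance = 1e-10)
  expect_true(res$wilks$lambda > 0 && res$wilks$lambda < 1)
})

test_that("a constant covariate reduces the comparison to one-way ANOVA", {
  set.seed(111)
  group <- factor(rep(c("a", "b"), c(10, 12)))
  y <- rnorm(22) + (group == "b")
  res <- ancova_group(data.frame(y = y), group, rep(0.07, 22))
  aovF <- summary(stats::aov(y ~ group))[[1]]$`F value`[1]
  expect_equal(res$per_dv$F, aovF, tolerance = 1e-10)
  expect_equal(res$per_dv$df2, 20)
})

test_that("the adjusted group F keeps its nominal type-I error under permutation", {
  set.seed(121)
  n <- 40
  group <- factor(rep(c("a", "b"), each = n / 2))
  covariate <- runif(n)
  y <- rnorm(n) + 0.5 * covariate
  B <- 1000
  crit <- qf(0.95, 1, n - 3)
  hits <- 0
  for (b in 1:B) {
    gp <- sample(group)
    if (ancova_F_oracle(y, gp, covariate) > crit) hits <- hits + 1
  }
  phat <- hits / B
  se <- sqrt(0.05 * 0.95 / B)
  expect_lt(abs(phat - 0.05), 3.3 * se)
})

test_that("stepwise selection recovers a planted signal and respects the forced block", {
  set.seed(131)
  n <- 100
  x1 <- rnorm(n)
  noise <- rnorm(n)
  covariate <- rnorm(n)
  y <- 2 * x1 + rnorm(n, sd = sd(x1) / 2)
  res <- forward_stepwise(y, data.frame(x1 = x1, noise = noise),
                          forced = data.frame(motion = covariate))
  expect_equal(res$selected, "x1")
  final <- res$steps[[length(res$steps)]]
  expect_gt(final$terms$B[final$terms$term == "x1"], 0)
  # forced covariate present in every step's model
  for (st in res$steps)
    expect_true("motion" %in% st$terms$term)
  # R^2 non-decreasing across steps
  r2 <- vapply(res$steps, `[[`, numeric(1), "r_squared")
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("step-1 R^2 equals the squared covariate correlation", {
  set.seed(141)
  n <- 50
  covariate <- rnorm(n)
  y <- 0.8 * covariate + rnorm(n)
  res <- forward_stepwise(y, data.frame(z = rnorm(n)),
                          forced = data.frame(motion = covariate),
                          p_enter = 1e-9)  # nothing qualifies
  expect_equal(res$steps[[1]]$r_squared, cor(y, covariate)^2,
               tolerance = 1e-12)
  expect_length(res$selected, 0)
})

test_that("standardized coefficients follow B * sd(x) / sd(y)", {
  set.seed(151)
  n <- 60
  x1 <- rnorm(n, sd = 3); x2 <- rnorm(n)
  cov <- rnorm(n)
  y <- x1 + 2 * x2 + rnorm(n)
  res <- forward_stepwise(y, data.frame(x1 = x1, x2 = x2),
                          forced = data.frame(motion = cov))
  final <- res$steps[[length(res$steps)]]$terms
  for (v in c("x1", "x2")) {
    row <- final[final$term == v, ]
    expect_equal(row$std_B, row$B * sd(get(v)) / sd(y), tolerance = 1e-12)
  }
})

test_that("collinear candidates are reported by name", {
  set.seed(161)
  n <- 30
  x <- rnorm(n)
  cov <- rnorm(n)
  y <- x + rnorm(n)
  expect_error(
    forward_stepwise(y, data.frame(x = x, copy = 2 * x + 3 * cov),
                     forced = data.frame(motion = cov)),
    "copy")
})

test_that("optional removal drops predictors whose p rises above p_remove", {
  set.seed(171)
  n <- 120
  z <- rnorm(n)
  x_proxy <- z + rnorm(n, sd = 0.4)   # enters first only via z
  y <- 3 * z + rnorm(n, sd = 0.5)
  cov <- rnorm(n)
  res <- forward_stepwise(y, data.frame(proxy = x_proxy, z = z),
                          forced = data.frame(motion = cov),
                          p_enter = 0.05, p_remove = 0.10)
  expect_true("z" %in% res$selected)
})
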