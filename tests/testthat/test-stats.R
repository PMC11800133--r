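test_that("KS normality test is calibrated and has power", {
  set.seed(1)
  # type-I: fraction of normal samples rejected at alpha = 0.05 (the cached
  # Monte-Carlo null makes the 1000 repetitions cheap)
  rej <- mean(replicate(1000, ks_normality(rnorm(100), n_mc = 500)$p < 0.05))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
  # power: exponential data at n = 200 is rejected almost always
  pow <- mean(replicate(100, ks_normality(rexp(200), n_mc = 500)$p < 0.05))
  expect_gt(pow, 0.9)

  expect_error(ks_normality(rnorm(4)), "at least 5")
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("summary-form and raw-form t-tests agree exactly", {
  set.seed(2)
  x <- rnorm(30, 1, 2); y <- rnorm(45, 1.5, 2.5)
  raw <- ttest_two_sample(x, y)
  summ <- ttest_two_sample(summary_group(30, mean(x), sd(x)),
                           summary_group(45, mean(y), sd(y)))
  expect_identical(raw$statistic, summ$statistic)
  expect_identical(raw$p, summ$p)
  # against the reference implementation
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(raw$p, ref$p.value, tolerance = 1e-12)
  refw <- t.test(x, y)
  w <- ttest_two_sample(x, y, pooled = FALSE)
  expect_equal(w$p, refw$p.value, tolerance = 1e-12)
})

test_that("identical groups give t = 0, p = 1", {
  g <- summary_group(20, 5, 1)
  r <- ttest_two_sample(g, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(ttest_two_sample(rep(1, 5), rep(1, 5)), "variance")
})

test_that("t-test p approximates the exhaustive permutation oracle", {
  set.seed(3)
  x <- rnorm(5); y <- rnorm(5, 1)
  obs <- ttest_two_sample(x, y)$statistic
  pool <- c(x, y)
  combs <- combn(10, 5)
  tperm <- apply(combs, 2, function(idx)
    ttest_two_sample(pool[idx], pool[-idx])$statistic)
  p_perm <- mean(abs(tperm) >= abs(obs) - 1e-12)
  expect_lt(abs(ttest_two_sample(x, y)$p - p_perm), 0.1)
})

test_that("pooled t-test type-I error is near nominal at the study sizes", {
  set.seed(4)
  nsim <- 10000
  a <- matrix(rnorm(46 * nsim), ncol = nsim)
  b <- matrix(rnorm(97 * nsim), ncol = nsim)
  pv <- vapply(seq_len(nsim), function(i)
    ttest_two_sample(a[, i], b[, i])$p, numeric(1))
  rate <- mean(pv < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("correlations match closed forms and rank logic", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  expect_equal(correlation(x, 2 * x + 1)$r, 1)
  y <- x^3
  expect_equal(correlation(x, y, "spearman")$r, 1)
  expect_lt(correlation(x, y, "pearson")$r, 1)

  set.seed(5)
  u <- rnorm(12); v <- rnorm(12)
  got <- correlation(u, v)
  # from-scratch covariance formula
  r_direct <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  ref <- cor.test(u, v)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  expect_error(correlation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(correlation(1:2, 2:3), "at least 3")
})

test_that("2x2 tests match hand arithmetic and the exact oracle", {
  # n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) by hand
  hand <- 152 * (22 * 50 - 75 * 5)^2 / (97 * 55 * 27 * 125)
  got <- categorical_2x2(22, 75, 5, 50, method = "pearson")
  expect_equal(got$statistic, hand, tolerance = 1e-10)

  prop <- categorical_2x2(10, 20, 5, 10, method = "pearson")
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)

  f <- categorical_2x2(2, 3, 4, 1, method = "fisher")
  expect_equal(f$p, fisher_exact_oracle(2, 3, 4, 1), tolerance = 1e-12)

  expect_error(categorical_2x2(0, 0, 0, 0), "zero")
  expect_error(categorical_2x2(1.5, 2, 3, 4), "integers")
})

test_that("Fisher p equals exhaustive enumeration on all small tables", {
  for (a in 0:4) for (b in 0:4) for (c_ in 0:4) for (d in 0:4) {
    if (a + b + c_ + d == 0) next
    if ((a + b) == 0 || (c_ + d) == 0) next
    expect_equal(categorical_2x2(a, b, c_, d, method = "fisher")$p,
                 fisher_exact_oracle(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("logistic fit recovers null and configured effects", {
  set.seed(6)
  n <- 10000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  f0 <- logistic_fit(X, y)
  expect_lt(max(abs(f0$coefficients)), 0.05)
  expect_equal(unname(f0$or), rep(1, 2), tolerance = 0.06)

  beta1 <- log(1.686) / 0.1
  alps <- rnorm(5000, 1.34, 0.24)
  y2 <- rbinom(5000, 1, plogis(-6 + beta1 * alps))
  f1 <- logistic_fit(cbind(alps = alps), y2, or_scale = 0.1)
  expect_gt(f1$or_scaled[["alps"]], 1.55)
  expect_lt(f1$or_scaled[["alps"]], 1.85)
})

test_that("logistic fit matches an independent Newton-Raphson solver", {
  set.seed(7)
  X <- cbind(a = rnorm(50), b = runif(50), c = rnorm(50, 2))
  y <- rbinom(50, 1, plogis(0.5 + 0.8 * X[, 1] - 1.2 * X[, 2]))
  f <- logistic_fit(X, y)
  oracle <- logistic_newton_oracle(X, y)
  expect_equal(unname(c(f$intercept, f$coefficients)), oracle,
               tolerance = 1e-8)
})

test_that("per-0.1 rescaling equals refitting the rescaled predictor", {
  set.seed(8)
  x <- rnorm(400, 1.4, 0.25)
  y <- rbinom(400, 1, plogis(-4 + 3 * x))
  f_nat <- logistic_fit(cbind(alps = x), y, or_scale = 0.1)
  f_dec <- logistic_fit(cbind(alps10 = x / 0.1), y)
  expect_equal(unname(f_nat$or_scaled), unname(f_dec$or), tolerance = 1e-6)
  expect_equal(unname(f_nat$or_scaled), unname(exp(0.1 * f_nat$coefficients)))
})

test_that("separation and degenerate designs are rejected", {
  x <- c(rep(0, 20), rep(1, 20)) + rnorm(40, sd = 0.01)
  y <- c(rep(0, 20), rep(1, 20))
  expect_error(logistic_fit(cbind(sep = x), y), "separation.*sep")
  expect_error(logistic_fit(cbind(k = rep(2, 40)), y), "constant")
  X <- cbind(a = rnorm(40), b = 0)
  X[, 2] <- 2 * X[, 1]
  expect_error(logistic_fit(X, y), "singular")
})

test_that("linear fit matches the normal-equation oracle", {
  set.seed(9)
  X <- matrix(rnorm(400), 100, 4)
  beta <- c(2, -1, 0.5, 3)
  y <- 1.5 + X %*% beta + rnorm(100, sd = 0.3)
  f <- linear_fit(X, y)
  X1 <- cbind(1, X)
  oracle <- solve(t(X1) %*% X1, t(X1) %*% y)
  expect_equal(unname(f$coefficients), as.vector(oracle), tolerance = 1e-10)

  y_exact <- 2 + 3 * X[, 1]
  fe <- suppressWarnings(linear_fit(X[, 1, drop = FALSE], y_exact))
  expect_lt(max(abs(fe$residuals)), 1e-10)
  expect_equal(fe$r_squared, 1)

  # predictors orthogonal to each other and the intercept decouple into
  # simple regressions
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100), 50, 2))))[, 2:3]
  yy <- Q %*% c(2, -3) + rnorm(50, sd = 0.1)
  fm <- linear_fit(Q, yy)
  s1 <- linear_fit(Q[, 1, drop = FALSE], yy)
  expect_equal(unname(fm$coefficients[2]), unname(s1$coefficients[2]),
               tolerance = 1e-8)

  expect_error(linear_fit(cbind(a = 1:10, b = 2 * (1:10)), rnorm(10)),
               "rank")
})

test_that("covariate screen keeps sub-threshold and mandated variables", {
  set.seed(10)
  n <- 400
  d <- data.frame(age = rnorm(n, 60, 10), sex = rbinom(n, 1, 0.4),
                  nihss_baseline = rnorm(n, 6, 4),
                  strong = rnorm(n), noise = rnorm(n))
  d$outcome <- rbinom(n, 1, plogis(1.5 * d$strong))
  sel <- covariate_screen(d, c("strong", "noise"), "outcome")
  expect_true("strong" %in% sel$selected)
  expect_true(all(c("age", "sex", "nihss_baseline") %in% sel$selected))

  all_in <- covariate_screen(d, c("strong", "noise"), "outcome",
                             threshold = 1.0)
  expect_true(all(c("strong", "noise") %in% all_in$selected))

  none <- covariate_screen(d, character(0), "outcome")
  expect_setequal(none$selected, c("age", "sex", "nihss_baseline"))

  # null calibration: about 10% of pure-noise candidates pass p < 0.1
  hits <- replicate(300, {
    dd <- data.frame(z = rnorm(200), outcome = rbinom(200, 1, 0.5))
    "z" %in% covariate_screen(dd, "z", "outcome",
                              always_include = character(0))$selected
  })
  expect_gt(mean(hits), 0.05)
  expect_lt(mean(hits), 0.16)
})
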