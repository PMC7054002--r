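test_that("OLS recovers an exact line and matches lm inference", {
  x <- 1:10
  r <- ols_fit(x, 2 * x)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  expect_equal(diff(r$slope_ci), 0, tolerance = 1e-12)

  set.seed(301)
  y <- 1.5 * x + rnorm(10)
  r2 <- ols_fit(x, y)
  ref <- summary(lm(y ~ x))
  expect_equal(r2$slope, unname(coef(ref)[2, 1]))
  expect_equal(r2$slope_se, unname(coef(ref)[2, 2]))
  expect_equal(r2$p_value, unname(coef(ref)[2, 4]))
  expect_equal(r2$r_squared, ref$r.squared)
  expect_error(ols_fit(rep(1, 5), rnorm(5)), "constant")
})

test_that("OLS slope recovery from the allometry generator", {
  # slope 0.9, noise tuned for R2 near 0.3, n = 142 specimens
  slopes <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    x <- runif(142, 3, 4.2)
    y <- 0.9 * x + rnorm(142, sd = 0.9 * sd(x) * sqrt(0.7 / 0.3))
    ols_fit(x, y)$slope
  }, 0)
  expect_lt(abs(mean(slopes) - 0.9), 0.05)
})

test_that("PGLS equals OLS on a star phylogeny and matches the dense oracle", {
  star <- ape::stree(12, type = "star")
  star$edge.length <- rep(1, 12)
  set.seed(311)
  x <- setNames(rnorm(12), star$tip.label)
  y <- setNames(2 + 0.5 * x + rnorm(12), star$tip.label)
  po <- pgls_fit(star, x, y)
  oo <- ols_fit(unname(x), unname(y))
  expect_equal(po$slope, oo$slope, tolerance = 1e-8)
  expect_equal(po$intercept, oo$intercept, tolerance = 1e-8)
  expect_equal(po$slope_se, oo$slope_se, tolerance = 1e-8)

  # explicit 3-tip GLS formula
  tr <- three_tip_tree()
  C <- phylo_covariance(tr, c("A", "B", "C"))
  xv <- setNames(c(1, 2, 4), c("A", "B", "C"))
  yv <- setNames(c(0.5, 1.1, 3.0), c("A", "B", "C"))
  X <- cbind(1, xv)
  beta <- solve(t(X) %*% solve(C) %*% X, t(X) %*% solve(C) %*% yv)
  fit <- pgls_fit(tr, xv, yv)
  expect_equal(fit$intercept, unname(beta[1, 1]), tolerance = 1e-10)
  expect_equal(fit$slope, unname(beta[2, 1]), tolerance = 1e-10)
})

test_that("PGLS agrees with the nlme GLS reference under Brownian correlation", {
  skip_if_not_installed("nlme")
  tr <- anthropoid_tree()
  x <- setNames(simulate_bm(tr, rate = 1, seed = 11)$tips[, 1], tr$tip.label)
  y <- setNames(0.5 * x + simulate_bm(tr, rate = 0.3, seed = 12)$tips[, 1],
                tr$tip.label)
  fit <- pgls_fit(tr, x, y)
  df <- data.frame(y = y, x = x, nm = names(y))
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, tr, form = ~nm))
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(fit$slope_se, sqrt(diag(ref$varBeta))[2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PGLS validates its tip matching", {
  tr <- three_tip_tree()
  expect_error(pgls_fit(tr, setNames(1:2, c("A", "B")),
                        setNames(1:3, c("A", "B", "C"))), "missing from x")
  expect_error(pgls_fit(tr, setNames(1:3, c("A", "B", "D")),
                        setNames(1:3, c("A", "B", "C"))), "D")
})

test_that("multivariate shape-size regression matches its univariate special case", {
  set.seed(321)
  x <- rnorm(30)
  y <- 1.2 * x + rnorm(30, sd = 0.5)
  ss <- shape_size_regression(matrix(y, ncol = 1), x, n_perm = 199, seed = 5)
  expect_equal(ss$r_squared, ols_fit(x, y)$r_squared, tolerance = 1e-10)

  # exact linear dependence across all columns
  Y <- cbind(2 * x, -x, 0.5 * x + 3)
  ss2 <- shape_size_regression(Y, x, n_perm = 199, seed = 5)
  expect_equal(ss2$r_squared, 1, tolerance = 1e-12)
  expect_equal(ss2$p_value, 1 / 200)
  expect_error(shape_size_regression(Y, rep(1, 30), n_perm = 199, seed = 1),
               "constant")
})

test_that("shape-size permutation test holds its size under the null", {
  rej <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    Y <- matrix(rnorm(25 * 4), 25, 4)
    x <- rnorm(25)
    shape_size_regression(Y, x, n_perm = 99, seed = 6000 + i)$p_value <= 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("ANCOVA returns near-zero interaction F for duplicated groups", {
  set.seed(331)
  x <- runif(30, 0, 1)
  y <- 1 + 2 * x + rnorm(30, sd = 0.1)
  a <- ancova(c(x, x), c(y, y), rep(c("p", "q"), each = 30))
  expect_lt(a$F_slopes, 1e-8)
  expect_lt(a$F_intercepts, 1e-8)
  expect_error(ancova(x, y, rep("p", 30)), "2 groups")
})

test_that("ANCOVA detects a grade shift and matches the classical construction", {
  set.seed(341)
  x <- runif(140, 3, 4.2)
  g <- rep(c("low", "high"), each = 70)
  y <- ifelse(g == "high", 0.5, 0) + 0.62 * x + rnorm(140, sd = 0.1)
  a <- ancova(x, y, g)
  expect_lt(a$p_intercepts, 1e-10)
  expect_gt(a$p_slopes, 0.001)   # no interaction was simulated
  # partial-F against the explicit model comparison
  f_ref <- anova(lm(y ~ x + g), lm(y ~ x * g))$F[2]
  expect_equal(a$F_slopes, f_ref)
})

test_that("isometry verdicts follow the confidence interval", {
  expect_equal(isometry_test(c(0.666, 1.128)), "isometry-not-rejected")
  expect_equal(isometry_test(c(0.25, 0.99)), "negative-allometry")
  expect_equal(isometry_test(c(1.01, 1.4)), "positive-allometry")
  r <- ols_fit(1:10, 2 * (1:10) + rnorm(10, sd = 1e-6))
  expect_equal(isometry_test(r), "positive-allometry")
})

test_that("allometry tables derive cube-root logs and round-trip", {
  tab <- allometry_table("s1", "sp", "G", Vol = 8, VolSC = 27, L = exp(2))
  expect_equal(tab$ln_Vol, log(2))     # log of cube root of 8
  expect_equal(tab$ln_VolSC, log(3))
  expect_equal(tab$ln_L, 2)
  expect_error(allometry_table("s", "sp", "G", Vol = -1, VolSC = 1, L = 1),
               "positive")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_allometry_table(tab, tf)
  back <- read_allometry_table(tf)
  expect_equal(back$ln_VolSC, tab$ln_VolSC, tolerance = 1e-12)
})

test_that("regression outputs are invariant to observation ordering", {
  set.seed(351)
  x <- rnorm(20); y <- 1 + x + rnorm(20)
  perm <- sample(20)
  r1 <- ols_fit(x, y); r2 <- ols_fit(x[perm], y[perm])
  expect_equal(r1$slope, r2$slope)
  expect_equal(r1$slope_ci, r2$slope_ci)
})
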