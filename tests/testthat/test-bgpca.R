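test_that("two-group geometry forces the single axis through the means", {
  tab <- tiny_two_group_table()
  m <- fit_bgpca(tab)
  expect_equal(ncol(m$rotation), 1L)
  # means (0,0) and (2,0): axis along x
  expect_equal(abs(m$rotation[, 1]), c(1, 0))
  sc <- project_bgpca(m, c(1.5, 7))
  expect_equal(unname(sc[1, 1]), 0.5)
})

test_that("identical group means flag a degenerate model", {
  X <- rbind(c(1, 2), c(3, 0), c(1, 2), c(3, 0))
  tab <- shape_table(X, paste0("s", 1:4), paste0("sp", 1:4),
                     c("a", "a", "b", "b"))
  m <- fit_bgpca(tab)
  expect_true(m$degenerate)
  expect_lt(max(m$eigenvalues), 1e-20)
})

test_that("bgPCA matches a brute-force eigendecomposition of the group-mean covariance", {
  set.seed(101)
  for (rep in 1:10) {
    n <- 40; p <- 6; g <- 4
    grp <- sample(rep(letters[1:g], each = n / g))
    X <- matrix(rnorm(n * p), n, p) +
      outer(as.integer(factor(grp)), seq_len(p))
    tab <- shape_table(X, paste0("s", 1:n), paste0("sp", 1:n), grp)
    m <- fit_bgpca(tab)
    gm <- t(sapply(sort(unique(grp)), function(gg)
      colMeans(X[grp == gg, , drop = FALSE])))
    S <- cov(gm)
    e <- eigen(S, symmetric = TRUE)
    expect_equal(m$eigenvalues, e$values[1:(g - 1)], tolerance = 1e-8)
    # eigenvectors up to sign
    for (j in 1:(g - 1)) {
      expect_equal(abs(sum(m$rotation[, j] * e$vectors[, j])), 1,
                   tolerance = 1e-8)
    }
    # scores = centered data times eigenvectors
    expect_equal(unname(m$scores),
                 unname(sweep(X, 2, colMeans(gm)) %*% m$rotation),
                 tolerance = 1e-10)
  }
})

test_that("bgPCA model invariants hold", {
  set.seed(111)
  sim <- simulate_shape_sample(sim_config(seed = 77))
  m <- fit_bgpca(sim$table)
  # orthonormal rotation
  expect_equal(crossprod(m$rotation), diag(ncol(m$rotation)),
               tolerance = 1e-8)
  # variance fractions sum to 1
  expect_equal(sum(m$var_explained), 1, tolerance = 1e-10)
  # at most g-1 non-trivial axes even when p >> g
  expect_lte(ncol(m$rotation), length(m$groups) - 1L)
  # group mean projections equal their coordinates in the eigenbasis
  gm_scores <- project_bgpca(m, m$group_means)
  expect_equal(unname(gm_scores),
               unname(sweep(m$group_means, 2, m$grand_mean) %*% m$rotation),
               tolerance = 1e-8)
})

test_that("projection centers, reproduces training scores, and is total", {
  set.seed(121)
  sim <- simulate_shape_sample(sim_config(seed = 78))
  m <- fit_bgpca(sim$table)
  expect_equal(unname(project_bgpca(m, m$grand_mean))[1, ],
               rep(0, ncol(m$rotation)), tolerance = 1e-10)
  expect_equal(project_bgpca(m, sim$table$descriptors), m$scores,
               tolerance = 1e-10)
  far <- m$grand_mean + 1e3
  expect_true(all(is.finite(project_bgpca(m, far))))
  expect_error(project_bgpca(m, c(1, 2)), "dimension mismatch")
})

test_that("rotating all descriptors leaves the analysis invariant", {
  set.seed(131)
  sim <- simulate_shape_sample(sim_config(p = 8, seed = 79))
  tab <- sim$table
  Q <- random_rotation(8)
  tab_rot <- shape_table(tab$descriptors %*% Q, tab$specimen, tab$species,
                         tab$group)
  m1 <- fit_bgpca(tab)
  m2 <- fit_bgpca(tab_rot)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-6)
  for (j in seq_len(ncol(m1$rotation)))
    expect_equal(abs(m1$scores[, j]), abs(m2$scores[, j]), tolerance = 1e-6)
  expect_equal(loo_classify(tab)$confusion, loo_classify(tab_rot)$confusion,
               tolerance = 1e-6)
})

test_that("leave-one-out classification separates and degrades as designed", {
  set.seed(141)
  # 10-sigma separation: perfect classification
  X <- rbind(matrix(rnorm(40, sd = 1), 20, 2),
             matrix(rnorm(40, mean = 10, sd = 1), 20, 2))
  tab <- shape_table(X, paste0("s", 1:40), paste0("sp", 1:40),
                     rep(c("a", "b"), each = 20))
  res <- loo_classify(tab)
  expect_equal(res$accuracy, 100)
  expect_equal(rowSums(res$confusion), c(a = 100, b = 100), tolerance = 0.1)

  # identical distributions: near-chance accuracy
  acc <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    X0 <- matrix(rnorm(80), 40, 2)
    t0 <- shape_table(X0, paste0("s", 1:40), paste0("sp", 1:40),
                      rep(c("a", "b"), each = 20))
    loo_classify(t0)$accuracy
  }, 0)
  expect_gte(mean(acc), 35)
  expect_lte(mean(acc), 65)

  expect_error(loo_classify(shape_table(matrix(rnorm(6), 3, 2),
                                        paste0("s", 1:3), paste0("sp", 1:3),
                                        c("a", "a", "b"))),
               "fewer than 2")
})

test_that("typicality probabilities follow the chi-square contract", {
  set.seed(151)
  sc <- rbind(matrix(rnorm(90), 30, 3),
              matrix(rnorm(90, mean = 4), 30, 3))
  grp <- rep(c("a", "b"), each = 30)
  cent_a <- colMeans(sc[grp == "a", ])
  tp <- typprob(sc, grp, cent_a)
  expect_equal(unname(tp$prob[1, "a"]), 1)
  expect_equal(unname(tp$d2[1, "a"]), 0, tolerance = 1e-12)

  # d2 at the 95th chi-square percentile gives p = 0.05
  W <- vestimorph:::pooled_within_cov(sc, grp)
  dir <- eigen(W)$vectors[, 1]
  target_d2 <- qchisq(0.95, df = 3)
  step <- dir * sqrt(target_d2 / drop(t(dir) %*% solve(W) %*% dir))
  tp2 <- typprob(sc, grp, cent_a + step)
  expect_equal(unname(tp2$prob[1, "a"]), 0.05, tolerance = 1e-8)

  # strictly decreasing in d2
  ps <- vapply(seq(0, 5, by = 0.5), function(s) {
    unname(typprob(sc, grp, cent_a + s * dir)$prob[1, "a"])
  }, 0)
  expect_true(all(diff(ps) < 0))

  # probabilities across groups need not sum to 1
  mid <- (cent_a + colMeans(sc[grp == "b", ])) / 2
  tpm <- typprob(sc, grp, mid)
  expect_true(all(tpm$prob >= 0 & tpm$prob <= 1))
})

test_that("the F-variant typicality is more conservative for small samples", {
  set.seed(161)
  sc <- matrix(rnorm(40), 20, 2)
  grp <- rep(c("a", "b"), each = 10)
  q <- colMeans(sc[grp == "a", ]) + c(2, 2)
  p_chi <- typprob(sc, grp, q, method = "chisq")$prob[1, "a"]
  p_f <- typprob(sc, grp, q, method = "f")$prob[1, "a"]
  expect_gt(p_f, p_chi)
})

test_that("hierarchical clustering recovers well-separated groups", {
  set.seed(171)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  X <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(24, sd = 0.5), 12, 2), 2, centers[i, ], `+`)))
  tab <- shape_table(X, paste0("s", 1:48), paste0("sp", 1:48),
                     rep(letters[1:4], each = 12))
  hc <- hca_confusion(tab)
  expect_equal(as.numeric(hc), rep(100, 4))

  # a group sitting between two others scores lowest
  centers2 <- rbind(c(0, 0), c(3, 0), c(10, 0))
  X2 <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(30, sd = 1), 15, 2), 2, centers2[i, ], `+`)))
  tab2 <- shape_table(X2, paste0("s", 1:45), paste0("sp", 1:45),
                      rep(c("left", "middle", "right"), each = 15))
  hc2 <- hca_confusion(tab2)
  expect_true(all(hc2 >= 0 & hc2 <= 100))
  expect_equal(names(which.min(hc2)), "middle")

  expect_error(hca_confusion(tab, g = 100), "fewer specimens")
})

test_that("bgPCA models round-trip through the plain-array archive", {
  sim <- simulate_shape_sample(sim_config(seed = 301))
  m <- fit_bgpca(sim$table)
  dir <- withr::local_tempdir()
  write_bgpca(m, dir)
  back <- read_bgpca(dir)
  expect_equal(unname(back$grand_mean), unname(m$grand_mean),
               tolerance = 1e-10)
  expect_equal(back$eigenvalues, m$eigenvalues, tolerance = 1e-10)
  expect_equal(unname(back$rotation), unname(m$rotation), tolerance = 1e-10)
  q <- sim$table$descriptors[3, ]
  expect_equal(project_bgpca(back, q), project_bgpca(m, q), tolerance = 1e-8)
})
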