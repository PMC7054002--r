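test_that("GPA aligns identical and rigidly transformed copies exactly", {
  set.seed(11)
  tpl <- ring_template()
  # identical copies: zero Procrustes distance after alignment
  out <- gpa(list(tpl, tpl), allow_scaling = FALSE)
  expect_lt(sqrt(mean((out$aligned[[1]] - out$aligned[[2]])^2)), 1e-10)

  # rotated + translated copy recovers the original to numerical precision
  R <- random_rotation()
  moved <- tpl %*% R + matrix(c(5, -2, 3), nrow(tpl), 3, byrow = TRUE)
  out <- gpa(list(tpl, moved), allow_scaling = FALSE)
  expect_lt(sqrt(mean((out$aligned[[1]] - out$aligned[[2]])^2)), 1e-8)

  # scaling contract: 2x copy matches only when scaling is allowed
  out_s <- gpa(list(tpl, 2 * tpl), allow_scaling = TRUE)
  expect_lt(sqrt(mean((out_s$aligned[[1]] - out_s$aligned[[2]])^2)), 1e-8)
  out_r <- gpa(list(tpl, 2 * tpl), allow_scaling = FALSE)
  expect_gt(sqrt(mean((out_r$aligned[[1]] - out_r$aligned[[2]])^2)), 1e-4)
})

test_that("GPA agrees with the two-configuration Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(21)
  tpl <- ring_template()
  noisy <- tpl + matrix(rnorm(length(tpl), sd = 0.05), nrow(tpl))
  out <- gpa(list(tpl, noisy), allow_scaling = TRUE)
  # vegan::procrustes minimizes the same similarity-transform criterion;
  # compare the residual sum of squares between the two aligned shapes
  ref <- vegan::procrustes(out$aligned[[1]], out$aligned[[2]],
                           scale = TRUE, symmetric = TRUE)
  mine <- sum((out$aligned[[1]] - out$aligned[[2]])^2) /
    sum(out$aligned[[1]]^2)
  expect_lt(abs(mine - ref$ss) / ref$ss, 0.05)
})

test_that("GPA output is invariant to input transforms and ordering", {
  set.seed(31)
  tpl <- ring_template()
  configs <- lapply(1:4, function(i)
    tpl + matrix(rnorm(length(tpl), sd = 0.03), nrow(tpl)))
  base_out <- gpa(configs, allow_scaling = TRUE)
  # arbitrary similarity transforms of every input
  messed <- lapply(configs, function(m)
    (runif(1, 0.5, 2) * m) %*% random_rotation() +
      matrix(rnorm(3, sd = 4), nrow(m), 3, byrow = TRUE))
  messed_out <- gpa(messed, allow_scaling = TRUE)
  # consensus equal up to rotation: compare via Procrustes-aligned RMSD
  rot <- svd(crossprod(messed_out$consensus, base_out$consensus))
  Q <- rot$u %*% t(rot$v)
  expect_lt(sqrt(mean((messed_out$consensus %*% Q - base_out$consensus)^2)),
            1e-6)
  # ordering invariance (consensus identical up to rotation; here same
  # configs so identical orientation too)
  perm_out <- gpa(configs[c(3, 1, 4, 2)], allow_scaling = TRUE)
  rot2 <- svd(crossprod(perm_out$consensus, base_out$consensus))
  Q2 <- rot2$u %*% t(rot2$v)
  expect_lt(sqrt(mean((perm_out$consensus %*% Q2 - base_out$consensus)^2)),
            1e-6)
})

test_that("aligned deviations from the consensus sum to zero", {
  set.seed(41)
  tpl <- ring_template()
  configs <- lapply(1:5, function(i)
    tpl + matrix(rnorm(length(tpl), sd = 0.05), nrow(tpl)))
  out <- gpa(configs, allow_scaling = FALSE)
  dev <- Reduce(`+`, lapply(out$aligned, function(m) m - out$consensus))
  expect_lt(max(abs(dev)), 1e-10)
})

test_that("degenerate configurations are rejected", {
  flat <- matrix(1, 10, 3)
  expect_error(gpa(list(flat, flat)), "degenerate")
  expect_error(gpa(list(ring_template())), "length")
})

test_that("flatten produces 3k-column rows and mirrors right-side specimens", {
  set.seed(51)
  cfg <- matrix(rnorm(12), 4, 3)
  out <- gpa(list(cfg, cfg + 0.01), allow_scaling = FALSE)
  tab <- flatten_configs(out, c("a", "b"), c("sp1", "sp2"), c("g", "g"))
  expect_equal(dim(tab), c(2L, 12L))
  expect_equal(tab$descriptors[1, 1:3], unname(out$aligned[[1]][1, ]))
  expect_error(flatten_configs(out, "a", c("sp1", "sp2"), c("g", "g")),
               "label count")

  # mirroring: reflecting x then aligning with mirror flag reproduces the
  # unreflected alignment
  tpl <- ring_template()
  mirrored <- tpl
  mirrored[, 1] <- -mirrored[, 1]
  straight <- gpa(list(tpl, tpl + 0.001), allow_scaling = FALSE)
  folded <- gpa(list(tpl, mirrored), allow_scaling = FALSE,
                mirror = c(FALSE, TRUE))
  expect_lt(sqrt(mean((folded$aligned[[1]] - folded$aligned[[2]])^2)), 1e-8)
})

test_that("species means average specimens and inherit group labels", {
  set.seed(61)
  tpl <- c(1, -2, 3, 0)
  tab <- shape_table(rbind(tpl, -tpl, c(5, 5, 5, 5)),
                     c("s1", "s2", "s3"),
                     c("spA", "spA", "spB"),
                     c("G1", "G1", "G2"))
  sm <- species_means(tab)
  expect_equal(nrow(sm$descriptors), 2L)
  expect_equal(unname(sm$descriptors["spA", ]), rep(0, 4))
  expect_equal(sm$group, c("G1", "G2"))

  # Monte-Carlo: mean of 5 noisy specimens is within 3 SE of the template
  template <- rnorm(6)
  reps <- 400
  hits <- vapply(seq_len(reps), function(i) {
    X <- matrix(rep(template, each = 5), 5) + matrix(rnorm(30, sd = 0.3), 5)
    tb <- shape_table(X, paste0("s", 1:5), rep("sp", 5), rep("G", 5))
    m <- species_means(tb)$descriptors[1, ]
    all(abs(m - template) < 3 * 0.3 / sqrt(5))
  }, TRUE)
  expect_gt(mean(hits), 0.9)   # per-coordinate 3-SE bound jointly, 6 coords
})

test_that("shape tables validate labels and round-trip through text", {
  X <- matrix(rnorm(12), 3, 4)
  expect_error(shape_table(X, c("a", "b"), c("x", "y", "z"), c("g", "g", "g")),
               "label length")
  expect_error(shape_table(X, c("a", "b", "c"), c("x", "y", ""), rep("g", 3)),
               "missing")
  tab <- shape_table(X, c("a", "b", "c"), c("x", "y", "z"), rep("g", 3))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_shape_table(tab, tf)
  back <- read_shape_table(tf)
  expect_equal(unname(back$descriptors), unname(tab$descriptors),
               tolerance = 1e-12)
  expect_equal(back$species, tab$species)
})

test_that("tree alignment reports species missing from the table", {
  tr <- three_tip_tree()
  tab <- shape_table(matrix(rnorm(4), 2, 2), c("A", "B"), c("A", "B"),
                     c("g", "g"))
  expect_error(align_to_tree(tab, tr), "C")
  tab3 <- shape_table(matrix(rnorm(6), 3, 2), c("C", "A", "B"),
                      c("C", "A", "B"), rep("g", 3))
  expect_equal(rownames(align_to_tree(tab3, tr)), tr$tip.label)
  expect_equal(align_to_tree(tab3, tr)[1, ], tab3$descriptors["A", ])
})

test_that("block-format landmark files parse into configurations", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("> spec_a", "0 0 0", "1 0 0", "0 1 0.5",
               "> spec_b", "0 0 0", "1.1 0 0", "0 0.9 0.4"), f)
  lm <- read_landmark_blocks(f)
  expect_equal(names(lm), c("spec_a", "spec_b"))
  expect_equal(dim(lm[[1]]), c(3L, 3L))
  expect_equal(lm[[2]][2, 1], 1.1)
  writeLines(c("> a", "0 0 0", "> b", "0 0 0", "1 1 1"), f)
  expect_error(read_landmark_blocks(f), "differ")
})
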