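new_regression_result <- function(method, slope, intercept, slope_se,
                                  intercept_se, slope_ci, intercept_ci,
                                  r_squared, p_value, n) {
  structure(list(method = method, slope = slope, intercept = intercept,
                 slope_se = slope_se, intercept_se = intercept_se,
                 slope_ci = slope_ci, intercept_ci = intercept_ci,
                 r_squared = r_squared, p_value = p_value, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(x$method, " regression (n = ", x$n, "): R2 = ",
      format(signif(x$r_squared, 3)), ", slope p = ",
      format(signif(x$p_value, 3)), "\n", sep = "")
  cat("  slope: ", format(signif(x$slope, 4)), " +/- ",
      format(signif(x$slope_se, 4)), "  95% CI [",
      format(signif(x$slope_ci[1], 4)), ", ",
      format(signif(x$slope_ci[2], 4)), "]\n", sep = "")
  cat("  intercept: ", format(signif(x$intercept, 4)), " +/- ",
      format(signif(x$intercept_se, 4)), "  95% CI [",
      format(signif(x$intercept_ci[1], 4)), ", ",
      format(signif(x$intercept_ci[2], 4)), "]\n", sep = "")
  invisible(x)
}

#' Ordinary least-squares regression
#'
#' Bivariate OLS with the classical normal-theory inference used throughout
#' the allometry battery: standard errors from the residual variance on
#' `n - 2` df, 95% confidence intervals from t quantiles, two-sided p-value
#' for the slope.
#'
#' @param x,y numeric vectors of equal length (n >= 3; x must vary).
#' @return a `regression_result` with method tag `"OLS"`.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant predictor")
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - 2)
  slope_se <- sqrt(sigma2 / sum(xc^2))
  intercept_se <- sqrt(sigma2 * (1 / n + mean(x)^2 / sum(xc^2)))
  tq <- stats::qt(0.975, n - 2)
  tstat <- slope / slope_se
  new_regression_result("OLS", slope, intercept, slope_se, intercept_se,
                        slope + c(-1, 1) * tq * slope_se,
                        intercept + c(-1, 1) * tq * intercept_se,
                        if (tss > 0) 1 - rss / tss else NA_real_,
                        2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE),
                        n)
}

#' Phylogenetic generalized least-squares regression
#'
#' GLS fit of `y` on `x` across the tips of a tree with error covariance
#' proportional to the Brownian phylogenetic covariance `C` (i.e. at
#' `lambda = 1`): `beta = (X' C^-1 X)^-1 X' C^-1 y` with `X = [1, x]`.
#' Standard errors come from `(X' C^-1 X)^-1` scaled by the GLS residual
#' variance on `n - 2` df. The coefficient of determination is
#' `1 - RSS_gls / TSS_gls`, with the total sum of squares taken about the
#' phylogenetic (GLS) mean of `y` — a documented choice, since several
#' conventions circulate for GLS R-squared.
#'
#' On a star phylogeny (`C` proportional to the identity) the fit reduces
#' exactly to [ols_fit()].
#'
#' @param tree a `phylo` object whose tips match `names(x)`/`names(y)`.
#' @param x,y named numeric vectors, one value per tip.
#' @return a `regression_result` with method tag `"PGLS"`.
#' @export
pgls_fit <- function(tree, x, y) {
  if (!is.null(names(x)) || !is.null(names(y))) {
    miss_x <- setdiff(tree$tip.label, names(x))
    miss_y <- setdiff(tree$tip.label, names(y))
    extra <- union(setdiff(names(x), tree$tip.label),
                   setdiff(names(y), tree$tip.label))
    if (length(miss_x) || length(miss_y) || length(extra))
      stop("tip mismatch; missing from x: ",
           paste(miss_x, collapse = ", "), "; missing from y: ",
           paste(miss_y, collapse = ", "), "; not in tree: ",
           paste(extra, collapse = ", "))
    x <- x[tree$tip.label]
    y <- y[tree$tip.label]
  }
  n <- length(tree$tip.label)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 3L) stop("need at least 3 tips")
  C <- phylo_covariance(tree)
  ch <- chol_safe(C)
  X <- cbind(1, x)
  # transform to iid space: solve L z = v with C = L L'
  Xs <- forwardsolve(t(ch), X)
  ys <- forwardsolve(t(ch), y)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  resid <- ys - Xs %*% beta
  rss <- sum(resid^2)
  sigma2 <- rss / (n - 2)
  covb <- sigma2 * solve(XtX)
  se <- sqrt(diag(covb))
  # TSS about the phylogenetic mean of y
  ones <- forwardsolve(t(ch), rep(1, n))
  a_hat <- sum(ones * ys) / sum(ones^2)
  tss <- sum((ys - a_hat * ones)^2)
  tq <- stats::qt(0.975, n - 2)
  tstat <- beta[2] / se[2]
  new_regression_result("PGLS", beta[2], beta[1], se[2], se[1],
                        beta[2] + c(-1, 1) * tq * se[2],
                        beta[1] + c(-1, 1) * tq * se[1],
                        if (tss > 0) 1 - rss / tss else NA_real_,
                        2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE),
                        n)
}

#' Multivariate shape-on-size regression with a permutation test
#'
#' Least-squares regression of every descriptor column on `[1, size]`
#' jointly. The effect size is `R2 = SS_model / SS_total` where sums of
#' squares are summed over all descriptor columns (deviations about column
#' means); significance is assessed by permuting the size vector (at least
#' 999 permutations, seeded), with `p = (1 + #[R2_perm >= R2]) /
#' (n_perm + 1)`.
#'
#' @param table a `shape_table` (or descriptor matrix).
#' @param size numeric vector, one value per specimen (e.g. log cube-root
#'   vestibular volume).
#' @param n_perm number of permutations.
#' @param seed mandatory RNG seed.
#' @return list with `r_squared`, `p_value`, `n`, `n_perm`, `seed`.
#' @export
shape_size_regression <- function(table, size, n_perm = 999, seed = NULL) {
  Y <- if (inherits(table, "shape_table")) table$descriptors else as.matrix(table)
  n <- nrow(Y)
  stopifnot(length(size) == n)
  if (n < 5L) stop("need at least 5 specimens")
  if (stats::sd(size) == 0) stop("constant size")
  if (is.null(seed)) stop("a seed is required for the permutation test")
  r2_of <- function(x) {
    xc <- x - mean(x)
    Yc <- sweep(Y, 2, colMeans(Y))
    b <- crossprod(xc, Yc) / sum(xc^2)      # 1 x p slopes
    ss_model <- sum(xc^2) * sum(b^2)
    ss_total <- sum(Yc^2)
    ss_model / ss_total
  }
  obs <- r2_of(size)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) r2_of(sample(size)), numeric(1))
  list(r_squared = obs, p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n = n, n_perm = n_perm, seed = seed)
}

#' ANCOVA homogeneity of slopes and intercepts
#'
#' Classical two-stage partial-F construction for a two-group allometric
#' comparison. The slope test takes the group-by-covariate interaction in
#' the full separate-slopes model; the intercept test takes the group main
#' effect in the common-slope model. A significant intercept test with a
#' non-significant slope test is the signature of an allometric grade shift:
#' parallel allometric lines at different heights.
#'
#' @param x,y numeric vectors.
#' @param groups factor-like with exactly 2 levels; each group needs at
#'   least 3 observations.
#' @return list with `F_slopes`, `p_slopes`, `df_slopes`, `F_intercepts`,
#'   `p_intercepts`, `df_intercepts`.
#' @export
ancova <- function(x, y, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (nlevels(groups) > 2L) stop("ancova() compares exactly 2 groups")
  if (any(table(groups) < 3L)) stop("each group needs at least 3 observations")
  full <- stats::lm(y ~ x * groups)
  common <- stats::lm(y ~ x + groups)
  nocov <- stats::lm(y ~ x)
  slope_tab <- stats::anova(common, full)
  int_tab <- stats::anova(nocov, common)
  list(F_slopes = slope_tab$F[2], p_slopes = slope_tab$`Pr(>F)`[2],
       df_slopes = c(slope_tab$Df[2], slope_tab$Res.Df[2]),
       F_intercepts = int_tab$F[2], p_intercepts = int_tab$`Pr(>F)`[2],
       df_intercepts = c(int_tab$Df[2], int_tab$Res.Df[2]))
}

#' Isometry verdict from a slope confidence interval
#'
#' Compares the expected isometric slope (1 for log cube-root volume against
#' log length, since both scale as length) with the 95% confidence interval
#' of an estimated slope: the relationship is allometric when the interval
#' excludes the expectation, positively so when the whole interval lies
#' above it and negatively when below.
#'
#' @param result a `regression_result` (or a length-2 numeric CI).
#' @param expected_slope isometric expectation (default 1).
#' @return one of `"isometry-not-rejected"`, `"positive-allometry"`,
#'   `"negative-allometry"`.
#' @export
isometry_test <- function(result, expected_slope = 1) {
  ci <- if (inherits(result, "regression_result")) result$slope_ci else result
  stopifnot(length(ci) == 2L, all(is.finite(ci)), ci[1] <= ci[2])
  if (ci[1] > expected_slope) return("positive-allometry")
  if (ci[2] < expected_slope) return("negative-allometry")
  "isometry-not-rejected"
}

#' Construct an allometry measurement table
#'
#' Per-specimen scalar size measurements: vestibular volume `Vol` (mm^3),
#' semicircular-canal plus common-crus volume `VolSC` (mm^3), and summed
#' canal streamline length `L` (mm). The log-transformed variables used in
#' the regressions are natural logs of the CUBE ROOTS of the volumes
#' (`ln_Vol = log(Vol^(1/3))`, `ln_VolSC = log(VolSC^(1/3))`) and the
#' natural log of the length, so the isometric expectation of `ln_VolSC`
#' against `ln_L` is a slope of exactly 1.
#'
#' @param specimen,species,group character vectors.
#' @param Vol,VolSC,L positive numeric vectors.
#' @return a data.frame of class `allometry_table` with the raw columns and
#'   derived `ln_Vol`, `ln_VolSC`, `ln_L`.
#' @export
allometry_table <- function(specimen, species, group, Vol, VolSC, L) {
  n <- length(specimen)
  stopifnot(length(species) == n, length(group) == n, length(Vol) == n,
            length(VolSC) == n, length(L) == n)
  if (any(Vol <= 0) || any(VolSC <= 0) || any(L <= 0))
    stop("all measurements must be positive")
  df <- data.frame(specimen = as.character(specimen),
                   species = as.character(species),
                   group = as.character(group),
                   Vol = Vol, VolSC = VolSC, L = L,
                   ln_Vol = log(Vol) / 3, ln_VolSC = log(VolSC) / 3,
                   ln_L = log(L))
  class(df) <- c("allometry_table", "data.frame")
  df
}

#' Write / read allometry tables as delimited text
#'
#' @param table an `allometry_table`.
#' @param file path.
#' @export
write_allometry_table <- function(table, file) {
  utils::write.table(table[, c("specimen", "species", "group",
                               "Vol", "VolSC", "L")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_allometry_table
#' @export
read_allometry_table <- function(file) {
  df <- utils::read.delim(file)
  need <- c("specimen", "species", "group", "Vol", "VolSC", "L")
  if (!all(need %in% names(df)))
    stop("allometry table must have columns: ", paste(need, collapse = ", "))
  allometry_table(df$specimen, df$species, df$group, df$Vol, df$VolSC, df$L)
}

#' Tabulate regression results in report form
#'
#' One row per fitted regression, mirroring the usual allometry-report
#' layout (R2, p, slope with SE and CI, intercept with SE and CI).
#'
#' @param results named list of `regression_result` objects.
#' @return a data.frame.
#' @export
regression_report <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(model = nm, method = r$method, n = r$n,
               R2 = r$r_squared, p = r$p_value,
               slope = r$slope, slope_SE = r$slope_se,
               slope_CI_lo = r$slope_ci[1], slope_CI_hi = r$slope_ci[2],
               intercept = r$intercept, intercept_SE = r$intercept_se,
               intercept_CI_lo = r$intercept_ci[1],
               intercept_CI_hi = r$intercept_ci[2])
  }))
}
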