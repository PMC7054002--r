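# Internal GLS helpers shared by the signal statistics, PGLS and ancestral
# reconstruction. Solves use Cholesky; a single jitter of 1e-10 * tr(C)/n is
# attempted before giving up on a non-PD matrix.

chol_safe <- function(C) {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-10 * sum(diag(C)) / nrow(C)
    ch <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
    if (is.null(ch)) stop("covariance matrix is not positive definite")
  }
  ch
}

# Phylogenetic (GLS) mean of tip values y under covariance C:
# a_hat = (1' C^-1 1)^-1 1' C^-1 y. Returns the mean plus the reusable
# solves. y may be a matrix (one column per trait).
gls_mean <- function(C, y) {
  y <- as.matrix(y)
  ch <- chol_safe(C)
  invC_y <- backsolve(ch, forwardsolve(t(ch), y))
  invC_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, nrow(C))))
  denom <- sum(invC_1)
  a_hat <- colSums(invC_y) / denom
  list(a_hat = a_hat, chol = ch, invC_1 = invC_1, denom = denom)
}

new_signal_result <- function(statistic, estimate, p_value, ...) {
  structure(c(list(statistic = statistic, estimate = estimate,
                   p_value = p_value), list(...)),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(x$statistic, " = ", format(signif(x$estimate, 4)), sep = "")
  if (!is.null(x$p_value) && !is.na(x$p_value))
    cat(" (p = ", format(signif(x$p_value, 3)), ")", sep = "")
  cat("\n")
  if (!is.null(x$logLik))
    cat("  logLik at optimum: ", format(x$logLik),
        "; at lambda = 0: ", format(x$logLik0), "\n", sep = "")
  if (!is.null(x$n_perm))
    cat("  permutations: ", x$n_perm, " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Profile log-likelihood of tip values under N(a 1, sigma2 C(lambda)), with
# a and sigma2 profiled analytically (sigma2 = GLS RSS / n, the ML variance).
lambda_loglik <- function(lam, C, y) {
  Cl <- lambda_transform(C, lam)
  n <- length(y)
  ch <- tryCatch(chol_safe(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  g <- gls_mean(Cl, y)
  resid <- y - g$a_hat
  invC_r <- backsolve(ch, forwardsolve(t(ch), resid))
  rss <- sum(resid * invC_r)
  if (rss <= 0) return(-Inf)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Estimates the branch-length scaling coefficient `lambda` in `[0, 1]` that
#' best explains the tip values under a multivariate-normal model with mean
#' `a 1` and covariance `sigma2 * C(lambda)`, where `C(lambda)` multiplies
#' the off-diagonal (shared-history) entries of the Brownian covariance by
#' `lambda`. The mean and rate are profiled analytically at each `lambda`, so
#' the search is one-dimensional (bounded golden-section/parabolic search,
#' tolerance 1e-6, with both endpoints checked). `lambda = 0` means tip
#' values are phylogenetically independent; `lambda = 1` means covariance
#' proportional to shared branch length (maximal signal).
#'
#' The p-value is a likelihood-ratio test of the estimate against
#' `lambda = 0` on 1 df.
#'
#' @param tree a `phylo` object.
#' @param tip_values named numeric vector, one value per tip (names matched
#'   against tip labels when present).
#' @return a `signal_result` with `estimate`, `p_value`, `logLik` (at the
#'   optimum) and `logLik0` (at `lambda = 0`).
#' @export
pagel_lambda <- function(tree, tip_values) {
  y <- match_tip_values(tree, tip_values)
  if (length(y) < 3L) stop("need at least 3 tips")
  if (stats::sd(y) == 0) stop("zero variance in tip values")
  C <- phylo_covariance(tree)
  opt <- stats::optimize(function(l) lambda_loglik(l, C, y),
                         interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, lambda_loglik(0, C, y), lambda_loglik(1, C, y))
  if (all(!is.finite(ll))) stop("non-finite likelihood for all lambda")
  best <- which.max(ll)
  lam_hat <- cand[best]
  ll_hat <- ll[best]
  ll0 <- ll[2]
  lr <- max(0, 2 * (ll_hat - ll0))
  new_signal_result("lambda", lam_hat,
                    stats::pchisq(lr, df = 1, lower.tail = FALSE),
                    logLik = ll_hat, logLik0 = ll0)
}

match_tip_values <- function(tree, tip_values) {
  y <- if (is.matrix(tip_values) || is.data.frame(tip_values)) {
    as.matrix(tip_values)
  } else {
    tip_values
  }
  nm <- if (is.matrix(y)) rownames(y) else names(y)
  if (!is.null(nm)) {
    missing <- setdiff(tree$tip.label, nm)
    if (length(missing))
      stop("no value for tip(s): ", paste(missing, collapse = ", "))
    y <- if (is.matrix(y)) y[tree$tip.label, , drop = FALSE] else y[tree$tip.label]
  } else {
    nt <- length(tree$tip.label)
    len <- if (is.matrix(y)) nrow(y) else length(y)
    if (len != nt)
      stop("tip values (", len, ") do not match tip count (", nt, ")")
  }
  y
}

# Core K computation given C-derived quantities; y one trait.
k_statistic <- function(C, y) {
  n <- length(y)
  g <- gls_mean(C, y)
  resid <- y - g$a_hat
  invC_r <- backsolve(g$chol, forwardsolve(t(g$chol), resid))
  num <- sum(resid^2)
  den <- sum(resid * invC_r)
  if (den <= 0) stop("degenerate denominator in K")
  expected <- (sum(diag(C)) - n / g$denom) / (n - 1)
  (num / den) / expected
}

#' Blomberg's K
#'
#' Ratio of the observed to the Brownian-expected partitioning of trait
#' variance on the tree: the mean squared deviation of tips from the
#' phylogenetic mean, over the same quantity standardized by the inverse
#' phylogenetic covariance, scaled by its expectation under Brownian motion.
#' `K` near 1 is consistent with Brownian evolution; `K < 1` means close
#' relatives resemble each other less than expected (variance within
#' clades); `K > 1` means more (variance between clades).
#'
#' @inheritParams pagel_lambda
#' @param n_perm if > 0, a tip-permutation p-value is attached (see
#'   [signal_permutation_test()]); requires `seed`.
#' @param seed RNG seed for the permutation test.
#' @return a `signal_result`.
#' @export
blomberg_k <- function(tree, tip_values, n_perm = 0, seed = NULL) {
  y <- match_tip_values(tree, tip_values)
  if (length(y) < 3L) stop("need at least 3 tips")
  if (stats::sd(y) == 0) stop("zero variance in tip values")
  C <- phylo_covariance(tree)
  k <- k_statistic(C, y)
  p <- NA_real_
  if (n_perm > 0) {
    p <- signal_permutation_test(tree, y, statistic = "K",
                                 n_perm = n_perm, seed = seed)$p_value
  }
  new_signal_result("K", k, p, n_perm = if (n_perm > 0) n_perm else NULL,
                    seed = seed)
}

# inverse symmetric square root via eigendecomposition
inv_sqrt_mat <- function(C, tol = 1e-10) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < tol * max(e$values))
    stop("covariance matrix is rank-deficient")
  e$vectors %*% diag(1 / sqrt(e$values), nrow(C)) %*% t(e$vectors)
}

k_mult_statistic <- function(C, Y, invsq = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  g <- gls_mean(C, Y)
  resid <- sweep(Y, 2, g$a_hat)
  if (is.null(invsq)) invsq <- inv_sqrt_mat(C)
  num <- sum(resid^2)
  den <- sum((invsq %*% resid)^2)
  if (den <= 0) stop("degenerate denominator in K_mult")
  expected <- (sum(diag(C)) - n / g$denom) / (n - 1)
  (num / den) / expected
}

#' Multivariate phylogenetic signal (K_mult)
#'
#' Multivariate generalization of Blomberg's K for a tips-by-traits matrix:
#' the summed squared Euclidean distance of tips to the phylogenetic mean
#' vector, over the same sum after premultiplying the mean-centered matrix
#' by the inverse square-root factor of the phylogenetic covariance
#' (computed from its eigendecomposition), divided by the univariate
#' Brownian expectation term. Reduces exactly to [blomberg_k()] when
#' `p = 1`.
#'
#' @param tree a `phylo` object.
#' @param tip_matrix tips x traits numeric matrix (rownames matched against
#'   tip labels when present).
#' @inheritParams blomberg_k
#' @return a `signal_result`.
#' @export
k_mult <- function(tree, tip_matrix, n_perm = 0, seed = NULL) {
  Y <- match_tip_values(tree, as.matrix(tip_matrix))
  if (nrow(Y) < 3L) stop("need at least 3 tips")
  C <- phylo_covariance(tree)
  k <- k_mult_statistic(C, Y)
  p <- NA_real_
  if (n_perm > 0) {
    p <- signal_permutation_test(tree, Y, statistic = "Kmult",
                                 n_perm = n_perm, seed = seed)$p_value
  }
  new_signal_result("Kmult", k, p, n_perm = if (n_perm > 0) n_perm else NULL,
                    seed = seed)
}

#' Tip-permutation significance test for K and K_mult
#'
#' Shuffles trait values across tips (destroying any association with the
#' tree while keeping the trait distribution), recomputes the statistic for
#' each permutation, and reports `p = (1 + #[permuted >= observed]) /
#' (n_perm + 1)`. Deterministic given `seed`. At least 99 permutations are
#' required for meaningful resolution.
#'
#' @param tree a `phylo` object.
#' @param data numeric vector (for `"K"`) or tips x traits matrix (for
#'   `"Kmult"`).
#' @param statistic `"K"` or `"Kmult"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed mandatory RNG seed.
#' @return a `signal_result` with the observed statistic and permutation
#'   p-value.
#' @export
signal_permutation_test <- function(tree, data, statistic = c("K", "Kmult"),
                                    n_perm = 999, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (is.null(seed)) stop("a seed is required for the permutation test")
  C <- phylo_covariance(tree)
  n <- nrow(C)
  set.seed(seed)
  if (statistic == "K") {
    y <- as.numeric(match_tip_values(tree, data))
    obs <- k_statistic(C, y)
    # vectorized nulls: a_hat = w'y with fixed weights, K from two
    # quadratic forms under the fixed C
    ch <- chol_safe(C)
    invC_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    denom <- sum(invC_1)
    w <- invC_1 / denom
    expected <- (sum(diag(C)) - n / denom) / (n - 1)
    invC <- chol2inv(ch)
    P <- vapply(seq_len(n_perm), function(b) sample(y), numeric(n))
    A <- drop(crossprod(w, P))            # phylogenetic means
    R <- sweep(P, 2, A)                   # residual matrix
    nums <- colSums(R^2)
    dens <- colSums(R * (invC %*% R))
    perm <- (nums / dens) / expected
  } else {
    Y <- match_tip_values(tree, as.matrix(data))
    invsq <- inv_sqrt_mat(C)
    obs <- k_mult_statistic(C, Y)
    perm <- vapply(seq_len(n_perm), function(b) {
      k_mult_statistic(C, Y[sample(nrow(Y)), , drop = FALSE], invsq = invsq)
    }, numeric(1))
  }
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  new_signal_result(statistic, obs, p, n_perm = n_perm, seed = seed,
                    null_statistics = perm)
}

#' Write signal results as delimited text
#'
#' @param results a `signal_result` or list of them.
#' @param file output path.
#' @export
write_signal_results <- function(results, file) {
  if (inherits(results, "signal_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(statistic = r$statistic, estimate = r$estimate,
               p_value = r$p_value,
               n_perm = if (is.null(r$n_perm)) NA_integer_ else r$n_perm,
               seed = if (is.null(r$seed)) NA_integer_ else r$seed)
  }))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
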