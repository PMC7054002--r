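#' Between-group principal components analysis
#'
#' Ordination by eigendecomposition of the covariance of the group mean
#' vectors, with every specimen projected onto the resulting axes. Group
#' means are unweighted by group size and the grand mean is the mean of the
#' group means (the standard bgPCA definition; the study's groups are close
#' to balanced). At most `g - 1` axes carry non-zero variance for `g` groups.
#' Unlike discriminant analysis, bgPCA does not sphere the within-group
#' scatter, so it does not exaggerate separation when `p` approaches `n`.
#'
#' Each eigenvector's largest-magnitude loading is made positive so that axis
#' signs are reproducible across platforms.
#'
#' @param table a `shape_table` with at least two groups.
#' @param retain number of axes to keep; defaults to `g - 1`.
#' @return an object of class `bgpca`: list with `grand_mean`, `groups`,
#'   `group_means` (g x p), `rotation` (p x m orthonormal eigenvectors),
#'   `eigenvalues` (length m), `var_explained`, `scores` (n x m), `labels`
#'   (training group per specimen), `degenerate` flag.
#' @export
fit_bgpca <- function(table, retain = NULL) {
  stopifnot(inherits(table, "shape_table"))
  X <- table$descriptors
  grp <- table$group
  groups <- sort(unique(grp))
  g <- length(groups)
  if (g < 2L) stop("need at least 2 groups")
  counts <- table(grp)
  if (any(counts == 0L)) stop("empty group")
  gm <- do.call(rbind, lapply(groups, function(gr)
    colMeans(X[grp == gr, , drop = FALSE])))
  rownames(gm) <- groups
  grand <- colMeans(gm)
  Mc <- sweep(gm, 2, grand)
  S <- crossprod(Mc) / (g - 1)
  eig <- eigen(S, symmetric = TRUE)
  m_max <- min(g - 1L, ncol(X))
  if (is.null(retain)) retain <- m_max
  retain <- min(retain, m_max)
  vals <- pmax(eig$values[seq_len(retain)], 0)
  vecs <- eig$vectors[, seq_len(retain), drop = FALSE]
  # deterministic sign: largest |loading| positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  degenerate <- sum(eig$values[seq_len(m_max)] > 0) == 0 ||
    max(vals) < 1e-12 * max(1, sum(abs(diag(S))))
  total <- sum(pmax(eig$values[seq_len(m_max)], 0))
  structure(list(
    grand_mean = grand,
    groups = groups,
    group_means = gm,
    rotation = vecs,
    eigenvalues = vals,
    var_explained = if (total > 0) vals / total else rep(0, retain),
    scores = sweep(X, 2, grand) %*% vecs,
    labels = grp,
    specimen = table$specimen,
    degenerate = degenerate
  ), class = "bgpca")
}

#' @export
print.bgpca <- function(x, ...) {
  cat("between-group PCA: ", length(x$groups), " groups, ",
      nrow(x$scores), " specimens, ", ncol(x$rotation), " axes retained\n",
      sep = "")
  cat("  eigenvalues:", format(signif(x$eigenvalues, 4)), "\n")
  cat("  variance explained:",
      paste0(format(round(100 * x$var_explained, 1)), "%"), "\n")
  if (x$degenerate) cat("  [degenerate: all group means coincide]\n")
  invisible(x)
}

#' Project query specimens onto fitted bgPCA axes
#'
#' A-posteriori projection, e.g. of fossil specimens, onto the tangent-space
#' axes identified by the extant training sample: `(query - grand mean)`
#' times the eigenvector matrix. Projection is total: queries far outside the
#' training span still receive finite scores.
#'
#' @param model a `bgpca` object.
#' @param queries numeric matrix (rows = specimens) or a `shape_table`.
#' @return score matrix, one row per query.
#' @export
project_bgpca <- function(model, queries) {
  stopifnot(inherits(model, "bgpca"))
  if (inherits(queries, "shape_table")) queries <- queries$descriptors
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1)
  if (ncol(queries) != length(model$grand_mean))
    stop("descriptor dimension mismatch: query has ", ncol(queries),
         ", model expects ", length(model$grand_mean))
  sweep(queries, 2, model$grand_mean) %*% model$rotation
}

#' Leave-one-out classification by group-centroid distance
#'
#' Each specimen is assigned to the group whose score-space centroid is
#' nearest (Euclidean distance in the retained bgPC space), with its own
#' group's centroid recomputed without it. By default the eigenbasis is held
#' fixed across folds (only centroids are recomputed), matching
#' centroid-distance classification; `refit = TRUE` refits the full bgPCA
#' per fold instead.
#'
#' @param table a `shape_table`; every group needs at least 2 specimens.
#' @param retain number of axes (default `g - 1`).
#' @param refit refit the eigenbasis in each fold?
#' @return an object of class `classification_result`: list with `confusion`
#'   (g x g row-normalized percentages, rows = true groups), `predicted`,
#'   `accuracy` (overall percent correct).
#' @export
loo_classify <- function(table, retain = NULL, refit = FALSE) {
  stopifnot(inherits(table, "shape_table"))
  grp <- table$group
  groups <- sort(unique(grp))
  counts <- table(grp)
  if (any(counts < 2L))
    stop("group(s) with fewer than 2 specimens: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  n <- nrow(table$descriptors)
  model <- fit_bgpca(table, retain = retain)
  predicted <- character(n)
  for (i in seq_len(n)) {
    if (refit) {
      sub <- shape_table(table$descriptors[-i, , drop = FALSE],
                         table$specimen[-i], table$species[-i], grp[-i],
                         provenance = table$provenance)
      mod_i <- fit_bgpca(sub, retain = retain)
      sc <- mod_i$scores
      q <- project_bgpca(mod_i, table$descriptors[i, , drop = FALSE])
      grp_i <- grp[-i]
    } else {
      sc <- model$scores[-i, , drop = FALSE]
      q <- model$scores[i, , drop = FALSE]
      grp_i <- grp[-i]
    }
    cent <- do.call(rbind, lapply(groups, function(gr)
      colMeans(sc[grp_i == gr, , drop = FALSE])))
    d2 <- rowSums(sweep(cent, 2, drop(q))^2)
    predicted[i] <- groups[which.min(d2)]
  }
  confusion <- matrix(0, length(groups), length(groups),
                      dimnames = list(true = groups, predicted = groups))
  for (gr in groups) {
    tab <- table(factor(predicted[grp == gr], levels = groups))
    confusion[gr, ] <- 100 * as.numeric(tab) / sum(tab)
  }
  structure(list(confusion = confusion, predicted = predicted,
                 truth = grp,
                 accuracy = 100 * mean(predicted == grp)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("cross-validated classification: ",
      format(round(x$accuracy, 1)), "% correct overall\n", sep = "")
  print(round(x$confusion, 1))
  invisible(x)
}

# Pooled within-group covariance of score rows: sum of per-group centered
# cross-products over (n - g), with optional ridge for near-singular cases.
pooled_within_cov <- function(scores, groups, ridge = 0) {
  gs <- sort(unique(groups))
  n <- nrow(scores)
  g <- length(gs)
  if (n <= g) stop("need more specimens than groups for a pooled covariance")
  S <- matrix(0, ncol(scores), ncol(scores))
  for (gr in gs) {
    sub <- scores[groups == gr, , drop = FALSE]
    S <- S + crossprod(sweep(sub, 2, colMeans(sub)))
  }
  S <- S / (n - g)
  if (ridge > 0) S <- S + diag(ridge * sum(diag(S)) / ncol(S), ncol(S))
  S
}

#' Typicality probability of group membership
#'
#' For each group, the squared Mahalanobis distance of a query's score vector
#' to the group centroid is computed under the pooled within-group covariance
#' of the training scores, and converted to the upper-tail chi-square
#' probability with `df` degrees of freedom (the number of retained axes).
#' These are probabilities of observing a score at least this far from the
#' centroid given membership in the group, not posterior probabilities of a
#' forced assignment, so they need not sum to one across groups; a value
#' below 0.05 indicates the query falls outside the group's variability.
#' `method = "f"` uses the small-sample F approximation for a new
#' observation instead of the chi-square tail.
#'
#' @param scores training score matrix (n x m).
#' @param groups training group labels.
#' @param query one score vector, or a matrix of queries (rows).
#' @param df degrees of freedom; defaults to `ncol(scores)`.
#' @param method `"chisq"` (default) or `"f"`.
#' @param ridge optional ridge coefficient for a near-singular pooled
#'   covariance (adds `ridge * trace/p` to the diagonal).
#' @return a list with `prob` (queries x groups), `d2` (squared Mahalanobis
#'   distances), `best` (highest-probability group per query).
#' @export
typprob <- function(scores, groups, query, df = NULL,
                    method = c("chisq", "f"), ridge = 0) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  stopifnot(ncol(query) == ncol(scores))
  if (is.null(df)) df <- ncol(scores)
  gs <- sort(unique(groups))
  W <- pooled_within_cov(scores, groups, ridge = ridge)
  Winv <- tryCatch(solve(W), error = function(e)
    stop("pooled within-group covariance is singular; supply ridge > 0"))
  d2 <- matrix(NA_real_, nrow(query), length(gs),
               dimnames = list(rownames(query), gs))
  prob <- d2
  for (j in seq_along(gs)) {
    cent <- colMeans(scores[groups == gs[j], , drop = FALSE])
    diff <- sweep(query, 2, cent)
    d2[, j] <- rowSums((diff %*% Winv) * diff)
    if (method == "chisq") {
      prob[, j] <- stats::pchisq(d2[, j], df = df, lower.tail = FALSE)
    } else {
      ng <- sum(groups == gs[j])
      fstat <- d2[, j] * ng * (ng - df) / (df * (ng^2 - 1))
      prob[, j] <- stats::pf(fstat, df, ng - df, lower.tail = FALSE)
    }
  }
  list(prob = prob, d2 = d2,
       best = gs[apply(prob, 1, which.max)])
}

#' Group-recovery check by hierarchical clustering
#'
#' Agglomerative clustering of the specimen descriptors (Ward linkage on
#' Euclidean distances by default; the linkage is configurable because no
#' single choice is canonical), cut at `g` clusters. Each cluster is labeled
#' by its majority group and each group's correct-classification probability
#' is the fraction of its members landing in a cluster labeled with that
#' group. Used to verify that the group structure seen in bgPCA pre-exists
#' in the raw descriptors rather than being induced by the ordination.
#'
#' @param table a `shape_table`.
#' @param g number of clusters; defaults to the number of groups.
#' @param linkage passed to [stats::hclust()] (default `"ward.D2"`).
#' @return named numeric vector of per-group correct-classification
#'   percentages, with the cluster assignment as attribute `"clusters"`.
#' @export
hca_confusion <- function(table, g = NULL, linkage = "ward.D2") {
  stopifnot(inherits(table, "shape_table"))
  groups <- sort(unique(table$group))
  if (is.null(g)) g <- length(groups)
  n <- nrow(table$descriptors)
  if (n < g) stop("fewer specimens (", n, ") than requested clusters (", g, ")")
  hc <- stats::hclust(stats::dist(table$descriptors), method = linkage)
  cl <- stats::cutree(hc, k = g)
  # majority group per cluster (ties broken by label order)
  cluster_label <- vapply(seq_len(g), function(k) {
    names(which.max(table(factor(table$group[cl == k], levels = groups))))
  }, character(1))
  assigned <- cluster_label[cl]
  out <- vapply(groups, function(gr) {
    100 * mean(assigned[table$group == gr] == gr)
  }, numeric(1))
  attr(out, "clusters") <- cl
  out
}

#' Serialize a bgPCA model to a directory of plain arrays
#'
#' Writes the grand mean, group means, eigenvectors, eigenvalues and
#' training scores as delimited text plus a `manifest.yaml` describing the
#' arrays, so that a fitted model can be archived or exchanged without any
#' binary format. [read_bgpca()] restores it.
#'
#' @param model a `bgpca` object.
#' @param dir output directory (created if needed).
#' @export
write_bgpca <- function(model, dir) {
  stopifnot(inherits(model, "bgpca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, col.names = NA)
  wt(matrix(model$grand_mean, 1), "grand_mean.tsv")
  wt(model$group_means, "group_means.tsv")
  wt(model$rotation, "rotation.tsv")
  wt(matrix(model$eigenvalues, 1), "eigenvalues.tsv")
  wt(model$scores, "scores.tsv")
  yaml::write_yaml(list(
    class = "bgpca", p = length(model$grand_mean),
    groups = as.list(model$groups), retained = ncol(model$rotation),
    degenerate = model$degenerate,
    labels = as.list(model$labels), specimen = as.list(model$specimen),
    arrays = c("grand_mean.tsv", "group_means.tsv", "rotation.tsv",
               "eigenvalues.tsv", "scores.tsv")),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Restore a bgPCA model written by [write_bgpca()]
#'
#' @param dir directory containing the manifest and arrays.
#' @return a `bgpca` object.
#' @export
read_bgpca <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  if (!identical(man$class, "bgpca")) stop("not a bgpca archive")
  rd <- function(f) {
    df <- utils::read.delim(file.path(dir, f), row.names = 1,
                            check.names = FALSE)
    as.matrix(df)
  }
  ev <- drop(rd("eigenvalues.tsv"))
  structure(list(
    grand_mean = drop(rd("grand_mean.tsv")),
    groups = unlist(man$groups),
    group_means = rd("group_means.tsv"),
    rotation = unname(rd("rotation.tsv")),
    eigenvalues = unname(ev),
    var_explained = if (sum(ev) > 0) unname(ev) / sum(ev)
                    else rep(0, length(ev)),
    scores = rd("scores.tsv"),
    labels = unlist(man$labels),
    specimen = unlist(man$specimen),
    degenerate = isTRUE(man$degenerate)
  ), class = "bgpca")
}
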