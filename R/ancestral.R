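# Covariance between any two nodes (tips or internals) under BM: the depth
# of their most recent common ancestor, computed from pairwise path
# distances as (depth_a + depth_b - dist_ab) / 2.
all_node_covariance <- function(tree) {
  D <- ape::dist.nodes(tree)
  depth <- node_depths(tree)
  (outer(depth, depth, `+`) - D) / 2
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Estimates the state of every internal node as the conditional expectation
#' of the joint multivariate-normal Brownian model given the tip values,
#' with the root state set to the phylogenetic GLS mean of the tips. This
#' joint-conditioning form is exact and identical to the re-rooted GLS mean
#' at each node (the usual ML estimator for continuous characters); traits
#' are processed independently. Per-node estimation variances are the
#' conditional variances scaled by the ML Brownian rate.
#'
#' @param tree a `phylo` object; terminal branches on the paths used must
#'   have positive length.
#' @param tip_values named numeric vector or tips x traits matrix.
#' @return an object of class `ancestral_states`: list with `node` (internal
#'   node ids, root first), `estimates` (nodes x traits), `variances`
#'   (nodes x traits), `root` (row index of the root), `trait_names`.
#' @export
ml_ancestral <- function(tree, tip_values) {
  Y <- match_tip_values(tree, if (is.null(dim(tip_values)))
    tip_values else as.matrix(tip_values))
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                   dimnames = list(tree$tip.label, "trait"))
  n <- length(tree$tip.label)
  pend <- tree$edge.length[tree$edge[, 2] <= n]
  if (any(pend <= 0)) {
    bad <- tree$tip.label[tree$edge[tree$edge[, 2] <= n, 2][pend <= 0]]
    stop("zero-length terminal branch at tip(s): ", paste(bad, collapse = ", "))
  }
  V <- all_node_covariance(tree)
  tips <- seq_len(n)
  internals <- (n + 1L):(n + tree$Nnode)
  Vtt <- V[tips, tips, drop = FALSE]
  Vnt <- V[internals, tips, drop = FALSE]
  Vnn <- V[internals, internals, drop = FALSE]
  ch <- chol_safe(Vtt)
  g <- gls_mean(Vtt, Y)
  resid <- sweep(Y, 2, g$a_hat)
  invC_r <- backsolve(ch, forwardsolve(t(ch), resid))
  # conditional mean: a_hat + V_nt V_tt^-1 (y - a_hat)
  est <- sweep(Vnt %*% invC_r, 2, g$a_hat, `+`)
  # conditional covariance diagonal, common to all traits up to the rate
  B <- backsolve(ch, forwardsolve(t(ch), t(Vnt)))
  condvar <- pmax(diag(Vnn) - rowSums(t(B) * Vnt), 0)
  # ML rate per trait
  rate <- colSums(resid * invC_r) / n
  variances <- outer(condvar, rate)
  rownames(est) <- rownames(variances) <- as.character(internals)
  colnames(est) <- colnames(variances) <- colnames(Y)
  structure(list(node = internals, estimates = est, variances = variances,
                 root = 1L, trait_names = colnames(Y)),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("ML ancestral states: ", length(x$node), " internal nodes x ",
      ncol(x$estimates), " trait(s)\n", sep = "")
  cat("  root estimate:", format(signif(x$estimates[x$root, ], 4)), "\n")
  invisible(x)
}

#' Write ancestral states as delimited text
#'
#' Long format: node id, trait, estimate, variance.
#'
#' @param states an `ancestral_states` object.
#' @param file output path.
#' @export
write_ancestral_states <- function(states, file) {
  df <- do.call(rbind, lapply(seq_along(states$trait_names), function(j) {
    data.frame(node = states$node, trait = states$trait_names[j],
               estimate = states$estimates[, j],
               variance = states$variances[, j])
  }))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Phylomorphospace: a phylogeny drawn through an ordination
#'
#' Places every tip at its ordination scores on a chosen pair of axes and
#' every internal node at its ML ancestral estimate, with the tree's edges
#' connecting them, so that the extent and direction of inferred shape
#' change can be read from branch length and orientation in the ordination
#' plane.
#'
#' @param tree a `phylo` object.
#' @param scores tips x 2 matrix of ordination scores (rownames matched
#'   against tip labels).
#' @return an object of class `phylomorphospace`: list with `coords`
#'   (all-node x 2 matrix, tips first), `edges` (the tree's edge matrix),
#'   `tip_labels`, `node_labels` (internal node labels when present).
#' @export
build_phylomorphospace <- function(tree, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) stop("scores must have exactly 2 columns (axes)")
  Y <- match_tip_values(tree, scores)
  anc <- ml_ancestral(tree, Y)
  coords <- rbind(Y, anc$estimates)
  rownames(coords) <- c(tree$tip.label,
                        if (!is.null(tree$node.label) &&
                            length(tree$node.label) == tree$Nnode)
                          tree$node.label
                        else as.character(anc$node))
  structure(list(coords = coords, edges = tree$edge,
                 tip_labels = tree$tip.label,
                 node_labels = tree$node.label,
                 n_tips = length(tree$tip.label)),
            class = "phylomorphospace")
}

#' @export
print.phylomorphospace <- function(x, ...) {
  cat("phylomorphospace: ", x$n_tips, " tips, ",
      nrow(x$coords) - x$n_tips, " internal nodes\n", sep = "")
  invisible(x)
}

#' @export
plot.phylomorphospace <- function(x, xlab = "axis 1", ylab = "axis 2",
                                  label_tips = TRUE, ...) {
  plot(x$coords, type = "n", xlab = xlab, ylab = ylab, ...)
  for (i in seq_len(nrow(x$edges))) {
    graphics::segments(x$coords[x$edges[i, 1], 1], x$coords[x$edges[i, 1], 2],
                       x$coords[x$edges[i, 2], 1], x$coords[x$edges[i, 2], 2],
                       col = "grey50")
  }
  tips <- seq_len(x$n_tips)
  graphics::points(x$coords[tips, , drop = FALSE], pch = 19)
  graphics::points(x$coords[-tips, , drop = FALSE], pch = 21, bg = "white")
  if (label_tips)
    graphics::text(x$coords[tips, , drop = FALSE], labels = x$tip_labels,
                   pos = 3, cex = 0.6)
  invisible(x)
}

#' Write phylomorphospace coordinates as delimited text
#'
#' @param pms a `phylomorphospace` object.
#' @param file output path.
#' @export
write_phylomorphospace <- function(pms, file) {
  df <- data.frame(node = rownames(pms$coords),
                   type = c(rep("tip", pms$n_tips),
                            rep("internal", nrow(pms$coords) - pms$n_tips)),
                   axis1 = pms$coords[, 1], axis2 = pms$coords[, 2])
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Back-project ordination scores into descriptor space
#'
#' Reverses the bgPCA rotation: descriptor = grand mean + sum of
#' score_j * eigenvector_j. For landmark-provenance models the flattened
#' descriptor is also reshaped to a k x 3 configuration, giving a synthetic
#' shape (e.g. a reconstructed ancestral configuration). For deformation
#' descriptors the reconstruction stops at the descriptor vector; mapping
#' it back to a surface requires the external registration machinery.
#'
#' @param model a `bgpca` object.
#' @param scores numeric vector of length `m <= retained components` (or a
#'   matrix of such rows).
#' @param as_landmarks reshape to k x 3 when the descriptor length is a
#'   multiple of 3 (default: automatic for a single score vector).
#' @return descriptor row(s); a k x 3 matrix when reshaped.
#' @export
backproject <- function(model, scores, as_landmarks = NULL) {
  stopifnot(inherits(model, "bgpca"))
  single <- is.null(dim(scores))
  if (single) scores <- matrix(scores, nrow = 1)
  m <- ncol(scores)
  if (m > ncol(model$rotation))
    stop("scores have ", m, " components but the model retains only ",
         ncol(model$rotation))
  desc <- sweep(scores %*% t(model$rotation[, seq_len(m), drop = FALSE]),
                2, model$grand_mean, `+`)
  p <- ncol(desc)
  if (is.null(as_landmarks)) as_landmarks <- single && p %% 3 == 0
  if (as_landmarks) {
    if (!single || p %% 3 != 0)
      stop("landmark reshape needs a single score vector and p divisible by 3")
    return(matrix(desc[1, ], ncol = 3, byrow = TRUE))
  }
  if (single) desc[1, ] else desc
}
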