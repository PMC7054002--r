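# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and ape's vcv machinery) so that agreement is a
# genuine two-route check.

# Shared-path covariance by explicit MRCA walk over parent pointers.
oracle_covariance <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    plen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  root <- n + 1L
  path_to_root <- function(node) {
    nodes <- node
    while (node != root) {
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + plen[node]
      node <- parent[node]
    }
    d
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    pi <- path_to_root(i)
    for (j in seq_len(i)) {
      pj <- path_to_root(j)
      common <- intersect(pi, pj)
      # MRCA = deepest common node
      mrca <- common[which.max(vapply(common, depth, 0))]
      C[i, j] <- C[j, i] <- depth(mrca)
    }
    C[i, i] <- depth(i)
  }
  C
}

# Dense-matrix evaluation of Blomberg's K from its explicit formula.
oracle_k <- function(C, y) {
  n <- length(y)
  invC <- solve(C)
  one <- rep(1, n)
  a_hat <- sum(invC %*% y) / sum(invC)
  r <- y - a_hat
  num <- sum(r^2) / drop(t(r) %*% invC %*% r)
  num / ((sum(diag(C)) - n / sum(invC)) / (n - 1))
}

# Joint-MVN conditional mean for internal node states under BM, built from
# the full tip+node covariance assembled from path depths.
oracle_ancestral <- function(tree, y) {
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  root <- n + 1L
  depth <- D[root, ]
  V <- (outer(depth, depth, `+`) - D) / 2
  tips <- seq_len(n)
  internals <- (n + 1L):(n + tree$Nnode)
  invV <- solve(V[tips, tips])
  a_hat <- sum(invV %*% y) / sum(invV)
  drop(a_hat + V[internals, tips] %*% invV %*% (y - a_hat))
}

# Small random shape helpers -------------------------------------------------

random_rotation <- function(d = 3) {
  qrres <- qr(matrix(rnorm(d * d), d))
  R <- qr.Q(qrres)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# stylized three-ring landmark template: three mutually near-orthogonal
# circular arcs (15 points each) evoking the semicircular canals
ring_template <- function(points_per_ring = 15) {
  th <- seq(0, 1.6 * pi, length.out = points_per_ring)
  r1 <- cbind(cos(th), sin(th), 0)
  r2 <- cbind(cos(th), 0, sin(th)) + matrix(c(0.3, 0, 0), points_per_ring,
                                            3, byrow = TRUE)
  r3 <- cbind(0, cos(th), sin(th)) + matrix(c(0, 0.3, 0.1), points_per_ring,
                                            3, byrow = TRUE)
  rbind(r1, 0.8 * r2, 0.9 * r3)
}

# Minimal fixtures ------------------------------------------------------------

three_tip_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

balanced_tree <- function(n = 8, depth = 1) {
  tr <- ape::stree(n, type = "balanced")
  tr$edge.length <- rep(depth / ceiling(log2(n)), nrow(tr$edge))
  tr
}

# two-group 2D table with exactly known geometry
tiny_two_group_table <- function() {
  X <- rbind(c(-0.5, 1), c(0.5, -1), c(1.5, 1), c(2.5, -1))
  shape_table(X, paste0("s", 1:4), paste0("sp", 1:4),
              c("g1", "g1", "g2", "g2"))
}
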