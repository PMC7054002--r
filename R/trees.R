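#' Parse a Newick string into a validated phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is an
#' `ape::phylo` object, the common currency of every phylogenetic computation
#' in the package. Branch lengths are mandatory: a Newick string without them
#' is rejected rather than silently given defaults, because every downstream
#' quantity (Brownian covariances, signal statistics, ancestral states) is a
#' function of time. Unit lengths can be requested explicitly for testing.
#'
#' @param text a Newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @param unit_lengths if `TRUE`, a branch-length-free Newick string is
#'   accepted and every edge is assigned length 1 (testing convenience only).
#' @return an object of class `phylo`, rooted, with `edge.length` set.
#' @export
parse_newick <- function(text, unit_lengths = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree)) {
    # locate the first structurally offending character for the message
    bad <- regexpr("[^(),:;_.'\" [:alnum:]-]", text)
    pos <- if (bad > 0) bad else nchar(text)
    stop("malformed Newick string near position ", pos, ": ",
         substr(text, max(1, pos - 10), min(nchar(text), pos + 10)))
  }
  if (is.null(tree$edge.length)) {
    if (unit_lengths) {
      tree$edge.length <- rep(1, nrow(tree$edge))
    } else {
      stop("Newick string has no branch lengths; refusing to assume a ",
           "default (use unit_lengths = TRUE for unit-length testing trees)")
    }
  }
  validate_tree(tree)
  tree
}

#' Read a phylogeny from a Newick file
#'
#' @param file path to a Newick file.
#' @inheritParams parse_newick
#' @return a `phylo` object.
#' @export
read_tree <- function(file, unit_lengths = FALSE) {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""),
               unit_lengths = unit_lengths)
}

#' Write a phylogeny to a Newick file or string
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_tree <- function(tree, file = NULL) {
  validate_tree(tree)
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Structural invariants: single root, unique tip labels, non-negative branch
# lengths, at least one non-degenerate root-to-tip path.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (sum(tree$edge.length) <= 0) stop("all branch lengths are zero")
  # exactly one root (a node that is never a child); polytomies, including
  # the star phylogeny, are legal
  n <- length(tree$tip.label)
  nodes <- seq_len(n + tree$Nnode)
  roots <- setdiff(nodes, tree$edge[, 2])
  if (length(roots) != 1L) stop("tree must have exactly one root")
  child_counts <- table(tree$edge[, 2])
  if (any(child_counts > 1L)) stop("a node has more than one parent")
  invisible(tree)
}

# Depth of every node (tips and internals) measured from the root, in the
# same time units as the branch lengths.
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  root <- n + 1L
  depth <- numeric(nnode)
  # preorder traversal: parents before children
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (i in seq_len(nrow(edges))) {
    depth[edges[i, 2]] <- depth[edges[i, 1]] + lens[i]
  }
  depth
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Builds the matrix `C` of shared root-to-tip path lengths: `C[i, i]` is the
#' depth of tip `i` and `C[i, j]` the depth of the most recent common ancestor
#' of tips `i` and `j`. Under Brownian motion with rate `sigma^2`, tip values
#' have covariance `sigma^2 * C`; every signal statistic, PGLS fit and
#' ancestral-state estimate in the package consumes this structure.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param taxa character vector of tip names defining the row/column order;
#'   defaults to `tree$tip.label`.
#' @return a symmetric positive-semidefinite matrix with `taxa` as dimnames.
#' @export
phylo_covariance <- function(tree, taxa = tree$tip.label) {
  validate_tree(tree)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(tree$tip.label) == 1L) {
    C <- matrix(sum(tree$edge.length), 1, 1,
                dimnames = list(tree$tip.label, tree$tip.label))
    return(C[taxa, taxa, drop = FALSE])
  }
  C <- ape::vcv.phylo(tree)
  C[taxa, taxa, drop = FALSE]
}

#' Pagel's lambda transformation of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lambda` while leaving the
#' diagonal untouched. `lambda = 1` returns `C` unchanged (full Brownian
#' covariance); `lambda = 0` gives the star-phylogeny limit in which species
#' are independent. Values outside `[0, 1]` are rejected, matching the
#' interpretable range of the scaling coefficient.
#'
#' @param C a phylogenetic covariance matrix from [phylo_covariance()].
#' @param lambda scalar in `[0, 1]`.
#' @return the transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}

# Age of a node in Ma before present: root age is the maximum root-to-tip
# depth, so extant tips of an ultrametric tree sit at age 0.
node_ages <- function(tree) {
  depth <- node_depths(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}

#' Attach a fossil tip to a dated phylogeny
#'
#' Adds a terminal branch for an extinct taxon. The attachment point is
#' specified in absolute time: `stem_attach_age` (Ma before present) must lie
#' on the root-ward path above the clade identified by `sister` (a tip name or
#' a set of tip names whose most recent common ancestor subtends that clade).
#' The new terminal branch runs from the attachment point down to `tip_age`,
#' the taxon's last occurrence, so the resulting tree is generally
#' non-ultrametric.
#'
#' @param tree a `phylo` object (typically ultrametric over extant taxa).
#' @param name tip label for the fossil.
#' @param sister tip label(s); the fossil is attached on the stem lineage
#'   above their MRCA (above the tip itself if a single label is given).
#' @param stem_attach_age age (Ma) of the attachment node; must exceed the
#'   age of the `sister` clade's crown node and not exceed the age of its
#'   parent node.
#' @param tip_age age (Ma) of the fossil tip (last occurrence); `0` for a
#'   hypothetical extant placement.
#' @return a `phylo` object with one more tip.
#' @export
attach_fossil_tip <- function(tree, name, sister, stem_attach_age, tip_age = 0) {
  validate_tree(tree)
  stopifnot(stem_attach_age > tip_age, tip_age >= 0)
  if (name %in% tree$tip.label) stop("tip '", name, "' already present")
  bad <- setdiff(sister, tree$tip.label)
  if (length(bad)) stop("sister taxa not in tree: ", paste(bad, collapse = ", "))
  ages <- node_ages(tree)
  node <- if (length(sister) == 1L) {
    match(sister, tree$tip.label)
  } else {
    ape::getMRCA(tree, sister)
  }
  node_age <- ages[node]
  if (stem_attach_age <= node_age)
    stop("stem_attach_age (", stem_attach_age,
         " Ma) is younger than the clade's crown node (", node_age, " Ma)")
  # climb root-ward until the attachment age falls inside the current edge
  root <- length(tree$tip.label) + 1L
  repeat {
    if (node == root)
      stop("stem_attach_age (", stem_attach_age,
           " Ma) is older than the root (", ages[root], " Ma)")
    parent <- tree$edge[match(node, tree$edge[, 2]), 1]
    if (stem_attach_age <= ages[parent]) break
    node <- parent
  }
  tip <- structure(list(
    edge = matrix(c(2L, 1L), 1, 2),
    tip.label = name,
    edge.length = stem_attach_age - tip_age,
    Nnode = 1L
  ), class = "phylo")
  out <- ape::bind.tree(tree, tip, where = node,
                        position = stem_attach_age - ages[node])
  validate_tree(out)
  out
}

#' Drop tips from a phylogeny
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels to remove.
#' @return the pruned `phylo` object.
#' @export
prune_tips <- function(tree, tips) {
  bad <- setdiff(tips, tree$tip.label)
  if (length(bad)) stop("tips not in tree: ", paste(bad, collapse = ", "))
  out <- ape::drop.tip(tree, tips)
  validate_tree(out)
  out
}

#' Write a covariance matrix as delimited text
#'
#' @param C matrix with taxon dimnames.
#' @param file output path (tab-separated, taxa as header row and first
#'   column).
#' @export
write_covariance <- function(C, file) {
  df <- data.frame(taxon = rownames(C), C, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a covariance matrix written by [write_covariance()]
#'
#' @param file input path.
#' @return the matrix with taxa dimnames.
#' @export
read_covariance <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  C <- as.matrix(df[, -1, drop = FALSE])
  rownames(C) <- df[[1]]
  C
}

#' Reference chronogram for the 27-species anthropoid sample
#'
#' A FIXTURE: a hard-coded, rooted, ultrametric chronogram over the 27 extant
#' anthropoid species of the study sample (4 clades: platyrrhines,
#' cercopithecoids, hylobatids, hominids), with nominal divergence times in Ma
#' drawn from the consensus molecular timescale for anthropoids. It mirrors
#' the published tree's topology and clade memberships but the node ages are
#' nominal round figures, not the study's exact chronogram (which is not
#' distributed as text). Use it to drive simulations and examples, not for
#' dating inference.
#'
#' @return a `phylo` object with 27 tips, root age 40 Ma.
#' @export
anthropoid_tree <- function() {
  # platyrrhine/catarrhine split 40 Ma, cercopithecoid-hominoid 29 Ma,
  # cercopithecoid crown 18 Ma, hominoid crown 20 Ma, hominid crown 16 Ma
  txt <- paste0(
    "((Cebus_apella:23,(Alouatta_palliata:19,Ateles_geoffroyi:19):4):17,",
    "((((Colobus_guereza:10,Piliocolobus_badius:10):3,",
    "(Nasalis_larvatus:12,(Trachypithecus_cristatus:9,",
    "(Presbytis_hosei:4,Presbytis_rubicunda:4):5):3):1):5,",
    "((Macaca_fascicularis:10,((Cercocebus_galeritus:6,Mandrillus_sphinx:6):2,",
    "(Lophocebus_albigena:7,(Papio_anubis:5,Theropithecus_gelada:5):2):1):2):4,",
    "(Miopithecus_talapoin:11,(Cercopithecus_mitis:9,",
    "(Chlorocebus_pygerythrus:7,Erythrocebus_patas:7):2):2):3):4):11,",
    "((Hoolock_hoolock:8,(Hylobates_lar:6,",
    "Symphalangus_syndactylus:6):2):12,(Pongo_pygmaeus:16,",
    "(Gorilla_gorilla:9,(Homo_sapiens:7,(Pan_troglodytes:2.5,",
    "Pan_paniscus:2.5):4.5):2):7):4):9):11);"
  )
  parse_newick(txt)
}

#' Clade membership of the reference sample
#'
#' @return a named character vector mapping each tip of [anthropoid_tree()]
#'   to its analysis group (`Platyrrhini`, `Cercopithecoidea`, `Hylobatidae`,
#'   `Hominidae`).
#' @export
anthropoid_groups <- function() {
  c(Cebus_apella = "Platyrrhini", Alouatta_palliata = "Platyrrhini",
    Ateles_geoffroyi = "Platyrrhini",
    Colobus_guereza = "Cercopithecoidea", Piliocolobus_badius = "Cercopithecoidea",
    Nasalis_larvatus = "Cercopithecoidea", Trachypithecus_cristatus = "Cercopithecoidea",
    Presbytis_hosei = "Cercopithecoidea", Presbytis_rubicunda = "Cercopithecoidea",
    Macaca_fascicularis = "Cercopithecoidea", Cercocebus_galeritus = "Cercopithecoidea",
    Mandrillus_sphinx = "Cercopithecoidea", Lophocebus_albigena = "Cercopithecoidea",
    Papio_anubis = "Cercopithecoidea", Theropithecus_gelada = "Cercopithecoidea",
    Miopithecus_talapoin = "Cercopithecoidea", Cercopithecus_mitis = "Cercopithecoidea",
    Chlorocebus_pygerythrus = "Cercopithecoidea", Erythrocebus_patas = "Cercopithecoidea",
    Hoolock_hoolock = "Hylobatidae", Hylobates_lar = "Hylobatidae",
    Symphalangus_syndactylus = "Hylobatidae",
    Pongo_pygmaeus = "Hominidae", Gorilla_gorilla = "Hominidae",
    Homo_sapiens = "Hominidae", Pan_troglodytes = "Hominidae",
    Pan_paniscus = "Hominidae")
}
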