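#' Construct a specimen-by-descriptor shape table
#'
#' The common currency of ordination and regression: an `n x p` descriptor
#' matrix (flattened aligned landmarks, or deformation-descriptor vectors
#' produced by an external registration) with complete specimen, species and
#' group labels. Covariance-based operations downstream require every group
#' to contain at least two specimens; the constructor only warns about
#' singleton groups so that query-only tables (e.g. fossils) remain legal.
#'
#' @param descriptors numeric matrix, one row per specimen.
#' @param specimen,species,group character vectors of length `nrow(descriptors)`.
#' @param provenance `"landmark"` (flattened k x 3 configurations, `p = 3k`)
#'   or `"deformation"` (externally produced descriptor vectors).
#' @return an object of class `shape_table`: a list with elements
#'   `descriptors`, `specimen`, `species`, `group`, `provenance`.
#' @export
shape_table <- function(descriptors, specimen, species, group,
                        provenance = c("deformation", "landmark")) {
  provenance <- match.arg(provenance)
  descriptors <- as.matrix(descriptors)
  storage.mode(descriptors) <- "double"
  n <- nrow(descriptors)
  specimen <- as.character(specimen)
  species <- as.character(species)
  group <- as.character(group)
  if (length(specimen) != n || length(species) != n || length(group) != n)
    stop("label length mismatch: ", n, " specimens but ",
         length(specimen), "/", length(species), "/", length(group),
         " specimen/species/group labels")
  if (anyNA(specimen) || anyNA(species) || anyNA(group) ||
      any(species == "") || any(group == ""))
    stop("missing species or group labels")
  if (anyNA(descriptors) || any(!is.finite(descriptors)))
    stop("non-finite descriptor values")
  if (anyDuplicated(specimen))
    stop("duplicate specimen ids")
  rownames(descriptors) <- specimen
  structure(list(descriptors = descriptors, specimen = specimen,
                 species = species, group = group, provenance = provenance),
            class = "shape_table")
}

#' @export
print.shape_table <- function(x, ...) {
  cat("shape_table: ", nrow(x$descriptors), " specimens x ",
      ncol(x$descriptors), " descriptors (", x$provenance, ")\n", sep = "")
  cat("  species: ", length(unique(x$species)),
      "; groups: ", paste(sort(unique(x$group)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.shape_table <- function(x) dim(x$descriptors)

#' Write a shape table as delimited text
#'
#' Columns `specimen`, `species`, `group`, then one column per descriptor
#' (`d1..dp` or `L<i>_<axis>` for landmark provenance).
#'
#' @param table a `shape_table`.
#' @param file output path.
#' @export
write_shape_table <- function(table, file) {
  stopifnot(inherits(table, "shape_table"))
  d <- table$descriptors
  if (is.null(colnames(d))) {
    colnames(d) <- if (table$provenance == "landmark" && ncol(d) %% 3 == 0) {
      paste0("L", rep(seq_len(ncol(d) / 3), each = 3), "_", c("x", "y", "z"))
    } else {
      paste0("d", seq_len(ncol(d)))
    }
  }
  df <- data.frame(specimen = table$specimen, species = table$species,
                   group = table$group, d, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a shape table written by [write_shape_table()]
#'
#' @param file input path.
#' @param provenance descriptor provenance tag.
#' @return a `shape_table`.
#' @export
read_shape_table <- function(file, provenance = c("deformation", "landmark")) {
  df <- utils::read.delim(file, check.names = FALSE)
  need <- c("specimen", "species", "group")
  if (!all(need %in% names(df)))
    stop("shape table must have columns: ", paste(need, collapse = ", "))
  shape_table(as.matrix(df[, setdiff(names(df), need), drop = FALSE]),
              df$specimen, df$species, df$group,
              provenance = match.arg(provenance))
}

centroid_size <- function(config) {
  ctr <- colMeans(config)
  sqrt(sum(sweep(config, 2, ctr)^2))
}

# Closed-form orthogonal Procrustes rotation of `config` onto `target`,
# restricted to proper rotations (det = +1) so that reflections never enter
# the superimposition. Both inputs must already be centered.
procrustes_rotation <- function(config, target) {
  sv <- svd(crossprod(config, target))
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(sv$v)
  }
  R
}

#' Generalized Procrustes superimposition of landmark configurations
#'
#' Removes position, orientation and (optionally) scale from a set of k x 3
#' landmark configurations. Each configuration is centered at the origin,
#' optionally scaled to unit centroid size, and iteratively rotated onto the
#' evolving consensus (coordinate-wise mean) with the closed-form orthogonal
#' Procrustes solution restricted to proper rotations. Iteration stops when
#' the consensus moves by less than `tol` (root summed squared displacement)
#' or after `max_iter` rounds.
#'
#' Configurations flagged in `mirror` have their x-axis negated before
#' alignment, the convention used to fold right-side specimens onto the left.
#'
#' @param configs list of numeric k x 3 (or k x d) matrices, identical k.
#' @param allow_scaling scale each configuration to centroid size 1?
#' @param mirror optional logical vector, one per configuration.
#' @param tol,max_iter convergence controls.
#' @return a list with `aligned` (list of aligned configurations),
#'   `consensus` (mean configuration) and `iterations`.
#' @export
gpa <- function(configs, allow_scaling = TRUE, mirror = NULL,
                tol = 1e-8, max_iter = 100L) {
  stopifnot(is.list(configs), length(configs) >= 2L)
  configs <- lapply(configs, as.matrix)
  k <- nrow(configs[[1]])
  d <- ncol(configs[[1]])
  if (!all(vapply(configs, nrow, 0L) == k) ||
      !all(vapply(configs, ncol, 0L) == d))
    stop("all configurations must share the same landmark count and dimension")
  if (!is.null(mirror)) {
    stopifnot(length(mirror) == length(configs))
    configs <- lapply(seq_along(configs), function(i) {
      m <- configs[[i]]
      if (mirror[i]) m[, 1] <- -m[, 1]
      m
    })
  }
  # center (and scale) each configuration
  configs <- lapply(configs, function(m) {
    m <- sweep(m, 2, colMeans(m))
    cs <- sqrt(sum(m^2))
    if (cs < 1e-12)
      stop("degenerate configuration: all landmarks coincident")
    if (allow_scaling) m <- m / cs
    m
  })
  consensus <- configs[[1]]
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    configs <- lapply(configs, function(m) m %*% procrustes_rotation(m, consensus))
    new_consensus <- Reduce(`+`, configs) / length(configs)
    if (allow_scaling) new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    shift <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (shift < tol || iterations >= max_iter) break
  }
  list(aligned = configs, consensus = consensus, iterations = iterations)
}

#' Flatten aligned configurations into a shape table
#'
#' Row `i` is the concatenated `(x, y, z)` coordinates of the landmarks of
#' specimen `i`, so `p = 3k` (landmark provenance).
#'
#' @param aligned list of aligned k x d configurations (from [gpa()]).
#' @param specimen,species,group labels, one per configuration.
#' @return a `shape_table` with `provenance = "landmark"`.
#' @export
flatten_configs <- function(aligned, specimen, species, group) {
  if (inherits(aligned, "list") && !is.null(aligned$aligned))
    aligned <- aligned$aligned
  n <- length(aligned)
  if (length(specimen) != n || length(species) != n || length(group) != n)
    stop("label count mismatch: ", n, " configurations")
  rows <- t(vapply(aligned, function(m) as.vector(t(m)),
                   numeric(nrow(aligned[[1]]) * ncol(aligned[[1]]))))
  shape_table(rows, specimen, species, group, provenance = "landmark")
}

#' Per-species mean shapes
#'
#' Collapses a specimen-level table to one row per species (the arithmetic
#' mean of its specimens' descriptors), the per-tip summary consumed by the
#' phylogenetic-signal and PGLS machinery. The group label is inherited; a
#' species spanning several groups is an error.
#'
#' @param table a `shape_table`.
#' @return a `shape_table` with one row per species (`specimen` = species).
#' @export
species_means <- function(table) {
  stopifnot(inherits(table, "shape_table"))
  sp <- sort(unique(table$species))
  grp <- vapply(sp, function(s) {
    g <- unique(table$group[table$species == s])
    if (length(g) != 1L)
      stop("species ", s, " is assigned to several groups: ",
           paste(g, collapse = ", "))
    g
  }, character(1))
  m <- do.call(rbind, lapply(sp, function(s) {
    colMeans(table$descriptors[table$species == s, , drop = FALSE])
  }))
  shape_table(m, sp, sp, grp, provenance = table$provenance)
}

#' Match a species-level shape table against tree tips
#'
#' @param table a species-level `shape_table` (one row per species).
#' @param tree a `phylo` object.
#' @return the table's descriptor matrix reordered to `tree$tip.label`.
#' @export
align_to_tree <- function(table, tree) {
  stopifnot(inherits(table, "shape_table"))
  missing <- setdiff(tree$tip.label, table$species)
  if (length(missing))
    stop("species in tree but absent from table: ",
         paste(missing, collapse = ", "))
  idx <- match(tree$tip.label, table$species)
  table$descriptors[idx, , drop = FALSE]
}

#' Read landmark configurations from a multi-specimen block file
#'
#' Plain-text block format: a line `> specimen_id` followed by k rows of
#' three whitespace-separated coordinates, repeated per specimen. All
#' specimens must share the same k.
#'
#' @param file input path.
#' @return a named list of k x 3 matrices.
#' @export
read_landmark_blocks <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '> specimen' header lines found")
  bounds <- c(heads, length(lines) + 1L)
  out <- lapply(seq_along(heads), function(i) {
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    coords <- do.call(rbind, lapply(strsplit(body, "[ \t]+"), as.numeric))
    if (ncol(coords) != 3L || anyNA(coords))
      stop("block for ", sub("^>\\s*", "", lines[heads[i]]),
           " is not k rows of 3 coordinates")
    coords
  })
  names(out) <- sub("^>\\s*", "", lines[heads])
  k <- vapply(out, nrow, 0L)
  if (length(unique(k)) != 1L)
    stop("landmark counts differ across specimens: ",
         paste(unique(k), collapse = ", "))
  out
}

#' Read landmark configurations from delimited text
#'
#' One row per specimen; columns `specimen` plus `L<i>_x`, `L<i>_y`, `L<i>_z`
#' for each landmark.
#'
#' @param file input path.
#' @return a named list of k x 3 matrices.
#' @export
read_landmarks <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  if (!"specimen" %in% names(df)) stop("missing 'specimen' column")
  coords <- as.matrix(df[, setdiff(names(df), "specimen"), drop = FALSE])
  if (ncol(coords) %% 3 != 0) stop("coordinate column count not a multiple of 3")
  out <- lapply(seq_len(nrow(coords)), function(i) {
    matrix(coords[i, ], ncol = 3, byrow = TRUE)
  })
  names(out) <- df$specimen
  out
}
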