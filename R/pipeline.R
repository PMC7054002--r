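#' Assemble a pipeline run configuration
#'
#' Plain-list configuration for the staged pipeline. All randomness flows
#' from one master seed: each stochastic stage draws from a named substream
#' derived deterministically from it. Can be round-tripped through YAML.
#'
#' @param tree_file,shape_file,allometry_file input paths (as written by
#'   [run_simulate()]).
#' @param out_dir output directory for reports.
#' @param seed master seed (mandatory whenever any stochastic stage runs).
#' @param n_perm permutation count for signal and shape-size tests.
#' @param retain number of bgPC axes to retain (default: groups - 1).
#' @param groups_col which column provides the grouping factor (`"group"`
#'   or `"species"`).
#' @return a list of class `run_config`.
#' @export
run_config <- function(tree_file = NULL, shape_file = NULL,
                       allometry_file = NULL, out_dir = "vestimorph_run",
                       seed = NULL, n_perm = 999, retain = NULL,
                       groups_col = "group") {
  structure(list(tree_file = tree_file, shape_file = shape_file,
                 allometry_file = allometry_file, out_dir = out_dir,
                 seed = seed, n_perm = n_perm, retain = retain,
                 groups_col = groups_col),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param file YAML path.
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, TRUE)], file)
  invisible(file)
}

# named substreams per stage, derived from the master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, signal = 23L, regression = 37L,
               fossil = 53L, allometry = 71L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

config_hash <- function(files) {
  files <- files[file.exists(files)]
  if (!length(files)) return(NA_character_)
  paste(substr(unname(tools::md5sum(files)), 1, 8), collapse = "-")
}

log_stage <- function(log_file, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(log_file)) cat(line, "\n", sep = "", file = log_file,
                              append = TRUE)
  invisible(line)
}

#' Simulate a full synthetic study and write it to disk
#'
#' Writes the tree (Newick), the specimen-level shape table, the allometry
#' table, the simulation truth and a manifest with the configuration hash
#' into `out_dir`. Re-running with the same seed reproduces every file
#' byte-for-byte.
#'
#' @param out_dir output directory.
#' @param seed mandatory master seed.
#' @param sim optional `sim_config` (its seed is overridden by `seed`).
#' @param force overwrite an existing non-empty directory?
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, seed = NULL, sim = NULL, force = FALSE) {
  if (is.null(seed)) stop("a master seed is required (refusing to simulate ",
                          "without one; pass seed = <int>)")
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  s <- stage_seed(seed, "simulate")
  if (is.null(sim)) {
    sim <- sim_config(seed = s)
  } else {
    sim$seed <- s
  }
  shapes <- simulate_shape_sample(sim)
  allo <- simulate_allometry(sim)
  paths <- list(tree = file.path(out_dir, "tree.nwk"),
                shapes = file.path(out_dir, "shape_table.tsv"),
                allometry = file.path(out_dir, "allometry.tsv"),
                truth = file.path(out_dir, "truth"))
  write_tree(sim$tree, paths$tree)
  write_shape_table(shapes$table, paths$shapes)
  write_allometry_table(allo$table, paths$allometry)
  write_sim_truth(shapes$truth, paths$truth)
  manifest <- list(seed = seed, stage_seed = s,
                   hash = config_hash(unlist(paths[1:3])))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  log_stage(log_file, "simulate",
            paste0("wrote ", out_dir, " (hash ", manifest$hash, ")"))
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Staged analysis over the files named in the configuration: species means
#' -> bgPCA -> leave-one-out classification and hierarchical-cluster check
#' -> phylogenetic signal per retained axis plus the multivariate statistic
#' -> OLS/PGLS/ANCOVA on the allometry table -> ancestral states and
#' phylomorphospace. One delimited-text report per stage is written into
#' `out_dir`; every report carries the configuration hash and seed in a
#' comment header. A stage failure aborts with the stage name and leaves a
#' `FAILED` marker file naming it.
#'
#' @param config a `run_config` (or path to its YAML form).
#' @return invisibly, a named list of the computed result objects.
#' @export
run_analyze <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$seed))
    stop("a master seed is required (stochastic stages are enabled)")
  for (f in c("tree_file", "shape_file", "allometry_file")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("input file missing: ", f, " = ", config[[f]])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  hash <- config_hash(c(config$tree_file, config$shape_file,
                        config$allometry_file))
  header <- sprintf("# config_hash: %s  seed: %d", hash, config$seed)
  write_report <- function(df, name) {
    path <- file.path(config$out_dir, name)
    writeLines(header, path)
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    path
  }
  results <- list()
  stage <- "load"
  on.exit({
    writeLines(paste("FAILED at stage:", stage),
               file.path(config$out_dir, "FAILED"))
  })
  run_stage <- function(name, expr) {
    stage <<- name
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed [E_", toupper(name), "]: ",
           conditionMessage(e), call. = FALSE)
    })
    log_stage(log_file, name,
              sprintf("done in %.2fs", as.numeric(Sys.time() - t0, "secs")))
    out
  }

  tree <- run_stage("load", read_tree(config$tree_file))
  table <- read_shape_table(config$shape_file)
  allo <- read_allometry_table(config$allometry_file)
  if (config$groups_col == "species") table$group <- table$species

  means <- run_stage("means", species_means(table))
  model <- run_stage("bgpca", fit_bgpca(table, retain = config$retain))
  results$bgpca <- model
  eig_df <- data.frame(axis = paste0("bgPC", seq_along(model$eigenvalues)),
                       eigenvalue = model$eigenvalues,
                       var_explained = model$var_explained)
  write_report(eig_df, "bgpca_eigenvalues.tsv")
  write_report(data.frame(specimen = table$specimen, group = table$group,
                          model$scores), "bgpca_scores.tsv")

  cls <- run_stage("classify", loo_classify(table, retain = config$retain))
  results$classification <- cls
  write_report(data.frame(group = rownames(cls$confusion),
                          round(cls$confusion, 1),
                          check.names = FALSE), "classification_confusion.tsv")
  hca <- run_stage("hca", hca_confusion(table))
  results$hca <- hca
  write_report(data.frame(group = names(hca), percent_correct = unname(hca)),
               "hca_confusion.tsv")

  results$signal <- run_stage("signal", {
    sm_scores <- project_bgpca(model, align_to_tree(means, tree))
    rownames(sm_scores) <- tree$tip.label
    sig <- list()
    for (j in seq_len(ncol(sm_scores))) {
      axis <- paste0("bgPC", j)
      y <- stats::setNames(sm_scores[, j], tree$tip.label)
      sig[[paste0("lambda_", axis)]] <- pagel_lambda(tree, y)
      sig[[paste0("K_", axis)]] <- blomberg_k(
        tree, y, n_perm = config$n_perm, seed = stage_seed(config$seed, "signal") + j)
    }
    sig$Kmult <- k_mult(tree, sm_scores, n_perm = config$n_perm,
                        seed = stage_seed(config$seed, "signal"))
    write_signal_results(sig, file.path(config$out_dir, "signal.tsv"))
    sig
  })

  results$regressions <- run_stage("regress", {
    sm_scores <- project_bgpca(model, align_to_tree(means, tree))
    sp_allo <- stats::aggregate(allo[, c("ln_Vol", "ln_VolSC", "ln_L")],
                                list(species = allo$species), mean)
    regs <- list()
    # individual-level OLS per axis vs ln Vol
    ind_scores <- model$scores
    lnvol <- allo$ln_Vol[match(table$specimen, allo$specimen)]
    ok <- !is.na(lnvol)
    for (j in seq_len(min(3, ncol(ind_scores)))) {
      regs[[paste0("OLS_bgPC", j, "_vs_lnVol")]] <-
        ols_fit(lnvol[ok], ind_scores[ok, j])
    }
    regs$OLS_lnVolSC_vs_lnL <- ols_fit(allo$ln_L, allo$ln_VolSC)
    # species-level PGLS
    idx <- match(tree$tip.label, sp_allo$species)
    if (!anyNA(idx)) {
      xv <- stats::setNames(sp_allo$ln_Vol[idx], tree$tip.label)
      for (j in seq_len(min(3, ncol(sm_scores)))) {
        yv <- stats::setNames(sm_scores[, j], tree$tip.label)
        regs[[paste0("PGLS_bgPC", j, "_vs_lnVol")]] <- pgls_fit(tree, xv, yv)
      }
      regs$PGLS_lnVolSC_vs_lnL <- pgls_fit(
        tree, stats::setNames(sp_allo$ln_L[idx], tree$tip.label),
        stats::setNames(sp_allo$ln_VolSC[idx], tree$tip.label))
    }
    write_report(regression_report(regs), "regressions.tsv")
    regs
  })

  results$ancova <- run_stage("ancova", {
    is_hominid <- allo$group == "Hominidae"
    if (length(unique(is_hominid)) == 2L) {
      a <- ancova(allo$ln_L, allo$ln_VolSC,
                  ifelse(is_hominid, "Hominidae", "other"))
      write_report(data.frame(test = c("slopes", "intercepts"),
                              F = c(a$F_slopes, a$F_intercepts),
                              p = c(a$p_slopes, a$p_intercepts)),
                   "ancova.tsv")
      a
    } else NULL
  })

  results$shape_size <- run_stage("shape_size", {
    lnvol <- allo$ln_Vol[match(table$specimen, allo$specimen)]
    ok <- !is.na(lnvol)
    if (sum(ok) >= 5) {
      ss <- shape_size_regression(table$descriptors[ok, , drop = FALSE],
                                  lnvol[ok], n_perm = config$n_perm,
                                  seed = stage_seed(config$seed, "regression"))
      write_report(data.frame(R2 = ss$r_squared, p = ss$p_value, n = ss$n),
                   "shape_size.tsv")
      ss
    } else NULL
  })

  results$ancestral <- run_stage("ancestral", {
    sm_scores <- project_bgpca(model, align_to_tree(means, tree))
    rownames(sm_scores) <- tree$tip.label
    anc <- ml_ancestral(tree, sm_scores)
    write_ancestral_states(anc, file.path(config$out_dir, "ancestral.tsv"))
    if (ncol(sm_scores) >= 2) {
      pms <- build_phylomorphospace(tree, sm_scores[, 1:2])
      write_phylomorphospace(pms, file.path(config$out_dir,
                                            "phylomorphospace.tsv"))
    }
    anc
  })

  on.exit()   # all stages succeeded: clear the FAILED marker hook
  if (file.exists(file.path(config$out_dir, "FAILED")))
    unlink(file.path(config$out_dir, "FAILED"))
  log_stage(log_file, "done", paste("reports in", config$out_dir))
  invisible(results)
}
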