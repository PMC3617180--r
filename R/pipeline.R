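#' Run the full mandible-shape analysis on a fixture bundle
#'
#' Orchestrates the whole workflow in the order of the study it
#' implements: GPA superimposition, per-taxon means, evolutionary
#' allometry (with residual shapes), PCA on the raw and the
#' size-corrected covariance, squared-change-parsimony ancestral shapes
#' with the tree projected into PC space, permutation tests of
#' phylogenetic signal on the whole tree and on user-defined clades,
#' homoplasy indices for clades small enough for exhaustive Steiner
#' search, CVA with leave-one-out cross-validation and classification of
#' ungrouped specimens for each grouping, between-group Procrustes
#' distance tests, and mechanical-advantage tables for taxon means,
#' group means, PC-reconstructed shapes and allometry-predicted sizes.
#' Stages are pure functions of the bundle and the configuration, so a
#' rerun with the same seed reproduces the report exactly.
#'
#' @param bundle directory containing `landmarks.tps`, `tree.nwk` (or any
#'   newick/NEXUS tree file named in `config$tree_file`) and `groups.tsv`
#'   — e.g. the output of [write_fixture_bundle()].
#' @param config named list of options; unset entries take the defaults:
#'   `seed` (1), `n_perm` (499), `clades` (named list of taxon vectors to
#'   test separately; default none), `steiner_max_taxa` (8; clades up to
#'   this size get exact SCI/SRI), `muscle_map` ([muscle_map()]),
#'   `pc_scores` (c(-0.1, 0.1)), `cs_values` (c(100, 300)), `groupings`
#'   (c("diet", "locomotion")).
#' @return a `pipeline_report` list with components `gpa`, `taxon_means`,
#'   `allometry`, `pca_raw`, `pca_residual`, `ancestral`,
#'   `tree_projection`, `signal` (whole tree + clades), `homoplasy`,
#'   `cva` (per grouping: model, classification, distances), `lever`
#'   (tables), and `provenance`.
#' @export
run_full_analysis <- function(bundle, config = list()) {
  defaults <- list(seed = 1L, n_perm = 499L, clades = list(),
                   steiner_max_taxa = 8L, muscle_map = muscle_map(),
                   pc_scores = c(-0.1, 0.1), cs_values = c(100, 300),
                   groupings = c("diet", "locomotion"),
                   tree_file = "tree.nwk")
  config <- utils::modifyList(defaults, as.list(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ds <- stage("read", {
    d <- read_tps(file.path(bundle, "landmarks.tps"))
    gf <- file.path(bundle, "groups.tsv")
    if (file.exists(gf)) d <- read_groups(gf, d)
    d
  })
  tree <- stage("read_tree",
                read_tree(file.path(bundle, config$tree_file),
                          taxa = unique(ds$taxon)))
  aligned <- stage("gpa", gpa_align(ds))
  means <- stage("taxon_means", taxon_mean_shapes(aligned))

  allom <- stage("allometry",
                 fit_allometry(means, n_perm = config$n_perm,
                               seed = config$seed))
  resid_ds <- stage("residuals", residual_shapes(allom, means))

  pca_raw <- stage("pca_raw", fit_shape_pca(means))
  pca_res <- stage("pca_residual", fit_shape_pca(resid_ds))

  anc <- stage("ancestral", reconstruct_ancestral_shapes(tree, means))
  proj <- stage("tree_projection",
                map_tree_to_ordination(pca_raw, tree, anc))

  signal <- list(full_tree = stage("signal",
    permutation_signal_test(tree, means, n_perm = config$n_perm,
                            seed = config$seed)))
  homoplasy <- list()
  for (cl in names(config$clades)) {
    taxa <- intersect(config$clades[[cl]], tree$tip.label)
    if (length(taxa) < 4L) next
    sub_tree <- ape::keep.tip(tree, taxa)
    sub_tree$edge.length <- rep(1, nrow(sub_tree$edge))
    sub_means <- means[match(taxa, means$taxon)]
    signal[[cl]] <- stage(paste0("signal_", cl),
      permutation_signal_test(sub_tree, sub_means, n_perm = config$n_perm,
                              seed = config$seed))
    if (length(taxa) <= config$steiner_max_taxa)
      homoplasy[[cl]] <- stage(paste0("homoplasy_", cl),
        homoplasy_indices(sub_tree, sub_means,
                          max_taxa_exhaustive = config$steiner_max_taxa))
  }

  cva <- list()
  for (gr in config$groupings) {
    has_groups <- sum(aligned[[gr]] != "ungrouped") >= 4L &&
      length(unique(aligned[[gr]][aligned[[gr]] != "ungrouped"])) >= 2L
    if (!has_groups) {
      cva[[gr]] <- list(skipped = paste("no usable", gr, "groups"))
      next
    }
    model <- stage(paste0("cva_", gr), fit_cva(aligned, gr))
    cls <- stage(paste0("classify_", gr),
                 classify_specimens(model, aligned, cross_validate = TRUE))
    dst <- stage(paste0("distances_", gr),
                 group_distance_tests(aligned, gr, n_perm = config$n_perm,
                                      seed = config$seed))
    cva[[gr]] <- list(model = model, classification = cls, distances = dst)
  }

  lever <- stage("lever", {
    mm <- config$muscle_map
    shapes <- lapply(seq_len(means$n), function(j)
      fold_shape(means$tangent[j, ] + flat_shape(means$consensus)))
    names(shapes) <- means$taxon
    tabs <- list(taxon_means = advantage_table(shapes, mm))
    grp_shapes <- list()
    for (dg in setdiff(unique(aligned$diet), "ungrouped")) {
      sel <- aligned$diet == dg
      grp_shapes[[dg]] <- fold_shape(colMeans(
        aligned$tangent[sel, , drop = FALSE]) + flat_shape(aligned$consensus))
    }
    if (length(grp_shapes))
      tabs$diet_means <- advantage_table(grp_shapes, mm)
    pc_shapes <- list()
    for (s in config$pc_scores)
      pc_shapes[[sprintf("PC1 score = %g", s)]] <- shape_at_score(pca_raw, 1, s)
    tabs$pc1 <- advantage_table(pc_shapes, mm)
    cs_shapes <- list()
    for (cs in config$cs_values)
      cs_shapes[[sprintf("Centroid size = %g mm", cs)]] <-
        predict_shape_at_size(allom, cs)
    tabs$predicted_size <- advantage_table(cs_shapes, mm)
    tabs
  })

  structure(list(
    gpa = list(n = aligned$n, k = aligned$k,
               iterations = aligned$gpa$iterations,
               converged = aligned$gpa$converged,
               consensus = aligned$consensus),
    taxon_means = means, aligned = aligned,
    allometry = allom, pca_raw = pca_raw, pca_residual = pca_res,
    ancestral = anc, tree_projection = proj,
    signal = signal, homoplasy = homoplasy,
    cva = cva, lever = lever,
    provenance = list(config = config[setdiff(names(config), "muscle_map")],
                      seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("sciurmorph")))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  GPA: %d specimens, %d landmarks, converged in %d iterations\n",
              x$gpa$n, x$gpa$k, x$gpa$iterations))
  cat(sprintf("  Allometry: %.2f%% of shape predicted by size (p = %.4g)\n",
              x$allometry$percent_predicted, x$allometry$p_permutation))
  cat(sprintf("  PCA: PC1 %.2f%%, PC2 %.2f%%\n",
              x$pca_raw$percent[1], x$pca_raw$percent[2]))
  cat(sprintf("  Signal: tree length %.4g, p = %.4g\n",
              x$signal$full_tree$observed_length, x$signal$full_tree$p_value))
  for (gr in names(x$cva))
    if (!is.null(x$cva[[gr]]$classification))
      cat(sprintf("  CVA (%s): %.1f%% correct (%.1f%% cross-validated)\n",
                  gr, x$cva[[gr]]$classification$percent_correct,
                  x$cva[[gr]]$classification$percent_correct_cv))
  invisible(x)
}
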