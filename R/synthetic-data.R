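#' Template landmark configurations
#'
#' `"squirrel_mandible_14"` is a fixed 14-landmark schematic of a sciurid
#' mandible in buccal view (x anterior, y dorsal, mm), with the condyle
#' pair (7, 8), incisor alveolus (1, 13), coronoid (4, 5), angular process
#' (10, 11) and masseteric ridge (14) in anatomically sensible relative
#' positions; in particular the incisor resistance arm exceeds every
#' default muscle moment arm, as on real mandibles. `"polygon"` gives a
#' regular k-gon (for `k = 4`, exactly the unit square), useful for toy
#' examples.
#'
#' @param style `"squirrel_mandible_14"` or `"polygon"`.
#' @param k landmark count for `"polygon"` (ignored otherwise).
#' @return a `k x 2` landmark matrix; deterministic.
#' @export
make_template <- function(style = c("squirrel_mandible_14", "polygon"),
                          k = 4L) {
  style <- match.arg(style)
  if (style == "squirrel_mandible_14") {
    m <- matrix(c(
      30.0, 6.0,   # 1  antero-dorsal border of incisive alveolus (bite point)
      24.0, 4.5,   # 2  most concave point of the diastema
      19.0, 5.5,   # 3  anterior alveolus of the lower premolar
      12.0, 6.0,   # 4  base of the coronoid process
       9.0, 12.0,  # 5  tip of the coronoid process
       6.5, 9.5,   # 6  most concave point of the incisura mandibulare
       4.0, 8.0,   # 7  anterior edge of the condylar articular surface
       2.5, 8.0,   # 8  posterior edge of the condylar articular surface
       2.0, 4.5,   # 9  most anterior point on the posterior-edge curve
       2.0, 1.0,   # 10 posterior tip of the angular process
       6.0, 0.0,   # 11 most ventral point of the angular process
      11.0, 1.5,   # 12 most dorsal point on the ventral border of the ramus
      29.5, 3.5,   # 13 antero-ventral border of the incisive alveolus
      17.0, 2.0),  # 14 anterior edge of the masseteric ridge
      ncol = 2, byrow = TRUE)
    return(m)
  }
  k <- as.integer(k)
  if (k < 3L) stop("polygon template needs k >= 3")
  ang <- 5 * pi / 4 + 2 * pi * (seq_len(k) - 1L) / k
  cbind(0.5 + sqrt(0.5) * cos(ang), 0.5 + sqrt(0.5) * sin(ang))
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data model: per-taxon mean shapes evolve by
#' Brownian motion on a (unit-branch-length) tree in the tangent space of
#' the template, dietary groups add a fixed shape offset, a common
#' allometric vector `b` adds `b * CS`, and individual specimens add
#' isotropic landmark noise. Shape-space amplitudes are kept small
#' relative to the (unit-size) template so that the simulated variation
#' stays in the small-variation regime the tangent-space methods assume.
#'
#' @param n_taxa number of taxa (ignored when `tree` is supplied).
#' @param tree optional `phylo`; otherwise a Yule topology is drawn and
#'   all branch lengths set to 1.
#' @param bm_sd Brownian-motion standard deviation per coordinate per
#'   unit branch (shape units; default 0.005).
#' @param diet_groups dietary categories to use (default the seven
#'   ecological groups).
#' @param diet_effect_sd size of each group's shape offset (default
#'   0.007); offsets are drawn once per group from an isotropic normal
#'   with this per-coordinate sd.
#' @param locomotion_groups locomotor categories cycled over taxa.
#' @param b_scale length of the allometric vector per mm of centroid
#'   size (default 1.2e-4: across the default size range the size effect
#'   then predicts on the order of a tenth of the among-taxon shape
#'   variance — weak but statistically detectable allometry).
#' @param cs_range centroid-size range in mm, sampled log-uniformly
#'   (default 50–800, pygmy squirrel to marmot).
#' @param n_specimens specimens per taxon (default 3).
#' @param noise_sd per-landmark-coordinate specimen noise (shape units,
#'   default 0.009).
#' @param template `k x 2` template configuration.
#' @param seed integer seed; all randomness flows from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_taxa = 40L, tree = NULL, bm_sd = 0.005,
                              diet_groups = setdiff(DIET_LEVELS, "ungrouped"),
                              diet_effect_sd = 0.007,
                              locomotion_groups = setdiff(LOCOMOTION_LEVELS,
                                                          "ungrouped"),
                              b_scale = 1.2e-4, cs_range = c(50, 800),
                              n_specimens = 3L, noise_sd = 0.009,
                              template = make_template("squirrel_mandible_14"),
                              seed = 1L) {
  stopifnot(bm_sd >= 0, diet_effect_sd >= 0, b_scale >= 0, noise_sd >= 0,
            n_specimens >= 1L, length(cs_range) == 2L,
            all(cs_range > 0), cs_range[2] >= cs_range[1])
  if (is.null(seed)) stop("a seed is mandatory")
  check_vocab(diet_groups, DIET_LEVELS, "diet")
  check_vocab(locomotion_groups, LOCOMOTION_LEVELS, "locomotion")
  structure(list(n_taxa = as.integer(n_taxa), tree = tree, bm_sd = bm_sd,
                 diet_groups = diet_groups, diet_effect_sd = diet_effect_sd,
                 locomotion_groups = locomotion_groups, b_scale = b_scale,
                 cs_range = cs_range, n_specimens = as.integer(n_specimens),
                 noise_sd = noise_sd, template = template,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Brownian motion of an m-vector along a rooted unit-branch-length tree;
# returns values at all nodes (tips 1..ntip, internals ntip+1..), root = 0.
simulate_bm <- function(tree, m, sd) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  vals <- matrix(0, nn, m)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(ord))) {
    par <- ord[e, 1]; ch <- ord[e, 2]
    vals[ch, ] <- vals[par, ] + stats::rnorm(m, sd = sd)
  }
  vals
}

#' Simulate a landmark dataset with known ground truth
#'
#' Taxon mean shapes are the unit-size template plus a Brownian deviation
#' accumulated along the tree, plus the taxon's diet-group offset, plus
#' `b * CS`. Each specimen is the taxon mean with isotropic landmark
#' noise, scaled to its centroid size and given a random rotation and
#' translation (what digitized photographs look like before
#' superimposition). Everything simulated is recorded in `truth`.
#'
#' @param config a [simulation_config()].
#' @return a list: `dataset` (raw-coordinate [shape_dataset()] with diet
#'   and locomotion labels), `tree` (`phylo`, unit branch lengths), and
#'   `truth` (template preshape, taxon mean tangent deviations and full
#'   mean vectors, internal-node Brownian deviations, allometric vector
#'   `b`, per-group effect vectors, group labels, taxon centroid sizes,
#'   the seed).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  z0 <- preshape(config$template)      # unit-size template
  k <- nrow(z0); m <- 2L * k

  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
    tree$tip.label <- sprintf("taxon_%02d", seq_len(config$n_taxa))
  }
  tree$edge.length <- rep(1, nrow(tree$edge))
  n_taxa <- length(tree$tip.label)

  bm <- simulate_bm(tree, m, config$bm_sd)
  diet <- rep_len(config$diet_groups, n_taxa)
  locom <- rep_len(config$locomotion_groups, n_taxa)
  effects <- matrix(stats::rnorm(length(config$diet_groups) * m,
                                 sd = config$diet_effect_sd),
                    nrow = length(config$diet_groups),
                    dimnames = list(config$diet_groups, NULL))
  b <- stats::rnorm(m); b <- b / sqrt(sum(b^2)) * config$b_scale
  cs <- exp(stats::runif(n_taxa, log(config$cs_range[1]),
                         log(config$cs_range[2])))

  mean_tang <- bm[seq_len(n_taxa), , drop = FALSE] +
    effects[diet, , drop = FALSE] + outer(cs, b)
  rownames(mean_tang) <- tree$tip.label
  mean_shapes <- sweep(mean_tang, 2, flat_shape(z0), `+`)

  n_spec <- n_taxa * config$n_specimens
  coords <- array(NA_real_, c(k, 2, n_spec))
  ids <- taxa <- sdiet <- slocom <- character(n_spec)
  j <- 0L
  for (t in seq_len(n_taxa)) {
    for (s in seq_len(config$n_specimens)) {
      j <- j + 1L
      v <- mean_shapes[t, ] + stats::rnorm(m, sd = config$noise_sd)
      sh <- fold_shape(v) * cs[t]
      th <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sh <- sh %*% R
      sh <- sweep(sh, 2, stats::runif(2, -50, 50), `+`)
      coords[, , j] <- sh
      ids[j] <- sprintf("%s_s%02d", tree$tip.label[t], s)
      taxa[j] <- tree$tip.label[t]
      sdiet[j] <- diet[t]; slocom[j] <- locom[t]
    }
  }
  dataset <- shape_dataset(coords, ids, taxa, sdiet, slocom)
  truth <- list(template = z0,
                taxon_mean_tangent = mean_tang,
                taxon_mean_shapes = mean_shapes,
                node_bm = bm[-seq_len(n_taxa), , drop = FALSE],
                b = b, diet_effects = effects,
                diet = stats::setNames(diet, tree$tip.label),
                locomotion = stats::setNames(locom, tree$tip.label),
                cs = stats::setNames(cs, tree$tip.label),
                seed = config$seed)
  list(dataset = dataset, tree = tree, truth = truth)
}

#' Write a simulated fixture bundle to a directory
#'
#' Materializes a simulation as the plain-text files the pipeline
#' consumes: `landmarks.tps`, `tree.nwk`, `groups.tsv`, `truth.json`
#' (ground truth) and `config.txt` (a key = value echo of the
#' configuration).
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory (default FALSE).
#' @return the directory path, invisibly; the simulation itself is
#'   attached as attribute `"simulation"`.
#' @export
write_fixture_bundle <- function(config = simulation_config(), dir,
                                 force = FALSE) {
  if (dir.exists(dir) && length(dir(dir, all.files = TRUE, no.. = TRUE)) &&
      !force)
    stop("directory ", dir, " is not empty (use force = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config)
  write_tps(sim$dataset, file.path(dir, "landmarks.tps"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write_groups(sim$dataset, file.path(dir, "groups.tsv"))
  jsonlite::write_json(lapply(sim$truth, unclass),
                       file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  cfg <- config[setdiff(names(config), c("template", "tree"))]
  writeLines(c(sprintf("%s = %s", names(cfg),
                       vapply(cfg, function(v) paste(format(v), collapse = " "),
                              character(1))),
               sprintf("template_k = %d", nrow(config$template))),
             file.path(dir, "config.txt"))
  out <- dir
  attr(out, "simulation") <- sim
  invisible(out)
}
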