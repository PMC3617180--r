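#' Muscle insertion to landmark mapping for lever-arm analysis
#'
#' Names the landmarks used as muscle insertion points and bite point in
#' the 14-landmark mandible scheme. The jaw pivot is the tip of the
#' mandibular condyle, taken as the midpoint of the condyle landmark pair
#' (7, 8); the bite point is the antero-dorsal border of the incisive
#' alveolus (landmark 1). Default insertions: temporalis dorsal fibers
#' `MT2p` at the coronoid tip (5), temporalis ventral fibers `MT` at the
#' base of the coronoid (4, the surrogate used for reconstructed shapes),
#' superficial masseter `MSM9p` at the posterior tip of the angular
#' process (10) and `MSM8p` at its most ventral point (11), anterior deep
#' masseter `MADM` at the anterior edge of the masseteric ridge (14).
#' The `MT2p`/`MSM8p`/`MSM9p` assignments follow the classical
#' lever-model nomenclature but are anatomically motivated choices, so
#' every index is overridable.
#'
#' @param MT2p,MT,MSM8p,MSM9p,MADM insertion landmark indices.
#' @param incisor bite-point (resistance) landmark index.
#' @param condyle length-2 vector; the pivot is their midpoint.
#' @return a `muscle_map` list.
#' @export
muscle_map <- function(MT2p = 5L, MT = 4L, MSM8p = 11L, MSM9p = 10L,
                       MADM = 14L, incisor = 1L, condyle = c(7L, 8L)) {
  stopifnot(length(condyle) == 2L, condyle[1] != condyle[2])
  structure(list(muscles = c(MT2p = MT2p, MT = MT, MSM8p = MSM8p,
                             MSM9p = MSM9p, MADM = MADM),
                 incisor = incisor, condyle = condyle),
            class = "muscle_map")
}

#' Jaw lever arms and mechanical advantage
#'
#' The pivot is the midpoint of the condyle landmark pair. Each muscle
#' moment arm is the Euclidean distance from the pivot to its insertion
#' landmark; the incisor resistance arm `RI` is the distance from the
#' pivot to the bite point. Mechanical advantage of a muscle is its
#' moment arm divided by `RI` (dimensionless, scale-free). On real
#' mandibles `RI` exceeds every moment arm, so advantages below 1 are
#' expected; an advantage of 1 or more triggers a warning, not an error.
#'
#' @param shape `k x 2` landmark configuration (or a 2k shape vector).
#' @param map a [muscle_map()]; indices must be valid for `k`.
#' @return a `lever_arms` list: `pivot` (x, y), `RI`, `arms` (named
#'   moment arms, same units as the input), `advantage` (named ratios).
#' @export
compute_lever_arms <- function(shape, map = muscle_map()) {
  if (is.null(dim(shape))) shape <- fold_shape(shape)
  stopifnot(inherits(map, "muscle_map"))
  k <- nrow(shape)
  idx <- c(map$muscles, map$incisor, map$condyle)
  if (any(idx < 1L | idx > k))
    stop("muscle map index out of range for k = ", k)
  pivot <- colMeans(shape[map$condyle, , drop = FALSE])
  dist_to <- function(i) sqrt(sum((shape[i, ] - pivot)^2))
  RI <- dist_to(map$incisor)
  if (RI <= 0)
    stop("degenerate resistance arm: pivot coincides with the incisor landmark")
  arms <- vapply(map$muscles, dist_to, numeric(1))
  if (any(arms >= RI))
    warning("moment arm(s) ", paste(names(arms)[arms >= RI], collapse = ", "),
            " not shorter than the incisor resistance arm")
  structure(list(pivot = pivot, RI = RI, arms = arms,
                 advantage = arms / RI),
            class = "lever_arms")
}

#' @export
print.lever_arms <- function(x, ...) {
  cat(sprintf("RI = %.4g; mechanical advantage: %s\n", x$RI,
              paste(sprintf("%s = %.2f", names(x$advantage), x$advantage),
                    collapse = ", ")))
  invisible(x)
}

#' Mechanical-advantage table for a collection of shapes
#'
#' One row per named shape with the five muscle mechanical advantages —
#' the layout used to compare species, group means, and shapes
#' reconstructed along ordination axes or at predicted sizes. Accepts
#' `k x 2` matrices, 2k shape vectors, or a [shape_dataset()] (one row
#' per specimen, from the aligned shapes when available).
#'
#' @param shapes a named list of configurations, or a `shape_dataset`.
#' @param map a [muscle_map()].
#' @param digits round advantages to this many decimals (default `NULL`,
#'   no rounding; the published tables use 2).
#' @return a data frame with columns `shape`, `RI`, `MT2p`, `MT`,
#'   `MSM8p`, `MSM9p`, `MADM`.
#' @export
advantage_table <- function(shapes, map = muscle_map(), digits = NULL) {
  if (inherits(shapes, "shape_dataset")) {
    ds <- shapes
    shapes <- lapply(seq_len(ds$n), function(j)
      if (isTRUE(ds$aligned))
        fold_shape(ds$tangent[j, ] + flat_shape(ds$consensus))
      else ds$coords[, , j])
    names(shapes) <- ds$specimen_id
  }
  stopifnot(is.list(shapes), length(shapes) >= 1L)
  if (is.null(names(shapes)))
    names(shapes) <- paste0("shape_", seq_along(shapes))
  ks <- vapply(shapes, function(s)
    if (is.null(dim(s))) length(s) / 2L else nrow(s), numeric(1))
  if (length(unique(ks)) != 1L)
    stop("all shapes must share the same landmark count")
  rows <- lapply(shapes, function(s) {
    la <- compute_lever_arms(s, map)
    c(RI = la$RI, la$advantage)
  })
  out <- data.frame(shape = names(shapes),
                    do.call(rbind, rows),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(digits))
    out[-1] <- lapply(out[-1], round, digits = digits)
  out
}
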