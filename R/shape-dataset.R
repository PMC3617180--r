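#' @keywords internal
"_PACKAGE"

#' Dietary group vocabulary
#'
#' Closed vocabulary of dietary categories used for specimen grouping:
#' frugivores, nut eaters, granivores, folivores, strict herbivores
#' (grasses and other hard plant tissue), bark gleaners, insectivores,
#' plus `"ungrouped"` for specimens without a known diet (e.g. fossils).
#' @export
DIET_LEVELS <- c("fruits", "nuts", "seeds", "leaves", "herbivore_ss",
                 "bark_gleaner", "insects", "ungrouped")

#' Locomotor group vocabulary
#'
#' Closed vocabulary of locomotor categories: terrestrial,
#' arboreal/scansorial, gliding, plus `"ungrouped"`.
#' @export
LOCOMOTION_LEVELS <- c("terrestrial", "arboreal_scansorial", "gliding",
                       "ungrouped")

#' Construct a shape dataset
#'
#' A `shape_dataset` bundles the landmark configurations of a sample of
#' specimens with their taxonomic and ecological labels. Coordinates are
#' stored as a `k x 2 x n` array (landmarks x dimensions x specimens), the
#' convention of landmark-morphometrics software. Centroid sizes are
#' computed from the raw coordinates at construction. After Procrustes
#' superimposition (see [gpa_align()]) the object additionally carries the
#' consensus shape and a matrix of tangent coordinates.
#'
#' Shape vectors throughout the package are laid out column-major:
#' `c(x_1..x_k, y_1..y_k)`, i.e. `as.vector()` of the `k x 2` matrix.
#'
#' @param coords numeric `k x 2 x n` array of raw landmark coordinates (mm).
#' @param specimen_id character vector of length `n`; unique specimen ids.
#' @param taxon character vector of length `n`; taxon of each specimen.
#' @param diet,locomotion character vectors of length `n` drawn from
#'   [DIET_LEVELS] / [LOCOMOTION_LEVELS]; default `"ungrouped"`.
#' @return an object of class `shape_dataset` with fields `coords`,
#'   `specimen_id`, `taxon`, `diet`, `locomotion`, `cs` (centroid sizes),
#'   `k`, `n`, `aligned` (logical), and once aligned `consensus`
#'   (`k x 2`, unit centroid size) and `tangent` (`n x 2k`).
#' @export
shape_dataset <- function(coords, specimen_id,
                          taxon = specimen_id,
                          diet = rep("ungrouped", length(specimen_id)),
                          locomotion = rep("ungrouped", length(specimen_id))) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  n <- dim(coords)[3]
  k <- dim(coords)[1]
  if (n == 0L) stop("shape_dataset must contain at least one specimen")
  if (k < 3L) stop("at least 3 landmarks are required, got ", k)
  if (!all(is.finite(coords))) stop("all landmark coordinates must be finite")
  specimen_id <- trimws(as.character(specimen_id))
  taxon <- trimws(as.character(taxon))
  if (length(specimen_id) != n || length(taxon) != n)
    stop("specimen_id/taxon length must match the number of specimens")
  if (any(!nzchar(taxon))) stop("taxon labels must be non-empty")
  check_vocab(diet, DIET_LEVELS, "diet")
  check_vocab(locomotion, LOCOMOTION_LEVELS, "locomotion")
  cs <- apply(coords, 3, centroid_size_xy)
  structure(list(coords = coords, specimen_id = specimen_id, taxon = taxon,
                 diet = as.character(diet),
                 locomotion = as.character(locomotion),
                 cs = cs, k = k, n = n,
                 aligned = FALSE, consensus = NULL, tangent = NULL),
            class = "shape_dataset")
}

check_vocab <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad))
    stop(sprintf("unknown %s token(s) %s; allowed: {%s}", what,
                 paste(sQuote(bad), collapse = ", "),
                 paste(levels, collapse = ", ")))
  invisible(TRUE)
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat(sprintf("shape_dataset: %d specimens, %d landmarks (2D), %d taxa\n",
              x$n, x$k, length(unique(x$taxon))))
  cat(sprintf("  centroid size: %.3g - %.3g\n", min(x$cs), max(x$cs)))
  cat(sprintf("  aligned: %s\n", if (isTRUE(x$aligned)) "yes" else "no"))
  invisible(x)
}

# fold a 2k shape vector into k x 2 landmark form
fold_shape <- function(v) matrix(v, ncol = 2)

# flatten k x 2 landmark form into a 2k vector (x block then y block)
flat_shape <- function(m) as.vector(m)

centroid_size_xy <- function(m) {
  ctr <- colMeans(m)
  sqrt(sum(sweep(m, 2, ctr)^2))
}

#' Subset a shape dataset
#'
#' @param x a `shape_dataset`.
#' @param i integer or logical index over specimens.
#' @param ... unused.
#' @return the subsetted `shape_dataset`; alignment fields are carried over.
#' @export
`[.shape_dataset` <- function(x, i, ...) {
  out <- shape_dataset(x$coords[, , i, drop = FALSE], x$specimen_id[i],
                       x$taxon[i], x$diet[i], x$locomotion[i])
  out$cs <- x$cs[i]
  if (isTRUE(x$aligned)) {
    out$aligned <- TRUE
    out$consensus <- x$consensus
    out$tangent <- x$tangent[i, , drop = FALSE]
  }
  out
}
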