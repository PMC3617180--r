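#' Principal component analysis of shape
#'
#' Eigendecomposition of the covariance matrix of tangent coordinates
#' (taxon means as rows; covariance, not correlation). Four dimensions are
#' lost to superimposition, so at most `min(n - 1, 2k - 4)` axes carry
#' variance; axes with eigenvalue below `1e-12 *` trace are dropped. For a
#' deterministic sign, each eigenvector's largest-magnitude entry is made
#' positive.
#'
#' @param dataset an aligned [shape_dataset()] (raw tangent coordinates or
#'   the residuals from [residual_shapes()]).
#' @return a `shape_pca`: `eigenvalues`, `vectors` (2k x m, orthonormal
#'   columns), `scores` (n x m), `percent` (of total variance), `center`
#'   (2k mean vector), `consensus`, `k`, `taxa`.
#' @export
fit_shape_pca <- function(dataset) {
  stopifnot(inherits(dataset, "shape_dataset"), isTRUE(dataset$aligned))
  Y <- dataset$tangent
  if (nrow(Y) < 3L) stop("PCA needs at least 3 taxa")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  e <- eigen(stats::cov(Yc), symmetric = TRUE)
  tot <- sum(pmax(e$values, 0))
  keep <- which(e$values > 1e-12 * tot)
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- Yc %*% vecs
  rownames(scores) <- dataset$taxon
  colnames(scores) <- colnames(vecs) <- paste0("PC", seq_along(keep))
  structure(list(eigenvalues = vals, vectors = vecs, scores = scores,
                 percent = 100 * vals / tot, center = ctr,
                 consensus = dataset$consensus, k = dataset$k,
                 taxa = dataset$taxon),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- min(4L, length(x$eigenvalues))
  cat(sprintf("Shape PCA: %d taxa, %d non-null axes\n",
              nrow(x$scores), length(x$eigenvalues)))
  cat(sprintf("  %s explain%s %s of the variance\n",
              paste(colnames(x$scores)[1:m], collapse = "/"),
              if (m == 1) "s" else "",
              paste(sprintf("%.2f%%", x$percent[1:m]), collapse = "/")))
  invisible(x)
}

#' Reconstruct the shape at a score along a principal axis
#'
#' `mean shape + score * eigenvector`, folded back to `k x 2` landmark
#' form: the wireframes drawn along ordination axes. At score 0 this is
#' the sample mean shape.
#'
#' @param pca a `shape_pca` from [fit_shape_pca()].
#' @param axis axis index (within the non-null axes).
#' @param score scalar position along the axis.
#' @return `k x 2` landmark configuration.
#' @export
shape_at_score <- function(pca, axis = 1L, score = 0) {
  stopifnot(inherits(pca, "shape_pca"))
  if (axis < 1L || axis > ncol(pca$vectors))
    stop("axis out of range 1..", ncol(pca$vectors))
  v <- pca$center + score * pca$vectors[, axis] + flat_shape(pca$consensus)
  fold_shape(v)
}

#' Project a phylogeny into ordination space
#'
#' Scores the reconstructed ancestral shapes of every internal node on the
#' retained principal axes, so that tree edges can be drawn in PC space.
#' Tip shapes project onto their ordinary PCA scores.
#'
#' @param pca a `shape_pca`.
#' @param tree the `phylo` object the ancestral states were computed on.
#' @param ancestors an `ancestral_states` object from
#'   [reconstruct_ancestral_shapes()].
#' @return a list with `node_scores` (internal nodes x axes),
#'   `tip_scores`, and `edges` (two-column matrix of row labels usable for
#'   plotting the projected tree).
#' @export
map_tree_to_ordination <- function(pca, tree, ancestors) {
  stopifnot(inherits(pca, "shape_pca"), inherits(ancestors, "ancestral_states"))
  if (!setequal(tree$tip.label, pca$taxa))
    stop("tree tips and PCA taxa differ")
  proj <- function(M) {
    sc <- sweep(M, 2, pca$center) %*% pca$vectors
    colnames(sc) <- colnames(pca$scores)
    sc
  }
  node_scores <- proj(ancestors$node_shapes)
  tip_scores <- pca$scores[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  lab <- c(tree$tip.label, rownames(ancestors$node_shapes))
  edges <- cbind(parent = lab[tree$edge[, 1]], child = lab[tree$edge[, 2]])
  list(node_scores = node_scores, tip_scores = tip_scores, edges = edges)
}
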