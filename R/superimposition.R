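#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard geometric-morphometric size measure, in
#' the units of the input coordinates.
#'
#' @param config `k x 2` numeric matrix of landmark coordinates.
#' @return a non-negative scalar; 0 only for a fully degenerate
#'   configuration (all landmarks coincident), which downstream
#'   superimposition rejects.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  stopifnot(ncol(config) == 2, nrow(config) >= 3, all(is.finite(config)))
  centroid_size_xy(config)
}

# Optimal rotation (no reflection) aligning centered B onto centered A:
# minimizes ||A - B R||_F over rotations R (Kabsch with determinant
# correction). Returns the 2x2 rotation matrix.
opt_rotation <- function(A, B) {
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

# center and scale a k x 2 configuration to unit centroid size (preshape)
preshape <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(m^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks coincide")
  m / cs
}

#' Full Procrustes distance between two configurations
#'
#' Minimum root summed squared difference after centering, scaling to unit
#' centroid size, optimal scaling and optimal rotation (reflections
#' disallowed). Symmetric in its arguments.
#'
#' @param a,b `k x 2` matrices (same `k`) or 2k shape vectors.
#' @return a scalar in `[0, 1]`.
#' @export
procrustes_distance <- function(a, b) {
  if (is.null(dim(a))) a <- fold_shape(a)
  if (is.null(dim(b))) b <- fold_shape(b)
  if (!identical(dim(a), dim(b)))
    stop("landmark count mismatch: ", nrow(a), " vs ", nrow(b))
  za <- preshape(a); zb <- preshape(b)
  s <- svd(crossprod(zb, za))
  g <- s$d[1] + sign(det(s$u %*% t(s$v))) * s$d[2]
  sqrt(max(0, 1 - min(1, g)^2))
}

#' Generalized Procrustes Analysis
#'
#' Superimposes all configurations by removing translation, scale and
#' rotation: each configuration is centered, scaled to unit centroid size
#' and rotated (no reflection) to the iteratively re-estimated consensus,
#' which is the arithmetic mean of the aligned configurations rescaled to
#' unit centroid size each iteration. The first specimen seeds the
#' consensus. Iteration stops when the consensus moves by less than `tol`
#' (root summed squared coordinate shift) or after `max_iter` iterations
#' (then a warning is issued and the result flagged).
#'
#' Tangent coordinates are obtained by orthogonal projection of each
#' aligned configuration onto the linear space tangent to shape space at
#' the consensus: `t = x - (x . c) c` with both vectorized and the
#' consensus `c` of unit norm. The final superimposition is rotated as a
#' block so that the consensus lies along its principal axes (major axis
#' on x), which makes the output invariant to any common similarity
#' transform of the inputs.
#'
#' @param dataset a [shape_dataset()] with at least 2 specimens.
#' @param tol convergence threshold on the consensus shift (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @return the dataset with `aligned = TRUE`, `consensus` (`k x 2`, unit
#'   centroid size, centered), `tangent` (`n x 2k` tangent coordinates)
#'   and `gpa` diagnostics (`iterations`, `converged`, per-iteration
#'   objective `ss_trace`).
#' @export
gpa_align <- function(dataset, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(dataset, "shape_dataset"))
  if (dataset$n < 2L) stop("GPA needs at least 2 specimens")
  X <- lapply(seq_len(dataset$n), function(j) preshape(dataset$coords[, , j]))
  consensus <- X[[1]]
  ss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    X <- lapply(X, function(m) m %*% opt_rotation(consensus, m))
    new_con <- Reduce(`+`, X) / length(X)
    new_con <- new_con / sqrt(sum(new_con^2))
    ss_trace[iter] <- sum(vapply(X, function(m) sum((m - new_con)^2),
                                 numeric(1)))
    shift <- sqrt(sum((new_con - consensus)^2))
    consensus <- new_con
    if (iter > 1L && shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  # deterministic orientation: rotate the whole superimposition so the
  # consensus lies along its principal axes (major axis on x), resolving
  # the 180-degree ambiguity by the sign of the largest-magnitude entry;
  # this makes the output invariant to a common rotation of the inputs
  pa <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  if (det(pa) < 0) pa[, 2] <- -pa[, 2]
  consensus <- consensus %*% pa
  if (flat_shape(consensus)[which.max(abs(consensus))] < 0) {
    pa <- -pa
    consensus <- -consensus
  }
  X <- lapply(X, function(m) m %*% pa)
  cvec <- flat_shape(consensus)
  tangent <- t(vapply(X, function(m) {
    v <- flat_shape(m)
    v - sum(v * cvec) * cvec
  }, numeric(2L * dataset$k)))
  rownames(tangent) <- dataset$specimen_id
  dataset$aligned <- TRUE
  dataset$consensus <- consensus
  dataset$tangent <- tangent
  dataset$gpa <- list(iterations = iter, converged = converged,
                      ss_trace = ss_trace)
  dataset
}

#' Per-taxon mean shapes
#'
#' Arithmetic mean of the tangent coordinates of all specimens within each
#' taxon, with the per-taxon mean centroid size carried along. Taxa keep
#' the diet/locomotion label of their specimens.
#'
#' @param dataset an aligned [shape_dataset()].
#' @return an aligned `shape_dataset` with one record per taxon, in order
#'   of first appearance; `tangent` holds the taxon mean tangent vectors
#'   and `cs` the taxon mean centroid sizes. `coords` holds the mean
#'   shapes folded to `k x 2` about the consensus.
#' @export
taxon_mean_shapes <- function(dataset) {
  stopifnot(inherits(dataset, "shape_dataset"))
  if (!isTRUE(dataset$aligned)) stop("dataset must be GPA-aligned first")
  taxa <- unique(dataset$taxon)
  m <- length(taxa)
  tang <- matrix(0, m, 2L * dataset$k, dimnames = list(taxa, NULL))
  cs <- numeric(m)
  diet <- locom <- character(m)
  cvec <- flat_shape(dataset$consensus)
  coords <- array(0, c(dataset$k, 2, m))
  for (j in seq_len(m)) {
    sel <- dataset$taxon == taxa[j]
    tang[j, ] <- colMeans(dataset$tangent[sel, , drop = FALSE])
    cs[j] <- mean(dataset$cs[sel])
    diet[j] <- dataset$diet[sel][1]
    locom[j] <- dataset$locomotion[sel][1]
    coords[, , j] <- fold_shape(tang[j, ] + cvec)
  }
  out <- shape_dataset(coords, taxa, taxa, diet, locom)
  out$cs <- cs
  out$aligned <- TRUE
  out$consensus <- dataset$consensus
  out$tangent <- tang
  out
}
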