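# --- squared-change parsimony core -----------------------------------------
#
# Works on a generic undirected edge list over node ids 1..N where 1..ntip
# are tips with known values and (ntip+1)..N are free internal nodes. With
# unit branch lengths the minimizer of the total squared change is the
# solution of the graph-Laplacian system in which every internal node equals
# the mean of its neighbours (per coordinate); the system is solved once for
# all coordinates jointly.
solve_sqcp <- function(edges, ntip, tips_mat) {
  tips_mat <- as.matrix(tips_mat)
  N <- max(edges)
  nint <- N - ntip
  m <- ncol(tips_mat)
  if (nint == 0L) {  # two-tip tree: the single edge is the whole length
    len <- sum((tips_mat[edges[1, 1], ] - tips_mat[edges[1, 2], ])^2)
    return(list(node_values = matrix(numeric(0), 0, m), length = len))
  }
  A <- matrix(0, nint, nint)
  rhs <- matrix(0, nint, m)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    ia <- a - ntip; ib <- b - ntip
    if (a > ntip) A[ia, ia] <- A[ia, ia] + 1
    if (b > ntip) A[ib, ib] <- A[ib, ib] + 1
    if (a > ntip && b > ntip) {
      A[ia, ib] <- A[ia, ib] - 1
      A[ib, ia] <- A[ib, ia] - 1
    } else if (a > ntip) {
      rhs[ia, ] <- rhs[ia, ] + tips_mat[b, ]
    } else if (b > ntip) {
      rhs[ib, ] <- rhs[ib, ] + tips_mat[a, ]
    }
  }
  X <- solve(A, rhs)
  all_vals <- rbind(tips_mat, X)
  len <- sum((all_vals[edges[, 1], ] - all_vals[edges[, 2], ])^2)
  list(node_values = X, length = len)
}

# tree length only (hot path for permutations)
sqcp_length <- function(edges, ntip, tips_mat)
  solve_sqcp(edges, ntip, tips_mat)$length

#' Squared-change parsimony ancestral shape reconstruction
#'
#' Internal node shapes minimizing the sum over tree edges of squared
#' shape change (unit branch lengths), obtained by solving the sparse
#' linear system in which each internal node equals the mean of its tree
#' neighbours. The minimized sum is the morphometric tree length; it is
#' invariant to the position of the root. Polytomies are handled (the
#' system is defined for any node degree).
#'
#' @param tree a rooted `phylo`; branch lengths are ignored (unit lengths
#'   by convention, see [read_tree()]).
#' @param tip_shapes numeric matrix, one row per taxon (rownames must
#'   match the tip labels), columns = tangent/shape coordinates. An
#'   aligned taxon-mean [shape_dataset()] is also accepted.
#' @return an `ancestral_states`: `node_shapes` (internal nodes x
#'   coordinates, rownames `node_<id>` in ape numbering), `tree_length`,
#'   and the `tree`.
#' @export
reconstruct_ancestral_shapes <- function(tree, tip_shapes) {
  if (inherits(tip_shapes, "shape_dataset")) {
    stopifnot(isTRUE(tip_shapes$aligned))
    tip_shapes <- structure(tip_shapes$tangent,
                            dimnames = list(tip_shapes$taxon, NULL))
  }
  tip_shapes <- as.matrix(tip_shapes)
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 tips")
  if (is.null(rownames(tip_shapes)))
    stop("tip_shapes must have taxon rownames")
  miss <- setdiff(tree$tip.label, rownames(tip_shapes))
  if (length(miss)) stop("no shape for tip(s): ", paste(miss, collapse = ", "))
  M <- tip_shapes[tree$tip.label, , drop = FALSE]
  sol <- solve_sqcp(tree$edge, ntip, M)
  rownames(sol$node_values) <- paste0("node_", ntip + seq_len(nrow(sol$node_values)))
  structure(list(node_shapes = sol$node_values, tree_length = sol$length,
                 tree = tree),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("Squared-change parsimony reconstruction: %d internal nodes, tree length = %.6g\n",
              nrow(x$node_shapes), x$tree_length))
  invisible(x)
}

#' Permutation test for phylogenetic signal
#'
#' Simulates the null hypothesis of complete absence of phylogenetic
#' structure by permuting the tip shapes among the terminal taxa and
#' recomputing the squared-change-parsimony tree length each time. A short
#' observed length relative to the permutation distribution indicates
#' signal, so the rejection tail is `permuted <= observed` and
#' `p = (1 + #{permuted <= observed}) / (1 + n_perm)`.
#'
#' @inheritParams reconstruct_ancestral_shapes
#' @param n_perm number of permutations (>= 99 recommended).
#' @param seed integer seed for the permutation stream.
#' @return a `signal_test`: `observed_length`, `permuted_lengths`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permutation_signal_test <- function(tree, tip_shapes, n_perm = 999L,
                                    seed = 1L) {
  if (inherits(tip_shapes, "shape_dataset")) {
    stopifnot(isTRUE(tip_shapes$aligned))
    tip_shapes <- structure(tip_shapes$tangent,
                            dimnames = list(tip_shapes$taxon, NULL))
  }
  tip_shapes <- as.matrix(tip_shapes)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop("signal test needs at least 4 tips")
  if (n_perm < 99L) warning("n_perm < 99 gives a very coarse p-value")
  M <- tip_shapes[tree$tip.label, , drop = FALSE]
  obs <- sqcp_length(tree$edge, ntip, M)
  perm <- with_seed(seed, {
    p <- numeric(n_perm)
    for (r in seq_len(n_perm))
      p[r] <- sqcp_length(tree$edge, ntip, M[sample(ntip), , drop = FALSE])
    p
  })
  p <- (1 + sum(perm <= obs)) / (1 + n_perm)
  structure(list(observed_length = obs, permuted_lengths = perm,
                 p_value = p, n_perm = n_perm, seed = seed),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf("Phylogenetic signal permutation test: tree length = %.6g, p (no signal) = %.4g (%d perms)\n",
              x$observed_length, x$p_value, x$n_perm))
  invisible(x)
}

# --- topology enumeration ----------------------------------------------------

# Apply FUN to the edge list of every unrooted binary topology on tips
# 1..ntip ((2*ntip - 5)!! of them), built by recursive edge insertion.
# Internal nodes are numbered ntip+1, ntip+2, ... as tips are added.
enumerate_topologies <- function(ntip, FUN) {
  stopifnot(ntip >= 3L)
  base <- cbind(c(ntip + 1L, ntip + 1L, ntip + 1L), c(1L, 2L, 3L))
  recurse <- function(edges, next_tip, next_int) {
    if (next_tip > ntip) { FUN(edges); return(invisible(NULL)) }
    for (e in seq_len(nrow(edges))) {
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(edges[e, 1], next_int),
                         c(next_int, edges[e, 2]),
                         c(next_int, next_tip))
      recurse(new_edges, next_tip + 1L, next_int + 1L)
    }
  }
  recurse(base, 4L, ntip + 2L)
  invisible(NULL)
}

# unrooted edge list of an ape phylo: suppress a degree-2 root by fusing
# its two incident edges
unrooted_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  root <- ntip + 1L
  inc <- which(edges[, 1] == root | edges[, 2] == root)
  if (length(inc) == 2L) {
    others <- vapply(inc, function(e) setdiff(edges[e, ], root), integer(1))
    edges <- rbind(edges[-inc, , drop = FALSE], others)
    # renumber internal nodes > root down by one
    edges[edges > root] <- edges[edges > root] - 1L
  }
  edges
}

# single NNI descent step family: the two exchanges across internal edge (u,v)
nni_neighbours <- function(edges, ntip) {
  out <- list()
  internal <- edges[, 1] > ntip & edges[, 2] > ntip
  for (e in which(internal)) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj_u <- setdiff(c(edges[edges[, 1] == u, 2], edges[edges[, 2] == u, 1]), v)
    adj_v <- setdiff(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]), u)
    if (length(adj_u) != 2L || length(adj_v) != 2L) next  # needs binary nodes
    for (bv in adj_v) {
      swap <- function(a, b) {
        ee <- edges
        ia <- which((ee[, 1] == u & ee[, 2] == a) | (ee[, 2] == u & ee[, 1] == a))[1]
        ib <- which((ee[, 1] == v & ee[, 2] == b) | (ee[, 2] == v & ee[, 1] == b))[1]
        ee[ia, ] <- c(u, b); ee[ib, ] <- c(v, a)
        ee
      }
      out[[length(out) + 1L]] <- swap(adj_u[2], bv)
    }
  }
  out
}

#' Shape consistency and retention indices (homoplasy)
#'
#' Quantifies homoplasy by comparing the observed tree length with the
#' minimum attainable over all unrooted binary topologies on the same tip
#' shapes (the squared-change Steiner-tree optimum) and the maximum,
#' taken as the star-tree length `sum ||tip - tip mean||^2` (a star
#' retains no clade structure; every binary topology can only shorten
#' it). Then `SCI = min / observed` and
#' `SRI = (max - observed) / (max - min)`, both in `[0, 1]`, with 1
#' meaning no homoplasy. All three lengths are computed on the unrooted
#' topology (a degree-2 root is suppressed first): with unit branch
#' lengths a root node splits one edge in two and halves its
#' squared-change contribution, which would make the observed length
#' incommensurable with the enumerated topologies.
#'
#' The exact minimum enumerates all `(2n - 5)!!` topologies, so it is
#' restricted to small tip counts (`max_taxa_exhaustive`, default 11,
#' mirroring the published limit of exhaustive Steiner search; counts
#' above ~8 take appreciable time). For larger trees set
#' `heuristic = TRUE` to use nearest-neighbour-interchange descent from
#' the observed topology; the minimum is then labelled approximate.
#'
#' @inheritParams reconstruct_ancestral_shapes
#' @param max_taxa_exhaustive refuse exhaustive search above this tip
#'   count (default 11).
#' @param heuristic use NNI descent instead of enumeration (default FALSE).
#' @return a `homoplasy_indices`: `observed_length`, `min_length`,
#'   `max_length`, `SCI`, `SRI`, `exact` (logical), `n_topologies`
#'   scanned.
#' @export
homoplasy_indices <- function(tree, tip_shapes, max_taxa_exhaustive = 11L,
                              heuristic = FALSE) {
  if (inherits(tip_shapes, "shape_dataset")) {
    stopifnot(isTRUE(tip_shapes$aligned))
    tip_shapes <- structure(tip_shapes$tangent,
                            dimnames = list(tip_shapes$taxon, NULL))
  }
  tip_shapes <- as.matrix(tip_shapes)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop("homoplasy indices need at least 4 tips")
  M <- tip_shapes[tree$tip.label, , drop = FALSE]
  # lengths are compared on the unrooted topology: a degree-2 root node
  # halves the squared change on its edge and would make the observed
  # length incommensurable with the enumerated (unrooted) topologies
  observed <- sqcp_length(unrooted_edges(tree), ntip, M)
  max_len <- sum(sweep(M, 2, colMeans(M))^2)

  if (!heuristic && ntip > max_taxa_exhaustive)
    stop("exhaustive Steiner search is limited to ", max_taxa_exhaustive,
         " taxa (", ntip, " given); set heuristic = TRUE for NNI descent")
  if (heuristic) {
    cur <- unrooted_edges(if (ape::is.binary(tree)) tree
                          else ape::multi2di(tree))
    cur_len <- sqcp_length(cur, ntip, M)
    n_scanned <- 1L
    repeat {
      nb <- nni_neighbours(cur, ntip)
      if (!length(nb)) break
      lens <- vapply(nb, sqcp_length, numeric(1), ntip = ntip, tips_mat = M)
      n_scanned <- n_scanned + length(nb)
      if (min(lens) < cur_len - 1e-12) {
        j <- which.min(lens); cur <- nb[[j]]; cur_len <- lens[j]
      } else break
    }
    min_len <- min(cur_len, observed)
    exact <- FALSE
  } else {
    env <- new.env()
    env$best <- Inf
    env$count <- 0L
    enumerate_topologies(ntip, function(edges) {
      env$count <- env$count + 1L
      len <- sqcp_length(edges, ntip, M)
      if (len < env$best) env$best <- len
    })
    min_len <- env$best
    n_scanned <- env$count
    exact <- TRUE
  }

  degenerate <- (max_len - min_len) <= 1e-12 * max(1, max_len)
  structure(list(observed_length = observed, min_length = min_len,
                 max_length = max_len,
                 SCI = if (observed > 0) min_len / observed else NA_real_,
                 SRI = if (!degenerate)
                   (max_len - observed) / (max_len - min_len) else NA_real_,
                 degenerate = degenerate, exact = exact,
                 n_topologies = n_scanned),
            class = "homoplasy_indices")
}

#' @export
print.homoplasy_indices <- function(x, ...) {
  cat(sprintf(
    "Homoplasy indices (%s search over %d topologies)\n  tree length: observed = %.6g, min = %.6g, max (star) = %.6g\n  SCI = %.3f, SRI = %.3f\n",
    if (x$exact) "exhaustive" else "NNI heuristic", x$n_topologies,
    x$observed_length, x$min_length, x$max_length, x$SCI, x$SRI))
  invisible(x)
}
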