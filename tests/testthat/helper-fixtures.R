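# Shared fixtures and independent numeric oracles.

# a non-degenerate asymmetric 5-landmark toy shape
toy_shape <- function() {
  matrix(c(0, 0, 4, 0.5, 5, 3, 2, 5, -1, 2.5), ncol = 2, byrow = TRUE)
}

rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

# apply a random similarity transform (rotation + translation + scale)
jitter_transform <- function(m, theta = runif(1, 0, 2 * pi),
                             scale = exp(runif(1, -1, 1)),
                             shift = runif(2, -10, 10)) {
  sweep(scale * m %*% rot2(theta), 2, shift, `+`)
}

# dataset of transformed copies of one shape (optionally + noise)
copies_dataset <- function(base = toy_shape(), n = 6, noise = 0) {
  coords <- array(NA_real_, c(nrow(base), 2, n))
  for (j in seq_len(n))
    coords[, , j] <- jitter_transform(base + matrix(rnorm(length(base),
                                                          sd = noise),
                                                    ncol = 2))
  shape_dataset(coords, sprintf("spec_%02d", seq_len(n)))
}

# Brute-force full Procrustes distance between two configurations:
# grid over rotation angle and scale, refined by local optimization.
# Independent of the SVD route used by the package.
brute_procrustes <- function(a, b) {
  ctr <- function(m) sweep(m, 2, colMeans(m))
  za <- ctr(a); za <- za / sqrt(sum(za^2))
  zb <- ctr(b); zb <- zb / sqrt(sum(zb^2))
  f <- function(p) sum((za - p[2] * zb %*% rot2(p[1]))^2)
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = 73)) {
    o <- optim(c(th, 1), f, method = "Nelder-Mead",
               control = list(reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  sqrt(max(0, best))
}

# Brute-force squared-change tree length: direct numeric minimization of
# the total squared change over all internal-node coordinates.
brute_tree_length <- function(tree, M) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  m <- ncol(M)
  Mt <- M[tree$tip.label, , drop = FALSE]
  obj <- function(x) {
    vals <- rbind(Mt, matrix(x, nint, m))
    sum((vals[tree$edge[, 1], ] - vals[tree$edge[, 2], ])^2)
  }
  start <- matrix(rep(colMeans(Mt), each = nint), nint, m)
  o <- optim(as.vector(start), obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  o2 <- optim(o$par, obj, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-14))
  o2$value
}

# small simulated study used by several tests
small_sim <- function(seed = 11, n_taxa = 15, ...) {
  simulate_dataset(simulation_config(n_taxa = n_taxa, seed = seed, ...))
}

# unit-length random direction in R^m
runit <- function(m) { v <- rnorm(m); v / sqrt(sum(v^2)) }

# build an aligned taxon-mean-style dataset directly from a tangent matrix
# (for statistical modules that only consume tangent rows + cs)
tangent_dataset <- function(tangent, cs, consensus, taxa = rownames(tangent)) {
  k <- length(consensus) / 2
  n <- nrow(tangent)
  coords <- array(NA_real_, c(k, 2, n))
  for (j in seq_len(n)) coords[, , j] <- matrix(tangent[j, ] + consensus,
                                                ncol = 2)
  ds <- shape_dataset(coords, taxa, taxa)
  ds$cs <- cs
  ds$aligned <- TRUE
  ds$consensus <- matrix(consensus, ncol = 2)
  ds$tangent <- tangent
  ds
}

# consensus/template vector used by tangent_dataset-based fixtures
unit_template_vec <- function() {
  tpl <- make_template("squirrel_mandible_14")
  tpl <- sweep(tpl, 2, colMeans(tpl))
  as.vector(tpl / sqrt(sum(tpl^2)))
}

# map a template-frame tangent vector into the frame of an aligned dataset:
# center it, rotate by the optimal rotation carrying the template preshape
# onto the consensus, then project out the directions superimposition
# removes — the consensus (size) direction and the in-plane rotation
# generator at the consensus
map_to_analysis_frame <- function(v, template, consensus) {
  ctr <- function(m) sweep(m, 2, colMeans(m))
  tpl <- ctr(template); tpl <- tpl / sqrt(sum(tpl^2))
  s <- svd(crossprod(tpl, consensus))
  R <- s$u %*% diag(c(1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  w <- as.vector(ctr(matrix(v, ncol = 2)) %*% R)
  cv <- as.vector(consensus)
  rv <- as.vector(consensus %*% matrix(c(0, -1, 1, 0), 2, 2))
  rv <- rv / sqrt(sum(rv^2))
  w <- w - sum(w * cv) * cv
  w - sum(w * rv) * rv
}

# absolute vector correlation
vec_cor <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
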