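# resolve a grouping spec ("diet", "locomotion", or an explicit vector)
# to a character vector over specimens; "ungrouped" marks exclusion
resolve_grouping <- function(dataset, grouping) {
  if (is.character(grouping) && length(grouping) == 1L) {
    if (!grouping %in% c("diet", "locomotion"))
      stop("grouping must be 'diet', 'locomotion', or a vector")
    dataset[[grouping]]
  } else {
    stopifnot(length(grouping) == dataset$n)
    as.character(grouping)
  }
}

#' Canonical variates analysis of Procrustes coordinates
#'
#' Ordination maximizing between-group relative to pooled within-group
#' variation. Procrustes tangent data are rank-deficient (4 dimensions
#' lost to superimposition), so the data are first reduced to the PCA
#' subspace spanning all variance above `1e-12 *` trace, capped at
#' `N - g` dimensions, which makes the pooled within-group covariance
#' invertible; the generalized eigenproblem is solved there and the axes
#' mapped back to landmark space for visualization. Axes are scaled so
#' canonical scores have pooled within-group variance 1. Individual
#' specimens are the units; specimens labelled `"ungrouped"` and groups
#' below `min_group_n` are excluded from the fit (but can still be
#' classified, see [classify_specimens()]).
#'
#' @param dataset an aligned [shape_dataset()].
#' @param grouping `"diet"`, `"locomotion"`, or a character vector over
#'   specimens.
#' @param min_group_n smallest group size admitted to the fit (default 2).
#' @return a `cva_model`: `axes` (reduced-space, d x m), `axes_shape`
#'   (2k x m, for wireframes), `eigenvalues`, `percent`, `scores`
#'   (fitted specimens x m), `group_means_canonical`, `groups`, `center`,
#'   `reduction` (2k x d PCA basis), `grouping` vector used, `fitted_ids`.
#' @export
fit_cva <- function(dataset, grouping = "diet", min_group_n = 2L) {
  stopifnot(inherits(dataset, "shape_dataset"), isTRUE(dataset$aligned))
  g <- resolve_grouping(dataset, grouping)
  usable <- g != "ungrouped"
  sizes <- table(g[usable])
  small <- names(sizes)[sizes < min_group_n]
  if (length(small))
    warning("excluding group(s) with < ", min_group_n, " specimens: ",
            paste(small, collapse = ", "))
  usable <- usable & !(g %in% small)
  groups <- sort(unique(g[usable]))
  if (length(groups) < 2L)
    stop("CVA needs at least 2 groups with >= ", min_group_n, " specimens")
  Y <- dataset$tangent[usable, , drop = FALSE]
  gf <- factor(g[usable], levels = groups)
  N <- nrow(Y); ng <- length(groups)

  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  e <- eigen(stats::cov(Yc), symmetric = TRUE)
  tot <- sum(pmax(e$values, 0))
  d <- min(sum(e$values > 1e-12 * tot), N - ng)
  if (d < 1L) stop("no usable dimensions after PCA reduction (N = ", N,
                   ", g = ", ng, ")")
  V <- e$vectors[, seq_len(d), drop = FALSE]
  Z <- Yc %*% V

  mu <- rowsum(Z, gf) / as.vector(table(gf))
  W <- matrix(0, d, d)
  for (lev in groups) {
    i <- gf == lev
    Zi <- sweep(Z[i, , drop = FALSE], 2, mu[lev, ])
    W <- W + crossprod(Zi)
  }
  W <- W / (N - ng)
  B <- crossprod(sweep(mu, 1, sqrt(as.vector(table(gf))), `*`))

  # generalized eigenproblem B a = lambda W a via Cholesky whitening
  C <- chol(W)                       # W = C'C
  Ci <- backsolve(C, diag(d))        # C^{-1}
  S <- t(Ci) %*% B %*% Ci
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  m <- min(ng - 1L, d)
  vals <- pmax(es$values[seq_len(m)], 0)
  A <- Ci %*% es$vectors[, seq_len(m), drop = FALSE]  # a' W a = 1
  for (j in seq_len(m)) {            # deterministic sign
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  scores <- Z %*% A
  rownames(scores) <- dataset$specimen_id[usable]
  colnames(scores) <- paste0("CV", seq_len(m))
  gm <- rowsum(scores, gf) / as.vector(table(gf))
  structure(list(axes = A, axes_shape = V %*% A, eigenvalues = vals,
                 percent = if (sum(vals) > 0) 100 * vals / sum(vals) else vals,
                 scores = scores, group_means_canonical = gm,
                 groups = groups, center = ctr, reduction = V,
                 grouping = g, fitted_ids = dataset$specimen_id[usable],
                 k = dataset$k),
            class = "cva_model")
}

#' @export
print.cva_model <- function(x, ...) {
  cat(sprintf("CVA: %d specimens in %d groups (%s), %d canonical axes\n",
              length(x$fitted_ids), length(x$groups),
              paste(x$groups, collapse = ", "), ncol(x$axes)))
  if (length(x$eigenvalues))
    cat(sprintf("  CV1 accounts for %.1f%% of among-group variance\n",
                x$percent[1]))
  invisible(x)
}

# canonical-space coordinates of arbitrary specimens under a fitted model
canonical_scores <- function(model, tangent) {
  sweep(tangent, 2, model$center) %*% model$reduction %*% model$axes
}

# Mahalanobis classification in canonical space with equal priors
classify_rows <- function(model, tangent) {
  sc <- canonical_scores(model, tangent)
  d2 <- sapply(model$groups, function(gr)
    rowSums(sweep(sc, 2, model$group_means_canonical[gr, ])^2))
  d2 <- matrix(d2, nrow = nrow(sc),
               dimnames = list(rownames(tangent), model$groups))
  post <- exp(-(d2 - apply(d2, 1, min)) / 2)
  post <- post / rowSums(post)
  pred <- model$groups[apply(d2, 1, which.min)]  # ties: lowest group index
  list(predicted = pred, posterior = post, d2 = d2)
}

#' Classify specimens with a fitted CVA model
#'
#' Each specimen is assigned to the group with smallest Mahalanobis
#' distance in canonical space; posterior membership probabilities use
#' equal priors, `p(g) proportional to exp(-D2_g / 2)`. Specimens
#' labelled `"ungrouped"` (e.g. a fossil) are classified without ever
#' entering the fit. With `cross_validate = TRUE` each fitted specimen is
#' re-classified by a model refitted with that specimen left out
#' (leave-one-out; the whole CVA is refitted per fold).
#'
#' @param model a `cva_model` fitted on `dataset`.
#' @param dataset the aligned dataset to classify (normally the one the
#'   model was fitted on).
#' @param cross_validate also compute leave-one-out predictions (default
#'   TRUE).
#' @return a `classification_table`: per-specimen data frame `table`
#'   (true group, predicted, posterior of the predicted group,
#'   cross-validated prediction), `posterior` matrix, `confusion` and
#'   `confusion_cv` (row percentages by true group), `percent_correct`,
#'   `percent_correct_cv`.
#' @export
classify_specimens <- function(model, dataset, cross_validate = TRUE) {
  stopifnot(inherits(model, "cva_model"),
            inherits(dataset, "shape_dataset"), isTRUE(dataset$aligned))
  g <- model$grouping
  if (length(g) != dataset$n)
    stop("dataset does not match the one the model was fitted on")
  res <- classify_rows(model, dataset$tangent)
  fitted_mask <- dataset$specimen_id %in% model$fitted_ids
  cv_pred <- rep(NA_character_, dataset$n)
  if (cross_validate) {
    for (i in which(fitted_mask)) {
      keep <- fitted_mask; keep[i] <- FALSE
      if (sum(g[keep] == g[i]) < 1L) {
        warning("leave-one-out fold for ", dataset$specimen_id[i],
                " empties its group; fold skipped")
        next
      }
      sub <- dataset[keep]
      m_i <- tryCatch(
        suppressWarnings(fit_cva(sub, g[keep])),
        error = function(e) NULL)
      if (is.null(m_i)) next
      cv_pred[i] <- classify_rows(m_i,
                                  dataset$tangent[i, , drop = FALSE])$predicted
    }
    cv_pred[!fitted_mask] <- res$predicted[!fitted_mask]  # never in the fit
  }
  correct <- res$predicted[fitted_mask] == g[fitted_mask]
  cv_ok <- fitted_mask & !is.na(cv_pred)
  confusion <- function(pred, mask) {
    tb <- table(true = factor(g[mask], levels = model$groups),
                predicted = factor(pred[mask], levels = model$groups))
    100 * prop.table(tb, 1)
  }
  structure(list(
    table = data.frame(specimen_id = dataset$specimen_id,
                       true = g,
                       predicted = res$predicted,
                       posterior = res$posterior[cbind(seq_len(dataset$n),
                                        match(res$predicted, model$groups))],
                       cv_predicted = cv_pred,
                       stringsAsFactors = FALSE),
    posterior = res$posterior,
    confusion = confusion(res$predicted, fitted_mask),
    confusion_cv = if (cross_validate) confusion(cv_pred, cv_ok) else NULL,
    percent_correct = 100 * mean(correct),
    percent_correct_cv = if (cross_validate)
      100 * mean(cv_pred[cv_ok] == g[cv_ok]) else NA_real_),
    class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("Classification: %.1f%% correct", x$percent_correct))
  if (!is.na(x$percent_correct_cv))
    cat(sprintf(" (%.1f%% after cross-validation)", x$percent_correct_cv))
  cat("\n")
  invisible(x)
}

#' Procrustes distances between group mean shapes, with permutation tests
#'
#' Pairwise full Procrustes distances between the mean shapes of the
#' groups, each tested by permutation: the two groups' specimens are
#' pooled, labels reshuffled, and the between-mean distance recomputed;
#' `p = (1 + #{permuted >= observed}) / (1 + n_perm)`.
#'
#' @param dataset an aligned [shape_dataset()].
#' @param grouping as in [fit_cva()].
#' @param n_perm permutations per pair (default 999).
#' @param seed integer seed.
#' @param min_group_n smallest admissible group (default 2).
#' @return a list with symmetric matrices `distance` (zero diagonal) and
#'   `p_value` (NA diagonal), and `groups`.
#' @export
group_distance_tests <- function(dataset, grouping = "diet", n_perm = 999L,
                                 seed = 1L, min_group_n = 2L) {
  stopifnot(inherits(dataset, "shape_dataset"), isTRUE(dataset$aligned))
  if (n_perm < 99L) warning("n_perm < 99 gives a very coarse p-value")
  g <- resolve_grouping(dataset, grouping)
  usable <- g != "ungrouped"
  sizes <- table(g[usable])
  keep <- names(sizes)[sizes >= min_group_n]
  groups <- sort(keep)
  ng <- length(groups)
  if (ng < 2L) stop("need at least 2 groups")
  cvec <- flat_shape(dataset$consensus)
  mean_shape <- function(rows)
    fold_shape(colMeans(dataset$tangent[rows, , drop = FALSE]) + cvec)
  D <- matrix(0, ng, ng, dimnames = list(groups, groups))
  P <- matrix(NA_real_, ng, ng, dimnames = list(groups, groups))
  pair_stats <- with_seed(seed, {
  for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
    ri <- which(g == groups[i]); rj <- which(g == groups[j])
    obs <- procrustes_distance(mean_shape(ri), mean_shape(rj))
    pool <- c(ri, rj); ni <- length(ri)
    n_ge <- 0L
    for (r in seq_len(n_perm)) {
      sh <- sample(pool)
      d <- procrustes_distance(mean_shape(sh[seq_len(ni)]),
                               mean_shape(sh[-seq_len(ni)]))
      if (d >= obs) n_ge <- n_ge + 1L
    }
    D[i, j] <- D[j, i] <- obs
    P[i, j] <- P[j, i] <- (1 + n_ge) / (1 + n_perm)
  }
  list(D = D, P = P)
  })
  D <- pair_stats$D
  P <- pair_stats$P
  list(distance = D, p_value = P, groups = groups, n_perm = n_perm,
       seed = seed)
}
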