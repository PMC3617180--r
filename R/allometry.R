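#' Multivariate regression of shape on centroid size
#'
#' Evolutionary allometry: each tangent coordinate of the taxon mean
#' shapes is regressed on centroid size (or log centroid size) by least
#' squares. The strength of allometry is summarized as the percentage of
#' total shape variation predicted by size in the Procrustes metric,
#' `100 * SS_predicted / SS_total`, with a Goodall-style F ratio
#' `(SS_pred / 1) / (SS_resid / (n - 2))` pooling all coordinates.
#' Significance is assessed by permuting the size values across taxa.
#'
#' @param dataset an aligned [shape_dataset()], normally the output of
#'   [taxon_mean_shapes()] — species/genus means are the regression units.
#' @param predictor `"CS"` (raw centroid size, the default) or `"logCS"`.
#' @param n_perm number of permutations (default 999; fewer than 99 draws
#'   a warning).
#' @param seed integer seed for the permutation stream.
#' @return an `allometry_model`: `slope` (2k shape change per unit
#'   predictor), `intercept` (2k), `percent_predicted`, `goodall_F`, `df`,
#'   `p_permutation`, `n`, `predictor`, `fitted` (n x 2k), plus the
#'   predictor values used.
#' @export
fit_allometry <- function(dataset, predictor = c("CS", "logCS"),
                          n_perm = 999L, seed = 1L) {
  stopifnot(inherits(dataset, "shape_dataset"), isTRUE(dataset$aligned))
  predictor <- match.arg(predictor)
  Y <- dataset$tangent
  n <- nrow(Y)
  if (n < 3L) stop("allometric regression needs at least 3 taxa")
  s <- if (predictor == "logCS") log(dataset$cs) else dataset$cs
  if (max(s) - min(s) <= 0) stop("predictor (centroid size) is constant")
  if (n_perm < 99L) warning("n_perm < 99 gives a very coarse p-value")

  fit_stat <- function(s) {
    sc <- s - mean(s)
    sxx <- sum(sc^2)
    Yc <- sweep(Y, 2, colMeans(Y))
    b <- drop(crossprod(Yc, sc)) / sxx
    pred_ss <- sum(b^2) * sxx
    tot_ss <- sum(Yc^2)
    list(b = b, pred_ss = pred_ss, tot_ss = tot_ss,
         pct = 100 * pred_ss / tot_ss)
  }
  obs <- fit_stat(s)
  exceed <- with_seed(seed, {
    e <- 0L
    for (r in seq_len(n_perm))
      if (fit_stat(sample(s))$pct >= obs$pct) e <- e + 1L
    e
  })
  resid_ss <- obs$tot_ss - obs$pred_ss
  ybar <- colMeans(Y)
  structure(list(
    slope = obs$b,
    intercept = ybar - obs$b * mean(s),
    percent_predicted = obs$pct,
    goodall_F = (obs$pred_ss / 1) / (resid_ss / (n - 2)),
    df = c(1L, n - 2L),
    p_permutation = (1 + exceed) / (1 + n_perm),
    n = n, n_perm = n_perm, seed = seed,
    predictor = predictor, predictor_values = s,
    fitted = outer(s - mean(s), obs$b) + rep(ybar, each = n),
    taxa = dataset$taxon,
    consensus = dataset$consensus, k = dataset$k),
    class = "allometry_model")
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf(
    "Shape ~ %s regression on %d taxon means\n  %% predicted = %.2f; Goodall F(%d, %d) = %.2f; permutation p = %.4g (%d perms)\n",
    x$predictor, x$n, x$percent_predicted, x$df[1], x$df[2], x$goodall_F,
    x$p_permutation, x$n_perm))
  invisible(x)
}

#' Predicted shape at a given size
#'
#' Evaluates the fitted allometric regression at a centroid size value and
#' folds the result back to landmark form about the consensus.
#'
#' @param model an `allometry_model`.
#' @param cs centroid size (or log centroid size if the model used
#'   `"logCS"`) at which to predict.
#' @return `k x 2` landmark configuration.
#' @export
predict_shape_at_size <- function(model, cs) {
  stopifnot(inherits(model, "allometry_model"))
  v <- model$intercept + model$slope * cs
  fold_shape(v + flat_shape(model$consensus))
}

#' Size-corrected (residual) shapes
#'
#' Subtracts the fitted allometric component from each taxon's tangent
#' vector. The residuals have zero mean and are orthogonal to the size
#' predictor; their covariance matrix is the basis of the size-corrected
#' ordination.
#'
#' @param model an `allometry_model` fitted on `dataset`.
#' @param dataset the aligned dataset the model was fitted on.
#' @return the dataset with `tangent` replaced by the residual vectors.
#' @export
residual_shapes <- function(model, dataset) {
  stopifnot(inherits(model, "allometry_model"),
            inherits(dataset, "shape_dataset"), isTRUE(dataset$aligned))
  if (!identical(model$taxa, dataset$taxon))
    stop("model and dataset taxa differ")
  dataset$tangent <- dataset$tangent - model$fitted
  rownames(dataset$tangent) <- dataset$taxon
  dataset
}

#' Test homogeneity of allometric slopes and intercepts across clades
#'
#' Shapes are projected onto the pooled common allometric axis (the
#' within-group pooled regression slope, normalized), giving one
#' regression score per taxon; a standard ANCOVA on the scores then tests
#' slope heterogeneity (group x size interaction, df = g - 1) and, under a
#' common slope, intercept differences (df = g - 1). Parametric p-values
#' are reported together with residual-permutation (Freedman–Lane)
#' p-values for robustness.
#'
#' @param dataset an aligned taxon-mean [shape_dataset()].
#' @param grouping named character vector mapping taxon to clade, or a
#'   vector aligned with the dataset's taxa.
#' @param n_perm permutations for the robustness p-values (default 999).
#' @param seed integer seed.
#' @param min_group_n groups with fewer taxa are dropped with a warning
#'   (default 3).
#' @return a list with `slope` and `intercept` components, each holding
#'   `F`, `df`, `p` (parametric) and `p_perm`, plus the groups used.
#' @export
test_common_allometry <- function(dataset, grouping, n_perm = 999L,
                                  seed = 1L, min_group_n = 3L) {
  stopifnot(inherits(dataset, "shape_dataset"), isTRUE(dataset$aligned))
  g <- if (!is.null(names(grouping))) {
    unname(grouping[dataset$taxon])
  } else {
    stopifnot(length(grouping) == dataset$n)
    as.character(grouping)
  }
  if (anyNA(g)) stop("grouping does not cover taxa: ",
                     paste(dataset$taxon[is.na(g)], collapse = ", "))
  keep_groups <- names(which(table(g) >= min_group_n))
  dropped <- setdiff(unique(g), keep_groups)
  if (length(dropped))
    warning("dropping groups with < ", min_group_n, " taxa: ",
            paste(dropped, collapse = ", "))
  sel <- g %in% keep_groups
  if (length(keep_groups) < 2L)
    stop("need at least 2 groups with >= ", min_group_n, " taxa")
  Y <- dataset$tangent[sel, , drop = FALSE]
  s <- dataset$cs[sel]
  grp <- factor(g[sel])

  # pooled within-group slope = common allometric axis
  num <- 0; den <- 0
  for (lev in levels(grp)) {
    i <- grp == lev
    sc <- s[i] - mean(s[i])
    Yc <- sweep(Y[i, , drop = FALSE], 2, colMeans(Y[i, , drop = FALSE]))
    num <- num + drop(crossprod(Yc, sc))
    den <- den + sum(sc^2)
  }
  b <- num / den
  axis <- b / sqrt(sum(b^2))
  z <- drop(Y %*% axis)

  full <- stats::lm(z ~ s * grp)
  main <- stats::lm(z ~ s + grp)
  size_only <- stats::lm(z ~ s)
  a_slope <- stats::anova(main, full)
  a_int <- stats::anova(size_only, main)
  slope_F <- a_slope$F[2]; slope_df <- c(a_slope$Df[2], a_slope$Res.Df[2])
  int_F <- a_int$F[2]; int_df <- c(a_int$Df[2], a_int$Res.Df[2])

  perm_F <- function(null_fit) {
    # Freedman-Lane: permute residuals of the reduced model
    fit0 <- stats::fitted(null_fit); res0 <- stats::resid(null_fit)
    function() {
      zs <- fit0 + sample(res0)
      f_full <- stats::lm(zs ~ s * grp)
      f_main <- stats::lm(zs ~ s + grp)
      f_size <- stats::lm(zs ~ s)
      c(stats::anova(f_main, f_full)$F[2], stats::anova(f_size, f_main)$F[2])
    }
  }
  counts <- with_seed(seed, {
    draw_slope <- perm_F(main)
    n_ge_slope <- 0L
    for (r in seq_len(n_perm))
      if (draw_slope()[1] >= slope_F) n_ge_slope <- n_ge_slope + 1L
    draw_int <- perm_F(size_only)
    n_ge_int <- 0L
    for (r in seq_len(n_perm))
      if (draw_int()[2] >= int_F) n_ge_int <- n_ge_int + 1L
    c(n_ge_slope, n_ge_int)
  })
  n_ge_slope <- counts[1]
  n_ge_int <- counts[2]

  list(slope = list(F = slope_F, df = slope_df,
                    p = a_slope$`Pr(>F)`[2],
                    p_perm = (1 + n_ge_slope) / (1 + n_perm)),
       intercept = list(F = int_F, df = int_df,
                        p = a_int$`Pr(>F)`[2],
                        p_perm = (1 + n_ge_int) / (1 + n_perm)),
       groups = keep_groups, dropped = dropped,
       common_axis = axis, scores = z, n = sum(sel))
}
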