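# grouped tangent fixture: g groups with mean offsets scaled by `sep`
# relative to the within-group spread
cva_fixture <- function(g = 3, n_per = 15, sep = 5, seed = 1,
                        within_sd = 0.005, ungrouped = 0) {
  set.seed(seed)
  m <- 28
  groups <- c("fruits", "nuts", "seeds", "leaves", "herbivore_ss",
              "bark_gleaner", "insects")[seq_len(g)]
  offsets <- matrix(rnorm(g * m, sd = sep * within_sd), g, m,
                    dimnames = list(groups, NULL))
  n <- g * n_per + ungrouped
  tang <- matrix(rnorm(n * m, sd = within_sd), n, m)
  lab <- c(rep(groups, each = n_per), rep("ungrouped", ungrouped))
  for (i in seq_len(g * n_per)) tang[i, ] <- tang[i, ] + offsets[lab[i], ]
  if (ungrouped > 0)  # park ungrouped specimens at the first group's mean
    for (i in (g * n_per + 1):n) tang[i, ] <- tang[i, ] + offsets[1, ]
  rownames(tang) <- sprintf("s%03d", seq_len(n))
  ds <- tangent_dataset(tang, rep(100, n), unit_template_vec(),
                        taxa = sprintf("s%03d", seq_len(n)))
  ds$diet <- lab
  list(ds = ds, labels = lab, offsets = offsets, groups = groups)
}

test_that("two-group CVA matches the closed-form discriminant direction", {
  fx <- cva_fixture(g = 2, n_per = 20, sep = 3, seed = 31)
  model <- fit_cva(fx$ds, "diet")
  expect_equal(ncol(model$axes), 1)
  # closed form in the reduced space: W^{-1} (mu1 - mu2)
  Z <- sweep(fx$ds$tangent, 2, model$center) %*% model$reduction
  g <- factor(fx$labels)
  mu <- rowsum(Z, g) / as.vector(table(g))
  W <- matrix(0, ncol(Z), ncol(Z))
  for (lev in levels(g)) {
    Zi <- sweep(Z[g == lev, , drop = FALSE], 2, mu[lev, ])
    W <- W + crossprod(Zi)
  }
  W <- W / (nrow(Z) - 2)
  a_ref <- solve(W, mu[1, ] - mu[2, ])
  expect_equal(vec_cor(model$axes[, 1], a_ref), 1, tolerance = 1e-6)
  # canonical separation equals the Mahalanobis distance between means
  d_canon <- unname(abs(diff(model$group_means_canonical[, 1])))
  d_mahal <- sqrt(mahalanobis(mu[1, ], mu[2, ], W))
  expect_equal(d_canon, d_mahal, tolerance = 1e-6)
})

test_that("CVA agrees with the lda oracle on scores and predictions", {
  skip_if_not_installed("MASS")
  fx <- cva_fixture(g = 3, n_per = 15, sep = 4, seed = 32)
  model <- fit_cva(fx$ds, "diet")
  Z <- sweep(fx$ds$tangent, 2, model$center) %*% model$reduction
  ld <- MASS::lda(Z, grouping = factor(fx$labels))
  pr <- predict(ld)
  cls <- classify_specimens(model, fx$ds, cross_validate = FALSE)
  expect_equal(cls$table$predicted, as.character(pr$class))
  # canonical scores agree axis-by-axis up to sign
  my_sc <- model$scores
  for (j in 1:2)
    expect_gt(abs(cor(my_sc[, j], pr$x[, j])), 1 - 1e-6)
})

test_that("canonical scores have unit pooled within-group variance", {
  fx <- cva_fixture(g = 4, n_per = 12, sep = 4, seed = 33)
  model <- fit_cva(fx$ds, "diet")
  g <- factor(fx$labels)
  for (j in seq_len(ncol(model$scores))) {
    ss <- 0
    for (lev in levels(g)) {
      x <- model$scores[g == lev, j]
      ss <- ss + sum((x - mean(x))^2)
    }
    expect_equal(ss / (nrow(model$scores) - nlevels(g)), 1,
                 tolerance = 1e-9)
  }
  expect_lte(ncol(model$axes), nlevels(g) - 1)
})

test_that("posteriors sum to 1; mean-point and equidistant cases behave", {
  fx <- cva_fixture(g = 3, n_per = 20, sep = 8, seed = 34)
  model <- fit_cva(fx$ds, "diet")
  cls <- classify_specimens(model, fx$ds, cross_validate = FALSE)
  expect_equal(unname(rowSums(cls$posterior)), rep(1, fx$ds$n),
               tolerance = 1e-12)

  # a specimen at a group's canonical mean gets that group with p > 0.99
  Z <- model$group_means_canonical
  target <- Z["fruits", ]
  # invert canonical map approximately: place tangent at the group mean
  sel <- fx$labels == "fruits"
  at_mean <- colMeans(fx$ds$tangent[sel, , drop = FALSE])
  r <- sciurmorph:::classify_rows(model, matrix(at_mean, 1))
  expect_equal(r$predicted, "fruits")
  expect_gt(r$posterior[1, "fruits"], 0.99)

  # midpoint between two far groups, far from the third: ~0.5/0.5
  mid <- (colMeans(fx$ds$tangent[fx$labels == "fruits", , drop = FALSE]) +
          colMeans(fx$ds$tangent[fx$labels == "nuts", , drop = FALSE])) / 2
  r2 <- sciurmorph:::classify_rows(model, matrix(mid, 1))
  expect_equal(unname(r2$posterior[1, "fruits"]),
               unname(r2$posterior[1, "nuts"]), tolerance = 0.2)
  expect_lt(r2$posterior[1, "seeds"], 0.05)
})

test_that("well-separated groups classify near-perfectly; LOO <= resub", {
  fx <- cva_fixture(g = 7, n_per = 12, sep = 5, seed = 35)
  model <- fit_cva(fx$ds, "diet")
  cls <- classify_specimens(model, fx$ds, cross_validate = TRUE)
  expect_gte(cls$percent_correct_cv, 90)
  expect_gte(cls$percent_correct, cls$percent_correct_cv - 1e-9)
  expect_equal(dim(cls$confusion), c(7, 7))
  expect_equal(unname(rowSums(cls$confusion)), rep(100, 7), tolerance = 1e-9)
})

test_that("ungrouped specimens are classified without entering the fit", {
  fx <- cva_fixture(g = 3, n_per = 15, sep = 8, seed = 36, ungrouped = 2)
  model <- fit_cva(fx$ds, "diet")
  expect_false(any(grepl("^s0(4[6-7])$", model$fitted_ids)))
  cls <- classify_specimens(model, fx$ds, cross_validate = TRUE)
  un <- cls$table[fx$labels == "ungrouped", ]
  # parked at the first group's mean, they classify to it with certainty
  expect_true(all(un$predicted == "fruits"))
  expect_true(all(un$posterior > 0.9))
})

test_that("grouping is data: locomotion and custom vectors run identically", {
  fx <- cva_fixture(g = 3, n_per = 10, sep = 5, seed = 37)
  ds <- fx$ds
  ds$locomotion <- rep(c("terrestrial", "arboreal_scansorial", "gliding"),
                       each = 10)
  m1 <- fit_cva(ds, "locomotion")
  m2 <- fit_cva(ds, ds$locomotion)
  expect_equal(m1$scores, m2$scores)
  expect_equal(m1$groups, c("arboreal_scansorial", "gliding", "terrestrial"))
})

test_that("degenerate groupings error; singleton groups are dropped", {
  fx <- cva_fixture(g = 2, n_per = 10, sep = 5, seed = 38)
  expect_error(fit_cva(fx$ds, rep("one", fx$ds$n)), "at least 2 groups")
  lab <- fx$labels
  lab[1] <- "insects"  # singleton
  expect_warning(m <- fit_cva(fx$ds, lab), "excluding")
  expect_equal(length(m$groups), 2)
})

test_that("group distances: symmetry, null uniformity hint, separated-group p", {
  fx <- cva_fixture(g = 3, n_per = 12, sep = 6, seed = 39)
  gd <- group_distance_tests(fx$ds, "diet", n_perm = 199, seed = 4)
  expect_equal(gd$distance, t(gd$distance))
  expect_true(all(diag(gd$distance) == 0))
  expect_true(all(gd$p_value[upper.tri(gd$p_value)] <= 1))
  # all three pairs strongly separated: minimal p
  expect_true(all(gd$p_value[upper.tri(gd$p_value)] == 1 / 200))

  # same group split at random: p is not extreme (single-draw sanity check)
  set.seed(40)
  m <- 28
  tang <- matrix(rnorm(40 * m, sd = 0.01), 40, m,
                 dimnames = list(sprintf("n%02d", 1:40), NULL))
  ds0 <- tangent_dataset(tang, rep(100, 40), unit_template_vec())
  ds0$diet <- rep(c("fruits", "nuts"), each = 20)
  gd0 <- group_distance_tests(ds0, "diet", n_perm = 199, seed = 5)
  expect_gt(gd0$p_value["fruits", "nuts"], 0.01)
})
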