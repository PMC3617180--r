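# sciurmorph

Landmark geometric morphometrics and phylogenetic comparative analysis of
the squirrel mandible, as an R package.

## The problem

Mandible shape in squirrels reflects two forces at once: what a species
eats (and how hard it must bite to eat it) and who its ancestors were.
Disentangling the two requires a chain of analyses that is usually spread
across several interactive programs. `sciurmorph` implements that chain
as tested, scriptable functions, for anyone working with 2D landmark data
on mandibles or comparable structures:

* **Superimposition** — Generalized Procrustes Analysis of $k$-landmark
  configurations (centering, unit centroid size, determinant-corrected
  rotations), tangent-space projection at the consensus, full Procrustes
  distances, per-taxon mean shapes.
* **Evolutionary allometry** — multivariate regression of shape on
  centroid size: percent of shape variation predicted
  ($100\,\mathrm{SS}_{pred}/\mathrm{SS}_{tot}$), Goodall-style
  $F = \mathrm{SS}_{pred}/(\mathrm{SS}_{res}/(n-2))$, permutation
  p-values, size-corrected residual shapes, and ANCOVA-style tests of
  slope/intercept homogeneity across clades.
* **Ordination** — PCA of the shape covariance matrix (raw or
  size-corrected), shape reconstruction along axes, projection of the
  phylogeny into PC space.
* **Phylogenetic signal and homoplasy** — squared-change parsimony
  ancestral shapes on a topology with unit branch lengths (each internal
  node is the mean of its neighbours; tree length
  $L = \sum_{edges}\lVert x_{parent}-x_{child}\rVert^2$), a permutation
  test of signal ($p = (1+\#\{L_{perm}\le L_{obs}\})/(1+n_{perm})$), and
  shape consistency / retention indices
  $\mathrm{SCI}=L_{min}/L_{obs}$,
  $\mathrm{SRI}=(L_{max}-L_{obs})/(L_{max}-L_{min})$ with the exact
  Steiner minimum from exhaustive topology enumeration (≤ 11 taxa).
* **Ecomorphological classification** — canonical variates analysis of
  Procrustes coordinates by dietary or locomotor group, Mahalanobis
  classification with equal-prior posteriors
  $p(g)\propto e^{-D_g^2/2}$, leave-one-out cross-validation (full refit
  per fold), classification of ungrouped specimens (e.g. fossils), and
  permutation tests on between-group Procrustes distances.
* **Biomechanics** — jaw-muscle moment arms from the condyle midpoint to
  insertion landmarks, the incisor resistance arm, and mechanical
  advantage ratios (arm/RI).
* **Synthetic data** — a generator with Brownian shape evolution on a
  phylogeny, dietary-group effects, a common allometric vector and
  specimen noise, with recorded ground truth; and a pipeline running the
  whole analysis end to end, reproducibly from a single seed.

## Worked example

Simulate a 20-taxon study (60 specimens, 7 dietary groups), write it as a
fixture bundle (TPS + newick + specimen table), and run the full
analysis:

```r
library(sciurmorph)

dir <- file.path(tempdir(), "demo")
write_fixture_bundle(simulation_config(n_taxa = 20, seed = 42), dir)
report <- run_full_analysis(dir, list(seed = 42, n_perm = 499,
  clades = list(clade_a = sprintf("taxon_%02d", 1:6))))
print(report)
```

```
Pipeline report
  GPA: 60 specimens, 14 landmarks, converged in 4 iterations
  Allometry: 15.24% of shape predicted by size (p = 0.006)
  PCA: PC1 28.74%, PC2 18.89%
  Signal: tree length 0.03631, p = 0.002
  CVA (diet): 98.3% correct (76.7% cross-validated)
  CVA (locomotion): 91.7% correct (56.7% cross-validated)
```

Size predicts 15% of among-genus shape variation (significant at 499
permutations); the observed squared-change tree length is far below the
permutation distribution, i.e. related taxa have similar mandibles; and
diet is recoverable from shape for three quarters of specimens even
under leave-one-out. The 6-taxon clade is small enough for the exact
Steiner search:

```r
print(report$homoplasy$clade_a)
```

```
Homoplasy indices (exhaustive search over 105 topologies)
  tree length: observed = 0.0190766, min = 0.0190766, max (star) = 0.0290987
  SCI = 1.000, SRI = 1.000
```

Here the observed topology *is* the Steiner-minimal tree — no homoplasy
in this clade. Mechanical advantages of the five jaw muscles for each
dietary group's mean shape (ratios of moment arm to incisor resistance
arm; higher = more forceful, slower bite):

```r
head(report$lever$diet_means)
```

```
         shape        RI      MT2p        MT     MSM8p     MSM9p      MADM
1       fruits 0.6990230 0.2594738 0.3192654 0.3126237 0.3003250 0.5505310
2         nuts 0.6893115 0.2417329 0.3146112 0.3255410 0.3098310 0.5637423
3        seeds 0.6958322 0.2643243 0.3230547 0.3043772 0.3096661 0.5394186
4       leaves 0.7033622 0.2525138 0.3256315 0.2992397 0.2632928 0.5522412
5 herbivore_ss 0.6896170 0.2455104 0.3419045 0.3259165 0.3238738 0.5820729
6 bark_gleaner 0.6974833 0.2664799 0.3384218 0.3171105 0.2695067 0.5423932
```

Every step is available on its own (`read_tps()`, `gpa_align()`,
`fit_allometry()`, `fit_shape_pca()`, `reconstruct_ancestral_shapes()`,
`permutation_signal_test()`, `homoplasy_indices()`, `fit_cva()`,
`classify_specimens()`, `compute_lever_arms()`, ...); see the vignette
in `vignettes/mandible-morphometrics.Rmd` for the models, conventions
and numerical choices.

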