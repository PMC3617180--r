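---
title: "Landmark morphometrics and phylogenetic comparative analysis of the sciurid mandible"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark morphometrics and phylogenetic comparative analysis of the sciurid mandible}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sciurmorph)
```

## The analytical model

`sciurmorph` implements a complete landmark-based analysis of mandible
shape in squirrels: how much of the shape variation among genera is
explained by size (evolutionary allometry), how much is structured by
shared ancestry (phylogenetic signal and homoplasy), how well dietary and
locomotor ecology can be read off the mandible (canonical variates
classification), and what the shapes imply biomechanically (jaw-muscle
mechanical advantage). The same machinery applies to any 2D landmark
study of comparable design; the 14-landmark mandible scheme in buccal
view (x anterior, y dorsal) is the package default.

The chain of assumptions, in order:

1. **Shape space.** A configuration of $k$ landmarks, after removing
   translation, scale (unit centroid size) and rotation, lives on a
   curved shape space. All statistics are computed in the linear space
   tangent to it at the sample consensus. This is accurate when shape
   variation is small — tangent and Procrustes distances agree within 1%
   for perturbations below about 5% of centroid size, which both real
   mandible samples and the synthetic data respect.
2. **Linearity of effects.** Allometry, group effects and phylogenetic
   divergence act additively on tangent coordinates.
3. **Topology-only phylogeny.** Branch lengths are deliberately ignored
   (all set to 1 at import); the comparative statements are about the
   branching order, not about rates.

## Generalized Procrustes Analysis

`gpa_align()` centers each configuration, scales it to unit centroid
size, and iteratively rotates all configurations to the re-estimated
consensus (itself rescaled to unit size each round). Numerical choices:

* rotations are proper (determinant-corrected); reflections are never
  folded in, since all specimens are digitized in the same orientation;
* the first specimen seeds the consensus; iteration stops when the
  consensus moves less than `1e-10` (root summed squared coordinates) or
  at 100 iterations, whichever comes first — on realistic data 4–6
  iterations suffice;
* the converged superimposition is rotated as a block so that the
  consensus lies along its principal axes, with the 180° ambiguity
  resolved by the sign of the largest consensus entry. This makes the
  output a pure function of the shapes: any common rotation, translation
  or scaling of the inputs leaves the aligned coordinates unchanged to
  `1e-8`;
* tangent coordinates are the orthogonal projection
  $t = x - (x \cdot c)\,c$ at the unit-norm consensus $c$ (the
  orthogonal rather than stereographic variant; at mandible-scale
  variation the difference is far below other error sources).

The summed squared distance to the consensus is non-increasing across
iterations (each half-step — rotation, then consensus update — minimizes
it in one block of variables), which the test suite asserts.

## Evolutionary allometry

Taxon (genus) mean shapes are the regression units. Each tangent
coordinate is regressed on centroid size (raw CS by default; log CS as an
option), giving a $2k$-vector slope $b$. Reported: the percentage of
total shape variation predicted by size in the Procrustes metric,
$100\,\mathrm{SS}_{pred}/\mathrm{SS}_{tot}$; a Goodall-style F pooling
all coordinates, $F = \mathrm{SS}_{pred} / (\mathrm{SS}_{res}/(n-2))$;
and a permutation p-value obtained by shuffling CS across taxa
(`p = (1 + #{permuted >= observed}) / (1 + n_perm)`, never exactly zero).
Under the no-allometry null the expected percentage is $100/(n-1)$, a
useful baseline when reading the number.

Slope/intercept homogeneity across clades (`test_common_allometry()`)
projects all shapes onto the pooled within-group slope direction and runs
a standard ANCOVA on the resulting scores: the group x size interaction F
tests slope heterogeneity, then, under a common slope, the group main
effect tests intercepts. The multivariate-to-score reduction is the
pragmatic univariate reading of a shape ANCOVA — single reported F values
imply a univariate test — and its type-I error is calibrated: with an
estimated projection axis the slope test rejects at 5.3% (nominal 5%)
over 300 null simulations in the development checks, and the acceptance
suite re-verifies the [3%, 7%] band at every run. Residual-permutation
(Freedman–Lane) p-values accompany the parametric ones.

## Ordination and the phylogeny in shape space

`fit_shape_pca()` eigendecomposes the covariance matrix (never the
correlation matrix) of taxon-mean tangent coordinates. Superimposition
removes 4 dimensions, so at most $\min(n-1, 2k-4)$ axes are non-null;
axes below `1e-12` of the trace are dropped, and each eigenvector's
largest-magnitude entry is made positive so output is reproducible across
platforms. PCA of allometry residuals gives the size-corrected
ordination, whose scores are uncorrelated with CS by construction.
`shape_at_score()` folds `mean + score * eigenvector` back to landmark
form — the wireframes drawn along ordination axes — and
`map_tree_to_ordination()` projects reconstructed ancestral shapes onto
the retained axes so the tree can be drawn in PC space.

## Squared-change parsimony, signal, and homoplasy

With unit branch lengths, the ancestral shapes minimizing the total
squared change along edges solve a linear system: every internal node is
the mean of its tree neighbours, per coordinate. `reconstruct_ancestral_shapes()`
solves this exactly (any node degrees, polytomies included) and reports
the minimized sum as the morphometric tree length.

One convention deserves care. A rooted binary tree carries a degree-2
root node. Because that node subdivides an edge, it halves that edge's
squared-change contribution, so the tree length depends on whether the
root node is kept. `reconstruct_ancestral_shapes()` honours the tree as
given — the root is a reconstructed node like any other. The homoplasy
indices, however, compare the observed length against minima and maxima
over *unrooted* topologies, so `homoplasy_indices()` suppresses a
degree-2 root before measuring; otherwise the observed (root-split)
length could undercut the true Steiner minimum and push the indices out
of $[0, 1]$. Tree length is invariant to where the tree is rooted as long
as the node set is unchanged (re-rooting at internal nodes), which the
tests verify.

The permutation test for phylogenetic signal shuffles the tip shapes
among the terminal taxa (full Fisher–Yates, one seeded stream per call)
and recomputes the tree length; short observed length means signal, so
`p = (1 + #{permuted <= observed}) / (1 + n_perm)`. The test is
deliberately conservative in aggregate: signal confined to one clade can
drive rejection for the whole tree, which is why the pipeline also runs
the test within user-defined clades.

Homoplasy is quantified by the shape consistency index
$\mathrm{SCI} = L_{min}/L_{obs}$ and the shape retention index
$\mathrm{SRI} = (L_{max}-L_{obs})/(L_{max}-L_{min})$. $L_{min}$ is the
exact Steiner optimum: every unrooted binary topology on the tips — there
are $(2n-5)!!$ of them — is optimized and the smallest length kept.
$L_{max}$ is the star-tree length $\sum_i \lVert x_i - \bar{x}\rVert^2$;
the tests confirm exhaustively (for $n \le 7$) that no binary topology
exceeds it, supporting this reading of the "maximal length of any tree".
Exhaustive search is refused above 11 taxa (and the pipeline default caps
clades at 8, where enumeration takes seconds); beyond that a
nearest-neighbour-interchange descent from the observed topology gives a
labelled-approximate minimum. Resolving a polytomy can only shorten a
tree, so restricting the enumeration to binary topologies is safe.

## Canonical variates and classification

`fit_cva()` works on individual specimens (taxon-mean mode is available
by passing a taxon-mean dataset): Procrustes tangent data are reduced to
the PCA subspace holding all variance above `1e-12` of the trace, capped
at $N - g$ dimensions so the pooled within-group covariance is
invertible; the between/within generalized eigenproblem is solved by
Cholesky whitening; axes are scaled to unit pooled within-group score
variance and mapped back to landmark space for wireframes. At most
$g - 1$ axes are non-null.

Classification is by Mahalanobis distance in canonical space with equal
priors: $p(g) \propto \exp(-D_g^2/2)$. Equal priors because group sample
sizes are artifacts of collecting, not of nature. Exact distance ties
resolve to the lowest group index (deterministic). Specimens labelled
`ungrouped` — fossils, taxa of unknown ecology — are scored and
classified but never enter the fit. Cross-validation is leave-one-out
with a full refit per fold; no shortcut formulas, correctness over speed
at desk scale. Between-group Procrustes distances are tested by pooling
and relabelling the two groups' specimens.

## The synthetic-data generator

No raw landmark data accompany the study this package re-implements
(the specimens are museum material), so `simulate_dataset()` generates
datasets with the statistical structure the analysis assumes, with full
ground truth recorded for recovery tests:

* taxon mean shapes = unit-size template + Brownian motion accumulated
  along a Yule (or user-supplied) topology with unit branches
  (`bm_sd = 0.005` per coordinate per branch),
* plus a fixed per-diet-group offset (`diet_effect_sd = 0.007`),
* plus a common allometric vector times centroid size
  (`b_scale = 1.2e-4` per mm; CS log-uniform on 50–800 mm, pygmy
  squirrel to marmot),
* specimens = taxon mean + isotropic landmark noise
  (`noise_sd = 0.009`), randomly rotated and translated as digitized
  photographs are.

The defaults were chosen to reproduce the qualitative regime reported
for the real mandible data — allometry predicting roughly a tenth of
among-genus shape variance yet clearly significant, a strong
phylogenetic signal, and dietary classification good but not perfect
(high-80s percent cross-validated) — so that pipeline output on synthetic
data reads like the real analysis. What the generator does *not* emulate:
correlated (anisotropic) landmark noise from digitizing, modular
covariation between mandible regions, unequal specimen counts, or
rate shifts across clades. Passing tests therefore certify the
estimators and their calibration under the assumed model, not robustness
to those violations.

All randomness flows from the single config seed; seeded routines
restore the caller's RNG state, so nested simulations never interfere.
Amplitudes are kept small relative to the template so the simulation
stays in the tangent-linear regime.

## The pipeline

`run_full_analysis(bundle, config)` runs, in order: GPA → taxon means →
allometry (+ residuals) → PCA on raw and size-corrected covariance →
ancestral shapes + tree projection → signal tests (whole tree, then each
configured clade with ≥ 4 tips) → SCI/SRI for clades within the
exhaustive-search cap → CVA per grouping with cross-validation and
classification of ungrouped specimens → group distance tests → lever-arm
tables for taxon means, diet-group means, PC-reconstructed shapes and
allometry-predicted sizes. Every stage is a pure function of
(bundle, config); a rerun with the same seed is `identical()`. Default
problem sizes (40 taxa × 3 specimens, 499 permutations, 7-taxon clade)
complete in well under a minute.

## Lever arms

The jaw pivot is the midpoint of the condyle landmark pair (7, 8); each
muscle moment arm is the point-to-point distance from the pivot to its
insertion landmark, and the incisor resistance arm RI runs from the pivot
to the antero-dorsal border of the incisive alveolus (landmark 1) — the
alveolus rather than the incisor tip, because tips wear. Mechanical
advantage is arm/RI, dimensionless and invariant to rigid motions and
scale. The default insertion map (temporalis MT2′ → coronoid tip 5,
MT → coronoid base 4, superficial masseter MSM9′ → 10 and MSM8′ → 11,
anterior deep masseter MADM → 14) follows the classical lever-model
nomenclature; the deeper masseter labels are anatomically motivated
choices rather than published assignments, so `muscle_map()` keeps every
index user-overridable. Arms are distances to landmarks, not
perpendicular distances to muscle action lines — the operational
definition used with these landmark schemes.

## Known limitations

* Strictly 2D; no semilandmarks, no 3D formats.
* Exhaustive Steiner search is factorial; 10–11 taxa are minutes-scale,
  12+ require the NNI heuristic.
* The ANCOVA reduction to regression scores tests heterogeneity *along
  the common allometric axis*; slope differences orthogonal to it are
  invisible to this test.
* Weighted (true-branch-length) squared-change parsimony,
  Ornstein–Uhlenbeck models, and phylogenetically corrected allometry are
  intentionally out of scope.
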