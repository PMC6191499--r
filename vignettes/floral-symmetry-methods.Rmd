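---
title: "Methods: symmetry decomposition of landmark shape variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symmetry decomposition of landmark shape variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florasym)
```

## The model

A specimen is a configuration of p labelled landmarks in 2D, digitised in a
fixed order. Shape is what remains after removing location, scale and
orientation: configurations are centred, scaled to unit centroid size
(CS = the square root of the summed squared landmark distances from the
centroid) and rotated onto a consensus by iterative least squares
(Generalised Procrustes Analysis). Statistics are computed in the linear
tangent space at the consensus, obtained by orthogonal projection of the
aligned coordinate vectors onto the hyperplane normal to the consensus
vector; at the small shape variances this package targets (landmark noise of
a few percent of CS), tangent and aligned deviations agree to first order.

Object symmetry for a finite symmetry group G (here Cn or Cnv in Schoenflies
notation) is analysed by *expansion*: every configuration is copied once per
group element. A reflection copy negates x and swaps the labels of
mirror-image landmarks (on-axis landmarks map to themselves); a rotation
copy permutes labels only, the matching rotation being supplied by the GPA.
Because the expanded dataset is closed under the group action, the GPA
consensus is exactly symmetric, and the sample covariance of the tangent
coordinates commutes with the orthogonal action of G on tangent space. Two
consequences drive everything else:

1. tangent space decomposes into orthogonal, complementary subspaces, one
   per irreducible representation type of G, and every eigenvector of the
   covariance lies in (or, for equal eigenvalues, spans) one of them;
2. the two-dimensional representation types that occur for rotation orders
   above 2 force *pairs* of exactly equal eigenvalues, whose eigenvector
   plane the PCA cannot orient.

PC classification therefore needs no visual inspection: for each single PC
and each group element g, the scores of the g-copies equal the scores of the
originals specimen by specimen when the PC's shape change is symmetric under
g, and equal the negated scores when it is antisymmetric. The resulting
per-element signature names the category ("fully symmetric", "rotation-only
symmetric", "symmetric under: ref_Cn00", "fully asymmetric"). Within a
two-dimensional eigenvalue-pair plane the copies' scores are rotated/
reflected images of the originals' scores, so score equality holds for no
element; such PCs are reported as "paired/unresolved" until rotated.

## Rotating equal-eigenvalue pairs

Within a pair plane any orthogonal basis is an equally valid pair of
eigenvectors. The canonical orientation rotates the basis so that the mean
score of all *unrotated* copies (rotation index 0) lies on the first axis.
The reason for including the reflected unrotated copies, not only the
identity copies, is substantive: writing m for the mean identity-copy score
in the plane and S for the action of the reflection on that plane, the mean
over unrotated copies is (m + Sm)/2 — the projection of m onto the
reflection-invariant line. The first rotated axis is therefore *exactly*
reflection-symmetric, and the orthogonal one antisymmetric, which is why
each rotated pair of a Cnv analysis splits into one bilaterally symmetric
and one totally asymmetric PC. For rotation-only groups there is no
invariant line; the rotation merely fixes a reproducible orientation and
each paired PC remains totally asymmetric, as it must. A pair whose mean
unrotated score is numerically at the origin has no defined direction and is
left unrotated with a warning.

## Counting dimensions

Centring removes 2 degrees of freedom exactly; unit scaling and the tangent
projection remove the radial direction exactly; and the first-order
optimality condition of the fitted rotation makes every aligned
configuration exactly orthogonal to the rotation direction at the consensus.
A 2D GPA thus leaves exactly 2p − 4 non-null dimensions, and the eigenvalue
threshold for "non-null" can be as strict as 1e-10 times the largest
eigenvalue. This yields the structural counts that the four built-in layouts
reproduce for any seed: 38 PCs (19 symmetric + 19 asymmetric) for the
bilateral p = 21 layout; 60 PCs in four categories of 15 for the disymmetric
p = 32 layout; 18 PCs with 8 pairs and 2 symmetric singletons for the
five-fold p = 11 layout; 16 PCs with 2 fully symmetric, 2 rotation-only
symmetric and 12 paired for the three-fold-plus-reflection p = 10 layout.

## Tunable parameters

* `tol` (GPA consensus change, default 1e-10) and `max_iter` (100): the
  superimposition converges in a handful of iterations for realistic
  landmark data; the tolerance is tight because the eigenvalue-pair equality
  and copy-score equality inherit the alignment error.
* `null_tol` (default 1e-10, relative): null-dimension threshold; see above.
* `pair_tol` (default 1e-6, relative): equal-eigenvalue detection. Pair
  equality is structural (exact up to floating point, since the copies are in
  the covariance), so the tolerance can sit many orders of magnitude above
  machine error and below any plausible eigenvalue spacing. Pairs are only
  sought for rotation orders above 2, where the group forces them. Three
  consecutive coincident eigenvalues raise an error rather than a guess.
* classification tolerance (`tol_scale`, default 1e-6 of each PC's score
  scale): same reasoning; ambiguous PCs are labelled, never dropped.
* `align_principal_axes` (default TRUE): display orientation only; ties in
  the consensus principal axes (which are the rule for rotation orders
  above 2, where the consensus covariance is isotropic) are resolved by a
  180-degree rotation making the first landmark's x non-negative.
  Only proper rotations are ever applied: a reflection absorbed by the fit
  would silently destroy the asymmetric component.

## The synthetic-data generator

`make_template()` builds a template that is exactly group-invariant by
construction, from orbit specifications (full orbits, mirror-line orbits,
centre), and emits the matching relabelling map; `flower_layout()` provides
the four study layouts with fixed, field-realistic radii and angles.
`simulate_flowers()` adds, in template coordinate space: an optional
deterministic directional-asymmetry offset, an optional per-specimen purely
asymmetric (group-symmetric part removed) fluctuating-asymmetry
displacement, and i.i.d. isotropic Gaussian landmark noise. The default
noise level is 2% of the template centroid size — small enough for
tangent-space linearity, large enough that the expanded covariance is full
rank at the study sample sizes. Sample sizes are 30 specimens per layout,
except 61 for the disymmetric layout whose expanded shape space has 60
dimensions (the rule of thumb that landmarks should number less than half
the individuals, applied to its 32 landmarks). `simulate_replicates()` nests
an imaging-level displacement (shared within an image) and a digitising-level
displacement per observation, with the `_aNbM` identifier grammar.

What the generator does *not* emulate: correlated biological covariance
structure, landmark-specific error, digitiser drift, outliers, or any real
allometry. Passing tests therefore demonstrate the machinery — counts,
orthogonality, invariances, parameter recovery — not biological claims about
real flowers; analyses of real material should still inspect outliers and
measurement error as usual.

## Measurement error and allometry

The nested Procrustes ANOVA runs on the original (non-expanded)
configurations — the recommended simple route, since the expanded dataset's
components live in subspaces of differing dimension. Degrees of freedom are
the balanced-design formulas scaled by s = 2p − 4 for shape (s = 1 for
centroid size); with 30 individuals × 2 imaging × 2 digitising and p = 21
this gives 1102/1140/2280 for shape and 29/30/60 for size. F is the mean
square ratio of adjacent nested levels and P uses the F distribution on
those df — the conventional parametric reference, reported to that
convention only. The allometry permutation test permutes sizes against
shapes and uses the (b + 1)/(n + 1) estimator; seeds are mandatory arguments
everywhere and the generator never touches the caller's RNG stream.

## Design choices and limitations

* Reflection is about the vertical axis (x negated), the digitising
  convention for flowers photographed face-on; templates follow it.
* Rotation copies are relabel-only; coordinate rotation is available
  (`rotate_coords = TRUE`) and yields identical results after GPA (tested).
* Both identifier grammars for disymmetric expansions (ori/ref twice vs.
  ori/ref × Cn) describe the same four copies; the package emits the
  rotation-based grammar and keeps an explicit copy index as the canonical
  record, which is also what classification uses.
* The NTS writer targets a minimal rectangular-matrix header
  (`1 nL v 0` with labelled rows); dialect variants with comment lines and
  wrapped rows are accepted on read.
* Scale factors are stored on read and applied only on explicit request,
  so pixel-space round trips are exact.
* Out of scope: semilandmark sliding, partial (non-scaling) Procrustes,
  3D acceptance analyses (the containers allow d = 3 but the symmetry
  machinery is exercised in 2D), the two-way mixed-model
  fluctuating/directional asymmetry ANOVA for complex symmetry, and
  hierarchical composite symmetry. For rotation orders that are not prime,
  the per-element signatures are reported but the finer factoring of the
  symmetric subspaces into per-prime-factor components is left to the user.

## Problem sizes

All worked analyses are desk scale: the largest expanded dataset is
244 configurations × 64 coordinates (disymmetric layout), a GPA of a few
iterations and an eigendecomposition of a 64 × 64 matrix. The test suite
(including 200-replicate recovery and type-I-error simulations) runs in
well under a minute.
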