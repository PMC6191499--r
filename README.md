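# florasym

Landmark-based geometric morphometrics of floral symmetry: decomposing 2D
shape variation into symmetric and asymmetric components for any finite
symmetry group.

## The problem

The corolla of a flower can be bilaterally symmetric (zygomorphy, symmetry
group C1v in Schoenflies notation), disymmetric with two perpendicular
mirror axes (C2v), purely rotationally symmetric like a pinwheel (Cn), or
actinomorphic with combined reflection and rotational symmetry (Cnv).
Quantifying how much of the shape variation in a population is *symmetric*
(variation among flowers) versus *asymmetric* (variation within flowers —
left–right asymmetry, adaxial–abaxial asymmetry, rotational asymmetry) is
fundamental for studies of canalization, developmental stability, modularity
and pollinator-mediated selection. Standard morphometric software handles
bilateral object symmetry only; `florasym` implements the general
object-symmetry framework for any finite symmetry group, for biologists who
digitise landmarks on flower photographs and want the full decomposition.

## The method

For a flower with *object symmetry* (the symmetry operators pass through the
structure itself), each configuration of p landmarks is copied once per
element of its symmetry group. Reflection copies have one coordinate negated
(x → −x) and the labels of mirror-image landmarks mutually swapped; rotation
copies are *relabelled only*, because the rotation that matches them to the
original is supplied by the superimposition itself. A single Generalised
Procrustes Analysis (GPA) of the expanded dataset — rotation-only
superimposition, unit centroid-size scaling, tangent-space projection —
yields a perfectly symmetric consensus. PCA of the tangent coordinates then
splits shape space into orthogonal, complementary subspaces:

* each principal component of a C1v analysis is either fully **symmetric**
  or fully **asymmetric** under the reflection, detectable from the score
  pattern of original versus reflected copies (equal vs. negated scores);
* groups with two perpendicular reflections (C2v) give four categories;
* rotation orders above 2 force **pairs of PCs with equal eigenvalues**
  whose eigenvector plane is rotationally indeterminate. `florasym` rotates
  each pair so that the mean score of all unrotated copies lies on the first
  axis; for groups with reflections this canonical orientation splits every
  pair into one bilaterally symmetric and one totally asymmetric PC.

Because every copy enters the covariance, the percentage of total variance
carried by each symmetry category can be read directly off the eigenvalues —
the quantity that software separating the components beforehand cannot
provide. A one-way nested Procrustes ANOVA (individuals / imaging /
digitising, Goodall-style F from mean-square ratios, shape degrees of
freedom 2p − 4 per effect level) tests the biological signal against
measurement error, and a multivariate regression of shape on (log) centroid
size with a permutation test quantifies allometry.

## Worked example

A pinwheel flower with five-fold rotational symmetry (C5): 11 landmarks (one
centre, two orbits of five), 30 simulated specimens with a small amount of
independent isotropic variation around each landmark.

```r
library(florasym)

lay <- flower_layout("vinca")          # template + relabelling map + group
ds  <- simulate_flowers(lay, n = 30, seed = 1)
res <- symmetry_pca(ds, lay$group, lay$map)
res
#> Symmetry decomposition (C5) of 30 specimens, 11 landmarks in 2D
#> Expanded dataset: 150 configurations; GPA converged in 4 iterations
#> 18 non-null PCs, 8 equal-eigenvalue pair(s) (rotated)
#>
#> Variance by symmetry category:
#>   fully asymmetric (pair)                       16 PCs   91.02%
#>   fully symmetric                                2 PCs    8.98%

head(eigen_table(res), 4)
#>   PC eigenvalue percent                category pair
#> 1  1  0.0007335   9.432 fully asymmetric (pair)    1
#> 2  2  0.0007335   9.432 fully asymmetric (pair)    1
#> 3  3  0.0005720   7.356 fully asymmetric (pair)    2
#> 4  4  0.0005720   7.356 fully asymmetric (pair)    2
```

Reading this: the expanded dataset (5 relabelled copies per flower) has
2·11 − 4 = 18 PCs with non-null eigenvalues. Sixteen of them occur as 8
pairs with exactly equal eigenvalues — each PC of a pair is totally
asymmetric under the five-fold rotation, and together the pairs carry ~91%
of the variance (the within-flower, asymmetric component). The two singleton
PCs are completely symmetric under rotation by 72° and carry the remaining
~9% (the among-flower, symmetric component). A scatterplot of a paired-PC
plane (`plot(res, type = "scores")`) shows a point cloud that is itself
five-fold symmetric, because the five copies of each flower are rotated
images of one another in score space.

Own data enter the same way: `read_tps("flowers.tps")` (or `read_nts`),
`read_relabelling("coVin.txt", p, group)` for the landmark-swap table, then
`symmetry_pca()`. Measurement-error designs use
`extract_classifier()` + `gpa()` + `procrustes_anova()` /
`centroid_size_anova()`, and `allometry()` regresses any shape component on
centroid size. A command-line front end (`exec/florasym`) chains the same
steps: `simulate`, `expand`, `analyze`, `error-anova`, `allometry`.

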