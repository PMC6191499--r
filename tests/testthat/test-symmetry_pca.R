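test_that("bilateral (C1v) decomposition: 38 PCs split 19 symmetric / 19 asymmetric", {
  run <- case_run("fedia")
  pca <- run$res$pca
  expect_equal(pca$n_nonnull, 2 * 21 - 4)
  tab <- table(pca$categories[1:pca$n_nonnull])
  expect_equal(sort(names(tab)), c("fully asymmetric", "fully symmetric"))
  expect_equal(unname(tab[["fully symmetric"]]), 19)
  expect_equal(unname(tab[["fully asymmetric"]]), 19)
  expect_equal(nrow(pca$pairs), 0)
  # empirical check of the order <= 2 rule: no accidental eigenvalue pairs
  expect_equal(nrow(detect_pairs(pca)$pairs), 0)
})

test_that("disymmetric (C2v) decomposition: 60 PCs in four categories of 15", {
  run <- case_run("erysimum")
  pca <- run$res$pca
  expect_equal(pca$n_nonnull, 2 * 32 - 4)
  tab <- table(pca$categories[1:pca$n_nonnull])
  expect_equal(length(tab), 4L)
  expect_true(all(tab == 15))
  expect_setequal(names(tab),
                  c("fully symmetric", "rotation-only symmetric",
                    "symmetric under: ref_Cn00", "symmetric under: ref_Cn01"))
})

test_that("rotational (C5) decomposition: 18 PCs, 8 pairs, 2 fully symmetric", {
  run <- case_run("vinca")
  pca <- run$res$pca
  expect_equal(pca$n_nonnull, 2 * 11 - 4)
  expect_equal(nrow(pca$pairs), 8)
  singles <- setdiff(1:pca$n_nonnull, as.vector(pca$pairs))
  expect_equal(length(singles), 2)
  expect_true(all(pca$categories[singles] == "fully symmetric"))
  expect_true(all(pca$categories[as.vector(pca$pairs)] == "fully asymmetric (pair)"))
})

test_that("actinomorphic (C3v) decomposition: 16 PCs = 2 + 2 + 6 pairs", {
  run <- case_run("trillium")
  pca <- run$res$pca
  expect_equal(pca$n_nonnull, 2 * 10 - 4)
  expect_equal(nrow(pca$pairs), 6)
  expect_equal(length(as.vector(pca$pairs)), 12)
  singles <- setdiff(1:pca$n_nonnull, as.vector(pca$pairs))
  expect_equal(sum(pca$categories[singles] == "fully symmetric"), 2)
  expect_equal(sum(pca$categories[singles] == "rotation-only symmetric"), 2)
  # after rotation each pair splits into one bilaterally symmetric and one
  # fully asymmetric PC
  for (r in seq_len(nrow(pca$pairs))) {
    labs <- pca$categories[pca$pairs[r, ]]
    expect_setequal(labs, c("symmetric under: ref_Cn00 (pair)",
                            "fully asymmetric (pair)"))
  }
})

test_that("within-pair eigenvalues are equal and the rotation is canonical", {
  for (nm in c("vinca", "trillium")) {
    pca <- case_run(nm)$res$pca
    for (r in seq_len(nrow(pca$pairs))) {
      a <- pca$pairs[r, 1]; b <- pca$pairs[r, 2]
      expect_lt(abs(pca$values[a] - pca$values[b]) / pca$values[a], 1e-8)
      # defining condition: mean unrotated-copy score sits on the first axis
      unrot <- pca$copy_index$rot == 0
      m <- colMeans(pca$scores[unrot, c(a, b)])
      expect_lt(abs(m[2]), 1e-10 * sqrt(pca$values[a]) * sqrt(sum(unrot)))
      expect_gt(m[1], 0)
    }
    # rotated eigenvectors stay orthonormal
    V <- pca$vectors[, 1:pca$n_nonnull]
    expect_lt(max(abs(crossprod(V) - diag(pca$n_nonnull))), 1e-10)
  }
})

test_that("eigendecomposition agrees with an independent SVD oracle", {
  fit <- case_run("vinca")$res$fit
  pca <- shape_pca(fit)
  Tc <- sweep(fit$tangent, 2, colMeans(fit$tangent))
  sv <- svd(Tc)$d^2 / (nrow(Tc) - 1)
  k <- pca$n_nonnull
  expect_equal(pca$values[1:k], sv[1:k], tolerance = 1e-8)
})

test_that("category variance percentages sum to 100", {
  for (nm in c("fedia", "erysimum", "vinca", "trillium")) {
    v <- case_run(nm)$res$variance
    expect_equal(sum(v), 100, tolerance = 1e-9)
  }
  expect_equal(sum(case_run("fedia")$res$variance[c("fully symmetric",
                                                    "fully asymmetric")]), 100)
})

test_that("paired-PC score clouds carry the symmetry of the group", {
  pca <- case_run("vinca")$res$pca
  s <- pca$scores[, pca$pairs[1, ]]
  rotated <- s %*% t(rot2(2 * pi / 5))
  # set equality: every rotated point coincides with a point of the cloud
  d <- outer(seq_len(nrow(s)), seq_len(nrow(s)), Vectorize(function(i, j)
    sqrt(sum((rotated[i, ] - s[j, ])^2))))
  expect_lt(max(apply(d, 1, min)), 1e-8 * max(abs(s)))
})

test_that("purely symmetric variation yields no asymmetric PCs", {
  lay <- flower_layout("fedia")
  set.seed(31)
  n <- 25
  coords <- array(NA_real_, c(21, 2, n))
  for (i in 1:n) {
    raw <- matrix(rnorm(42, sd = 0.05), 21, 2)
    coords[, , i] <- lay$template + florasym:::.symmetrise(raw, lay$group, lay$map)
  }
  res <- symmetry_pca(landmark_dataset(coords), lay$group, lay$map)
  k <- res$pca$n_nonnull
  expect_equal(k, 19)  # the asymmetric subspace is empty
  expect_true(all(res$pca$categories[1:k] == "fully symmetric"))
})

test_that("symmetric component is group-invariant; symmetric input has zero asymmetry", {
  run <- case_run("trillium")
  sym <- symmetric_component(run$res$fit)
  for (i in c(1, 7)) {
    x <- sym$coords[, , i]
    expect_lt(procrustes_distance(reflect_relabel(x, run$lay$map), x), 1e-8)
    expect_lt(procrustes_distance(rotate_relabel(x, run$lay$map, 1), x), 1e-8)
  }
  # noiseless symmetric specimens: every asymmetry component vanishes
  lay <- flower_layout("vinca")
  ds <- simulate_flowers(lay, n = 3, noise_sd = 0, seed = 4)
  fit <- gpa(expand_dataset(ds, lay$group, lay$map))
  asym <- asymmetry_component(fit, reflect = FALSE, rot = 1)
  expect_lt(max(abs(asym)), 1e-10)
})
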