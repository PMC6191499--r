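make_error_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lay <- flower_layout("fedia")
      ds <- simulate_flowers(lay, n = 30, seed = 17)
      reps <- simulate_replicates(ds, 2, 2, imaging_sd = 0.01,
                                  digitising_sd = 0.004, seed = 18)
      fit <- gpa(reps)
      cache <<- list(reps = reps, fit = fit, cl = reps$classifiers)
    }
    cache
  }
})

test_that("shape and size ANOVA reproduce the nested design df exactly", {
  st <- make_error_study()
  shp <- procrustes_anova(st$fit, st$cl$individual, st$cl$imaging, st$cl$digitising)
  expect_equal(shp$df, c(1102, 1140, 2280))  # (n-1)s, n(m-1)s, nm(r-1)s with s = 38
  siz <- centroid_size_anova(st$fit$centroid_sizes, st$cl$individual,
                             st$cl$imaging, st$cl$digitising)
  expect_equal(siz$df, c(29, 30, 60))
  # F is the mean-square ratio of adjacent nested levels
  expect_equal(shp$F[1], shp$MS[1] / shp$MS[2])
  expect_equal(shp$F[2], shp$MS[2] / shp$MS[3])
  expect_true(all(shp$SS >= 0) && all(siz$SS >= 0))
  expect_true(is.na(shp$F[3]) && is.na(shp$P[3]))
  # the imaging error dominates digitising by construction
  expect_gt(shp$F[2], 1)
})

test_that("effect sums of squares conserve the total", {
  st <- make_error_study()
  shp <- procrustes_anova(st$fit, st$cl$individual, st$cl$imaging, st$cl$digitising)
  expect_equal(sum(shp$SS), attr(shp, "ss_total"), tolerance = 1e-8)
  # and the total equals the Procrustes SS of the tangent data
  expect_equal(attr(shp, "ss_total"),
               sum(sweep(st$fit$tangent, 2, colMeans(st$fit$tangent))^2),
               tolerance = 1e-10)
})

test_that("identical replicates give zero error sums of squares", {
  lay <- flower_layout("vinca")
  ds <- simulate_flowers(lay, n = 6, seed = 2)
  reps <- simulate_replicates(ds, 2, 2, imaging_sd = 0, digitising_sd = 0, seed = 3)
  fit <- gpa(reps)
  cl <- reps$classifiers
  shp <- procrustes_anova(fit, cl$individual, cl$imaging, cl$digitising)
  expect_lt(shp$SS[2], 1e-20)
  expect_lt(shp$SS[3], 1e-20)
  siz <- centroid_size_anova(fit$centroid_sizes, cl$individual, cl$imaging,
                             cl$digitising)
  expect_lt(siz$SS[2] + siz$SS[3], 1e-20)
})

test_that("size ANOVA agrees with the lm() nested-ANOVA oracle", {
  set.seed(41)
  ind <- rep(sprintf("i%02d", 1:8), each = 6)
  img <- rep(rep(c("a1", "a2", "a3"), each = 2), 8)
  dig <- rep(c("b1", "b2"), 24)
  y <- rnorm(48)
  ours <- centroid_size_anova(y, ind, img, dig)
  orc <- suppressWarnings(anova(lm(y ~ ind / img / dig)))  # saturated fit
  expect_equal(ours$SS, orc$`Sum Sq`[1:3], tolerance = 1e-8)
  expect_equal(ours$df, orc$Df[1:3])
  expect_equal(ours$MS, orc$`Mean Sq`[1:3], tolerance = 1e-8)
})

test_that("unbalanced designs are refused", {
  st <- make_error_study()
  cl <- st$cl
  expect_error(centroid_size_anova(st$fit$centroid_sizes[-1],
                                   cl$individual[-1], cl$imaging[-1],
                                   cl$digitising[-1]),
               "unbalanced")
})

test_that("allometry regression: perfect fit, determinism, degenerate input", {
  set.seed(51)
  sizes <- runif(20, 1, 3)
  direction <- rnorm(10)
  shape <- outer(log(sizes), direction)  # exact linear dependence on size
  res <- allometry(shape, sizes, use_log = TRUE, n_perm = 99, seed = 7)
  expect_equal(res$percent_predicted, 100, tolerance = 1e-10)
  expect_equal(res$p_value, 1 / 100)  # smallest attainable with 99 rounds
  res2 <- allometry(shape, sizes, use_log = TRUE, n_perm = 99, seed = 7)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res, res2)
  expect_error(allometry(shape, rep(2, 20), n_perm = 9, seed = 1), "constant")
  expect_error(allometry(shape, sizes, n_perm = 9), "seed")
})
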