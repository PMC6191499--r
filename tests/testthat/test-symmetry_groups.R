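test_that("symmetry groups enumerate elements with the identity first", {
  for (spec in list(list(1, TRUE, 2), list(2, TRUE, 4), list(5, FALSE, 5),
                    list(3, TRUE, 6))) {
    g <- symmetry_group(spec[[1]], reflection = spec[[2]])
    expect_equal(nrow(g$elements), spec[[3]])
    expect_false(g$elements$reflect[1])
    expect_equal(g$elements$rot[1], 0L)
  }
  expect_error(symmetry_group(1, reflection = FALSE), "trivial")
})

test_that("relabelling maps are validated: bijection, involution, cyclic powers", {
  expect_s3_class(relabelling_map(5, reflection = c(3, 2, 1, 4, 5)),
                  "relabelling_map")
  expect_error(relabelling_map(5, reflection = c(2, 3, 1, 4, 5)), "involution")
  expect_error(relabelling_map(5, reflection = c(1, 1, 3, 4, 5)), "not a permutation")
  # C5 rotation columns must be successive powers of the generator
  gen <- c(5, 1, 2, 3, 4)
  pw <- list(gen); for (k in 2:4) pw[[k]] <- gen[pw[[k - 1]]]
  good <- do.call(cbind, pw)
  expect_s3_class(relabelling_map(5, rotations = good), "relabelling_map")
  bad <- good; bad[, 3] <- good[, 2]
  expect_error(relabelling_map(5, rotations = bad), "cyclic consistency")
})

test_that("relabelling files enforce the per-group column counts", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(c(3, 2, 1, 4, 5)), f)
  m <- read_relabelling(f, 5, symmetry_group(1, reflection = TRUE))
  expect_equal(m$reflection, c(3L, 2L, 1L, 4L, 5L))
  expect_error(read_relabelling(f, 5, symmetry_group(5)), "needs 4")
  lay <- flower_layout("trillium")
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_relabelling(lay$map, f2)
  back <- read_relabelling(f2, 10, lay$group)
  expect_equal(back$reflection, lay$map$reflection)
  expect_equal(back$rotations, lay$map$rotations)
})

test_that("reflection copies negate x and swap paired labels", {
  map <- relabelling_map(3, reflection = c(3, 2, 1))
  # on-axis landmark fixed; hand-derived asymmetric example
  x <- matrix(c(2, 0, 0, 1, -1, 0), ncol = 2, byrow = TRUE)
  expect_equal(reflect_relabel(x, map),
               matrix(c(1, 0, 0, 1, -2, 0), ncol = 2, byrow = TRUE))
  # a perfectly symmetric configuration is invariant
  sym <- matrix(c(1, 2, 0, 2, -1, 2), ncol = 2, byrow = TRUE)
  expect_equal(reflect_relabel(sym, map), sym)
  expect_error(reflect_relabel(x, relabelling_map(3, rotations = cbind(c(2, 3, 1)))),
               "no reflection")
})

test_that("rotation copies are relabel-only and close under the group", {
  lay <- flower_layout("vinca")
  x <- lay$template + 0.05  # break the symmetry
  y <- x
  for (k in 1:5) y <- rotate_relabel(y, lay$map, 1)
  expect_equal(y, x)  # five rotations restore the original labels
  # relabelled copy of the symmetric template superimposes exactly
  expect_lt(procrustes_distance(rotate_relabel(lay$template, lay$map, 2),
                                lay$template), 1e-12)
  expect_error(rotate_relabel(x, lay$map, 5), "out of range")
})

test_that("dataset expansion produces |group| copies with the id grammar", {
  ds <- random_dataset(n = 3, p = 21)
  fed <- flower_layout("fedia")
  ex <- expand_dataset(ds, fed$group, fed$map)
  expect_equal(n_configurations(ex), 6L)
  expect_equal(ex$ids[1:2], c("rnd01_ori_Cn00", "rnd01_ref_Cn00"))
  tril <- flower_layout("trillium")
  ds10 <- random_dataset(n = 3, p = 10)
  ex6 <- expand_dataset(ds10, tril$group, tril$map)
  expect_equal(n_configurations(ex6), 18L)
  expect_equal(ex6$ids[1:6],
               paste0("rnd01_", c("ori_Cn00", "ref_Cn00", "ori_Cn01",
                                  "ref_Cn01", "ori_Cn02", "ref_Cn02")))
  vin <- flower_layout("vinca")
  ex5 <- expand_dataset(random_dataset(n = 3, p = 11), vin$group, vin$map)
  expect_equal(n_configurations(ex5), 15L)
  expect_equal(ex5$ids[1:5], paste0("rnd01_Cn0", 0:4))
  # closure: relabelling a rotation copy gives the next rotation copy exactly
  for (k in 0:4)
    expect_equal(rotate_relabel(ex5$coords[, , 1 + k], vin$map, 1),
                 ex5$coords[, , 1 + (k + 1) %% 5])
})

test_that("expanding twice with C1v matches one C2v expansion up to superimposition", {
  ery <- flower_layout("erysimum")
  ds <- simulate_flowers(ery, n = 2, seed = 7)
  ex_c2v <- expand_dataset(ds, ery$group, ery$map)
  # route 2: reflect about the vertical axis, then about the horizontal one
  c1v <- symmetry_group(1, reflection = TRUE)
  map_lr <- relabelling_map(32, reflection = ery$map$reflection)
  # relabelling for the horizontal-axis reflection = vertical reflection
  # composed with the 180-degree rotation
  map_ab <- relabelling_map(32, reflection = ery$map$rotations[ery$map$reflection, 1])
  step1 <- expand_dataset(ds, c1v, map_lr)
  step2 <- expand_dataset(step1, c1v, map_ab)
  expect_equal(n_configurations(step2), n_configurations(ex_c2v))
  for (i in 1:2) {
    a <- which(ex_c2v$copy_index$source == i)
    b <- which(grepl(sprintf("^ind%03d_", i), step2$ids))
    d <- outer(a, b, Vectorize(function(x, y)
      procrustes_distance(ex_c2v$coords[, , x], step2$coords[, , y])))
    # each copy from one route has exactly one zero-distance partner in the other
    expect_true(all(apply(d < 1e-9, 1, sum) == 1))
    expect_true(all(apply(d < 1e-9, 2, sum) == 1))
  }
})

test_that("matching symmetry reflects non-reference units onto the reference", {
  map <- relabelling_map(3, reflection = c(3, 2, 1))
  right <- matrix(c(2, 0, 0, 1, -1, 0), ncol = 2, byrow = TRUE)
  left <- reflect_relabel(right, map)  # exact mirror unit
  ds <- landmark_dataset(array(c(right, left), c(3, 2, 2)),
                         ids = c("i1_R", "i1_L"),
                         classifiers = data.frame(side = c("R", "L")))
  matched <- match_units(ds, "side", "R", map)
  expect_equal(matched$coords[, , 2], right)
  expect_lt(procrustes_distance(matched$coords[, , 1], matched$coords[, , 2]), 1e-12)
  all_r <- match_units(ds[1], "side", "R", map)
  expect_equal(all_r$coords, ds[1]$coords)
  expect_error(match_units(ds, "side", "Q", map), "unknown reference level")
  expect_error(match_units(ds, "wing", "R", map), "not defined")
})
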