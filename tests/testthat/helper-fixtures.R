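# memoised case-study pipeline runs shared across test files
.case_runs <- new.env(parent = emptyenv())

case_run <- function(name, seed = 1) {
  key <- paste(name, seed, sep = "_")
  if (is.null(.case_runs[[key]])) {
    lay <- flower_layout(name)
    ds <- simulate_flowers(lay, n = lay$default_n, seed = seed)
    .case_runs[[key]] <- list(lay = lay, ds = ds,
                              res = symmetry_pca(ds, lay$group, lay$map))
  }
  .case_runs[[key]]
}

# a scalene (asymmetric) triangle
tri <- function() matrix(c(0, 0, 3, 0, 1, 2), ncol = 2, byrow = TRUE)

rot2 <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2)

random_dataset <- function(n = 5, p = 7, seed = 99) {
  set.seed(seed)
  landmark_dataset(array(rnorm(p * 2 * n), c(p, 2, n)),
                   ids = sprintf("rnd%02d", seq_len(n)))
}
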