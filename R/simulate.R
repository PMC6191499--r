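#' Orbit specification for a symmetric landmark template
#'
#' A template is built orbit by orbit: a `"full"` orbit places a landmark in
#' general position and its images under every group element (`2n` landmarks
#' for `Cnv`, `n` for `Cn`), an `"axis"` orbit places a landmark on the
#' mirror line (its `n` rotational images; on-axis landmarks are fixed by
#' the reflection), and a `"centre"` orbit is a single landmark on the
#' rotation centre.
#'
#' @param kind `"full"`, `"axis"`, or `"centre"`
#' @param radius distance from the centre (may be signed for `"axis"`
#'   orbits: negative values sit on the lower half of the mirror line);
#'   must be non-zero except for `"centre"`
#' @param angle angular offset of the representative landmark, in radians
#'   counterclockwise from the positive y axis (the mirror line)
#' @return an object of class `orbit_spec`
#' @export
orbit <- function(kind = c("full", "axis", "centre"), radius = 1, angle = 0) {
  kind <- match.arg(kind)
  if (kind != "centre" && radius == 0)
    stop("a non-centre orbit needs a non-zero radius")
  structure(list(kind = kind, radius = radius, angle = angle),
            class = "orbit_spec")
}

#' Build a symmetric template and its relabelling map
#'
#' Generates landmark coordinates by applying every group element to each
#' orbit representative, so the template is exactly invariant under the
#' group; the matching relabelling map is emitted simultaneously and is
#' correct by construction. Reflection is about the vertical (y) axis,
#' rotation is by `2*pi/n` counterclockwise.
#'
#' @param group a [symmetry_group()]
#' @param orbits list of [orbit()] specifications
#' @return a list with `template` (`p x 2` matrix), `map`
#'   (a [relabelling_map()]), and `group`
#' @export
make_template <- function(group, orbits) {
  stopifnot(inherits(group, "symmetry_group"))
  n <- group$order
  a <- 2 * pi / n
  rot <- function(v, k) {
    th <- a * k
    c(cos(th) * v[1L] - sin(th) * v[2L], sin(th) * v[1L] + cos(th) * v[2L])
  }
  coords <- NULL
  refl <- integer(0)
  gen <- integer(0)   # generator rotation permutation
  base <- 0L
  for (ob in orbits) {
    if (!inherits(ob, "orbit_spec")) stop("orbits must be built with orbit()")
    if (ob$kind == "centre") {
      coords <- rbind(coords, c(0, 0))
      refl <- c(refl, base + 1L)
      gen <- c(gen, base + 1L)
      base <- base + 1L
    } else if (ob$kind == "axis") {
      if (!group$reflection && ob$kind == "axis")
        stop("'axis' orbits need a group with reflection")
      v <- c(0, ob$radius)
      pts <- t(vapply(0:(n - 1L), function(k) rot(v, k), numeric(2L)))
      coords <- rbind(coords, pts)
      # mirror of R^k v is R^{-k} v; rotating by -a sends R^k v to R^{k-1} v
      refl <- c(refl, base + ((n - (0:(n - 1L))) %% n) + 1L)
      gen <- c(gen, base + ((0:(n - 1L) - 1L) %% n) + 1L)
      base <- base + n
    } else {
      v <- ob$radius * c(sin(ob$angle), cos(ob$angle))
      ptsA <- t(vapply(0:(n - 1L), function(k) rot(v, k), numeric(2L)))
      if (group$reflection) {
        w <- c(-v[1L], v[2L])
        ptsB <- t(vapply(0:(n - 1L), function(k) rot(w, k), numeric(2L)))
        coords <- rbind(coords, ptsA, ptsB)
        ks <- 0:(n - 1L)
        refl <- c(refl,
                  base + n + ((n - ks) %% n) + 1L,   # mirror of A_k is B_{(n-k) mod n}
                  base + ((n - ks) %% n) + 1L)       # mirror of B_k is A_{(n-k) mod n}
        gen <- c(gen,
                 base + ((ks - 1L) %% n) + 1L,
                 base + n + ((ks - 1L) %% n) + 1L)
        base <- base + 2L * n
      } else {
        coords <- rbind(coords, ptsA)
        ks <- 0:(n - 1L)
        gen <- c(gen, base + ((ks - 1L) %% n) + 1L)
        base <- base + n
      }
    }
  }
  p <- nrow(coords)
  rotations <- if (n > 1L) {
    m <- matrix(NA_integer_, p, n - 1L)
    pw <- gen
    for (k in seq_len(n - 1L)) { m[, k] <- pw; pw <- gen[pw] }
    m
  }
  map <- relabelling_map(p, reflection = if (group$reflection) refl,
                         rotations = rotations)
  # sanity: the template must be exactly group-invariant under its own map
  for (j in seq_len(nrow(group$elements))) {
    el <- group$elements[j, ]
    img <- .apply_element(coords, map, el$reflect, el$rot, n)
    if (max(abs(img - coords)) > 1e-12)
      stop("internal error: template is not invariant under its own relabelling map")
  }
  list(template = coords, map = map, group = group)
}

#' Built-in flower template layouts
#'
#' Ready-made templates emulating the four case-study corolla layouts:
#' \describe{
#'   \item{`"fedia"`}{bilateral symmetry `C1v`: 8 mirror landmark pairs plus
#'     5 on-axis landmarks, p = 21 (a zygomorphic corolla).}
#'   \item{`"erysimum"`}{disymmetry `C2v`: 8 full orbits of 4, p = 32 (a
#'     crucifer corolla with two perpendicular mirror axes).}
#'   \item{`"vinca"`}{rotational symmetry `C5`: one centre landmark plus two
#'     full 5-orbits, p = 11 (a pinwheel corolla).}
#'   \item{`"trillium"`}{actinomorphy `C3v`: one full 6-orbit, one on-axis
#'     3-orbit and a centre landmark, p = 10.}
#' }
#' Radii and angles are fixed, field-realistic choices; what matters for the
#' method is the orbit structure, not the exact geometry.
#'
#' @param name one of `"fedia"`, `"erysimum"`, `"vinca"`, `"trillium"`
#' @return as [make_template()]: list with `template`, `map`, `group`,
#'   plus `name` and `default_n` (the sample size used in the worked
#'   analyses: 30, except 61 for `"erysimum"` where full rank of the
#'   64-variable expanded covariance asks for more specimens than
#'   variables/2)
#' @export
flower_layout <- function(name = c("fedia", "erysimum", "vinca", "trillium")) {
  name <- match.arg(name)
  deg <- pi / 180
  out <- switch(name,
    fedia = {
      g <- symmetry_group(1L, reflection = TRUE)
      pairs <- Map(function(r, th) orbit("full", r, th * deg),
                   c(1.00, 0.95, 0.80, 0.70, 0.60, 0.50, 0.45, 0.35),
                   c(25, 60, 100, 140, 35, 75, 115, 150))
      axis <- Map(function(r) orbit("axis", r),
                  c(1.05, 0.55, 0.15, -0.35, -0.95))
      c(make_template(g, c(pairs, axis)), list(default_n = 30L))
    },
    erysimum = {
      g <- symmetry_group(2L, reflection = TRUE)
      obs <- Map(function(r, th) orbit("full", r, th * deg),
                 c(1.00, 0.90, 0.80, 0.70, 0.60, 0.50, 0.42, 0.34),
                 c(20, 40, 65, 80, 30, 55, 70, 15))
      c(make_template(g, obs), list(default_n = 61L))
    },
    vinca = {
      g <- symmetry_group(5L)
      obs <- list(orbit("centre"),
                  orbit("full", 1.00, 10 * deg),
                  orbit("full", 0.60, 38 * deg))
      c(make_template(g, obs), list(default_n = 30L))
    },
    trillium = {
      g <- symmetry_group(3L, reflection = TRUE)
      obs <- list(orbit("full", 1.00, 28 * deg),
                  orbit("axis", 0.55),
                  orbit("centre"))
      c(make_template(g, obs), list(default_n = 30L))
    })
  out$name <- name
  out
}

# run fn with a locally-seeded RNG, leaving the caller's RNG state alone
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

#' Simulate a sample of flower configurations from a template
#'
#' Each specimen is the template plus, in order: an optional deterministic
#' directional-asymmetry displacement (shared by every specimen), an
#' optional specimen-specific fluctuating-asymmetry displacement (Gaussian
#' noise with its group-symmetric part removed, so it is purely asymmetric),
#' and independent isotropic Gaussian noise of standard deviation
#' `noise_sd` on every coordinate. Noise is added in template coordinate
#' space, before any Procrustes treatment.
#'
#' @param layout a list with `template`, `map`, `group` as returned by
#'   [make_template()] or [flower_layout()]
#' @param n number of specimens (at least 2)
#' @param noise_sd isotropic landmark noise sd, in template units; the
#'   default is 2% of the template centroid size -- small enough for
#'   tangent-space linearity, large enough for full-rank covariances
#' @param seed mandatory RNG seed; the caller's RNG state is not touched
#' @param da_offset optional `p x 2` deterministic displacement
#'   (directional asymmetry when it is group-asymmetric)
#' @param fa_sd optional sd of the fluctuating-asymmetry displacement
#' @param id_prefix specimen id prefix; ids are zero-padded
#'   (`ind001, ind002, ...`) so that character-range classifiers line up
#' @return a [landmark_dataset()] of `n` configurations
#' @export
simulate_flowers <- function(layout, n, noise_sd = NULL, seed,
                             da_offset = NULL, fa_sd = NULL,
                             id_prefix = "ind") {
  if (missing(seed)) stop("an explicit 'seed' is required")
  n <- as.integer(n)
  if (n < 2L) stop("at least 2 specimens are required")
  tpl <- layout$template
  p <- nrow(tpl)
  if (is.null(noise_sd)) noise_sd <- 0.02 * centroid_size(tpl)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  base <- tpl
  if (!is.null(da_offset)) {
    da_offset <- as.matrix(da_offset)
    if (!all(dim(da_offset) == dim(tpl)))
      stop("da_offset must match the template dimensions")
    base <- base + da_offset
  }
  coords <- .with_seed(seed, function() {
    out <- array(NA_real_, c(p, 2L, n))
    for (i in seq_len(n)) {
      x <- base
      if (!is.null(fa_sd) && fa_sd > 0) {
        raw <- matrix(stats::rnorm(p * 2L, sd = fa_sd), p, 2L)
        x <- x + (raw - .symmetrise(raw, layout$group, layout$map))
      }
      out[, , i] <- x + matrix(stats::rnorm(p * 2L, sd = noise_sd), p, 2L)
    }
    out
  })
  landmark_dataset(coords, ids = sprintf("%s%03d", id_prefix, seq_len(n)))
}

#' Expand specimens into nested imaging and digitising replicates
#'
#' Emulates a measurement-error study: each specimen is re-imaged
#' `n_imaging` times and each image digitised `n_digitising` times. An
#' imaging-level Gaussian displacement is shared by all digitisings of an
#' image, and each digitising adds an independent displacement on top. Ids
#' follow the `"<id>_a1b1"` grammar and `individual` / `imaging` /
#' `digitising` classifiers are populated automatically.
#'
#' @param dataset a [landmark_dataset()] of specimens
#' @param n_imaging,n_digitising replicate counts (default 2 each)
#' @param imaging_sd,digitising_sd per-coordinate displacement sds
#' @param seed mandatory RNG seed
#' @return a [landmark_dataset()] of
#'   `n * n_imaging * n_digitising` configurations
#' @export
simulate_replicates <- function(dataset, n_imaging = 2L, n_digitising = 2L,
                                imaging_sd, digitising_sd, seed) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (missing(seed)) stop("an explicit 'seed' is required")
  if (imaging_sd < 0 || digitising_sd < 0) stop("sds must be non-negative")
  n <- n_configurations(dataset); p <- n_landmarks(dataset); d <- n_dimensions(dataset)
  nrep <- n_imaging * n_digitising
  res <- .with_seed(seed, function() {
    coords <- array(NA_real_, c(p, d, n * nrep))
    ids <- character(n * nrep)
    cls <- data.frame(individual = character(n * nrep),
                      imaging = character(n * nrep),
                      digitising = character(n * nrep))
    idx <- 0L
    for (i in seq_len(n)) {
      for (a in seq_len(n_imaging)) {
        img_shift <- matrix(stats::rnorm(p * d, sd = imaging_sd), p, d)
        for (b in seq_len(n_digitising)) {
          idx <- idx + 1L
          dig_shift <- matrix(stats::rnorm(p * d, sd = digitising_sd), p, d)
          coords[, , idx] <- dataset$coords[, , i] + img_shift + dig_shift
          ids[idx] <- sprintf("%s_a%db%d", dataset$ids[i], a, b)
          cls$individual[idx] <- dataset$ids[i]
          cls$imaging[idx] <- paste0("a", a)
          cls$digitising[idx] <- paste0("b", b)
        }
      }
    }
    list(coords = coords, ids = ids, cls = cls)
  })
  landmark_dataset(res$coords, ids = res$ids, classifiers = res$cls)
}
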