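#' Finite symmetry group (Schoenflies Cn / Cnv)
#'
#' Represents the finite symmetry groups relevant to object symmetry of
#' flowers: `Cn` (n-fold rotation only) and `Cnv` (n-fold rotation combined
#' with reflection). `C1v` is bilateral symmetry (zygomorphy), `C2v`
#' disymmetry, `C5` pure rotational symmetry of order 5, `C3v` actinomorphy
#' of order 3. Group elements are enumerated as (reflect, rotation index)
#' pairs, the identity `(FALSE, 0)` first, in the order
#' `ori_Cn00, ref_Cn00, ori_Cn01, ref_Cn01, ...` used for expanded-dataset
#' identifiers.
#'
#' @param order rotation order `n >= 1`
#' @param reflection does the group contain reflections?
#' @return an object of class `symmetry_group` with fields `order`,
#'   `reflection`, and `elements` (a data.frame with columns `reflect`, `rot`).
#' @examples
#' symmetry_group(1, reflection = TRUE)  # C1v, bilateral symmetry
#' symmetry_group(5)                     # C5, pinwheel
#' @export
symmetry_group <- function(order = 1L, reflection = FALSE) {
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("rotation order must be an integer >= 1")
  if (order == 1L && !reflection)
    stop("C1 is the trivial group; no symmetry to analyse")
  refl <- if (reflection) c(FALSE, TRUE) else FALSE
  elements <- expand.grid(reflect = refl, rot = 0:(order - 1L),
                          KEEP.OUT.ATTRS = FALSE)
  elements <- elements[, c("reflect", "rot")]
  rownames(elements) <- element_suffix(elements, reflection)
  structure(list(order = order, reflection = reflection, elements = elements),
            class = "symmetry_group")
}

# id suffixes following the ori/ref x CnXX grammar; rotation-only groups
# drop the ori/ref part (Vinca-style "ind1_Cn00")
element_suffix <- function(elements, reflection) {
  rot <- sprintf("Cn%02d", elements$rot)
  if (reflection) paste(ifelse(elements$reflect, "ref", "ori"), rot, sep = "_")
  else rot
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat(sprintf("Symmetry group %s: %d element(s)\n", format(x), nrow(x$elements)))
  cat(" ", paste(rownames(x$elements), collapse = " "), "\n")
  invisible(x)
}

#' @export
format.symmetry_group <- function(x, ...)
  sprintf("C%d%s", x$order, if (x$reflection) "v" else "")

#' Landmark relabelling map for a symmetry group
#'
#' A relabelling map records how landmark labels swap under each symmetry
#' transformation: one permutation for the reflection (an involution pairing
#' mirror-image landmarks and fixing on-axis landmarks) and one permutation
#' per successive rotation. Rotation permutations must be the successive
#' powers of the first one (cyclic consistency).
#'
#' @param p number of landmarks
#' @param reflection integer permutation of `1..p` for the reflected copy, or
#'   `NULL` for rotation-only groups
#' @param rotations integer `p x (n-1)` matrix, one column per successive
#'   rotation, or `NULL` when the rotation order is 1
#' @return an object of class `relabelling_map`
#' @export
relabelling_map <- function(p, reflection = NULL, rotations = NULL) {
  p <- as.integer(p)
  chk_perm <- function(v, what) {
    v <- as.integer(v)
    if (length(v) != p || !setequal(v, seq_len(p)))
      stop(sprintf("%s is not a permutation of 1..%d", what, p))
    v
  }
  if (!is.null(reflection)) {
    reflection <- chk_perm(unname(reflection), "reflection column")
    if (!identical(reflection[reflection], seq_len(p)))
      stop("reflection relabelling must be an involution (applying it twice must restore the labels)")
  }
  if (!is.null(rotations)) {
    rotations <- as.matrix(rotations)
    dimnames(rotations) <- NULL
    storage.mode(rotations) <- "integer"
    for (k in seq_len(ncol(rotations)))
      chk_perm(rotations[, k], sprintf("rotation column %d", k))
    gen <- rotations[, 1L]
    pw <- gen
    for (k in seq_len(ncol(rotations))[-1L]) {
      pw <- gen[pw]
      if (!identical(pw, rotations[, k]))
        stop(sprintf("rotation column %d is not the %d-th power of the first rotation (cyclic consistency violated)",
                     k, k))
    }
  }
  structure(list(p = p, reflection = reflection, rotations = rotations),
            class = "relabelling_map")
}

#' @export
print.relabelling_map <- function(x, ...) {
  cat(sprintf("Relabelling map for %d landmarks:", x$p))
  if (!is.null(x$reflection)) cat(" reflection")
  if (!is.null(x$rotations)) cat(sprintf(" + %d rotation column(s)", ncol(x$rotations)))
  cat("\n")
  invisible(x)
}

#' Read a relabelling map from a text file
#'
#' Reads whitespace-delimited integer columns of 1-based landmark indices,
#' one row per landmark (the "coFed.txt"/"coVin.txt"/"coTri.txt" convention):
#' a single reflection column for `C1v`; `n-1` rotation columns for `Cn`;
#' and `n` columns, the reflection first followed by the successive
#' rotations, for `Cnv`.
#'
#' @param path path to the map file
#' @param p number of landmarks
#' @param group the [symmetry_group()] the map belongs to
#' @return a validated [relabelling_map()]
#' @export
read_relabelling <- function(path, p, group) {
  stopifnot(inherits(group, "symmetry_group"))
  m <- as.matrix(utils::read.table(path, header = FALSE))
  n <- group$order
  expected <- (n - 1L) + as.integer(group$reflection)
  if (ncol(m) != expected)
    stop(sprintf("relabelling file has %d column(s); group %s needs %d (%s)",
                 ncol(m), format(group), expected,
                 if (group$reflection && n > 1L) "reflection first, then successive rotations"
                 else if (group$reflection) "the reflection" else "the successive rotations"))
  if (nrow(m) != p)
    stop(sprintf("relabelling file has %d rows but p = %d landmarks", nrow(m), p))
  if (group$reflection)
    relabelling_map(p, reflection = m[, 1L],
                    rotations = if (n > 1L) m[, -1L, drop = FALSE])
  else
    relabelling_map(p, rotations = m)
}

#' Write a relabelling map to a text file
#' @param map a [relabelling_map()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_relabelling <- function(map, path) {
  stopifnot(inherits(map, "relabelling_map"))
  m <- cbind(map$reflection, map$rotations)
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reflected, relabelled copy of a configuration
#'
#' Produces the reflected copy used in object-symmetry analysis: coordinates
#' are mirrored about the vertical axis (x negated) and labels of
#' mirror-image landmarks are mutually swapped, so that output landmark `i`
#' is the reflection of input landmark `reflection[i]`. On-axis landmarks
#' map onto themselves; a perfectly symmetric configuration is invariant.
#'
#' @param coords `p x d` coordinate matrix
#' @param map a [relabelling_map()] with a reflection column
#' @return `p x d` matrix of the reflected relabelled copy
#' @export
reflect_relabel <- function(coords, map) {
  stopifnot(inherits(map, "relabelling_map"))
  if (is.null(map$reflection))
    stop("the relabelling map has no reflection column")
  out <- coords[map$reflection, , drop = FALSE]
  out[, 1L] <- -out[, 1L]
  out
}

#' Rotated, relabelled copy of a configuration
#'
#' For rotational object symmetry the coordinates are copied unchanged and
#' only the labels are permuted: the rotation needed to match the copy onto
#' the original is supplied by the Procrustes superimposition itself.
#' Optionally the corresponding coordinate rotation by `2*pi*k/n` can be
#' applied as well; downstream results are identical since GPA removes
#' orientation.
#'
#' @param coords `p x d` coordinate matrix
#' @param map a [relabelling_map()] with rotation columns
#' @param k rotation index, `1 <= k <= n-1`
#' @param rotate_coords also rotate the coordinates (default `FALSE`)
#' @param order rotation order `n`, required when `rotate_coords = TRUE`
#' @return `p x d` matrix of the relabelled copy
#' @export
rotate_relabel <- function(coords, map, k, rotate_coords = FALSE, order = NULL) {
  stopifnot(inherits(map, "relabelling_map"))
  if (is.null(map$rotations)) stop("the relabelling map has no rotation columns")
  k <- as.integer(k)
  if (k < 1L || k > ncol(map$rotations))
    stop(sprintf("rotation index k = %d out of range 1..%d", k, ncol(map$rotations)))
  out <- coords[map$rotations[, k], , drop = FALSE]
  if (rotate_coords) {
    if (is.null(order)) stop("'order' is required when rotate_coords = TRUE")
    a <- 2 * pi * k / order
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
    out[, 1:2] <- out[, 1:2, drop = FALSE] %*% t(R)
  }
  out
}

# apply one group element to a configuration in template coordinate space
# (true coordinate transform + relabelling); used by the simulator and by
# symmetry checks
.apply_element <- function(coords, map, reflect, rot, order) {
  out <- coords
  if (reflect) out <- reflect_relabel(out, map)
  if (rot > 0L) out <- rotate_relabel(out, map, rot, rotate_coords = TRUE, order = order)
  out
}

# group-orbit average in template space: exactly invariant under the group
.symmetrise <- function(coords, group, map) {
  el <- group$elements
  acc <- 0
  for (j in seq_len(nrow(el)))
    acc <- acc + .apply_element(coords, map, el$reflect[j], el$rot[j], group$order)
  acc / nrow(el)
}

#' Expand a dataset with transformed relabelled copies
#'
#' For each source configuration generates one copy per symmetry-group
#' element: reflection elements get the coordinate reflection plus the
#' reflection relabelling, rotation elements get the relabelling only (the
#' rotation is supplied by the GPA), and combined elements get both. Copies
#' are ordered specimen by specimen following the element order of the group
#' and ids carry the `_ori_Cn00 / _ref_Cn00 / _ori_Cn01 ...` suffix grammar
#' (`_Cn00, _Cn01, ...` for rotation-only groups). A `copy_index` recording
#' (source, reflect, rot) is attached as the canonical record.
#'
#' @param dataset a [landmark_dataset()]
#' @param group a [symmetry_group()]
#' @param map a [relabelling_map()] consistent with `group` and the dataset
#' @param rotate_coords also apply coordinate rotations to rotation copies
#'   (default `FALSE`; results after GPA are identical)
#' @return an expanded [landmark_dataset()] with
#'   `n_configurations = n_sources * |group elements|`
#' @export
expand_dataset <- function(dataset, group, map, rotate_coords = FALSE) {
  stopifnot(inherits(dataset, "landmark_dataset"),
            inherits(group, "symmetry_group"),
            inherits(map, "relabelling_map"))
  p <- n_landmarks(dataset); d <- n_dimensions(dataset)
  if (map$p != p)
    stop(sprintf("relabelling map is for %d landmarks but the dataset has %d", map$p, p))
  if (group$reflection && is.null(map$reflection))
    stop("group ", format(group), " needs a reflection column in the relabelling map")
  if (group$order > 1L &&
      (is.null(map$rotations) || ncol(map$rotations) != group$order - 1L))
    stop("group ", format(group), " needs ", group$order - 1L,
         " rotation column(s) in the relabelling map")
  el <- group$elements
  ne <- nrow(el); n <- n_configurations(dataset)
  coords <- array(NA_real_, c(p, d, n * ne))
  ids <- character(n * ne)
  suff <- rownames(el)
  idx <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(ne)) {
      idx <- idx + 1L
      X <- dataset$coords[, , i]
      if (el$reflect[j]) X <- reflect_relabel(X, map)
      if (el$rot[j] > 0L)
        X <- rotate_relabel(X, map, el$rot[j],
                            rotate_coords = rotate_coords, order = group$order)
      coords[, , idx] <- X
      ids[idx] <- paste(dataset$ids[i], suff[j], sep = "_")
    }
  }
  copy_index <- data.frame(source = rep(seq_len(n), each = ne),
                           reflect = rep(el$reflect, n),
                           rot = rep(el$rot, n))
  out <- landmark_dataset(coords, ids = ids, copy_index = copy_index)
  attr(out, "group") <- group
  attr(out, "map") <- map
  out
}

#' Match repeated units to a reference orientation (matching symmetry)
#'
#' For physically disconnected repeated parts digitised as separate
#' configurations (e.g. left and right petals), configurations whose side
#' classifier differs from the reference level are reflected (x negated) and
#' relabelled so that all units share the orientation of the reference and
#' can enter a single joint GPA.
#'
#' @param dataset a [landmark_dataset()] with a side classifier defined
#' @param side_classifier name of the classifier holding the unit side
#' @param reference_level classifier level used as the reference orientation
#' @param map a [relabelling_map()] with a reflection column
#' @return the dataset with non-reference units reflected and relabelled
#' @export
match_units <- function(dataset, side_classifier, reference_level, map) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (is.null(dataset$classifiers) || !side_classifier %in% names(dataset$classifiers))
    stop("classifier '", side_classifier, "' is not defined on the dataset")
  side <- dataset$classifiers[[side_classifier]]
  if (!reference_level %in% side)
    stop("unknown reference level '", reference_level, "' for classifier '",
         side_classifier, "'")
  flip <- which(side != reference_level)
  for (i in flip)
    dataset$coords[, , i] <- reflect_relabel(dataset$coords[, , i], map)
  dataset
}
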