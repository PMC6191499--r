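#' Landmark dataset
#'
#' Container for a set of landmark configurations sharing the same landmark
#' count `p` and dimensionality `d`. Coordinates are stored as a `p x d x n`
#' array in digitising order, the convention used by standard morphometric
#' software: landmark order must be identical across all configurations of a
#' dataset, otherwise the Procrustes superimposition is meaningless.
#'
#' @param coords numeric `p x d x n` array (or a `p x d` matrix for a single
#'   configuration) of landmark coordinates, `d` = 2 or 3.
#' @param ids character vector of specimen identifiers, one per configuration.
#' @param scales optional numeric vector of positive scale factors (physical
#'   units per pixel), one per configuration. Stored, never applied implicitly.
#' @param classifiers optional `data.frame` of categorical variables with one
#'   row per configuration (e.g. individual, imaging, digitising).
#' @param copy_index optional `data.frame` with columns `source`, `reflect`,
#'   `rot` recording, for expanded datasets, which source specimen and which
#'   symmetry-group element each configuration corresponds to.
#' @return an object of class `landmark_dataset`.
#' @seealso [read_tps()], [expand_dataset()], [gpa()]
#' @export
landmark_dataset <- function(coords, ids = NULL, scales = NULL,
                             classifiers = NULL, copy_index = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), ncol(coords), 1L))
  if (!is.array(coords) || length(dim(coords)) != 3L)
    stop("'coords' must be a p x d x n array")
  p <- dim(coords)[1L]; d <- dim(coords)[2L]; n <- dim(coords)[3L]
  if (p < 3L) stop("at least 3 landmarks are required (p >= 3)")
  if (!d %in% c(2L, 3L)) stop("dimensionality must be 2 or 3")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (is.null(ids)) ids <- sprintf("specimen%03d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("'ids' must have one entry per configuration")
  if (!is.null(scales)) {
    scales <- rep_len(as.numeric(scales), n)
    if (any(!is.finite(scales) | scales <= 0)) stop("scale factors must be positive")
  }
  if (!is.null(classifiers)) {
    classifiers <- as.data.frame(classifiers, stringsAsFactors = FALSE)
    if (nrow(classifiers) != n)
      stop("'classifiers' must have one row per configuration")
  }
  structure(list(coords = coords, ids = ids, scales = scales,
                 classifiers = classifiers, copy_index = copy_index),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  dm <- dim(x$coords)
  cat(sprintf("Landmark dataset: %d configurations, %d landmarks in %dD\n",
              dm[3L], dm[1L], dm[2L]))
  if (!is.null(x$scales)) cat("  scale factors present (not applied)\n")
  if (!is.null(x$classifiers))
    cat("  classifiers:", paste(names(x$classifiers), collapse = ", "), "\n")
  if (!is.null(x$copy_index))
    cat(sprintf("  expanded: %d copies per source specimen\n",
                dm[3L] / length(unique(x$copy_index$source))))
  invisible(x)
}

#' Number of landmarks, dimensions, configurations
#' @param x a `landmark_dataset`
#' @return integer
#' @export
n_landmarks <- function(x) dim(x$coords)[1L]

#' @rdname n_landmarks
#' @export
n_dimensions <- function(x) dim(x$coords)[2L]

#' @rdname n_landmarks
#' @export
n_configurations <- function(x) dim(x$coords)[3L]

#' Subset a landmark dataset by configuration
#' @param x a `landmark_dataset`
#' @param i index vector of configurations to keep
#' @param ... unused
#' @export
`[.landmark_dataset` <- function(x, i, ...) {
  landmark_dataset(x$coords[, , i, drop = FALSE], ids = x$ids[i],
                   scales = if (!is.null(x$scales)) x$scales[i],
                   classifiers = if (!is.null(x$classifiers)) x$classifiers[i, , drop = FALSE],
                   copy_index = if (!is.null(x$copy_index)) x$copy_index[i, , drop = FALSE])
}

#' Flatten configurations to a rectangular matrix
#'
#' Returns an `n x (p*d)` matrix with coordinates in the flat order
#' x1, y1, x2, y2, ..., xp, yp (and x1, y1, z1, ... in 3D).
#' @param x a `landmark_dataset` or a `p x d x n` array
#' @return numeric matrix with specimen ids as row names when available
#' @export
flatten_coords <- function(x) {
  a <- if (inherits(x, "landmark_dataset")) x$coords else x
  n <- dim(a)[3L]
  m <- t(apply(a, 3L, function(m) as.vector(t(m))))
  if (n == 1L) m <- matrix(m, nrow = 1L)
  if (inherits(x, "landmark_dataset")) rownames(m) <- x$ids
  m
}

# inverse of flatten_coords for one row
.unflatten <- function(v, d) matrix(v, ncol = d, byrow = TRUE)
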