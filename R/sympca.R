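#' PCA of Procrustes tangent coordinates
#'
#' Eigenanalysis of the sample covariance matrix (divisor N-1) of the
#' tangent coordinates, with scores centred on the grand mean. Every copy of
#' an expanded dataset counts as one observation. Eigenvalues below
#' `null_tol` times the largest are treated as null dimensions: GPA of 2D
#' data removes exactly 4 degrees of freedom, so a full-rank expanded
#' dataset has `2p - 4` non-null PCs. The sign of each eigenvector is fixed
#' so its largest-magnitude loading is positive.
#'
#' @param fit a [gpa()] result
#' @param null_tol relative eigenvalue tolerance for null dimensions
#'   (default 1e-10)
#' @return an object of class `shape_pca` with fields `values`, `vectors`
#'   (columns orthonormal), `scores`, `n_nonnull`, `categories`, `pairs`,
#'   plus the copy index of the fitted dataset
#' @export
shape_pca <- function(fit, null_tol = 1e-10) {
  stopifnot(inherits(fit, "gpa_fit"))
  T <- fit$tangent
  if (nrow(T) < 2L) stop("PCA needs at least two configurations")
  Tc <- sweep(T, 2L, colMeans(T))
  eig <- eigen(stats::cov(T), symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  flip <- vapply(seq_len(ncol(vectors)), function(j) {
    v <- vectors[, j]; v[which.max(abs(v))] < 0
  }, NA)
  vectors[, flip] <- -vectors[, flip]
  scores <- Tc %*% vectors
  n_nonnull <- sum(values > null_tol * values[1L])
  rownames(scores) <- fit$ids
  structure(list(values = values, vectors = vectors, scores = scores,
                 n_nonnull = n_nonnull, null_tol = null_tol,
                 categories = rep(NA_character_, length(values)),
                 pairs = matrix(integer(0), 0L, 2L),
                 rotated_pairs = logical(0),
                 ids = fit$ids, copy_index = fit$copy_index,
                 p = fit$p, d = fit$d, consensus = fit$consensus),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d non-null PCs (of %d dimensions)\n",
              x$n_nonnull, length(x$values)))
  if (nrow(x$pairs))
    cat(sprintf("  %d equal-eigenvalue pair(s)\n", nrow(x$pairs)))
  if (!all(is.na(x$categories))) {
    tab <- table(x$categories[seq_len(x$n_nonnull)])
    for (nm in names(tab)) cat(sprintf("  %3d PC(s): %s\n", tab[[nm]], nm))
  }
  invisible(x)
}

# scores of the copies under element (reflect, rot), ordered by source,
# paired against the identity copies
.copy_scores <- function(pca, j, reflect, rot) {
  ci <- pca$copy_index
  sel <- ci$reflect == reflect & ci$rot == rot
  id0 <- ci$reflect == FALSE & ci$rot == 0L
  list(g = pca$scores[sel, j][order(ci$source[sel])],
       o = pca$scores[id0, j][order(ci$source[id0])])
}

# per-element symmetry signature of one PC: +1 if scores of the g-copies
# equal those of the originals for every specimen, -1 if they equal the
# negated scores, 0 if neither (mixed, as inside unresolved pairs)
.pc_signature <- function(pca, j, group, tol_scale = 1e-6) {
  el <- group$elements
  thr <- tol_scale * max(sqrt(pca$values[j]), max(abs(pca$scores[, j])))
  sig <- integer(nrow(el))
  sig[1L] <- 1L
  for (e in seq_len(nrow(el))[-1L]) {
    s <- .copy_scores(pca, j, el$reflect[e], el$rot[e])
    sig[e] <- if (max(abs(s$g - s$o)) <= thr) 1L
              else if (max(abs(s$g + s$o)) <= thr) -1L else 0L
  }
  names(sig) <- rownames(el)
  sig
}

# human-readable category label from a signature; an unpaired PC must be
# symmetric or antisymmetric under every element, so a mixed (0) entry marks
# it unclassified, while inside rotated pairs mixed entries are expected
.signature_label <- function(sig, group, paired = FALSE) {
  plus <- names(sig)[sig == 1L][-1L]   # drop the identity
  ne <- length(sig) - 1L
  if (length(plus) == ne) return("fully symmetric")
  if (!paired && any(sig == 0L)) return("unclassified")
  if (length(plus) == 0L) return("fully asymmetric")
  el <- group$elements[-1L, , drop = FALSE]
  rot_only <- rownames(el)[!el$reflect]
  if (group$reflection && setequal(plus, rot_only) && length(rot_only))
    return("rotation-only symmetric")
  paste0("symmetric under: ", paste(plus, collapse = ", "))
}

#' Classify principal components into symmetry categories
#'
#' For each unpaired non-null PC and each group element, compares the scores
#' of the transformed relabelled copies with those of the originals: equal
#' scores mean the PC's shape change is symmetric under that element,
#' negated scores antisymmetric. The per-element signature determines the
#' category (e.g. "fully symmetric", "fully asymmetric", "rotation-only
#' symmetric"). PCs that belong to equal-eigenvalue pairs (see
#' [detect_pairs()]) are labelled `"paired/unresolved"` until rotated with
#' [rotate_pc_pairs()]. PCs whose signature matches no symmetry pattern are
#' labelled `"unclassified"` and reported, never dropped.
#'
#' @param pca a [shape_pca()] result carrying a copy index
#' @param group the [symmetry_group()] used for the expansion
#' @param tol_scale classification tolerance as a fraction of each PC's
#'   score scale (default 1e-6; copy structure makes equality exact up to
#'   floating point)
#' @return the `shape_pca` object with `categories` (and `signatures`) filled
#' @export
classify_pcs <- function(pca, group, tol_scale = 1e-6) {
  stopifnot(inherits(pca, "shape_pca"), inherits(group, "symmetry_group"))
  if (is.null(pca$copy_index))
    stop("PC classification needs the copy index of an expanded dataset")
  paired <- rep(FALSE, length(pca$values))
  if (nrow(pca$pairs)) paired[as.vector(pca$pairs)] <- TRUE
  sigs <- vector("list", length(pca$values))
  for (j in seq_len(pca$n_nonnull)) {
    if (paired[j] && !isTRUE(pca$rotated_pairs[.pair_of(pca, j)])) {
      pca$categories[j] <- "paired/unresolved"
      next
    }
    sig <- .pc_signature(pca, j, group, tol_scale)
    sigs[[j]] <- sig
    lab <- .signature_label(sig, group, paired = paired[j])
    if (paired[j]) lab <- paste0(lab, " (pair)")
    pca$categories[j] <- lab
  }
  if (any(pca$categories[seq_len(pca$n_nonnull)] == "unclassified", na.rm = TRUE))
    warning("some PCs matched no symmetry signature and were labelled 'unclassified'")
  pca$signatures <- sigs
  pca
}

.pair_of <- function(pca, j) {
  hit <- which(pca$pairs[, 1L] == j | pca$pairs[, 2L] == j)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Detect equal-eigenvalue PC pairs
#'
#' For rotation orders above 2 the group-invariant covariance forces pairs
#' of equal eigenvalues whose eigenvector planes are rotationally
#' indeterminate. Consecutive non-null eigenvalues whose relative difference
#' is below `rel_tol` are grouped into pairs; no PC may belong to two pairs.
#' Three consecutive coincident eigenvalues signal a degenerate fixture (or
#' a tolerance that is too loose) and raise an error.
#'
#' @param pca a [shape_pca()] result
#' @param rel_tol relative eigenvalue tolerance (default 1e-6)
#' @return the `shape_pca` object with `pairs` filled
#' @export
detect_pairs <- function(pca, rel_tol = 1e-6) {
  stopifnot(inherits(pca, "shape_pca"))
  v <- pca$values[seq_len(pca$n_nonnull)]
  close <- abs(diff(v)) < rel_tol * pmax(v[-length(v)], v[-1L])
  pairs <- matrix(integer(0), 0L, 2L)
  j <- 1L
  while (j < length(v)) {
    if (close[j]) {
      if (j < length(v) - 1L && close[j + 1L])
        stop(sprintf("three consecutive eigenvalues coincide near PC%d: use a smaller rel_tol or check the fixture for degeneracy", j))
      pairs <- rbind(pairs, c(j, j + 1L))
      j <- j + 2L
    } else j <- j + 1L
  }
  pca$pairs <- pairs
  pca$rotated_pairs <- rep(FALSE, nrow(pairs))
  pca
}

#' Rotate equal-eigenvalue PC pairs to a canonical orientation
#'
#' Within each pair's eigenvector plane any orthogonal rotation is an
#' equally valid eigenbasis. The canonical choice rotates the pair so that
#' the mean score of all *unrotated* copies (rotation index 0: the original
#' configurations together with their reflected unrotated copies, when the
#' group has reflections) lies on the first axis of the pair. For groups
#' with reflections this mean is exactly invariant under the reflection and
#' therefore sits on the reflection-invariant line of the plane, so the
#' first rotated PC shows bilaterally symmetric shape changes and the second
#' totally asymmetric ones. Eigenvalues and orthonormality are untouched;
#' rotated PCs are re-classified by [classify_pcs()]. A pair whose mean
#' unrotated score vanishes has no defined direction and is left unrotated
#' with a warning.
#'
#' @param pca a [shape_pca()] result with pairs detected
#' @param group the [symmetry_group()] used for the expansion
#' @return the `shape_pca` object with rotated vectors/scores and updated
#'   categories
#' @export
rotate_pc_pairs <- function(pca, group) {
  stopifnot(inherits(pca, "shape_pca"))
  if (is.null(pca$copy_index))
    stop("pair rotation needs the copy index of an expanded dataset")
  unrot <- pca$copy_index$rot == 0L
  for (k in seq_len(nrow(pca$pairs))) {
    a <- pca$pairs[k, 1L]; b <- pca$pairs[k, 2L]
    m <- colMeans(pca$scores[unrot, c(a, b), drop = FALSE])
    nm <- sqrt(sum(m^2))
    if (nm < 1e-12 * sqrt(pca$values[a])) {
      warning(sprintf("pair (PC%d, PC%d): mean unrotated score is at the origin; pair left unrotated", a, b))
      next
    }
    u1 <- m / nm; u2 <- c(-u1[2L], u1[1L])
    G <- cbind(u1, u2)
    pca$vectors[, c(a, b)] <- pca$vectors[, c(a, b)] %*% G
    pca$scores[, c(a, b)] <- pca$scores[, c(a, b)] %*% G
    pca$rotated_pairs[k] <- TRUE
  }
  if (nrow(pca$pairs)) pca <- classify_pcs(pca, group)
  pca
}

#' Percent of variance per symmetry category
#'
#' Sums the eigenvalue shares of the non-null PCs in each symmetry category;
#' percentages sum to 100 over all categories.
#'
#' @param pca a classified [shape_pca()] result
#' @return named numeric vector of percentages
#' @export
category_variance <- function(pca) {
  stopifnot(inherits(pca, "shape_pca"))
  k <- seq_len(pca$n_nonnull)
  if (all(is.na(pca$categories[k]))) stop("classify the PCs first")
  v <- pca$values[k]
  tapply(v, pca$categories[k], sum) / sum(v) * 100
}

#' Symmetric component of an expanded, superimposed dataset
#'
#' The symmetric component of each source specimen is the average of its
#' aligned copies over all group elements: an exactly group-invariant shape,
#' the "variation among flowers" part of the decomposition.
#'
#' @param fit a [gpa()] result on an expanded dataset
#' @return a [landmark_dataset()] of one symmetrised configuration per
#'   source specimen (in the aligned/Procrustes coordinate frame)
#' @export
symmetric_component <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  ci <- fit$copy_index
  if (is.null(ci)) stop("the fit does not come from an expanded dataset")
  src <- sort(unique(ci$source))
  p <- fit$p; d <- fit$d
  out <- array(NA_real_, c(p, d, length(src)))
  for (s in seq_along(src)) {
    sel <- which(ci$source == src[s])
    out[, , s] <- apply(fit$aligned[, , sel, drop = FALSE], c(1L, 2L), mean)
  }
  base_ids <- vapply(src, function(s) {
    id <- fit$ids[which(ci$source == s & !ci$reflect & ci$rot == 0L)[1L]]
    sub("_(ori|ref)?_?Cn[0-9]+$", "", id)
  }, "")
  landmark_dataset(out, ids = paste0(base_ids, "_sym"))
}

#' Asymmetry component with respect to one symmetry operator
#'
#' For each source specimen, the difference between the aligned original
#' configuration and its aligned transformed relabelled copy under the given
#' group element: e.g. left-right asymmetry for the reflection element, or
#' adaxial-abaxial asymmetry for the second reflection of a disymmetric
#' flower. A perfectly symmetric specimen has zero asymmetry.
#'
#' @param fit a [gpa()] result on an expanded dataset
#' @param reflect,rot the group element (reflection flag and rotation index)
#' @return a `p x d x n_sources` array of landmark-wise deviations, with the
#'   source ids as an attribute
#' @export
asymmetry_component <- function(fit, reflect = TRUE, rot = 0L) {
  stopifnot(inherits(fit, "gpa_fit"))
  ci <- fit$copy_index
  if (is.null(ci)) stop("the fit does not come from an expanded dataset")
  src <- sort(unique(ci$source))
  p <- fit$p; d <- fit$d
  out <- array(NA_real_, c(p, d, length(src)))
  for (s in seq_along(src)) {
    i0 <- which(ci$source == src[s] & !ci$reflect & ci$rot == 0L)
    ig <- which(ci$source == src[s] & ci$reflect == reflect & ci$rot == rot)
    if (length(i0) != 1L || length(ig) != 1L)
      stop("missing copies for specimen ", src[s])
    out[, , s] <- fit$aligned[, , i0] - fit$aligned[, , ig]
  }
  attr(out, "ids") <- fit$ids[ci$source %in% src & !ci$reflect & ci$rot == 0L]
  out
}
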