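#' Centroid size
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid, the standard geometric measure of size.
#'
#' @param coords a `p x d` coordinate matrix
#' @return a positive number; 0 (with a warning) if all landmarks coincide
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  cs <- sqrt(sum(sweep(coords, 2L, colMeans(coords))^2))
  if (cs == 0) warning("degenerate configuration: all landmarks coincide (centroid size 0)")
  cs
}

#' @rdname centroid_size
#' @param dataset a [landmark_dataset()]
#' @return `centroid_sizes`: named numeric vector, one size per configuration
#' @export
centroid_sizes <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  out <- apply(dataset$coords, 3L, centroid_size)
  names(out) <- dataset$ids
  out
}

# optimal rotation (det +1, never a reflection) aligning centred A onto B:
# argmin_R ||A R - B||_F over rotations
.opa_rotation <- function(A, B) {
  M <- crossprod(A, B)
  sv <- svd(M)
  d <- ncol(A)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  sv$u %*% diag(c(rep(1, d - 1L), s), d) %*% t(sv$v)
}

#' Full Procrustes distance between two configurations
#'
#' Centres and scales both configurations to unit centroid size, finds the
#' optimal rotation (rotations only, no reflection) of the first onto the
#' second, and returns the square root of the remaining sum of squares.
#'
#' @param a,b `p x d` coordinate matrices with corresponding landmarks
#' @return non-negative number
#' @export
procrustes_distance <- function(a, b) {
  A <- .centre_scale(a); B <- .centre_scale(b)
  sqrt(sum((A %*% .opa_rotation(A, B) - B)^2))
}

.centre_scale <- function(x) {
  x <- sweep(as.matrix(x), 2L, colMeans(x))
  cs <- sqrt(sum(x^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  x / cs
}

#' Generalised Procrustes Analysis
#'
#' Iterative least-squares superimposition of all configurations: each is
#' centred, scaled to unit centroid size and rotated (optimal orthogonal
#' rotation *without* reflection -- reflections are explicit data operations
#' in symmetry analysis and must never be absorbed by the fit) onto the
#' current consensus; the consensus is recomputed as the normalised mean and
#' the procedure repeats until its change falls below `tol`. Optionally the
#' final consensus is aligned to its principal axes with all configurations
#' co-rotated. Aligned configurations are then projected onto the tangent
#' space orthogonal to the consensus.
#'
#' @param dataset a [landmark_dataset()] with at least two configurations
#' @param align_principal_axes rotate the final consensus to its principal
#'   axes (default `TRUE`); ties are resolved by rotating so the first
#'   landmark has non-negative x
#' @param tol convergence tolerance on the consensus change (default 1e-10)
#' @param max_iter maximum number of iterations (default 100)
#' @return an object of class `gpa_fit` with fields `consensus` (`p x d`,
#'   unit centroid size), `aligned` (`p x d x n`), `tangent` (`n x p*d`
#'   matrix in flat x1,y1,... order), `centroid_sizes` (of the raw input
#'   configurations), `iterations`, `converged`, `ids`, `copy_index`.
#' @export
gpa <- function(dataset, align_principal_axes = TRUE, tol = 1e-10,
                max_iter = 100L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_configurations(dataset)
  if (n < 2L) stop("GPA needs at least two configurations")
  p <- n_landmarks(dataset); d <- n_dimensions(dataset)
  cs <- centroid_sizes(dataset)
  if (any(cs == 0)) stop("degenerate configuration(s) with centroid size 0")
  X <- array(NA_real_, dim(dataset$coords))
  for (i in seq_len(n)) X[, , i] <- .centre_scale(dataset$coords[, , i])
  consensus <- X[, , 1L]
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% .opa_rotation(X[, , i], consensus)
    newcon <- apply(X, c(1L, 2L), mean)
    newcon <- newcon / sqrt(sum(newcon^2))
    delta <- sqrt(sum((newcon - consensus)^2))
    consensus <- newcon
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("GPA did not converge in %d iterations (last change %.3g)",
                    max_iter, delta))
  if (align_principal_axes) {
    V <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
    if (det(V) < 0) V[, d] <- -V[, d]          # rotation, not a reflection
    consensus <- consensus %*% V
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% V
    if (consensus[1L, 1L] < 0) {               # 180-degree rotation for determinism
      consensus[, 1:2] <- -consensus[, 1:2]
      X[, 1:2, ] <- -X[, 1:2, ]
    }
  }
  flat <- t(apply(X, 3L, function(m) as.vector(t(m))))
  cvec <- as.vector(t(consensus))
  tangent <- flat - tcrossprod(flat %*% cvec, cvec)  # orthogonal to consensus
  rownames(tangent) <- dataset$ids
  out <- structure(list(consensus = consensus, aligned = X, tangent = tangent,
                        centroid_sizes = cs, iterations = iter,
                        converged = converged, ids = dataset$ids,
                        copy_index = dataset$copy_index,
                        p = p, d = d),
                   class = "gpa_fit")
  attr(out, "group") <- attr(dataset, "group")
  attr(out, "map") <- attr(dataset, "map")
  out
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("Generalised Procrustes fit: %d configurations, %d landmarks in %dD\n",
              length(x$ids), x$p, x$d))
  cat(sprintf("  %d iteration(s), %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  total Procrustes SS around consensus: %.6g\n", sum(x$tangent^2)))
  invisible(x)
}

#' Export a Procrustes fit as a flat coordinate table
#'
#' @param x a [gpa()] result
#' @param row.names,optional,... ignored (S3 signature)
#' @param what `"tangent"` (default), `"aligned"`, or `"consensus"`
#' @return a data.frame with specimen ids and flat x1,y1,... columns
#' @export
as.data.frame.gpa_fit <- function(x, row.names = NULL, optional = FALSE,
                                  what = c("tangent", "aligned", "consensus"), ...) {
  what <- match.arg(what)
  m <- switch(what,
              tangent = x$tangent,
              aligned = flatten_coords(x$aligned),
              consensus = matrix(as.vector(t(x$consensus)), 1L))
  cn <- paste0(rep(c("x", "y", "z")[seq_len(x$d)], x$p),
               rep(seq_len(x$p), each = x$d))
  out <- as.data.frame(m)
  names(out) <- cn
  if (what != "consensus") out <- cbind(id = x$ids, out)
  out
}
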