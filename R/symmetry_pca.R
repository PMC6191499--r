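#' Symmetry decomposition of landmark shape variation
#'
#' The full object-symmetry pipeline in one call: the dataset of original
#' configurations is expanded with one transformed relabelled copy per
#' symmetry-group element, superimposed by a single Generalised Procrustes
#' Analysis, and the PCA of the tangent coordinates is classified into
#' symmetry categories. Equal-eigenvalue PC pairs (which arise for rotation
#' orders above 2) are detected and, by default, rotated to their canonical
#' orientation so that their shape changes become interpretable.
#'
#' @param dataset a [landmark_dataset()] of original configurations (one per
#'   specimen or replicate)
#' @param group a [symmetry_group()]
#' @param map a [relabelling_map()] consistent with `group`
#' @param align_principal_axes,tol,max_iter passed to [gpa()]
#' @param null_tol passed to [shape_pca()]
#' @param pair_tol passed to [detect_pairs()]
#' @param rotate_pairs rotate detected pairs to the canonical orientation
#'   (default `TRUE`)
#' @return an object of class `symmetry_pca` with components `expanded`
#'   (the expanded dataset), `fit` (the [gpa()] result), `pca` (the
#'   classified [shape_pca()]), `group`, `map`, and `variance`
#'   (per-category percentages)
#' @examples
#' lay <- flower_layout("vinca")
#' ds <- simulate_flowers(lay, n = 30, seed = 1)
#' fit <- symmetry_pca(ds, lay$group, lay$map)
#' fit
#' @export
symmetry_pca <- function(dataset, group, map, align_principal_axes = TRUE,
                         tol = 1e-10, max_iter = 100L, null_tol = 1e-10,
                         pair_tol = 1e-6, rotate_pairs = TRUE) {
  expanded <- expand_dataset(dataset, group, map)
  fit <- gpa(expanded, align_principal_axes = align_principal_axes,
             tol = tol, max_iter = max_iter)
  pca <- shape_pca(fit, null_tol = null_tol)
  # equal-eigenvalue pairs are forced by the group only for rotation orders
  # above 2; for lower orders every PC is a singleton
  if (group$order > 2L) pca <- detect_pairs(pca, rel_tol = pair_tol)
  pca <- classify_pcs(pca, group)
  if (rotate_pairs && nrow(pca$pairs)) pca <- rotate_pc_pairs(pca, group)
  structure(list(expanded = expanded, fit = fit, pca = pca, group = group,
                 map = map, variance = category_variance(pca),
                 call = match.call()),
            class = "symmetry_pca")
}

#' @export
print.symmetry_pca <- function(x, ...) {
  cat(sprintf("Symmetry decomposition (%s) of %d specimens, %d landmarks in %dD\n",
              format(x$group), n_configurations(x$expanded) / nrow(x$group$elements),
              x$pca$p, x$pca$d))
  cat(sprintf("Expanded dataset: %d configurations; GPA %sconverged in %d iterations\n",
              n_configurations(x$expanded),
              if (x$fit$converged) "" else "NOT ", x$fit$iterations))
  cat(sprintf("%d non-null PCs", x$pca$n_nonnull))
  if (nrow(x$pca$pairs))
    cat(sprintf(", %d equal-eigenvalue pair(s)%s", nrow(x$pca$pairs),
                if (any(x$pca$rotated_pairs)) " (rotated)" else ""))
  cat("\n\nVariance by symmetry category:\n")
  v <- sort(x$variance, decreasing = TRUE)
  tab <- table(x$pca$categories[seq_len(x$pca$n_nonnull)])
  for (nm in names(v))
    cat(sprintf("  %-45s %2d PCs  %6.2f%%\n", nm, tab[[nm]], v[[nm]]))
  invisible(x)
}

#' @export
summary.symmetry_pca <- function(object, n_pcs = 10L, ...) {
  print(object)
  cat("\nLeading eigenvalues:\n")
  et <- eigen_table(object)
  print(utils::head(et, n_pcs), row.names = FALSE, digits = 4)
  invisible(et)
}

#' Eigenvalue / category table of a symmetry decomposition
#'
#' @param x a [symmetry_pca()] result
#' @return a data.frame with one row per non-null PC: eigenvalue, percent of
#'   total variance, symmetry category, and pair membership
#' @export
eigen_table <- function(x) {
  stopifnot(inherits(x, "symmetry_pca"))
  k <- seq_len(x$pca$n_nonnull)
  pair_id <- rep(NA_integer_, length(k))
  for (r in seq_len(nrow(x$pca$pairs))) pair_id[x$pca$pairs[r, ]] <- r
  data.frame(PC = k, eigenvalue = x$pca$values[k],
             percent = x$pca$values[k] / sum(x$pca$values[k]) * 100,
             category = x$pca$categories[k], pair = pair_id)
}

#' PC scores of a symmetry decomposition
#' @param x a [symmetry_pca()] result
#' @param pcs which PCs to return (default all non-null)
#' @return matrix of scores (rows = expanded configurations) with the copy
#'   index bound as attributes
#' @export
pc_scores <- function(x, pcs = NULL) {
  stopifnot(inherits(x, "symmetry_pca"))
  if (is.null(pcs)) pcs <- seq_len(x$pca$n_nonnull)
  s <- x$pca$scores[, pcs, drop = FALSE]
  colnames(s) <- paste0("PC", pcs)
  attr(s, "copy_index") <- x$pca$copy_index
  s
}

#' Plot a symmetry decomposition
#'
#' `type = "scree"` draws the eigenvalue profile coloured by symmetry
#' category; `type = "shape"` draws the consensus with displacement arrows
#' for one PC (a simple landmark-displacement plot); `type = "scores"`
#' scatters two PCs, colouring copies by group element -- for paired PCs the
#' point cloud itself shows the symmetry of the group.
#'
#' @param x a [symmetry_pca()] result
#' @param type one of `"scree"`, `"shape"`, `"scores"`
#' @param pc PC to display for `type = "shape"`
#' @param pcs two PCs for `type = "scores"` (default `c(1, 2)`)
#' @param magnitude score magnitude for the displacement arrows (default
#'   0.1, the conventional display value)
#' @param ... passed to the underlying plot
#' @return invisibly, `x`
#' @export
plot.symmetry_pca <- function(x, type = c("scree", "shape", "scores"),
                              pc = 1L, pcs = c(1L, 2L), magnitude = 0.1, ...) {
  type <- match.arg(type)
  k <- seq_len(x$pca$n_nonnull)
  if (type == "scree") {
    cats <- factor(x$pca$categories[k])
    graphics::barplot(x$pca$values[k] / sum(x$pca$values[k]) * 100,
                      names.arg = k, col = as.integer(cats) + 1L,
                      xlab = "PC", ylab = "% of total variance", ...)
    graphics::legend("topright", legend = levels(cats),
                     fill = seq_along(levels(cats)) + 1L, bty = "n", cex = 0.8)
  } else if (type == "shape") {
    cons <- x$fit$consensus
    v <- .unflatten(x$pca$vectors[, pc], x$pca$d) * magnitude
    graphics::plot(cons, asp = 1, pch = 19, xlab = "x", ylab = "y",
                   main = sprintf("PC%d (%s)", pc, x$pca$categories[pc]), ...)
    graphics::arrows(cons[, 1L], cons[, 2L], cons[, 1L] + v[, 1L],
                     cons[, 2L] + v[, 2L], length = 0.05, col = "red3")
  } else {
    s <- x$pca$scores[, pcs]
    ci <- x$pca$copy_index
    elt <- factor(paste0(ifelse(ci$reflect, "ref_", "ori_"),
                         sprintf("Cn%02d", ci$rot)))
    graphics::plot(s, col = as.integer(elt) + 1L, pch = 19, asp = 1,
                   xlab = paste0("PC", pcs[1L]), ylab = paste0("PC", pcs[2L]), ...)
    graphics::legend("topright", legend = levels(elt),
                     col = seq_along(levels(elt)) + 1L, pch = 19, bty = "n", cex = 0.8)
  }
  invisible(x)
}
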