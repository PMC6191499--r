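# balanced one-way nested sums of squares for a multivariate response:
# individual, imaging within individual, digitising within imaging
.nested_ss <- function(Y, individual, imaging, digitising) {
  Y <- as.matrix(Y)
  individual <- as.character(individual)
  imaging <- as.character(imaging)
  digitising <- as.character(digitising)
  n <- nrow(Y)
  if (length(individual) != n || length(imaging) != n || length(digitising) != n)
    stop("classifier length does not match the number of observations")
  ind <- individual
  img <- paste(individual, imaging, sep = "\r")
  dig <- paste(img, digitising, sep = "\r")
  n_ind <- length(unique(ind))
  n_img <- length(unique(img)) / n_ind
  n_dig <- length(unique(dig)) / (n_ind * n_img)
  balanced <- n_img == round(n_img) && n_dig == round(n_dig) &&
    all(table(ind) == n_img * n_dig) && all(table(img) == n_dig) &&
    all(table(dig) == 1L)
  if (!balanced)
    stop("unbalanced design: every individual needs the same number of imaging sessions and every image the same number of digitisings, with one observation per cell")
  grand <- colMeans(Y)
  mean_by <- function(f) {
    m <- rowsum(Y, f) / as.vector(table(f))
    m[f, , drop = FALSE]
  }
  M_ind <- mean_by(ind); M_img <- mean_by(img)
  ss_ind <- sum(sweep(M_ind, 2L, grand)^2)
  ss_img <- sum((M_img - M_ind)^2)
  ss_dig <- sum((Y - M_img)^2)
  list(ss = c(ss_ind, ss_img, ss_dig),
       n_ind = n_ind, n_img = as.integer(n_img), n_dig = as.integer(n_dig),
       ss_total = sum(sweep(Y, 2L, grand)^2))
}

.anova_table <- function(ns, s) {
  df <- c(individual = (ns$n_ind - 1L) * s,
          imaging = ns$n_ind * (ns$n_img - 1L) * s,
          digitising = ns$n_ind * ns$n_img * (ns$n_dig - 1L) * s)
  ms <- ns$ss / df
  f <- c(ms[1L] / ms[2L], ms[2L] / ms[3L], NA)
  p <- c(stats::pf(f[1L], df[1L], df[2L], lower.tail = FALSE),
         stats::pf(f[2L], df[2L], df[3L], lower.tail = FALSE), NA)
  out <- data.frame(effect = c("Individual", "Imaging", "Digitising"),
                    SS = ns$ss, MS = ms, df = df, F = f, P = p,
                    row.names = NULL)
  attr(out, "ss_total") <- ns$ss_total
  class(out) <- c("procrustes_anova_table", "data.frame")
  out
}

#' @export
print.procrustes_anova_table <- function(x, ...) {
  cat("Effect        SS             MS             df      F        P\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-12s  %-13.8g  %-13.10g  %-6d  %-7s  %s\n",
                x$effect[i], x$SS[i], x$MS[i], x$df[i],
                if (is.na(x$F[i])) "" else sprintf("%.2f", x$F[i]),
                if (is.na(x$P[i])) "" else if (x$P[i] < 1e-4) "<0.0001"
                else sprintf("%.4f", x$P[i])))
  invisible(x)
}

#' Procrustes ANOVA for measurement error (shape)
#'
#' One-way nested analysis of variance of the Procrustes tangent
#' coordinates for a balanced individuals / imaging / digitising design,
#' testing the biological variation among specimens directly against the
#' measurement error due to imaging and to digitising. Sums of squares are
#' summed over all `p*d` coordinates and degrees of freedom are scaled by
#' the shape-space dimension `s = p*d - d - d*(d-1)/2 - 1` (`2p - 4` in 2D).
#' F is the Goodall-style ratio of the mean squares of adjacent nested
#' levels, with P from the F distribution on the corresponding df.
#'
#' The analysis is meant for a GPA of the original (non-expanded)
#' configurations; expanded datasets live in reduced-dimension subspaces
#' with different shape dimensions per component.
#'
#' @param fit a [gpa()] result on the original configurations
#' @param individual,imaging,digitising classifier vectors (or names of
#'   classifiers attached to `fit` -- not supported here, pass vectors)
#' @return a `procrustes_anova_table` data.frame with SS, MS, df, F, P
#' @export
procrustes_anova <- function(fit, individual, imaging, digitising) {
  stopifnot(inherits(fit, "gpa_fit"))
  ns <- .nested_ss(fit$tangent, individual, imaging, digitising)
  s <- fit$p * fit$d - fit$d - (fit$d * (fit$d - 1L)) %/% 2L - 1L
  .anova_table(ns, s)
}

#' Nested ANOVA for centroid size
#'
#' Univariate one-way nested ANOVA of centroid size for the same balanced
#' individuals / imaging / digitising design as [procrustes_anova()].
#'
#' @param sizes numeric vector of centroid sizes (e.g.
#'   `centroid_sizes(dataset)` or `fit$centroid_sizes`)
#' @param individual,imaging,digitising classifier vectors
#' @return a `procrustes_anova_table` data.frame
#' @export
centroid_size_anova <- function(sizes, individual, imaging, digitising) {
  ns <- .nested_ss(matrix(as.numeric(sizes), ncol = 1L),
                   individual, imaging, digitising)
  .anova_table(ns, 1L)
}

#' Multivariate regression of shape on size (allometry)
#'
#' Least-squares regression of the shape variables (tangent coordinates or
#' a symmetric/asymmetric component) onto centroid size or its logarithm,
#' with the percentage of shape variation predicted by size and a
#' permutation test of its significance: sizes are randomly permuted
#' against shapes and the p-value is the plus-one-corrected proportion of
#' permutations whose predicted sum of squares reaches the observed one.
#'
#' @param shape numeric matrix of shape variables, one row per specimen
#' @param sizes numeric vector of centroid sizes, one per specimen
#' @param use_log regress on log centroid size (default `TRUE`)
#' @param n_perm number of permutation rounds (default 999)
#' @param seed mandatory RNG seed for the permutations
#' @return a list with `percent_predicted`, `p_value`, `n_perm`, and the
#'   regression coefficient matrix `coefficients`
#' @export
allometry <- function(shape, sizes, use_log = TRUE, n_perm = 999L, seed) {
  if (missing(seed)) stop("an explicit 'seed' is required for the permutation test")
  shape <- as.matrix(shape)
  sizes <- as.numeric(sizes)
  if (length(sizes) != nrow(shape))
    stop("one size value per specimen is required")
  if (n_perm < 1L) stop("n_perm must be at least 1")
  x <- if (use_log) log(sizes) else sizes
  if (stats::sd(x) == 0) stop("size vector is constant; regression undefined")
  xc <- x - mean(x)
  Yc <- sweep(shape, 2L, colMeans(shape))
  sxx <- sum(xc^2)
  beta <- drop(crossprod(Yc, xc)) / sxx
  ss_pred <- sum(beta^2) * sxx
  ss_tot <- sum(Yc^2)
  perm_ss <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    vapply(seq_len(n_perm), function(b) {
      xp <- sample(xc)
      sum(drop(crossprod(Yc, xp))^2) / sxx
    }, 0)
  })
  list(percent_predicted = 100 * ss_pred / ss_tot,
       p_value = (1 + sum(perm_ss >= ss_pred)) / (n_perm + 1),
       n_perm = n_perm,
       coefficients = beta)
}
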