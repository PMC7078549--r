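## Dynamics similarity between structures: mode covariances reduced to the
## aligned core, compared pairwise with the Bhattacharyya coefficient.

#' Mode covariance of the aligned core, in a common frame
#'
#' Takes the full internal-mode covariance `sum v v^T / lambda`, rotates it
#' into a common superposition frame (covariances transform as
#' `(I (x) R) C (I (x) R)^T` under a rigid rotation R of the structure),
#' and marginalizes to the core atoms by sub-block selection.
#'
#' @param modes `ModeSet` of one structure.
#' @param core_idx integer vector of that structure's core residue indices.
#' @param rotation optional 3 x 3 rotation into the common frame (e.g. from
#'   [superimpose()] against the reference structure); identity if NULL.
#' @param id label for the structure.
#' @return object of class `CoreCovariance`: list with `id`, `n` (core
#'   columns) and `sigma` (3n x 3n symmetric PSD matrix).
#' @export
core_covariance <- function(modes, core_idx, rotation = NULL, id = "") {
  if (length(core_idx) == 0L) stop("empty core", call. = FALSE)
  if (any(core_idx < 1 | core_idx > modes$n))
    stop("core indices out of range", call. = FALSE)
  cv <- mode_covariance(modes)
  if (!is.null(rotation)) {
    G <- kronecker(diag(modes$n), rotation)
    cv <- G %*% cv %*% t(G)
  }
  sel <- as.vector(t(outer(core_idx, 1:3, function(i, a) 3 * (i - 1) + a)))
  sigma <- cv[sel, sel, drop = FALSE]
  sigma <- (sigma + t(sigma)) / 2
  structure(list(id = id, n = length(core_idx), sigma = sigma),
            class = "CoreCovariance")
}

logdet_sym <- function(m) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("matrix not positive definite in log-determinant",
                         call. = FALSE)
  sum(log(ev))
}

#' Bhattacharyya coefficient between two core covariances
#'
#' BC between the zero-mean Gaussians defined by covariances A and B:
#' `det(A)^{1/4} det(B)^{1/4} / det((A+B)/2)^{1/2}`, evaluated in the
#' principal subspace of `(A+B)/2` retaining `variance_fraction` of its
#' variance. The projection regularizes the determinant form, which is
#' degenerate for rank-deficient covariances; absolute BC values therefore
#' depend on the retained fraction, while the induced clustering topology
#' is the robust comparison surface.
#'
#' @param A,B `CoreCovariance` objects (or plain matrices) on the same core.
#' @param variance_fraction fraction of the mean-covariance variance kept
#'   in the projection subspace (default 0.95).
#' @return list with `bc` (score in (0, 1]) and `dim` (subspace dimension).
#' @export
bc_score <- function(A, B, variance_fraction = 0.95) {
  a <- if (inherits(A, "CoreCovariance")) A$sigma else as.matrix(A)
  b <- if (inherits(B, "CoreCovariance")) B$sigma else as.matrix(B)
  if (!all(dim(a) == dim(b)))
    stop("covariance dimensions differ: ", nrow(a), " vs ", nrow(b),
         call. = FALSE)
  a <- (a + t(a)) / 2; b <- (b + t(b)) / 2
  tol <- 1e-8 * max(abs(diag(a)), abs(diag(b)), 1)
  if (min(eigen(a, symmetric = TRUE, only.values = TRUE)$values) < -tol ||
      min(eigen(b, symmetric = TRUE, only.values = TRUE)$values) < -tol)
    stop("covariance input is not positive semi-definite", call. = FALSE)
  s <- (a + b) / 2
  es <- eigen(s, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  cum <- cumsum(ev) / sum(ev)
  k <- max(1L, which(cum >= variance_fraction)[1])
  U <- es$vectors[, seq_len(k), drop = FALSE]
  ap <- t(U) %*% a %*% U
  bp <- t(U) %*% b %*% U
  sp <- (ap + bp) / 2
  bc <- exp(0.25 * logdet_sym(ap) + 0.25 * logdet_sym(bp) -
              0.5 * logdet_sym(sp))
  list(bc = min(bc, 1), dim = k)
}

#' Pairwise Bhattacharyya similarity matrix
#'
#' All-pairs [bc_score()] over a list of core covariances, with clustering
#' of the distance `1 - BC` and optional heatmap/dendrogram artifacts.
#'
#' @param covs named list of `CoreCovariance`s on the same core.
#' @param variance_fraction passed to [bc_score()].
#' @param heatmap_file,newick_file optional artifact paths.
#' @return object of class `BCMatrix`: list with `labels`, `matrix` (BC
#'   scores, unit diagonal), `dims` (subspace dimension per pair),
#'   `cluster` (from [cluster_distances()] on 1 - BC).
#' @export
bc_matrix <- function(covs, variance_fraction = 0.95,
                      heatmap_file = NULL, newick_file = NULL) {
  if (is.null(names(covs)))
    names(covs) <- vapply(covs, function(x) x$id, "")
  nms <- names(covs)
  n <- length(covs)
  m <- matrix(1, n, n, dimnames = list(nms, nms))
  dims <- matrix(NA_integer_, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sc <- bc_score(covs[[i]], covs[[j]], variance_fraction)
    m[i, j] <- m[j, i] <- sc$bc
    dims[i, j] <- dims[j, i] <- sc$dim
  }
  cl <- cluster_distances(1 - m, heatmap_file = NULL,
                          newick_file = newick_file)
  if (!is.null(heatmap_file) && n > 1) {
    pheatmap::pheatmap(m, cluster_rows = cl$hclust, cluster_cols = cl$hclust,
                       filename = heatmap_file, silent = TRUE)
  }
  structure(list(labels = nms, matrix = m, dims = dims, cluster = cl),
            class = "BCMatrix")
}

#' @export
print.BCMatrix <- function(x, ...) {
  cat("BCMatrix over", length(x$labels), "structures\n")
  print(round(x$matrix, 4))
  invisible(x)
}
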