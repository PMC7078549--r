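#' @keywords internal
"_PACKAGE"

## Coordinate vectors are stored node-major: node i occupies components
## (3i-2, 3i-1, 3i) of a length-3N vector, matching the Hessian layout.

vec_to_xyz <- function(v) {
  stopifnot(length(v) %% 3 == 0)
  matrix(v, ncol = 3, byrow = TRUE)
}

xyz_to_vec <- function(x) as.vector(t(x))

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are deterministic per seed without clobbering
#' the session stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## van der Waals radii (A) used for clash and tunnel free-space tests.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `reference`
#' over a point correspondence, with the reflection branch excluded.
#'
#' @param mobile n x 3 coordinate matrix (A).
#' @param reference n x 3 coordinate matrix (A).
#' @param correspondence optional 2-column integer matrix of
#'   (mobile index, reference index) pairs; default pairs rows 1:1.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (A) and `fitted` (transformed mobile points over the correspondence).
#'   The transform acts as `x %*% t(rotation) + translation`.
#' @export
superimpose <- function(mobile, reference, correspondence = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(correspondence)) {
    n <- min(nrow(mobile), nrow(reference))
    correspondence <- cbind(seq_len(n), seq_len(n))
  }
  correspondence <- as.matrix(correspondence)
  P <- mobile[correspondence[, 1], , drop = FALSE]
  Q <- reference[correspondence[, 2], , drop = FALSE]
  n <- nrow(P)
  if (n < 3L)
    stop("superimpose needs at least 3 corresponding points, got ", n,
         call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  sv_p <- svd(P0)$d; sv_q <- svd(Q0)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1) || sv_q[2] < 1e-8 * max(sv_q[1], 1))
    stop("degenerate (collinear) point set: rigid fit is underdetermined",
         call. = FALSE)
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cq - as.vector(R %*% cp)
  fitted <- P %*% t(R) + matrix(tr, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, fitted = fitted)
}

#' Apply a rigid transform returned by [superimpose()]
#' @param xyz n x 3 matrix.
#' @param transform list with `rotation` and `translation`.
#' @export
apply_transform <- function(xyz, transform) {
  xyz <- as.matrix(xyz)
  xyz %*% t(transform$rotation) +
    matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Root-mean-square deviation between two coordinate sets (no fitting)
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}
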