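## Calpha elastic network with a distance-dependent force constant,
## normal modes, fluctuation profiles and cross-correlation maps.
##
## Node coordinates are kept in Angstrom; distances entering the force
## constant law and the energy are converted to nm at evaluation time, so
## force constants are in kJ mol-1 nm-2 and eigenvalues in the same units.

#' Force-field constants of the Calpha pair potential
#'
#' The spring constant between two Calpha nodes depends on their
#' equilibrium separation r0 (nm): `a*r0 - b` for close pairs
#' (r0 < d, roughly bonded neighbours) and `c*r0^-6` beyond.
#'
#' @param a slope of the short-range branch, kJ mol-1 nm-3.
#' @param b intercept of the short-range branch, kJ mol-1 nm-2.
#' @param c prefactor of the long-range r^-6 branch, kJ mol-1 nm4.
#' @param d branch-switch distance, nm.
#' @export
enm_constants <- function(a = 8.6e5, b = 2.39e5, c = 128, d = 0.4) {
  list(a = a, b = b, c = c, d = d)
}

#' Pairwise force constant of the Calpha force field
#'
#' @param r0 equilibrium distance(s) in nm; must be > 0.
#' @param constants list from [enm_constants()].
#' @return force constant(s), kJ mol-1 nm-2. The short-range branch is
#'   clamped at zero (with a warning) where `a*r0 - b` would be negative.
#' @export
pair_force_constant <- function(r0, constants = enm_constants()) {
  if (any(r0 <= 0)) stop("r0 must be positive (nm)", call. = FALSE)
  k <- ifelse(r0 < constants$d,
              constants$a * r0 - constants$b,
              constants$c * r0^(-6))
  if (any(k < 0)) {
    warning(sum(k < 0), " pair(s) below the zero of the short-range branch; ",
            "force constant clamped at 0", call. = FALSE)
    k[k < 0] <- 0
  }
  k
}

#' Build the Calpha elastic network
#'
#' Connects every node pair by a Hookean spring whose constant follows
#' [pair_force_constant()]; the r^-6 branch makes distant pairs negligibly
#' stiff, so no cutoff is needed for correctness. An optional hard cutoff
#' (nm) drops pairs beyond it for speed; at 4.0 nm the six lowest internal
#' eigenvalues of compact domain-sized structures change by well under 1%
#' (~0.01% measured on ~120-residue synthetic sandwich folds), while
#' tighter cutoffs soften the low-frequency spectrum noticeably (~0.8% at
#' 3.5 nm, 2-3% at 2.5-3.0 nm).
#'
#' @param xyz N x 3 node coordinates (A): Calpha positions, optionally with
#'   cofactor beads appended via [with_cofactor_nodes()].
#' @param cutoff optional interaction cutoff in nm (default: none).
#' @param constants list from [enm_constants()].
#' @return object of class `ElasticNetwork`: list with `xyz` (A), `springs`
#'   (data.frame i, j, r0 (nm), k), `constants`, `n`.
#' @export
build_network <- function(xyz, cutoff = NULL, constants = enm_constants()) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (!all(is.finite(xyz))) stop("non-finite node coordinates", call. = FALSE)
  n <- nrow(xyz)
  d_ang <- as.matrix(stats::dist(xyz))
  ut <- which(upper.tri(d_ang), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  r0 <- d_ang[ut] / 10  # A -> nm
  if (any(r0 < 1e-6))
    stop("coincident nodes (pair distance < 1e-6 nm)", call. = FALSE)
  if (!is.null(cutoff)) {
    keep <- r0 <= cutoff
    i <- i[keep]; j <- j[keep]; r0 <- r0[keep]
  }
  k <- pair_force_constant(r0, constants)
  structure(list(xyz = xyz, n = n,
                 springs = data.frame(i = i, j = j, r0 = r0, k = k),
                 constants = constants),
            class = "ElasticNetwork")
}

#' @export
print.ElasticNetwork <- function(x, ...) {
  cat("ElasticNetwork:", x$n, "nodes,", nrow(x$springs), "springs\n")
  invisible(x)
}

#' Elastic energy of a configuration
#'
#' Total network energy `V = sum k/2 (|rij| - rij0)^2` evaluated at the
#' given coordinates (A); distances are converted to nm, so the value is in
#' kJ mol-1.
#' @param network `ElasticNetwork`.
#' @param xyz N x 3 coordinates (A); defaults to the equilibrium positions.
#' @export
network_energy <- function(network, xyz = network$xyz) {
  xyz <- as.matrix(xyz)
  s <- network$springs
  dv <- xyz[s$j, , drop = FALSE] - xyz[s$i, , drop = FALSE]
  d <- sqrt(rowSums(dv^2)) / 10
  sum(s$k / 2 * (d - s$r0)^2)
}

#' Gradient of the elastic energy
#'
#' @return length-3N vector, kJ mol-1 per Angstrom of node displacement.
#' @keywords internal
network_energy_gradient <- function(network, xyz = network$xyz) {
  xyz <- as.matrix(xyz)
  s <- network$springs
  dv <- xyz[s$j, , drop = FALSE] - xyz[s$i, , drop = FALSE]
  d_ang <- sqrt(rowSums(dv^2))
  d <- d_ang / 10
  ## dV/dd = k (d - r0) [per nm]; per A = /10; direction unit vector
  f <- s$k * (d - s$r0) / 10 / d_ang
  g <- matrix(0, network$n, 3)
  contrib <- dv * f
  for (a in 1:3) {
    g[, a] <- tapply_sum(contrib[, a], s$j, network$n) -
      tapply_sum(contrib[, a], s$i, network$n)
  }
  xyz_to_vec(g)
}

tapply_sum <- function(x, index, n) {
  out <- numeric(n)
  s <- tapply(x, index, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Hessian of the elastic network at equilibrium
#'
#' Second derivative of the network energy at the equilibrium
#' configuration: for each spring the off-diagonal 3 x 3 block is
#' `-k u u^T` with `u` the unit equilibrium direction, and diagonal blocks
#' accumulate the opposite so block row sums vanish.
#'
#' @param network `ElasticNetwork`.
#' @return symmetric 3N x 3N matrix, kJ mol-1 nm-2.
#' @export
enm_hessian <- function(network) {
  n <- network$n
  xyz <- network$xyz
  s <- network$springs
  H <- matrix(0, 3 * n, 3 * n)
  dv <- xyz[s$j, , drop = FALSE] - xyz[s$i, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  u <- dv / d
  for (p in seq_len(nrow(s))) {
    K <- s$k[p] * tcrossprod(u[p, ])
    bi <- (3 * (s$i[p] - 1) + 1):(3 * s$i[p])
    bj <- (3 * (s$j[p] - 1) + 1):(3 * s$j[p])
    H[bi, bj] <- H[bi, bj] - K
    H[bj, bi] <- H[bj, bi] - K
    H[bi, bi] <- H[bi, bi] + K
    H[bj, bj] <- H[bj, bj] + K
  }
  H
}

#' Normal modes of the elastic network
#'
#' Dense symmetric eigendecomposition of the Hessian with uniform unit
#' masses. Eigenvalues are returned in ascending order; the six rigid-body
#' modes of a connected network are identified by magnitude (eigenvalue
#' below `rigid_tol` times the largest) and flagged as trivial.
#'
#' @param network `ElasticNetwork`.
#' @param rigid_tol relative tolerance for rigid modes (default 1e-6).
#' @return object of class `ModeSet`: `values` (ascending, length 3N),
#'   `vectors` (3N x 3N, orthonormal columns), `n` nodes, `trivial` count
#'   (6 for a connected non-collinear network).
#' @export
compute_modes <- function(network, rigid_tol = 1e-6) {
  comp <- network_components(network)
  if (max(comp) > 1L)
    stop("network is disconnected (", max(comp), " components); ",
         "component sizes: ", paste(tabulate(comp), collapse = ", "),
         call. = FALSE)
  H <- enm_hessian(network)
  e <- eigen(H, symmetric = TRUE)
  ord <- rev(seq_along(e$values))
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  ## rigid-body count from geometry: 6 for non-collinear node sets,
  ## 5 for collinear ones (no rotation about the axis)
  sv <- svd(sweep(network$xyz, 2, colMeans(network$xyz)))$d
  ntriv <- if (sv[2] < 1e-8 * max(sv[1], 1)) 5L else 6L
  if (values[ntriv] > rigid_tol * max(values))
    stop("expected ", ntriv, " rigid-body modes but eigenvalue ", ntriv,
         " is not numerically zero (", format(values[ntriv]), ")",
         call. = FALSE)
  ## separator between the rigid block and the softest internal mode
  tol <- sqrt(max(values[ntriv], 1e-300) * values[ntriv + 1])
  structure(list(values = values, vectors = vectors,
                 n = network$n, trivial = ntriv, rigid_tol = tol),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat("ModeSet:", x$n, "nodes,", length(x$values), "modes,",
      x$trivial, "trivial; lowest internal eigenvalue",
      format(x$values[x$trivial + 1], digits = 4), "\n")
  invisible(x)
}

network_components <- function(network) {
  n <- network$n
  s <- network$springs[network$springs$k > 0, , drop = FALSE]
  comp <- integer(n); cur <- 0L
  adj <- vector("list", n)
  for (p in seq_len(nrow(s))) {
    adj[[s$i[p]]] <- c(adj[[s$i[p]]], s$j[p])
    adj[[s$j[p]]] <- c(adj[[s$j[p]]], s$i[p])
  }
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cur <- cur + 1L
      queue <- v; comp[v] <- cur
      while (length(queue)) {
        u <- queue[[1]]; queue <- queue[-1]
        nb <- adj[[u]]
        new <- nb[comp[nb] == 0L]
        comp[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  comp
}

#' Per-node displacement blocks of a mode
#' @keywords internal
mode_displacements <- function(modes, m) {
  vec_to_xyz(modes$vectors[, m])
}

#' Covariance implied by the internal (non-trivial) modes
#'
#' `C = sum_{m > 6} v_m v_m^T / lambda_m`, the pseudo-inverse of the
#' Hessian restricted to internal motion.
#' @param modes `ModeSet`.
#' @return 3N x 3N matrix.
#' @export
mode_covariance <- function(modes) {
  nt <- (modes$trivial + 1L):length(modes$values)
  V <- modes$vectors[, nt, drop = FALSE]
  lam <- modes$values[nt]
  if (any(lam <= modes$rigid_tol))
    stop("non-positive eigenvalue among internal modes", call. = FALSE)
  V %*% (t(V) / lam)
}

#' Normalized per-residue fluctuations
#'
#' `F_i = sum_{m=7}^{3N} ||d_mi||^2 / lambda_m`, the positional variance of
#' node i summed over internal modes weighted by inverse eigenvalue, then
#' normalized (default: divided by the mean so the profile averages 1).
#'
#' @param modes `ModeSet`.
#' @param normalize "mean" (default) or "none".
#' @return object of class `FluctuationProfile`: list with `fluctuations`
#'   (normalized), `raw`, `normalization` (the constant divided out).
#' @export
fluctuations <- function(modes, normalize = c("mean", "none")) {
  normalize <- match.arg(normalize)
  nt <- (modes$trivial + 1L):length(modes$values)
  lam <- modes$values[nt]
  if (any(lam <= modes$rigid_tol))
    stop("non-positive eigenvalue among internal modes (disconnected network?)",
         call. = FALSE)
  V <- modes$vectors[, nt, drop = FALSE]
  sq <- V^2 / rep(lam, each = nrow(V))
  per_comp <- rowSums(sq)
  raw <- per_comp[seq(1, 3 * modes$n, 3)] +
    per_comp[seq(2, 3 * modes$n, 3)] +
    per_comp[seq(3, 3 * modes$n, 3)]
  const <- if (normalize == "mean") mean(raw) else 1
  structure(list(fluctuations = raw / const, raw = raw,
                 normalization = const), class = "FluctuationProfile")
}

#' Cross-correlation map of node displacements
#'
#' `C_ij = sum_m (v_mi . v_mj) / lambda_m / sqrt(F_i F_j)` over internal
#' modes, with the unnormalized fluctuations in the denominator; +1 is
#' fully correlated motion, -1 fully anti-correlated.
#'
#' @param modes `ModeSet`.
#' @return object of class `CorrelationMap`: N x N symmetric matrix in
#'   `$map` with unit diagonal.
#' @export
correlations <- function(modes) {
  cov3 <- mode_covariance(modes)
  n <- modes$n
  idx <- function(a) seq(a, 3 * n, 3)
  num <- cov3[idx(1), idx(1)] + cov3[idx(2), idx(2)] + cov3[idx(3), idx(3)]
  f <- diag(num)
  cmap <- num / sqrt(outer(f, f))
  cmap <- (cmap + t(cmap)) / 2
  structure(list(map = cmap), class = "CorrelationMap")
}

#' Block summaries of a correlation map
#'
#' Summarises coupling within and between residue blocks (e.g. the two
#' dynamical domains either side of the beta4/beta5 split): per block pair,
#' the maximum absolute and mean off-diagonal correlation.
#'
#' @param cmap `CorrelationMap` (or plain matrix).
#' @param blocks named list of integer vectors of residue indices.
#' @return data.frame with columns block_a, block_b, max_abs_c, mean_c.
#' @export
domain_blocks <- function(cmap, blocks) {
  m <- if (inherits(cmap, "CorrelationMap")) cmap$map else as.matrix(cmap)
  n <- nrow(m)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  for (b in blocks) {
    if (length(b) == 0L) stop("empty block", call. = FALSE)
    if (any(b < 1 | b > n)) stop("block indices out of range", call. = FALSE)
  }
  all_idx <- unlist(blocks)
  if (anyDuplicated(all_idx)) stop("overlapping blocks", call. = FALSE)
  out <- NULL
  nb <- names(blocks)
  for (ai in seq_along(blocks)) for (bi in ai:length(blocks)) {
    sub <- m[blocks[[ai]], blocks[[bi]], drop = FALSE]
    if (ai == bi) {
      off <- sub[row(sub) != col(sub)]
      if (length(off) == 0L) off <- 0
    } else off <- as.vector(sub)
    out <- rbind(out, data.frame(block_a = nb[ai], block_b = nb[bi],
                                 max_abs_c = max(abs(off)),
                                 mean_c = mean(off),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Write a ModeSet as a plain-text matrix file
#'
#' One block per mode: a line `MODE <number> <eigenvalue>` (reporting
#' convention: internal modes start at 7) then N
#' rows of the 3-component node displacements.
#' @param modes `ModeSet`.
#' @param path output file.
#' @param n_modes number of internal modes to write (default all).
#' @export
write_modes <- function(modes, path,
                        n_modes = length(modes$values) - modes$trivial) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in seq_len(n_modes)) {
    col <- modes$trivial + m
    cat(sprintf("MODE %d %.10g\n", col, modes$values[col]), file = con)
    utils::write.table(format(mode_displacements(modes, col), digits = 10),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a mode file written by [write_modes()]
#' @param path mode file.
#' @param n number of nodes.
#' @export
read_modes <- function(path, n) {
  lines <- readLines(path)
  heads <- grep("^MODE ", lines)
  values <- numeric(0); vecs <- list()
  for (h in seq_along(heads)) {
    parts <- strsplit(lines[heads[h]], " +")[[1]]
    values <- c(values, as.numeric(parts[3]))
    block <- lines[(heads[h] + 1):(heads[h] + n)]
    vecs[[h]] <- xyz_to_vec(do.call(rbind,
      lapply(strsplit(trimws(block), " +"), as.numeric)))
  }
  list(numbers = vapply(heads, function(h)
    as.integer(strsplit(lines[h], " +")[[1]][2]), 1L),
    values = values, vectors = do.call(cbind, vecs))
}
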