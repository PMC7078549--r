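## Conformer generation along individual low-frequency modes: Calpha
## displacement, elastic-energy relaxation restricted to mode space, and
## all-atom rebuilding by a 3-residue sliding-window rigid fit.

#' Displace a structure along one normal mode
#'
#' `x = x0 + s * A * v_m` with `v_m` the unit-normalized 3N eigenvector and
#' the amplitude factor `A` in Angstrom units, so the Calpha RMSD to the
#' parent is exactly `A / sqrt(N)`.
#'
#' @param model parent `StructureModel`.
#' @param modes `ModeSet` of the parent's network (Calpha nodes first; any
#'   extra nodes, e.g. cofactor beads, are ignored for the model output).
#' @param mode mode number in the reporting convention: modes 1-6 are the
#'   rigid-body modes, 7 is the first internal mode.
#' @param amplitude amplitude factor A >= 0 (default 15).
#' @param direction +1 or -1.
#' @return object of class `ModeConformer`: list with `id`, `mode`,
#'   `direction`, `amplitude`, `xyz` (displaced Calpha coordinates),
#'   `rmsd` (A, to the parent).
#' @export
displace_along_mode <- function(model, modes, mode, amplitude = 15,
                                direction = 1) {
  if (mode <= modes$trivial)
    stop("mode ", mode, " is a trivial (rigid-body) mode; internal modes ",
         "start at ", modes$trivial + 1, call. = FALSE)
  if (mode > length(modes$values)) stop("mode index out of range", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  direction <- sign(direction)
  v <- vec_to_xyz(modes$vectors[, mode])
  x0 <- ca_xyz(model)
  if (nrow(v) < nrow(x0)) stop("mode set smaller than the model", call. = FALSE)
  disp <- direction * amplitude * v
  xyz <- x0 + disp[seq_len(nrow(x0)), , drop = FALSE]
  structure(list(id = model$id, mode = mode, direction = direction,
                 amplitude = amplitude, xyz = xyz,
                 rmsd = amplitude / sqrt(modes$n)),
            class = "ModeConformer")
}

#' Relax a conformation in normal-mode space
#'
#' Minimizes the full (anharmonic-in-geometry) network energy over
#' displacement coefficients restricted to the span of the `k` lowest
#' internal modes plus the six rigid-body modes, starting from the given
#' conformation. Energy never increases; the input is returned (with a
#' warning) if the optimizer fails to improve it.
#'
#' When relaxing a conformer that was displaced along one mode, that mode
#' must be excluded from the basis (`exclude_modes`), otherwise the
#' quadratic energy simply drives the structure back to equilibrium and
#' the displacement is undone; excluding it holds the imposed deformation
#' while the remaining soft modes release local strain.
#'
#' @param xyz conformation to relax (N x 3, A; N = network size).
#' @param network `ElasticNetwork` (defines the energy).
#' @param modes `ModeSet` of that network (defines the basis).
#' @param k number of internal modes in the basis (default 20).
#' @param exclude_modes mode numbers (reporting convention) removed from
#'   the basis, typically the displaced mode (default none).
#' @param max_iter iteration cap (default 500).
#' @param tol gradient tolerance per coefficient (default 1e-8).
#' @return list with `xyz` (relaxed), `energy_before`, `energy_after`,
#'   `coefficients`, `converged`.
#' @export
relax_in_mode_space <- function(xyz, network, modes, k = 20L,
                                exclude_modes = integer(0),
                                max_iter = 500L, tol = 1e-8) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != network$n)
    stop("conformation size does not match the network", call. = FALSE)
  nb <- min(modes$trivial + k, length(modes$values))
  cols <- setdiff(seq_len(nb), exclude_modes)
  B <- modes$vectors[, cols, drop = FALSE]
  nb <- length(cols)
  x0v <- xyz_to_vec(xyz)
  fn <- function(cc) network_energy(network, vec_to_xyz(x0v + B %*% cc))
  gr <- function(cc) as.vector(
    crossprod(B, network_energy_gradient(network, vec_to_xyz(x0v + B %*% cc))))
  e0 <- fn(rep(0, nb))
  opt <- stats::optim(rep(0, nb), fn, gr, method = "BFGS",
                      control = list(maxit = max_iter,
                                     reltol = .Machine$double.eps,
                                     abstol = 0))
  converged <- opt$convergence == 0L &&
    max(abs(gr(opt$par))) <= tol * max(1, abs(opt$value))
  if (opt$convergence != 0L)
    warning("mode-space relaxation hit the iteration cap; ",
            "returning best found", call. = FALSE)
  if (opt$value > e0) {
    warning("relaxation failed to lower the energy; returning the input",
            call. = FALSE)
    return(list(xyz = xyz, energy_before = e0, energy_after = e0,
                coefficients = rep(0, nb), converged = FALSE))
  }
  relaxed <- vec_to_xyz(x0v + B %*% opt$par)
  ## the energy is flat along rigid-body motion, so the optimizer may end
  ## with an arbitrary rigid drift; remove it (gauge fixing, energy exact)
  fit <- tryCatch(superimpose(relaxed, xyz), error = function(e) NULL)
  if (!is.null(fit)) relaxed <- fit$fitted
  list(xyz = relaxed,
       energy_before = e0, energy_after = opt$value,
       coefficients = opt$par, converged = converged)
}

#' Rebuild an all-atom model onto a deformed Calpha trace
#'
#' For each residue i, fits the rigid transform superimposing the parent
#' Calphas of the 3-residue window (i-1, i, i+1) onto the target window and
#' applies it to all atoms of residue i; terminal residues reuse the first
#' and last windows. Collinear windows fall back to the previous residue's
#' transform with a warning.
#'
#' @param parent `StructureModel` with all-atom coordinates.
#' @param target_ca N x 3 target Calpha coordinates (same residue count).
#' @return `StructureModel` with rebuilt atoms; its residue Calphas are the
#'   rebuilt CA atom positions.
#' @export
rebuild_all_atom <- function(parent, target_ca) {
  if (is.null(parent$atoms))
    stop("parent model has no all-atom coordinates", call. = FALSE)
  target_ca <- as.matrix(target_ca)
  n <- n_residues(parent)
  if (nrow(target_ca) != n)
    stop("residue count mismatch: parent ", n, ", target ", nrow(target_ca),
         call. = FALSE)
  if (n < 3L) stop("need at least 3 residues for window fits", call. = FALSE)
  pca <- ca_xyz(parent)
  atoms <- parent$atoms
  new_xyz <- as.matrix(atoms[, c("x", "y", "z")])
  prev_tf <- NULL
  for (i in seq_len(n)) {
    w <- if (i == 1L) 1:3 else if (i == n) (n - 2):n else (i - 1):(i + 1)
    tf <- tryCatch(superimpose(pca[w, , drop = FALSE],
                               target_ca[w, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(tf)) {
      if (is.null(prev_tf))
        stop("collinear window at residue ", i, " with no prior transform",
             call. = FALSE)
      warning("collinear Calpha window at residue ", i,
              "; reusing the previous residue's transform", call. = FALSE)
      tf <- prev_tf
    }
    rows <- which(atoms$res_index == i)
    if (length(rows))
      new_xyz[rows, ] <- apply_transform(new_xyz[rows, , drop = FALSE], tf)
    prev_tf <- tf
  }
  out <- parent
  out$atoms[, c("x", "y", "z")] <- new_xyz
  ca_rows <- which(atoms$atom == "CA")
  ca_rows <- ca_rows[match(seq_len(n), atoms$res_index[ca_rows])]
  ok <- !is.na(ca_rows)
  out$residues[ok, c("x", "y", "z")] <- new_xyz[ca_rows[ok], , drop = FALSE]
  out
}

#' Steric-clash report for an all-atom model
#'
#' Counts non-bonded heavy-atom pairs (residue separation >= 2) closer than
#' `threshold` (default 2.4 A), as a cheap structural-quality check on
#' rebuilt conformers.
#'
#' @param model `StructureModel` with atoms.
#' @param threshold clash distance, A.
#' @return list with `count` and `clashes` (data.frame i, j, distance,
#'   res_i, res_j).
#' @export
clash_report <- function(model, threshold = 2.4) {
  if (is.null(model$atoms)) stop("model has no atoms", call. = FALSE)
  a <- model$atoms[toupper(model$atoms$element) != "H", , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (nrow(xyz) < 2L)
    return(list(count = 0L, clashes = data.frame()))
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(a$res_index, a$res_index, "-"))
  hit <- which(upper.tri(d) & d < threshold & sep >= 2, arr.ind = TRUE)
  clashes <- data.frame(i = hit[, 1], j = hit[, 2],
                        distance = d[hit],
                        res_i = a$res_index[hit[, 1]],
                        res_j = a$res_index[hit[, 2]])
  clashes <- clashes[order(clashes$distance), , drop = FALSE]
  rownames(clashes) <- NULL
  list(count = nrow(clashes), clashes = clashes)
}

#' Generate, relax and (optionally) rebuild conformers for a mode sweep
#'
#' Convenience driver: for each requested mode and direction, displaces the
#' parent Calpha trace, relaxes in mode space, rebuilds all atoms when the
#' parent carries them, and collects per-conformer metadata.
#'
#' @param model parent `StructureModel`.
#' @param network `ElasticNetwork` on the model's Calphas.
#' @param modes `ModeSet`.
#' @param mode_numbers internal-mode numbers (default 7:12).
#' @param amplitude amplitude factor (default 15).
#' @param relax_k basis size for relaxation (default 20).
#' @return list with `conformers` (list of `StructureModel`s keyed
#'   "m<mode><+/->") and `metadata` (data.frame).
#' @export
mode_sweep <- function(model, network, modes, mode_numbers = 7:12,
                       amplitude = 15, relax_k = 20L) {
  out <- list(); meta <- NULL
  x0 <- ca_xyz(model)
  for (m in mode_numbers) for (s in c(1, -1)) {
    cf <- displace_along_mode(model, modes, m, amplitude, s)
    rx <- relax_in_mode_space(cf$xyz, network, modes, k = relax_k,
                              exclude_modes = m)
    conf <- model
    conf$residues[, c("x", "y", "z")] <- rx$xyz[seq_len(nrow(x0)), ]
    clashes <- NA_integer_
    if (!is.null(model$atoms)) {
      conf <- rebuild_all_atom(model, rx$xyz[seq_len(nrow(x0)), , drop = FALSE])
      clashes <- clash_report(conf)$count
    }
    key <- sprintf("m%d%s", m, if (s > 0) "+" else "-")
    out[[key]] <- conf
    meta <- rbind(meta, data.frame(
      id = model$id, mode = m, direction = s, amplitude = amplitude,
      rmsd_displaced = cf$rmsd,
      rmsd_relaxed = coord_rmsd(rx$xyz[seq_len(nrow(x0)), ], x0),
      energy_before = rx$energy_before, energy_after = rx$energy_after,
      clash_count = clashes))
  }
  list(conformers = out, metadata = meta)
}
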