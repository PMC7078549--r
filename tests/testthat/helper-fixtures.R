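## Fixtures are built in code at test time; nothing binary is stored.

## Raw fixed-width PDB record
pdb_line <- function(type = "ATOM", serial, name, resname, chain, resno,
                     x, y, z, occ = 1.00, b = 0.00, element = "C",
                     alt = " ", insert = " ") {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name_fmt, alt, resname, chain, resno, insert,
          x, y, z, occ, b, element)
}

## A small two-chain PDB file: n residues per chain, CA (+ optional CB)
write_two_chain_pdb <- function(path, n = 5, with_cb = FALSE) {
  lines <- character(0); serial <- 0
  for (ch in c("A", "B")) {
    for (i in seq_len(n)) {
      serial <- serial + 1
      off <- if (ch == "A") 0 else 50
      lines <- c(lines, pdb_line("ATOM", serial, "CA", "ALA", ch, i,
                                 3.8 * i + off, 0.5 * i, 0.25 * i^2))
      if (with_cb) {
        serial <- serial + 1
        lines <- c(lines, pdb_line("ATOM", serial, "CB", "ALA", ch, i,
                                   3.8 * i + off + 1, 0.5 * i + 1, 0.25 * i^2))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

## PDB with a CoA heterogroup carrying the 11 bead atoms (plus some
## protein residues); positions spaced ~3.5 A so bead spacing is realistic
coa_bead_names <- c("C", "C3P", "C6P", "C9P", "CCP",
                    "P1A", "C4B", "P3B", "N9A", "N6A", "N3A")

write_coa_pdb <- function(path, drop_atom = NULL, n_res = 3) {
  lines <- character(0); serial <- 0
  for (i in seq_len(n_res)) {
    serial <- serial + 1
    lines <- c(lines, pdb_line("ATOM", serial, "CA", "GLY", "A", i,
                               3.8 * i, 0, 0))
  }
  beads <- setdiff(coa_bead_names, drop_atom)
  for (k in seq_along(coa_bead_names)) {
    nm <- coa_bead_names[k]
    if (!nm %in% beads) next
    serial <- serial + 1
    el <- substr(nm, 1, 1)
    lines <- c(lines, pdb_line("HETATM", serial, nm, "ACO", "A", 900,
                               10 + 3.5 * k, 5, 2, element = el))
  }
  writeLines(c(lines, "END"), path)
  path
}

## Rigid transform helpers
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_model <- function(model, R, t = c(0, 0, 0)) {
  out <- model
  out$residues[, c("x", "y", "z")] <-
    ca_xyz(model) %*% t(R) + matrix(t, n_residues(model), 3, byrow = TRUE)
  if (!is.null(model$atoms)) {
    a <- as.matrix(model$atoms[, c("x", "y", "z")])
    out$atoms[, c("x", "y", "z")] <- a %*% t(R) +
      matrix(t, nrow(a), 3, byrow = TRUE)
  }
  out
}

## Random connected network of n nodes (coordinates in a compact blob)
random_network <- function(n, seed = 1) {
  natdyn:::with_seed(seed, {
    xyz <- matrix(stats::rnorm(3 * n, 0, 3), ncol = 3)
    ## keep nodes at least ~3 A apart so spring constants stay positive
    for (i in 2:n) {
      repeat {
        d <- sqrt(rowSums((xyz[1:(i - 1), , drop = FALSE] -
                             matrix(xyz[i, ], i - 1, 3, byrow = TRUE))^2))
        if (min(d) > 3) break
        xyz[i, ] <- stats::rnorm(3, 0, 4)
      }
    }
    build_network(xyz)
  })
}

ca_xyz_from_net <- function(net) net$xyz

## displace one flattened coordinate (node-major) by h (A)
bump <- function(xyz, comp, h) {
  v <- natdyn:::xyz_to_vec(xyz)
  v[comp] <- v[comp] + h
  natdyn:::vec_to_xyz(v)
}

## Displacement with zero net translation and zero angular cross-term:
## for such a field the optimal rigid fit is exactly the identity, so the
## minimal RMSD equals ||d|| / sqrt(n) by construction.
rigid_orthogonal_displacement <- function(xyz, target_rmsd, seed = 1) {
  natdyn:::with_seed(seed, {
    n <- nrow(xyz)
    x0 <- sweep(xyz, 2, colMeans(xyz))
    d <- matrix(stats::rnorm(3 * n), ncol = 3)
    d <- sweep(d, 2, colMeans(d))
    ## remove the angular part: solve M omega = L(d), d' = d - omega x x_i
    Lmat <- function(v) colSums(cbind(
      x0[, 2] * v[, 3] - x0[, 3] * v[, 2],
      x0[, 3] * v[, 1] - x0[, 1] * v[, 3],
      x0[, 1] * v[, 2] - x0[, 2] * v[, 1]))
    M <- matrix(0, 3, 3)
    for (i in seq_len(n)) {
      xi <- x0[i, ]
      M <- M + (sum(xi^2) * diag(3) - tcrossprod(xi))
    }
    omega <- solve(M, Lmat(d))
    rot_field <- cbind(omega[2] * x0[, 3] - omega[3] * x0[, 2],
                       omega[3] * x0[, 1] - omega[1] * x0[, 3],
                       omega[1] * x0[, 2] - omega[2] * x0[, 1])
    d <- d - rot_field
    d <- sweep(d, 2, colMeans(d))
    d * target_rmsd / sqrt(mean(rowSums(d^2)))
  })
}

## Independent grid-search superposition oracle: coarse-to-fine search
## over rotations (centroids aligned), far from the svd path.
grid_search_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  euler <- function(a, b, c) rot_z(a * 180 / pi) %*%
    matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
           byrow = TRUE) %*% rot_z(c * 180 / pi)
  eval_r <- function(a, b, c) {
    R <- euler(a, b, c)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- c(0, 0, 0); best_v <- Inf
  step <- pi / 12
  grid <- seq(-pi, pi, by = step)
  for (a in grid) for (b in seq(0, pi, by = step)) for (c in grid) {
    v <- eval_r(a, b, c)
    if (v < best_v) { best_v <- v; best <- c(a, b, c) }
  }
  for (lvl in 1:6) {
    step <- step / 4
    g <- seq(-3, 3) * step
    for (da in g) for (db in g) for (dc in g) {
      v <- eval_r(best[1] + da, best[2] + db, best[3] + dc)
      if (v < best_v) { best_v <- v; best2 <- best + c(da, db, dc) }
    }
    if (exists("best2")) { best <- best2; rm(best2) }
  }
  best_v
}

## Direct text-mode TunnelProfile for arithmetic tests
make_profile <- function(offsets, areas) {
  structure(list(offsets = offsets, areas = areas, step = diff(offsets)[1],
                 max_radius = 6, grid = 0.25, probe = 0, axis = NULL),
            class = "TunnelProfile")
}

## Straight tunnel axis for fixtures with a known geometry (e.g. the
## synthetic channel along z)
manual_axis <- function(origin, normal, half_length = 15) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(origin = origin, normal = normal, anchors = NA,
                 half_length = half_length, sphere_radius = 1),
            class = "TunnelAxis")
}

## Tiny all-atom helix model (CA + CB per residue) for rebuild tests
make_allatom_helix <- function(n = 20) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
  cb <- cbind(3.5 * cos(th), 3.5 * sin(th), 1.5 * i + 0.5)
  residues <- data.frame(resname = "ALA", resno = seq_len(n), insert = "",
                         x = ca[, 1], y = ca[, 2], z = ca[, 3],
                         stringsAsFactors = FALSE)
  atoms <- data.frame(
    res_index = rep(seq_len(n), each = 2),
    atom = rep(c("CA", "CB"), n),
    element = "C",
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    stringsAsFactors = FALSE)
  structure_model("helix_allatom", residues, atoms)
}
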