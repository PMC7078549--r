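make_test_system <- function(seed = 1, n = NULL) {
  spec <- if (is.null(n)) default_fold_spec(seed = seed) else
    fold_spec(list(list(type = "helix", length = n)), seed = seed)
  f <- make_fold(spec)
  suppressWarnings({
    net <- build_network(ca_xyz(f))
    md <- compute_modes(net)
  })
  list(model = f, net = net, modes = md)
}

test_that("mode displacement has exact amplitude-to-RMSD algebra", {
  sys <- make_test_system(seed = 1, n = 100)
  ## zero amplitude is the identity
  c0 <- displace_along_mode(sys$model, sys$modes, 7, amplitude = 0)
  expect_equal(c0$xyz, ca_xyz(sys$model), ignore_attr = TRUE)
  expect_equal(c0$rmsd, 0)
  ## A = 15 over N = 100 -> RMSD exactly 1.5 A
  c15 <- displace_along_mode(sys$model, sys$modes, 7, amplitude = 15)
  expect_equal(coord_rmsd(c15$xyz, ca_xyz(sys$model)), 1.5, tolerance = 1e-12)
  expect_equal(c15$rmsd, 15 / sqrt(100))
  ## directions are sign-symmetric
  cp <- displace_along_mode(sys$model, sys$modes, 8, 10, direction = 1)
  cn <- displace_along_mode(sys$model, sys$modes, 8, 10, direction = -1)
  x0 <- ca_xyz(sys$model)
  expect_equal(cp$xyz - x0, -(cn$xyz - x0), tolerance = 1e-12)
  expect_equal(coord_rmsd(cp$xyz, x0), coord_rmsd(cn$xyz, x0))
  ## trivial modes are refused
  expect_error(displace_along_mode(sys$model, sys$modes, 3, 5), "trivial")
})

test_that("mode-space relaxation is a descent that stays near the parent", {
  sys <- make_test_system(seed = 2)
  x0 <- ca_xyz(sys$model)
  ## equilibrium input is returned unchanged
  rx0 <- relax_in_mode_space(x0, sys$net, sys$modes, k = 10)
  expect_equal(rx0$xyz, x0, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rx0$energy_after, 0, tolerance = 1e-8)

  for (m in c(7, 9, 12)) {
    cf <- displace_along_mode(sys$model, sys$modes, m, amplitude = 15)
    rx <- relax_in_mode_space(cf$xyz, sys$net, sys$modes, k = 10)
    expect_lte(rx$energy_after, rx$energy_before)
    pre <- coord_rmsd(cf$xyz, x0)
    expect_lte(coord_rmsd(rx$xyz, x0), 2 * pre)
  }
})

test_that("excluding the displaced mode preserves the imposed deformation", {
  sys <- make_test_system(seed = 7)
  x0 <- ca_xyz(sys$model)
  cf <- displace_along_mode(sys$model, sys$modes, 7, amplitude = 15)
  pre <- coord_rmsd(cf$xyz, x0)
  ## with the displaced mode in the basis the minimum is the parent
  back <- relax_in_mode_space(cf$xyz, sys$net, sys$modes, k = 10)
  expect_lt(coord_rmsd(back$xyz, x0), 0.1 * pre)
  ## excluding it holds the deformation while strain is released; drift
  ## into other soft modes stays bounded (synthetic folds are more
  ## anharmonic than crystal structures, so the bound is generous)
  held <- relax_in_mode_space(cf$xyz, sys$net, sys$modes, k = 10,
                              exclude_modes = 7)
  expect_gt(coord_rmsd(held$xyz, x0), 0.5 * pre)
  expect_lt(coord_rmsd(held$xyz, x0), 2.5 * pre)
  expect_lte(held$energy_after, held$energy_before)
})

test_that("restricted relaxation matches an independent minimizer over the same basis", {
  sys <- make_test_system(seed = 3, n = 10)
  cf <- displace_along_mode(sys$model, sys$modes, sys$modes$trivial + 1,
                            amplitude = 6)
  k <- 4L
  rx <- relax_in_mode_space(cf$xyz, sys$net, sys$modes, k = k)
  ## independent path: Nelder-Mead (no gradient) over the same coefficients
  nb <- sys$modes$trivial + k
  B <- sys$modes$vectors[, seq_len(nb), drop = FALSE]
  x0v <- as.vector(t(cf$xyz))
  fn <- function(cc) network_energy(sys$net,
                                    matrix(x0v + B %*% cc, ncol = 3,
                                           byrow = TRUE))
  opt <- stats::optim(rep(0, nb), fn, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  oracle <- matrix(x0v + B %*% opt$par, ncol = 3, byrow = TRUE)
  ## the energy is exactly flat along the rigid-body coefficients, so the
  ## two minimizers may drift apart by a rigid move; compare modulo it
  fit <- superimpose(rx$xyz, oracle)
  expect_lt(max(abs(fit$fitted - oracle)), 1e-3)
  expect_equal(rx$energy_after, opt$value, tolerance = 1e-4)
})

test_that("all-atom rebuild reproduces identity and global rotations exactly", {
  h <- make_allatom_helix(20)
  ## identity target
  rb <- rebuild_all_atom(h, ca_xyz(h))
  expect_equal(as.matrix(rb$atoms[, c("x", "y", "z")]),
               as.matrix(h$atoms[, c("x", "y", "z")]), tolerance = 1e-6,
               ignore_attr = TRUE)
  ## a global rotation is reproduced by every window
  set.seed(4)
  R <- random_rotation(); tv <- c(3, -1, 2)
  target <- ca_xyz(h) %*% t(R) + matrix(tv, 20, 3, byrow = TRUE)
  rb2 <- rebuild_all_atom(h, target)
  expected <- as.matrix(h$atoms[, c("x", "y", "z")]) %*% t(R) +
    matrix(tv, nrow(h$atoms), 3, byrow = TRUE)
  expect_equal(as.matrix(rb2$atoms[, c("x", "y", "z")]), expected,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(rebuild_all_atom(h, ca_xyz(h)[1:10, ]), "mismatch")
})

test_that("rebuild tracks a smooth bend and matches a per-window fit oracle", {
  h <- make_allatom_helix(20)
  x0 <- ca_xyz(h)
  ## smooth bend: rotate about x by an angle growing along the chain
  ang <- seq(0, 0.15, length.out = 20)
  target <- t(vapply(seq_len(20), function(i) {
    a <- ang[i]
    Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3,
                 byrow = TRUE)
    as.vector(Rx %*% x0[i, ])
  }, numeric(3)))
  expect_lt(coord_rmsd(target, x0), 2)  # deformation stays moderate
  rb <- rebuild_all_atom(h, target)
  expect_lt(coord_rmsd(ca_xyz(rb), target), 0.5)

  ## oracle: independent window-wise fit through bio3d for interior residues
  a_parent <- as.matrix(h$atoms[, c("x", "y", "z")])
  for (i in c(5, 10, 15)) {
    w <- (i - 1):(i + 1)
    fixed <- as.vector(t(target[w, ]))
    mobil_ca <- as.vector(t(x0[w, ]))
    rows <- which(h$atoms$res_index == i)
    mobile_all <- as.vector(t(a_parent[rows, ]))
    moved <- bio3d::fit.xyz(fixed = fixed, mobile = c(mobil_ca, mobile_all),
                            fixed.inds = 1:9, mobile.inds = 1:9)
    oracle <- matrix(moved[-(1:9)], ncol = 3, byrow = TRUE)
    got <- as.matrix(rb$atoms[rows, c("x", "y", "z")])
    expect_equal(got, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("clash report counts close non-bonded heavy pairs", {
  h <- make_allatom_helix(20)
  expect_equal(clash_report(h)$count, 0)

  ## two atoms from sequence-distant residues forced to 1.0 A apart
  res3 <- data.frame(resname = "ALA", resno = 1:3, insert = "",
                     x = c(0, 20, 1), y = 0, z = 0, stringsAsFactors = FALSE)
  bad <- structure_model("clashpair", res3, atoms = data.frame(
    res_index = 1:3, atom = "CA", element = "C",
    x = c(0, 20, 1), y = 0, z = 0, stringsAsFactors = FALSE))
  rep_bad <- clash_report(bad)
  expect_equal(rep_bad$count, 1)
  expect_equal(rep_bad$clashes$distance[1], 1.0, tolerance = 1e-9)
  expect_equal(sort(c(rep_bad$clashes$res_i[1], rep_bad$clashes$res_j[1])),
               c(1, 3))
  ## hydrogen atoms and bonded neighbours are ignored
  hh <- h
  hh$atoms$element[2] <- "H"
  expect_equal(clash_report(hh)$count, 0)
})

test_that("clash count tends not to decrease with amplitude on a fixed mode", {
  sys <- make_test_system(seed = 5)
  f <- sys$model
  ## decorate with CA-only atom records so clashes are measurable
  f$atoms <- data.frame(res_index = seq_len(n_residues(f)), atom = "CA",
                        element = "C", x = f$residues$x, y = f$residues$y,
                        z = f$residues$z, stringsAsFactors = FALSE)
  counts <- vapply(c(0, 5, 10, 15), function(A) {
    cf <- displace_along_mode(f, sys$modes, 7, amplitude = A)
    m <- f
    m$residues[, c("x", "y", "z")] <- cf$xyz
    m$atoms[, c("x", "y", "z")] <- cf$xyz
    clash_report(m)$count
  }, 1L)
  expect_equal(counts[1], 0L)
  if (any(diff(counts) < 0))
    message("clash count non-monotone over amplitudes: ",
            paste(counts, collapse = ", "))
  expect_lte(counts[1], counts[4])
})

test_that("mode sweeps at amplitude 15 keep conformers near the parent", {
  sys <- make_test_system(seed = 6)
  sw <- mode_sweep(sys$model, sys$net, sys$modes, mode_numbers = 7:9,
                   amplitude = 15, relax_k = 10)
  expect_equal(nrow(sw$metadata), 6)
  expect_true(all(sw$metadata$rmsd_displaced < 2))
  ## relaxation releases strain without drifting far from the parent
  ## (crystal-structure inputs stay well under 2x; the synthetic folds'
  ## stronger anharmonic coupling pushes some modes slightly above)
  expect_true(all(sw$metadata$rmsd_relaxed <
                    2.5 * sw$metadata$rmsd_displaced))
  ## the displaced-mode component is held, so the conformers stay deformed
  expect_true(all(sw$metadata$rmsd_relaxed > 0.5 * sw$metadata$rmsd_displaced))
  expect_true(all(sw$metadata$energy_after <= sw$metadata$energy_before))
})
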