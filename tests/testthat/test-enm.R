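test_that("pair force constant follows the printed piecewise law", {
  k <- enm_constants()
  expect_equal(k$a, 8.6e5)
  expect_equal(k$b, 2.39e5)
  expect_equal(k$c, 128)
  expect_equal(k$d, 0.4)
  ## hand arithmetic from the printed constants
  expect_equal(pair_force_constant(0.3), 8.6e5 * 0.3 - 2.39e5)  # 1.9e4
  expect_equal(pair_force_constant(0.3), 1.9e4)
  expect_equal(pair_force_constant(0.5), 128 * 0.5^-6)          # 8192
  expect_equal(pair_force_constant(0.5), 8192)
  ## branch chosen strictly by r0 < d
  expect_equal(pair_force_constant(0.4), 128 * 0.4^-6)
  expect_error(pair_force_constant(0), "positive")
  expect_error(pair_force_constant(-1), "positive")
  expect_warning(k0 <- pair_force_constant(0.25), "clamped")
  expect_equal(k0, 0)
})

test_that("build_network forms springs with the right constants and invariances", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0))  # 3 A = 0.3 nm
  net <- build_network(xyz)
  expect_equal(nrow(net$springs), 1)
  expect_equal(net$springs$k, 1.9e4)
  expect_equal(net$springs$r0, 0.3)

  ## translation invariance of the spring list
  f <- make_fold(default_fold_spec(seed = 4))
  n1 <- build_network(ca_xyz(f))
  n2 <- build_network(ca_xyz(f) + 100)
  expect_equal(n1$springs, n2$springs, tolerance = 1e-9)

  expect_error(build_network(rbind(c(0, 0, 0), c(0, 0, 0))), "coincident")
  expect_error(build_network(matrix(0, 1, 3)), "at least 2")
})

test_that("the recommended 4 nm speed cutoff leaves the low-frequency spectrum nearly unchanged", {
  f <- make_fold(default_fold_spec(seed = 4))
  suppressWarnings({
    full <- compute_modes(build_network(ca_xyz(f)))
    cut <- compute_modes(build_network(ca_xyz(f), cutoff = 4.0))
  })
  lo <- full$trivial + 1:6
  expect_equal(cut$values[lo], full$values[lo], tolerance = 0.01)
  ## and the cutoff network really is smaller
  suppressWarnings(
    expect_lt(nrow(build_network(ca_xyz(f), cutoff = 4.0)$springs),
              nrow(build_network(ca_xyz(f))$springs)))
})

test_that("the Hessian matches the analytic 2-body form and a finite-difference oracle", {
  k <- 1.9e4
  net <- build_network(rbind(c(0, 0, 0), c(3, 0, 0)))
  H <- enm_hessian(net)
  expect_equal(dim(H), c(6, 6))
  Hexp <- matrix(0, 6, 6)
  Hexp[1, 1] <- Hexp[4, 4] <- k
  Hexp[1, 4] <- Hexp[4, 1] <- -k
  expect_equal(H, Hexp, tolerance = 1e-9)

  ## finite differences of the energy on random 5-node networks;
  ## energy is in nm units, coordinates in A, so d2V/dxA2 = H / 100
  for (seed in 1:2) {
    net5 <- random_network(5, seed = seed)
    H5 <- enm_hessian(net5)
    expect_equal(max(abs(H5 - t(H5))), 0)
    h <- 1e-3
    x0 <- ca_xyz_from_net(net5)
    num <- matrix(0, 15, 15)
    for (a in 1:15) for (b in a:15) {
      pp <- bump(x0, a, h) ; pp <- bump(pp, b, h)
      pm <- bump(x0, a, h) ; pm <- bump(pm, b, -h)
      mp <- bump(x0, a, -h); mp <- bump(mp, b, h)
      mm <- bump(x0, a, -h); mm <- bump(mm, b, -h)
      num[a, b] <- num[b, a] <-
        (network_energy(net5, pp) - network_energy(net5, pm) -
           network_energy(net5, mp) + network_energy(net5, mm)) / (4 * h^2)
    }
    expect_equal(num * 100, H5, tolerance = 1e-4 * max(abs(H5)),
                 ignore_attr = TRUE)
  }
})

test_that("modes diagonalize correctly: 2-body eigenvalue, rigid modes, orthonormality", {
  k <- 1.9e4
  net <- build_network(rbind(c(0, 0, 0), c(3, 0, 0)))
  md <- compute_modes(net)
  nonzero <- md$values[md$values > md$rigid_tol]
  expect_length(nonzero, 1)
  expect_equal(nonzero, 2 * k, tolerance = 1e-9)

  f <- make_fold(default_fold_spec(seed = 4))
  suppressWarnings(m <- compute_modes(build_network(ca_xyz(f))))
  expect_equal(m$trivial, 6)
  expect_equal(sum(m$values < m$rigid_tol), 6)
  VtV <- crossprod(m$vectors)
  expect_lt(max(abs(VtV - diag(nrow(VtV)))), 1e-8)
  ## unit per-mode displacement norm
  expect_equal(colSums(m$vectors^2), rep(1, ncol(m$vectors)),
               ignore_attr = TRUE)
})

test_that("a disconnected network is refused with component information", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(500, 500, 500), c(503.8, 500, 500),
               c(500, 503.8, 500))
  suppressWarnings(net <- build_network(xyz, cutoff = 2.5))
  expect_error(compute_modes(net), "disconnected")
})

test_that("quadratic energy matches mode eigenvalues for small displacements", {
  net <- random_network(8, seed = 3)
  md <- compute_modes(net)
  e0 <- network_energy(net)
  expect_equal(e0, 0, tolerance = 1e-20)
  eps <- 1e-6  # A; small enough that anharmonic terms are < 1e-6 relative
  for (m in md$trivial + c(1, 3, 10)) {
    x <- ca_xyz_from_net(net) + eps * matrix(md$vectors[, m], ncol = 3,
                                             byrow = TRUE)
    expect_equal(network_energy(net, x),
                 0.5 * md$values[m] * (eps / 10)^2, tolerance = 1e-6)
  }
})

test_that("fluctuations match the Hessian pseudo-inverse and are invariant to rigid moves", {
  net <- random_network(7, seed = 9)
  md <- compute_modes(net)
  fl <- fluctuations(md)
  expect_equal(mean(fl$fluctuations), 1, tolerance = 1e-12)
  expect_true(all(fl$fluctuations >= 0))

  ## raw Fi = per-node trace of the Moore-Penrose pseudo-inverse
  P <- MASS::ginv(enm_hessian(net))
  tr <- vapply(seq_len(net$n), function(i)
    sum(diag(P)[(3 * i - 2):(3 * i)]), 1)
  expect_equal(fl$raw, tr, tolerance = 1e-8 * max(tr), ignore_attr = TRUE)

  ## rotation + translation invariance
  set.seed(10)
  R <- random_rotation()
  net_rot <- build_network(ca_xyz_from_net(net) %*% t(R) + 12)
  fl_rot <- fluctuations(compute_modes(net_rot))
  expect_equal(fl_rot$fluctuations, fl$fluctuations, tolerance = 1e-6)
})

test_that("a mirror-symmetric structure has a mirror-symmetric profile", {
  set.seed(12)
  half <- matrix(rnorm(21, sd = 3), ncol = 3)
  half[, 1] <- half[, 1] + 4  # keep away from the mirror plane x = 0
  mirror <- half[rev(seq_len(nrow(half))), ] %*% diag(c(-1, 1, 1))
  xyz <- rbind(half, mirror)
  suppressWarnings(
    fl <- fluctuations(compute_modes(build_network(xyz)))$fluctuations)
  expect_equal(fl, rev(fl), tolerance = 1e-8)
})

test_that("correlations are properly normalized and match the pseudo-inverse oracle", {
  ## 2-body: single internal stretching mode, perfectly anti-correlated
  net2 <- build_network(rbind(c(0, 0, 0), c(3, 0, 0)))
  c2 <- correlations(compute_modes(net2))$map
  expect_equal(c2[1, 2], -1, tolerance = 1e-10)

  net <- random_network(6, seed = 14)
  cm <- correlations(compute_modes(net))$map
  expect_equal(diag(cm), rep(1, 6), ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(abs(cm) <= 1 + 1e-8))
  expect_equal(cm, t(cm), tolerance = 1e-12)

  P <- MASS::ginv(enm_hessian(net))
  n <- net$n
  idx <- function(a) seq(a, 3 * n, 3)
  num <- P[idx(1), idx(1)] + P[idx(2), idx(2)] + P[idx(3), idx(3)]
  oracle <- num / sqrt(outer(diag(num), diag(num)))
  expect_equal(cm, oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("uniform spring scaling rescales fluctuations and leaves correlations unchanged", {
  xyz <- ca_xyz_from_net(random_network(6, seed = 15))
  s <- 4
  base <- enm_constants()
  scaled <- enm_constants(a = base$a * s, b = base$b * s, c = base$c * s)
  m1 <- compute_modes(build_network(xyz, constants = base))
  m2 <- compute_modes(build_network(xyz, constants = scaled))
  f1 <- fluctuations(m1); f2 <- fluctuations(m2)
  expect_equal(f2$raw, f1$raw / s, tolerance = 1e-9 * max(f1$raw))
  expect_equal(correlations(m2)$map, correlations(m1)$map, tolerance = 1e-8)
})

test_that("domain block summaries match hand arithmetic", {
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.8
  m[3, 4] <- m[4, 3] <- 0.6
  m[1, 3] <- m[3, 1] <- 0.1
  m[1, 4] <- m[4, 1] <- -0.2
  m[2, 3] <- m[3, 2] <- 0.05
  m[2, 4] <- m[4, 2] <- 0.15
  db <- domain_blocks(m, list(a = 1:2, b = 3:4))
  inter <- db[db$block_a == "a" & db$block_b == "b", ]
  expect_equal(inter$max_abs_c, 0.2)
  expect_equal(inter$mean_c, mean(c(0.1, -0.2, 0.05, 0.15)))
  intra_a <- db[db$block_a == "a" & db$block_b == "a", ]
  expect_equal(intra_a$max_abs_c, 0.8)

  zero <- diag(4)
  db0 <- domain_blocks(zero, list(a = 1:2, b = 3:4))
  expect_equal(db0[db0$block_a == "a" & db0$block_b == "b", "max_abs_c"], 0)

  expect_error(domain_blocks(m, list(a = 1:3, b = 3:4)), "overlapping")
  expect_error(domain_blocks(m, list(a = integer(0))), "empty")
})

test_that("mode files round-trip through the text format", {
  net <- build_network(rbind(c(0, 0, 0), c(3, 0, 0)))
  md <- compute_modes(net)
  path <- withr::local_tempfile(fileext = ".txt")
  write_modes(md, path)
  txt <- readLines(path)
  expect_true(any(grepl("^MODE 6 38000", txt)))
  back <- read_modes(path, n = 2)
  expect_equal(back$values[1], 2 * 1.9e4, tolerance = 1e-9)
  expect_equal(abs(sum(back$vectors[, 1] * md$vectors[, 6])), 1,
               tolerance = 1e-8)
})
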