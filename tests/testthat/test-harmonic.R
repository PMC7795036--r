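# numerical Hessian of the spring energy E = gamma/2 sum (|ri-rj| - d0)^2
# at the equilibrium geometry, by central differences: an oracle fully
# independent of the analytic super-block assembly
numeric_hessian <- function(xyz, cutoff, gamma = 1, h = 1e-5) {
  n <- nrow(xyz)
  d0 <- as.matrix(dist(xyz))
  contact <- d0 <= cutoff & d0 > 0
  energy <- function(v) {
    X <- matrix(v, n, 3)
    e <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (!contact[i, j]) next
      e <- e + 0.5 * gamma * (sqrt(sum((X[i, ] - X[j, ])^2)) - d0[i, j])^2
    }
    e
  }
  v0 <- as.numeric(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (a in 1:(3 * n)) for (b in a:(3 * n)) {
    vpp <- v0; vpp[a] <- vpp[a] + h; vpp[b] <- vpp[b] + h
    vpm <- v0; vpm[a] <- vpm[a] + h; vpm[b] <- vpm[b] - h
    vmp <- v0; vmp[a] <- vmp[a] - h; vmp[b] <- vmp[b] + h
    vmm <- v0; vmm[a] <- vmm[a] - h; vmm[b] <- vmm[b] - h
    H[a, b] <- H[b, a] <-
      (energy(vpp) - energy(vpm) - energy(vmp) + energy(vmm)) / (4 * h^2)
  }
  # coordinate order differs from the package's (x1..xn,y1..yn,z1..zn vs
  # interleaved); eigenvalues are permutation-invariant so no remapping
  H
}

test_that("a dimer has one stretch mode and five rigid-body modes", {
  m <- build_enm(rbind(c(0, 0, 0), c(5, 0, 0)), cutoff = 13, gamma = 2)
  expect_equal(m$n_zero_modes, 5)
  nz <- m$values[m$values > max(m$values) * 1e-8]
  expect_length(nz, 1)
  expect_equal(nz, 2 * 2)   # stretch eigenvalue = 2 * gamma
})

test_that("triangle eigenvalues match a finite-difference Hessian oracle", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 1.5 * sqrt(3), 0))
  m <- build_enm(xyz, cutoff = 10, gamma = 1.3)
  expect_equal(m$n_zero_modes, 6)
  nz <- m$values[-(1:6)]
  expect_length(nz, 3)
  oracle <- sort(eigen(numeric_hessian(xyz, 10, 1.3),
                       symmetric = TRUE)$values)
  expect_equal(nz, oracle[-(1:6)], tolerance = 1e-4)
})

test_that("eigenvalues are translation invariant; modes orthonormal; PSD", {
  toy <- generate_toy_ensemble(toy_receptor_spec(
    residues_per_helix = 7, n_frames_per_state = 1, noise_sigma = 0, seed = 1))
  xyz <- toy$ensemble$xyz[, , 1]
  m1 <- build_enm(xyz, cutoff = 13)
  m2 <- build_enm(sweep(xyz, 2, c(10, -4, 7), "+"), cutoff = 13)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
  expect_equal(m1$n_zero_modes, 6)
  G <- crossprod(m1$vectors)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  expect_true(all(m1$values >= 0))
})

test_that("a disconnected network is rejected with advice", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(100, 0, 0), c(103, 0, 0))
  expect_error(build_enm(xyz, cutoff = 10), "cutoff")
})

test_that("zero temperature reproduces the reference exactly", {
  m <- build_enm(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(0, 0, 5)),
                 cutoff = 13)
  h <- generate_harmonic_trajectory(m, n_frames = 5, n_modes = 3,
                                    temperature_scale = 0, seed = 1)
  for (f in 1:5)
    expect_equal(h$xyz[, , f], m$ref_xyz, ignore_attr = TRUE)
})

test_that("single-mode trajectories stay in the span of that mode", {
  m <- build_enm(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(0, 0, 5)),
                 cutoff = 13)
  h <- generate_harmonic_trajectory(m, n_frames = 20, n_modes = 1, seed = 2)
  v1 <- m$vectors[, m$n_zero_modes + 1]
  ref <- as.numeric(t(m$ref_xyz))
  for (f in 1:20) {
    d <- as.numeric(t(h$xyz[, , f])) - ref
    cosim <- abs(sum(d * v1)) / sqrt(sum(d^2))
    expect_equal(cosim, 1, tolerance = 1e-10)
  }
  expect_error(generate_harmonic_trajectory(m, n_frames = 5, n_modes = 99),
               "available")
})

test_that("mode amplitudes satisfy equipartition at large frame counts", {
  toy <- generate_toy_ensemble(toy_receptor_spec(
    residues_per_helix = 7, n_frames_per_state = 1, noise_sigma = 0, seed = 1))
  m <- build_enm(toy$ensemble, cutoff = 13)
  nm <- 10; Tsc <- 2
  h <- generate_harmonic_trajectory(m, n_frames = 10000, n_modes = nm,
                                    temperature_scale = Tsc, seed = 5)
  ref <- as.numeric(t(m$ref_xyz))
  D <- vapply(seq_len(n_frames(h)),
              function(f) as.numeric(t(h$xyz[, , f])) - ref,
              numeric(length(ref)))
  A <- t(m$vectors[, m$n_zero_modes + seq_len(nm)]) %*% D
  lam <- m$values[m$n_zero_modes + seq_len(nm)]
  rel_err <- abs(apply(A, 1, var) - Tsc / lam) / (Tsc / lam)
  expect_lt(max(rel_err), 0.05)
  # mean structure within 3 standard errors of the reference (aggregate
  # RMS over coordinates; per-coordinate exceedances are expected by
  # chance among 3N coordinates)
  se <- sqrt(rowSums(sweep(m$vectors[, m$n_zero_modes + seq_len(nm)]^2,
                           2, Tsc / lam, "*")) / 10000)
  expect_lte(sqrt(mean(rowMeans(D)^2)), 3 * sqrt(mean(se^2)))
})

test_that("trajectories are bitwise reproducible under a fixed seed", {
  m <- build_enm(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(0, 0, 5)),
                 cutoff = 13)
  h1 <- generate_harmonic_trajectory(m, n_frames = 10, n_modes = 2, seed = 7)
  h2 <- generate_harmonic_trajectory(m, n_frames = 10, n_modes = 2, seed = 7)
  expect_identical(h1$xyz, h2$xyz)
})

test_that("nonzero eigenvalues agree with an independent ANM implementation", {
  toy <- generate_toy_ensemble(toy_receptor_spec(
    residues_per_helix = 7, n_frames_per_state = 1, noise_sigma = 0, seed = 1))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(toy$ensemble, f)
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  ref <- suppressWarnings(bio3d::nma(pdb, ff = "anm", cutoff = 13,
                                     mass = FALSE, temp = NULL))
  ours <- build_enm(toy$ensemble, cutoff = 13)
  nz_ours <- ours$values[-(1:ours$n_zero_modes)]
  nz_ref <- sort(ref$L[ref$L > 1e-8])
  expect_equal(length(nz_ours), length(nz_ref))
  expect_lt(max(abs(nz_ours - nz_ref) / nz_ours), 1e-3)
})

test_that("two-state harmonic ensembles concatenate and tag states", {
  set.seed(20)
  inact <- matrix(runif(36, 0, 12), 12, 3)
  act <- inact + matrix(rnorm(36, 0, 1), 12, 3)
  ens <- make_two_state_harmonic_ensemble(inact, act,
                                          n_frames_per_state = 20,
                                          cutoff = 15, n_modes = 5,
                                          temperature_scale = 0.1, seed = 3)
  expect_equal(n_frames(ens), 40)
  expect_equal(ens$frames$state, rep(c("inactive", "active"), each = 20))
  solo <- make_two_state_harmonic_ensemble(inact,
                                           n_frames_per_state = 20,
                                           cutoff = 15, n_modes = 5,
                                           temperature_scale = 0.1, seed = 3)
  expect_equal(n_frames(solo), 20)
  expect_true(all(solo$frames$state == "inactive"))
})

test_that("two toy states preserve their activation gap when concatenated", {
  spec <- toy_receptor_spec(n_frames_per_state = 1, noise_sigma = 0, seed = 2)
  toy <- generate_toy_ensemble(spec)
  inact <- toy$ensemble$xyz[, , 1]
  act <- toy$ensemble$xyz[, , 2]
  ens <- make_two_state_harmonic_ensemble(inact, act,
                                          n_frames_per_state = 40,
                                          n_modes = 10,
                                          temperature_scale = 0.05, seed = 9)
  dl <- compute_delta(ens, toy$truth$delta_spec)
  gap <- mean(dl$delta[ens$frames$state == "active"]) -
    mean(dl$delta[ens$frames$state == "inactive"])
  expect_equal(gap, 8, tolerance = 0.2)
})
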