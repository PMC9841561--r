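test_that("toy molecules are reproducibly chiral and mirror into enantiomers", {
  a <- build_toy_system(h_m = 1)
  b <- build_toy_system(h_m = 1)
  expect_identical(a$system$positions, b$system$positions)
  expect_equal(triple_product_handedness(a$system$positions), 1)

  m <- build_toy_system(h_m = -1)
  expect_equal(triple_product_handedness(m$system$positions), -1)
  # the h_m = -1 molecule is exactly the xz-mirror of the h_m = +1 one
  expect_identical(m$system$positions[, 1], a$system$positions[, 1])
  expect_identical(m$system$positions[, 2], -a$system$positions[, 2])
  expect_identical(m$system$positions[, 3], a$system$positions[, 3])
  expect_identical(m$bonds$r0, a$bonds$r0)   # bond lengths mirror-invariant

  flipped <- mirror_reflect(a, "xz")
  expect_equal(flipped$h_m, -1)
  expect_identical(flipped$system$positions, m$system$positions)

  expect_error(build_toy_system(n_atoms = 4), "n_atoms")
  bigger <- build_toy_system(n_atoms = 7, seed = 3)
  expect_equal(n_atoms(bigger$system), 7)
  expect_identical(bigger$system$positions,
                   build_toy_system(n_atoms = 7, seed = 3)$system$positions)
})

test_that("chiral force field: analytic forces match finite differences", {
  mol <- build_toy_system()
  p <- chiral_params()
  ff <- chiral_force_field(p, mol)
  set.seed(5)
  worst <- 0
  for (r in 1:10) {
    x <- mol$system$positions + matrix(rnorm(15, sd = 0.4), 5, 3)
    fa <- ff(x)$forces
    for (i in 1:5) for (ax in 1:3) {
      xp <- x; xp[i, ax] <- xp[i, ax] + 1e-5
      xm <- x; xm[i, ax] <- xm[i, ax] - 1e-5
      fn <- -(ff(xp)$energy - ff(xm)$energy) / 2e-5
      worst <- max(worst, abs(fn - fa[i, ax]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("chiral term is regular on the axis and vanishes with kappa0", {
  mol <- build_toy_system()
  # atom placed exactly on the helix axis: chiral contribution must be zero
  x <- mol$system$positions
  x[1, 1:2] <- 0
  p <- chiral_params()
  f_on <- chiral_surface_force(x, p, mol)
  expect_true(all(is.finite(f_on$forces)))
  p0 <- chiral_params(kappa0 = 1e-300)  # parameter constraint keeps kappa0 finite
  f_off <- chiral_surface_force(x, p0, mol)
  # with the corrugation off, the surface exerts zero torque about the axis
  tau_z <- sum(x[, 1] * f_off$forces[, 2] - x[, 2] * f_off$forces[, 1])
  bond_only <- bond_force_field(mol)(x)
  tau_bond <- sum(x[, 1] * bond_only$forces[, 2] - x[, 2] * bond_only$forces[, 1])
  expect_equal(tau_z, tau_bond, tolerance = 1e-10)
})

test_that("velocity Verlet integrates free flight and a harmonic period", {
  sys <- atomic_system("C", 2, matrix(c(0, 0, 5), 1, 3))
  ff0 <- function(pos) list(forces = matrix(0, 1, 3), energy = 0)
  tr <- velocity_verlet_run(sys, matrix(c(1, 0, 0), 1, 3), ff0,
                            dt = 0.5, n_steps = 10)
  expect_equal(tr$positions[1, 1, 11], 5, tolerance = 1e-14)   # 10 x 0.5 x 1

  # harmonic oscillator over one full analytic period
  k <- 2; m <- 4
  omega <- sqrt(k / m / eV_per_amuA2fs2_test)
  period <- 2 * pi / omega
  sysh <- atomic_system("C", m, matrix(c(0.3, 0, 0), 1, 3))
  ffh <- function(pos) list(forces = cbind(-k * pos[, 1], 0, 0),
                            energy = 0.5 * k * pos[1, 1]^2)
  trh <- velocity_verlet_run(sysh, matrix(0, 1, 3), ffh,
                             dt = period / 1000, n_steps = 1000)
  expect_equal(trh$positions[1, 1, 1001], 0.3, tolerance = 1e-3)

  # surface-tagged atoms stay frozen with zero velocity
  sys2 <- atomic_system(c("C", "Cu"), c(2, 63), rbind(c(0, 0, 3), c(0, 0, 0)),
                        tags = c("adsorbate", "surface"))
  ff1 <- function(pos) list(forces = matrix(1, 2, 3), energy = 0)
  tr2 <- velocity_verlet_run(sys2, matrix(0, 2, 3), ff1, dt = 0.5, n_steps = 4)
  expect_equal(tr2$positions[2, , 5], c(0, 0, 0))
  expect_equal(tr2$velocities[2, , 5], c(0, 0, 0))
  expect_error(velocity_verlet_run(sys, matrix(0, 1, 3), ff0, dt = 0.5,
                                   n_steps = 5, stride = 2), "multiple")
})

test_that("integration aborts with the step index on non-finite forces", {
  sys <- atomic_system("C", 1, matrix(c(0, 0, 1), 1, 3))
  ffbad <- function(pos) {
    if (pos[1, 3] > 1.4) list(forces = matrix(NaN, 1, 3), energy = NaN)
    else list(forces = matrix(c(0, 0, 1), 1, 3), energy = -pos[1, 3])
  }
  expect_error(
    velocity_verlet_run(sys, matrix(c(0, 0, 0.1), 1, 3), ffbad,
                        dt = 0.5, n_steps = 50),
    "at step [0-9]+")
})

test_that("mirror reflection is an exact involution with pseudovector Lz", {
  tr <- random_trajectory(n_atoms = 5, n_frames = 8, seed = 21)
  twice <- mirror_reflect(mirror_reflect(tr, "xz"), "xz")
  expect_identical(twice$positions, tr$positions)
  expect_identical(twice$velocities, tr$velocities)

  for (plane in c("xz", "yz")) {
    m <- mirror_reflect(tr, plane)
    L0 <- angular_momentum_series(tr, exclude = character())
    L1 <- angular_momentum_series(m, exclude = character())
    # Lz flips exactly; the same holds under the second vertical plane
    expect_identical(L1$Lz, -L0$Lz)
    expect_identical(m$meta$h_m, -tr$meta$h_m)
  }
})

test_that("mirrored parameters generate the mirror-image potential", {
  mol <- build_toy_system(h_m = 1)
  p <- chiral_params(phi0 = 0.3, axis_xy = c(0.2, -0.1))
  set.seed(8)
  x <- mol$system$positions + matrix(rnorm(15, sd = 0.3), 5, 3)
  for (plane in c("xz", "yz")) {
    ax <- if (plane == "xz") 2 else 1
    xm <- x; xm[, ax] <- -xm[, ax]
    f1 <- chiral_surface_force(x, p, mol)
    f2 <- chiral_surface_force(xm, mirror_reflect(p, plane),
                               mirror_reflect(mol, plane))
    expect_equal(f2$energy, f1$energy, tolerance = 1e-12)
    fm <- f1$forces; fm[, ax] <- -fm[, ax]
    expect_equal(f2$forces, fm, tolerance = 1e-12)
  }
})

test_that("a groove-guided point mass picks up Lz with the surface sense", {
  # single off-axis light atom bonded to a counterweight on the axis; the
  # helical groove should torque it with a sign set by h_s, and not at all
  # for kappa0 -> 0
  probe_lz <- function(h_s, kappa0 = 0.13) {
    mol <- build_toy_system(h_m = 1)
    p <- chiral_params(kappa0 = kappa0, h_s = h_s)
    v0 <- apply_translational_kick(matrix(0, 5, 3), mol$system, 3)
    tr <- velocity_verlet_run(mol$system, v0, chiral_force_field(p, mol),
                              dt = 0.5, n_steps = 200)
    L <- angular_momentum_series(tr)
    mean(L$Lz[L$time >= 50])
  }
  lz_plus <- probe_lz(+1)
  lz_tiny <- probe_lz(+1, kappa0 = 1e-12)
  expect_gt(abs(lz_plus), 1)
  expect_lt(abs(lz_tiny), 1e-6)
  # note: flipping h_s alone (without mirroring the molecule) changes the
  # diastereomeric pairing, so only the kappa0 -> 0 null is exact here
})

test_that("ensemble generation is deterministic and labelled", {
  p <- chiral_params()
  mol <- build_toy_system()
  e1 <- generate_ensemble(p, mol, n_traj = 3, seeds = 4:6, n_steps = 50)
  e2 <- generate_ensemble(p, mol, n_traj = 3, seeds = 4:6, n_steps = 50)
  expect_identical(e1$trajectories[[2]]$positions, e2$trajectories[[2]]$positions)
  expect_identical(e1$trajectories[[2]]$velocities, e2$trajectories[[2]]$velocities)
  meta <- ensemble_meta(e1)
  expect_equal(meta$seed, 4:6)
  expect_equal(meta$h_m, rep(1, 3))
  expect_equal(meta$kick_energy, rep(1.2 * 5 * p$D, 3))
  expect_error(generate_ensemble(p, mol, n_traj = 2, seeds = 1:3), "one seed")
})
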