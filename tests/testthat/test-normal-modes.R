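test_that("finite-displacement Hessian recovers analytic curvatures", {
  # 1-D harmonic well V = k x^2 / 2 acting on the x coordinate of one atom
  sys <- atomic_system("C", 12, matrix(c(0.3, 0, 2), 1, 3))
  k <- 1
  ff <- function(pos) list(forces = cbind(-k * pos[, 1], 0, 0),
                           energy = 0.5 * k * pos[1, 1]^2)
  H <- finite_displacement_hessian(sys, ff, delta = 0.01)
  expect_equal(H[1, 1], 1, tolerance = 1e-8)
  expect_equal(max(abs(H[-1, ])), 0, tolerance = 1e-10)

  # zero-force free particle: identically zero Hessian
  ff0 <- function(pos) list(forces = matrix(0, nrow(pos), 3), energy = 0)
  expect_equal(max(abs(finite_displacement_hessian(sys, ff0, 0.01))), 0)

  # frozen atoms are not displaced and get zero rows/columns
  sys2 <- atomic_system(c("C", "Cu"), c(12, 63), matrix(0:5, 2, 3),
                        tags = c("adsorbate", "surface"))
  ff2 <- function(pos) list(forces = -pos, energy = 0.5 * sum(pos^2))
  H2 <- finite_displacement_hessian(sys2, ff2, delta = 0.01)
  expect_equal(H2[4:6, ], matrix(0, 3, 6))
  expect_equal(diag(H2)[1:3], rep(1, 3), tolerance = 1e-8)
})

test_that("diatomic stretch frequency matches the analytic value", {
  # equal 1 amu masses, spring k = 1 eV/A^2 along x:
  # omega = sqrt(2 k / m * conv) = 0.13891 rad/fs (conv = 9.6485e-3)
  k <- 1
  H <- matrix(0, 6, 6)
  H[1, 1] <- H[4, 4] <- k
  H[1, 4] <- H[4, 1] <- -k
  nm <- compute_normal_modes(H, masses = c(1, 1))
  omega_expected <- sqrt(2 * k / eV_per_amuA2fs2_test)
  expect_equal(max(nm$omega), omega_expected, tolerance = 1e-10)
  expect_equal(omega_expected, 0.138914, tolerance = 1e-5)
})

test_that("mode eigenvectors are mass-weighted orthonormal", {
  set.seed(2)
  masses <- runif(3, 1, 16)
  A <- matrix(rnorm(81), 9)
  H <- crossprod(A)   # positive definite: a bound minimum
  nm <- compute_normal_modes(H, masses)
  gram <- t(nm$vectors) %*% nm$vectors
  expect_equal(gram, diag(length(nm$omega)), tolerance = 1e-8)
  expect_true(all(diff(nm$omega2) >= -1e-12))   # ascending order
})

test_that("reaction-coordinate flagging follows the saddle structure", {
  H <- saddle_hessian()
  nm <- compute_normal_modes(H, masses = rep(2, 3))
  expect_equal(nm$reaction_coordinate, 1L)
  expect_equal(nm$mode_class[1], "reaction")
  expect_true(nm$omega[1] < 0)

  # a second negative eigenvalue is not a first-order saddle
  H2 <- diag(c(-1, -0.5, rep(1, 7)))
  expect_error(compute_normal_modes(H2, masses = rep(1, 3)), "first-order saddle")

  # no negative eigenvalue: reaction coordinate absent
  nm3 <- compute_normal_modes(diag(9), masses = rep(1, 3))
  expect_true(is.na(nm3$reaction_coordinate))
})

test_that("tr projection yields free modes that span rigid motions", {
  mol <- build_toy_system()
  H <- finite_displacement_hessian(mol$system, bond_force_field(mol),
                                   delta = 0.003)
  nm <- compute_normal_modes(H, mol$system$masses, project_tr = TRUE,
                             positions = mol$system$positions)
  expect_equal(sum(nm$mode_class == "free"), 6)
  expect_equal(sum(nm$mode_class == "vibration"), 9)
  expect_true(all(abs(nm$omega2[nm$mode_class == "free"]) < 1e-8))
})

test_that("equipartition sampler satisfies the exact energy ledger", {
  masses <- rep(2, 3)
  nm <- compute_normal_modes(saddle_hessian(), masses)
  sys <- atomic_system(rep("C", 3), masses, matrix(rnorm(9), 3, 3))
  kT <- kB_test * 300
  for (seed in c(1, 42, 999)) {
    s <- sample_initial_velocities(nm, masses, 300, seed, system = sys)
    osc <- s$mode_class == "vibration"
    # every oscillatory mode carries total energy kT exactly
    expect_equal(s$mode_energies[osc], rep(kT, sum(osc)), tolerance = 1e-12)
    expect_equal(sum(s$mode_energies[osc]), (length(nm$omega) - 1) * kT,
                 tolerance = 1e-12)
    # reaction coordinate: kinetic energy exactly kT/2
    expect_equal(s$mode_kinetic[nm$reaction_coordinate], kT / 2,
                 tolerance = 1e-15)
    # total Cartesian kinetic energy equals the mode ledger
    ke <- 0.5 * sum(masses * rowSums(s$velocities^2)) * eV_per_amuA2fs2_test
    expect_equal(ke, sum(s$mode_kinetic), tolerance = 1e-10)
  }
})

test_that("a seven-mode set at 300 K assigns 6.5 kT in total", {
  # 6 oscillatory modes at kT plus the reaction coordinate at kT/2:
  # 6.5 * 0.0258520 eV = 0.16804 eV
  set.seed(9)
  masses <- rep(1, 3)
  Q <- qr.Q(qr(matrix(rnorm(81), 9)))[, 1:7]
  nm <- structure(
    list(omega = c(-0.1, seq(0.2, 0.7, length.out = 6)),
         omega2 = c(-0.01, seq(0.2, 0.7, length.out = 6)^2),
         vectors = Q, reaction_coordinate = 1L,
         mode_class = c("reaction", rep("vibration", 6)),
         masses = masses, frozen = rep(FALSE, 3)),
    class = "normal_modes")
  # orient the reaction coordinate along +z deterministically
  sys <- atomic_system(rep("C", 3), masses, matrix(0, 3, 3))
  s <- tryCatch(
    sample_initial_velocities(nm, masses, 300, seed = 5, system = sys),
    error = function(e) NULL
  )
  if (is.null(s)) {   # rc may have a zero z projection for this random basis
    nm$vectors[, 1] <- 0
    nm$vectors[3, 1] <- 1   # z of atom 1
    nm$vectors[, 2:7] <- qr.Q(qr(cbind(nm$vectors[, 1], Q[, 2:7])))[, 2:7]
    s <- sample_initial_velocities(nm, masses, 300, seed = 5, system = sys)
  }
  expect_equal(sum(s$mode_energies), 6.5 * kB_test * 300, tolerance = 1e-12)
  expect_equal(6.5 * kB_test * 300, 0.16804, tolerance = 1e-4)
})

test_that("sampling is seed-reproducible, T = 0 is silent, modes round-trip", {
  masses <- rep(2, 3)
  nm <- compute_normal_modes(saddle_hessian(), masses)
  sys <- atomic_system(rep("C", 3), masses, matrix(rnorm(9), 3, 3))
  a <- sample_initial_velocities(nm, masses, 300, 7, system = sys)
  b <- sample_initial_velocities(nm, masses, 300, 7, system = sys)
  expect_identical(a$velocities, b$velocities)
  expect_identical(a$phases, b$phases)

  z <- sample_initial_velocities(nm, masses, 0, 7, system = sys)
  expect_equal(max(abs(z$velocities)), 0)
  expect_error(sample_initial_velocities(nm, masses, -1, 7, system = sys),
               "temperature")

  # velocities projected back onto the modes recover the mode velocities
  qdot <- project_velocities(a$velocities, nm, masses)
  kT_mech <- kB_test * 300 / eV_per_amuA2fs2_test
  osc <- which(nm$mode_class == "vibration")
  expect_equal(qdot[osc], sqrt(2 * kT_mech) * cos(a$phases[osc]),
               tolerance = 1e-10)
})

test_that("fixed_kinetic scheme realises kT kinetic energy per mode", {
  masses <- rep(2, 3)
  nm <- compute_normal_modes(saddle_hessian(), masses)
  sys <- atomic_system(rep("C", 3), masses, matrix(rnorm(9), 3, 3))
  s <- sample_initial_velocities(nm, masses, 300, 3, scheme = "fixed_kinetic",
                                 system = sys)
  osc <- s$mode_class == "vibration"
  expect_equal(s$mode_kinetic[osc], rep(kB_test * 300, sum(osc)),
               tolerance = 1e-12)
})

test_that("reaction-coordinate velocity points toward desorption", {
  masses <- c(2, 2)
  # explicit 2-atom saddle: the negative mode is the z stretch
  H <- matrix(0, 6, 6)
  H[3, 3] <- H[6, 6] <- -0.2
  H[3, 6] <- H[6, 3] <- -0.2  # symmetric z motion has eigenvalue -0.2
  H[1, 1] <- H[2, 2] <- H[4, 4] <- H[5, 5] <- 1
  sys <- atomic_system(c("C", "C"), masses, rbind(c(0, 0, 2), c(0, 0, 3)))
  nm <- compute_normal_modes(H, masses)
  s <- sample_initial_velocities(nm, masses, 300, 1, system = sys)
  com_vz <- sum(masses * s$velocities[, 3]) / sum(masses)
  rc_contrib <- project_velocities(s$velocities, nm, masses)[nm$reaction_coordinate]
  expect_true(rc_contrib != 0)
  # the rc component alone must push the COM upward
  disp <- matrix(nm$vectors[, nm$reaction_coordinate] / sqrt(rep(masses, each = 3)),
                 ncol = 3, byrow = TRUE)
  expect_true(sign(rc_contrib) * sum(masses * disp[, 3]) > 0)
})

test_that("translational kick boosts the adsorbate COM by the exact energy", {
  sys <- atomic_system(c("C", "N", "Cu"), c(44.5, 44.594, 63.5),
                       matrix(rnorm(9), 3, 3),
                       tags = c("adsorbate", "adsorbate", "surface"))
  v0 <- matrix(0, 3, 3)
  v1 <- apply_translational_kick(v0, sys, kick_energy = 1.8)
  m_ads <- 44.5 + 44.594      # 89.094 amu
  expected <- sqrt(2 * 1.8 / eV_per_amuA2fs2_test / m_ads)
  expect_equal(v1[1, 3], expected, tolerance = 1e-12)
  expect_equal(expected, 0.019746, tolerance = 1e-4)   # ~1975 m/s
  expect_equal(v1[3, ], rep(0, 3))                     # surface untouched
  # COM kinetic energy gained is exactly the kick energy
  ke <- 0.5 * m_ads * sum((colSums(sys$masses[1:2] * v1[1:2, ]) / m_ads)^2) *
    eV_per_amuA2fs2_test
  expect_equal(ke, 1.8, tolerance = 1e-12)

  expect_identical(apply_translational_kick(v0, sys, 0), v0)
  vdown <- apply_translational_kick(v0, sys, 1, direction = c(0, 0, -1))
  expect_true(vdown[1, 3] < 0)
})
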