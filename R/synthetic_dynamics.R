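#' Parameters of the synthetic chiral "helical groove" surface potential
#'
#' A conservative stand-in for a first-principles potential-energy surface of
#' a chiral adsorbate on an intrinsically chiral metal face.  Each adsorbate
#' atom at \eqn{(x, y, z)} feels
#' \deqn{V = D(1 - e^{-a(z - z_e)})^2 - D
#'   + \kappa_\mathrm{eff}\, s(\rho)\, e^{-(z - z_e)/\lambda}
#'     \cos(\varphi - h_s \gamma (z - z_e) - \varphi_0),}
#' a Morse attraction in the surface-normal coordinate plus a helical
#' corrugation that winds with height at pitch \eqn{\gamma} and sense
#' \eqn{h_s} (the surface handedness).  \eqn{\varphi} is the azimuth about a
#' vertical helix axis, \eqn{\rho} the lateral distance to it, and
#' \eqn{s(\rho) = 1 - e^{-\rho^2/\rho_0^2}} softens the core so the force is
#' regular on the axis.  Diastereomerism enters through a single scalar,
#' \deqn{\kappa_\mathrm{eff} = \kappa_0 (1 + \beta\, h_m h_s),}
#' so matched handedness (\eqn{h_m h_s = +1}) feels a corrugation
#' \eqn{(1+\beta)/(1-\beta)} times stronger than mismatched.  Intramolecular
#' structure is maintained by harmonic bonds of stiffness `bond_k`.
#'
#' @param D Morse well depth per adsorbate atom, eV.
#' @param a Morse width, 1/angstrom.
#' @param z_e equilibrium height of the Morse well, angstrom.
#' @param kappa0 chiral corrugation amplitude, eV.
#' @param beta diastereomeric contrast in `[0, 1)`.
#' @param lambda decay length of the corrugation with height, angstrom.
#' @param gamma helical pitch, rad/angstrom.
#' @param h_s surface handedness, +1 or -1.
#' @param axis_xy lateral position of the helix axis, angstrom.
#' @param rho0 core-softening radius, angstrom.
#' @param bond_k intramolecular bond stiffness, eV/angstrom^2.
#' @param phi0 azimuthal phase of the groove, rad.
#' @return an object of class `chiral_params`.
#' @export
chiral_params <- function(D = 0.5, a = 1.0, z_e = 2.0, kappa0 = 0.14,
                          beta = 0.8, lambda = 2.0, gamma = 1.0, h_s = 1,
                          axis_xy = c(0, 0), rho0 = 0.5, bond_k = 1,
                          phi0 = 0) {
  stopifnot(D > 0, a > 0, lambda > 0, rho0 > 0, bond_k > 0,
            h_s %in% c(-1, 1), beta >= 0, beta < 1, length(axis_xy) == 2)
  structure(
    list(D = D, a = a, z_e = z_e, kappa0 = kappa0, beta = beta,
         lambda = lambda, gamma = gamma, h_s = h_s,
         axis_xy = as.numeric(axis_xy), rho0 = rho0, bond_k = bond_k,
         phi0 = phi0),
    class = "chiral_params"
  )
}

# Fixed chiral 5-atom template: four light atoms wound along a right-handed
# helix of radius 1.1 A at half the default groove pitch (0.5 vs gamma = 1
# rad/A), plus one heavy counterweight near the axis that puts the COM
# exactly on the helix axis.  The azimuthal offset registers the helix with
# the groove at the build height at the maximum-torque phase
# (build_toy_system passes the offset for its com_height).  The
# matched-handedness molecule spans only (gamma - 0.5) dz of groove phase
# and couples near-coherently; its mirror image spans (gamma + 0.5) dz and
# partially self-cancels.  Both enantiomers therefore respond to the bare
# corrugation (so beta = 0 leaves them statistically alike), while the
# kappa_eff contrast times the coherence ratio separates them at beta > 0.
toy_template <- function(registry_offset = 0) {
  pitch_mol <- 0.5
  zl <- c(-1.05, -0.35, 0.35, 1.05)
  # groove registry: maximum-torque phase at the build height
  reg <- pi / 2 + registry_offset
  phi <- pitch_mol * zl + reg
  rh <- 1.1
  m_light <- 3
  m_heavy <- 24
  lights <- cbind(rh * cos(phi), rh * sin(phi), zl)
  # counterweight cancels the lights' lateral mass moment
  xy_h <- -m_light * colSums(lights[, 1:2]) / m_heavy
  # row order chosen so the first-four-atom triple product is +1
  pos <- rbind(c(xy_h, 0), lights[c(2, 1, 3, 4), ])
  masses <- c(m_heavy, rep(m_light, 4))
  com <- colSums(pos * masses) / sum(masses)
  list(positions = sweep(pos, 2, com), masses = masses)
}

#' Build a reproducible chiral toy molecule
#'
#' A non-planar cluster of point masses joined by all-pairs harmonic bonds
#' whose rest lengths are the build geometry.  Molecular handedness is the
#' sign of the scalar triple product
#' \eqn{(r_2 - r_1)\cdot((r_3 - r_1)\times(r_4 - r_1))}; the
#' \eqn{h_m = -1} molecule is the xz-mirror image (y negated) of the
#' \eqn{h_m = +1} template, so the pair are exact enantiomers.  Atoms beyond
#' the five-atom template are added at seeded reproducible positions.
#'
#' @param n_atoms number of atoms (>= 5: the helical template has four
#'   light atoms plus the axis counterweight).
#' @param h_m requested molecular handedness, +1 or -1.
#' @param com_height initial centre-of-mass height, angstrom.
#' @param seed integer seed for the extra-atom positions (n_atoms > 5).
#' @param axis_xy lateral COM position (the helix axis of the surface
#'   potential by default).
#' @param bond_k bond stiffness, eV/angstrom^2.
#' @return object of class `toy_molecule`: `system` (an [atomic_system()]),
#'   `bonds` (data frame `i, j, r0, k`), `h_m`.
#' @export
build_toy_system <- function(n_atoms = 5, h_m = 1, com_height = 3.3,
                             seed = 1, axis_xy = c(0, 0), bond_k = 1) {
  stopifnot(n_atoms >= 5, h_m %in% c(-1, 1))
  # register the helix with the default groove (gamma = 1, z_e = 2) at the
  # requested start height
  tmpl <- toy_template(registry_offset = com_height - 2.0)
  pos <- tmpl$positions
  masses <- tmpl$masses
  if (n_atoms > 5) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    extra <- matrix(stats::runif(3 * (n_atoms - 5), -0.8, 0.8), ncol = 3)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    pos <- rbind(pos, extra)
    masses <- c(masses, rep(3, n_atoms - 5))
    com <- colSums(pos * masses) / sum(masses)
    pos <- sweep(pos, 2, com)
  }
  if (triple_product_handedness(pos) != 1) pos[, 2] <- -pos[, 2]  # canonical +1
  if (h_m == -1) pos[, 2] <- -pos[, 2]
  # all-pairs bonds at the build geometry
  pairs <- utils::combn(n_atoms, 2)
  bonds <- data.frame(
    i = pairs[1, ], j = pairs[2, ],
    r0 = apply(pairs, 2, function(ij) sqrt(sum((pos[ij[1], ] - pos[ij[2], ])^2))),
    k = bond_k
  )
  pos <- sweep(pos, 2, -c(axis_xy, com_height))   # place COM
  sys <- atomic_system(rep("X", n_atoms), masses, pos,
                       tags = rep("adsorbate", n_atoms))
  mol <- structure(list(system = sys, bonds = bonds, h_m = h_m),
                   class = "toy_molecule")
  stopifnot(triple_product_handedness(sys$positions) == h_m)
  mol
}

#' Handedness of a point cluster by scalar triple product
#'
#' @param positions N x 3 matrix (N >= 4); the first four atoms define the
#'   chirality.
#' @return +1 or -1; errors when the four reference atoms are coplanar.
#' @export
triple_product_handedness <- function(positions) {
  positions <- as_xyz_matrix(positions)
  stopifnot(nrow(positions) >= 4)
  tp <- sum((positions[2, ] - positions[1, ]) *
              cross3(positions[3, ] - positions[1, ],
                     positions[4, ] - positions[1, ]))
  if (abs(tp) < 1e-10) stop("reference atoms are coplanar: no handedness", call. = FALSE)
  sign(tp)
}

#' @export
print.toy_molecule <- function(x, ...) {
  cat("<toy_molecule> ", n_atoms(x$system), " atoms, h_m = ",
      sprintf("%+d", x$h_m), ", ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Forces and potential of the chiral surface + bond network
#'
#' Analytic gradient of the potential described in [chiral_params()], plus
#' the intramolecular harmonic bond terms of the molecule.  The external
#' (surface) terms act on adsorbate-tagged atoms only; surface-tagged atoms
#' get zero force.  The potential depends on positions only, so exact
#' dynamics on it conserve total energy.
#'
#' @param positions N x 3 matrix, angstrom.
#' @param params a [chiral_params()].
#' @param molecule a [build_toy_system()] result (bond table, handedness,
#'   tags).
#' @return `list(forces = <N x 3, eV/A>, energy = <eV>)`.
#' @export
chiral_surface_force <- function(positions, params, molecule) {
  positions <- as_xyz_matrix(positions)
  p <- params
  tags <- molecule$system$tags
  ads <- tags == "adsorbate"
  n <- nrow(positions)
  forces <- matrix(0, n, 3)
  energy <- 0

  kappa_eff <- p$kappa0 * (1 + p$beta * molecule$h_m * p$h_s)

  if (any(ads)) {
    x <- positions[ads, 1]; y <- positions[ads, 2]; z <- positions[ads, 3]
    u <- z - p$z_e
    emu <- exp(-p$a * u)
    energy <- energy + sum(p$D * (1 - emu)^2 - p$D)
    fz <- -2 * p$D * p$a * (1 - emu) * emu

    dx <- x - p$axis_xy[1]; dy <- y - p$axis_xy[2]
    rho2 <- dx^2 + dy^2
    w <- exp(-rho2 / p$rho0^2)
    s <- -expm1(-rho2 / p$rho0^2)          # 1 - exp(-rho^2/rho0^2)
    s_over_rho2 <- ifelse(rho2 > 1e-30, s / rho2, 1 / p$rho0^2)
    phi <- atan2(dy, dx)                   # 0 on the axis; s kills the term there
    psi <- phi - p$h_s * p$gamma * u - p$phi0
    g <- exp(-u / p$lambda)
    cs <- cos(psi); sn <- sin(psi)

    energy <- energy + kappa_eff * sum(s * g * cs)
    sx <- 2 * dx / p$rho0^2 * w
    sy <- 2 * dy / p$rho0^2 * w
    dVdx <- kappa_eff * g * (sx * cs + sn * dy * s_over_rho2)
    dVdy <- kappa_eff * g * (sy * cs - sn * dx * s_over_rho2)
    dVdz <- kappa_eff * s * g * (-cs / p$lambda + p$h_s * p$gamma * sn)

    forces[ads, 1] <- -dVdx
    forces[ads, 2] <- -dVdy
    forces[ads, 3] <- fz - dVdz
  }

  bf <- bond_forces(positions, molecule$bonds)
  forces <- forces + bf$forces
  list(forces = forces, energy = energy + bf$energy)
}

bond_forces <- function(positions, bonds) {
  n <- nrow(positions)
  forces <- matrix(0, n, 3)
  energy <- 0
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    d <- positions[i, ] - positions[j, ]
    r <- sqrt(sum(d^2))
    if (r < 1e-12) stop("coincident bonded atoms", call. = FALSE)
    stretch <- r - bonds$r0[b]
    energy <- energy + 0.5 * bonds$k[b] * stretch^2
    f <- -bonds$k[b] * stretch * d / r
    forces[i, ] <- forces[i, ] + f
    forces[j, ] <- forces[j, ] - f
  }
  list(forces = forces, energy = energy)
}

#' Force-field closures for the toy system
#'
#' `chiral_force_field()` binds parameters and molecule into a
#' `function(positions)` suitable for [velocity_verlet_run()] and
#' [finite_displacement_hessian()].  `bond_force_field()` is the
#' intramolecular (gas-phase) part only, used to build the molecule's
#' internal normal modes.
#'
#' @param params a [chiral_params()].
#' @param molecule a [build_toy_system()] result.
#' @return a function of an N x 3 position matrix returning
#'   `list(forces, energy)`.
#' @export
chiral_force_field <- function(params, molecule) {
  force(params); force(molecule)
  function(positions) chiral_surface_force(positions, params, molecule)
}

#' @rdname chiral_force_field
#' @export
bond_force_field <- function(molecule) {
  bonds <- molecule$bonds
  function(positions) bond_forces(as_xyz_matrix(positions), bonds)
}

#' Velocity-Verlet NVE integration
#'
#' Standard velocity Verlet at fixed `dt`; surface-tagged atoms are held
#' fixed with zero velocity.  Frames (including the initial state) are
#' recorded every `stride` steps; the recorded per-frame potential and
#' kinetic energies are kept in `meta$energy` for conservation checks.
#'
#' @param system an [atomic_system()] providing the initial positions.
#' @param velocities N x 3 initial velocities, A/fs.
#' @param force_field `function(positions) -> list(forces, energy)`.
#' @param dt time step, fs (> 0).
#' @param n_steps number of steps; must be a multiple of `stride`.
#' @param stride frame recording interval in steps.
#' @param meta metadata list attached to the trajectory.
#' @return a [trajectory()].
#' @export
velocity_verlet_run <- function(system, velocities, force_field, dt, n_steps,
                                stride = 1, meta = list()) {
  stopifnot(inherits(system, "atomic_system"), dt > 0, n_steps >= 1)
  if (n_steps %% stride != 0) stop("n_steps must be a multiple of stride", call. = FALSE)
  n <- n_atoms(system)
  v <- as_xyz_matrix(velocities)
  stopifnot(nrow(v) == n)
  x <- system$positions
  frozen <- system$tags == "surface"
  v[frozen, ] <- 0
  inv_m <- .acc_conv / system$masses        # (eV/A)/amu -> A/fs^2
  inv_m[frozen] <- 0

  nrec <- n_steps %/% stride + 1L
  pos <- array(NA_real_, c(n, 3, nrec))
  vel <- array(NA_real_, c(n, 3, nrec))
  epot <- ekin <- numeric(nrec)

  ff <- force_field(x)
  if (!all(is.finite(ff$forces)) || !is.finite(ff$energy)) {
    stop("non-finite forces at step 0", call. = FALSE)
  }
  a <- ff$forces * inv_m
  rec <- 1L
  record <- function(k) {
    pos[, , rec] <<- x
    vel[, , rec] <<- v
    epot[rec] <<- ff$energy
    ekin[rec] <<- 0.5 * sum(system$masses * rowSums(v^2)) * .eV_per_amuA2fs2
    rec <<- rec + 1L
  }
  record(0L)
  for (k in seq_len(n_steps)) {
    vh <- v + 0.5 * dt * a
    vh[frozen, ] <- 0
    x <- x + dt * vh
    ff <- force_field(x)
    if (!all(is.finite(ff$forces)) || !is.finite(ff$energy)) {
      stop("non-finite energy/forces at step ", k, call. = FALSE)
    }
    a <- ff$forces * inv_m
    v <- vh + 0.5 * dt * a
    v[frozen, ] <- 0
    if (k %% stride == 0L) record(k)
  }
  times <- (0:(nrec - 1L)) * dt * stride
  meta$energy <- tibble::tibble(time = times, potential = epot, kinetic = ekin,
                                total = epot + ekin)
  trajectory(system, times, pos, vel, meta = meta)
}

#' Mirror reflection through a vertical plane
#'
#' Reflects positions and velocities through the xz plane (y -> -y) or yz
#' plane (x -> -x); both contain the surface normal, which mirror symmetry
#' arguments require (a horizontal mirror would turn the surface upside
#' down, so it is rejected).  Handedness metadata (`h_m`, `h_s`) is negated.
#' For `chiral_params` the returned parameter set generates exactly the
#' mirror-image potential: `h_s` flips, the helix axis and azimuthal phase
#' transform accordingly.  Angular momentum is a pseudovector, so the
#' component parallel to the mirror plane (here \eqn{L_z}) changes sign
#' under the reflection while the in-plane behaviour is preserved.
#'
#' @param obj an `atomic_system`, `trajectory`, `toy_molecule`,
#'   `chiral_params`, or `ensemble`.
#' @param plane `"xz"` or `"yz"`.
#' @return an object of the same class, reflected.
#' @export
mirror_reflect <- function(obj, plane = c("xz", "yz")) {
  plane <- match.arg(plane)
  UseMethod("mirror_reflect")
}

mirror_axis <- function(plane) if (plane == "xz") 2L else 1L

#' @export
mirror_reflect.atomic_system <- function(obj, plane = c("xz", "yz")) {
  plane <- match.arg(plane)
  ax <- mirror_axis(plane)
  obj$positions[, ax] <- -obj$positions[, ax]
  if (!is.null(obj$cell)) obj$cell[, ax] <- -obj$cell[, ax]
  obj
}

#' @export
mirror_reflect.trajectory <- function(obj, plane = c("xz", "yz")) {
  plane <- match.arg(plane)
  ax <- mirror_axis(plane)
  obj$system <- mirror_reflect(obj$system, plane)
  obj$positions[, ax, ] <- -obj$positions[, ax, ]
  obj$velocities[, ax, ] <- -obj$velocities[, ax, ]
  for (key in c("h_m", "h_s")) {
    if (!is.null(obj$meta[[key]])) obj$meta[[key]] <- -obj$meta[[key]]
  }
  obj
}

#' @export
mirror_reflect.toy_molecule <- function(obj, plane = c("xz", "yz")) {
  plane <- match.arg(plane)
  obj$system <- mirror_reflect(obj$system, plane)
  obj$h_m <- -obj$h_m
  obj
}

#' @export
mirror_reflect.chiral_params <- function(obj, plane = c("xz", "yz")) {
  plane <- match.arg(plane)
  obj$h_s <- -obj$h_s
  if (plane == "xz") {
    obj$axis_xy[2] <- -obj$axis_xy[2]
    obj$phi0 <- -obj$phi0
  } else {
    obj$axis_xy[1] <- -obj$axis_xy[1]
    obj$phi0 <- pi - obj$phi0
  }
  obj
}

#' @export
mirror_reflect.ensemble <- function(obj, plane = c("xz", "yz")) {
  plane <- match.arg(plane)
  obj$trajectories <- lapply(obj$trajectories, mirror_reflect, plane = plane)
  obj
}

#' Generate a seeded NVE desorption ensemble on the toy potential
#'
#' For each seed: the molecule's internal normal modes (finite-displacement
#' Hessian of the bond network, rigid translations/rotations projected out)
#' receive equipartition energies with random phases via
#' [sample_initial_velocities()]; the free rigid-body directions receive
#' thermal kinetic energy by the same phase rule; a translational kick along
#' +z boosts the COM by `kick_energy`; the system is then propagated with
#' [velocity_verlet_run()] on the full chiral-surface + bond potential.
#'
#' The default kick, 1.2 x D per adsorbate atom, exceeds the total binding
#' well (n_ads x D) by 20 percent so that most trajectories desorb, mirroring
#' the high-energy-tail focus of desorption sampling.
#'
#' Initial velocities are sampled in a handedness-canonical frame: for an
#' `h_m = -1` molecule the modes are built on its xz-mirror image and the
#' sampled velocities are reflected back.  Enantiomers therefore get exactly
#' mirror-related initial conditions under matched seeds (an independent
#' diagonalisation of the mirrored Hessian would break the symmetry at
#' machine precision through eigenvector sign/rotation freedom), and since
#' the force field is exactly mirror-equivariant, the whole ensemble obeys
#' mirror(generate(params, mol)) = generate(mirror(params), mirror(mol))
#' frame by frame to floating-point roundoff.
#'
#' @param params a [chiral_params()].
#' @param molecule a [build_toy_system()] result (its `h_m` and geometry are
#'   used as the shared start of all trajectories).
#' @param n_traj number of trajectories.
#' @param temperature kelvin.
#' @param kick_energy eV; default `1.2 * n_ads * params$D`.
#' @param seeds integer vector, one per trajectory; default `seq_len(n_traj)`.
#' @param dt,n_steps,stride integration schedule (default 400 x 0.5 fs).
#' @param delta finite-displacement step for the internal-mode Hessian,
#'   angstrom.
#' @param scheme phase-sampling scheme, see [sample_initial_velocities()].
#' @param label ensemble label.
#' @return an [ensemble()]; each trajectory's `meta` records `seed`, `h_m`,
#'   `h_s`, `kick_energy` and `kappa_eff`.
#' @export
generate_ensemble <- function(params, molecule, n_traj = 48, temperature = 300,
                              kick_energy = NULL, seeds = NULL, dt = 0.5,
                              n_steps = 400, stride = 1, delta = 0.003,
                              scheme = "total_energy_phase", label = "") {
  stopifnot(inherits(params, "chiral_params"), inherits(molecule, "toy_molecule"))
  if (is.null(seeds)) seeds <- seq_len(n_traj)
  if (length(seeds) != n_traj) stop("need one seed per trajectory", call. = FALSE)
  sys <- molecule$system
  n_ads <- sum(sys$tags == "adsorbate")
  if (is.null(kick_energy)) kick_energy <- 1.2 * n_ads * params$D

  # internal modes are identical for every trajectory: compute once, in the
  # handedness-canonical (h_m = +1) frame for exact enantiomer symmetry
  canon <- if (molecule$h_m == -1) mirror_reflect(molecule, "xz") else molecule
  H <- finite_displacement_hessian(canon$system, bond_force_field(canon),
                                   delta = delta)
  modes <- compute_normal_modes(H, canon$system$masses, project_tr = TRUE,
                                positions = canon$system$positions)
  ff <- chiral_force_field(params, molecule)
  kappa_eff <- params$kappa0 * (1 + params$beta * molecule$h_m * params$h_s)

  trajs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    samp <- tryCatch(
      sample_initial_velocities(modes, sys$masses, temperature, seeds[i],
                                scheme = scheme, system = canon$system),
      error = function(e) stop("trajectory ", i, ": ", conditionMessage(e), call. = FALSE)
    )
    vs <- samp$velocities
    if (molecule$h_m == -1) vs[, 2] <- -vs[, 2]
    v0 <- apply_translational_kick(vs, sys, kick_energy)
    trajs[[i]] <- tryCatch(
      velocity_verlet_run(sys, v0, ff, dt = dt, n_steps = n_steps,
                          stride = stride,
                          meta = list(seed = seeds[i], h_m = molecule$h_m,
                                      h_s = params$h_s, kick_energy = kick_energy,
                                      kappa_eff = kappa_eff,
                                      temperature = temperature)),
      error = function(e) stop("trajectory ", i, ": ", conditionMessage(e), call. = FALSE)
    )
  }
  ensemble(trajs, label = label)
}
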