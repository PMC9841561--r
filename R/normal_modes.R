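#' Hessian by central finite displacement of a force field
#'
#' \eqn{H_{ab} = -(F_a(x + \delta e_b) - F_a(x - \delta e_b)) / (2\delta)},
#' symmetrised.  Only mobile (non-frozen) atoms are displaced; rows and
#' columns of frozen coordinates are zero.
#'
#' @param system an [atomic_system()].
#' @param force_field function of an N x 3 position matrix returning
#'   `list(forces = <N x 3, eV/A>, energy = <eV>)`.
#' @param delta displacement step in angstrom (> 0).
#' @param frozen logical mask of frozen atoms; defaults to the
#'   surface-tagged atoms.
#' @return 3N x 3N symmetric Hessian in eV/A^2.
#' @export
finite_displacement_hessian <- function(system, force_field, delta = 0.01,
                                        frozen = system$tags == "surface") {
  stopifnot(inherits(system, "atomic_system"), delta > 0)
  n <- n_atoms(system)
  stopifnot(length(frozen) == n)
  mobile <- which(!frozen)
  H <- matrix(0, 3 * n, 3 * n)
  x0 <- system$positions
  for (i in mobile) {
    for (ax in 1:3) {
      b <- 3L * (i - 1L) + ax
      xp <- x0; xp[i, ax] <- xp[i, ax] + delta
      xm <- x0; xm[i, ax] <- xm[i, ax] - delta
      fp <- force_field(xp)$forces
      fm <- force_field(xm)$forces
      if (!all(is.finite(fp)) || !all(is.finite(fm))) {
        stop("force evaluation failed at coordinate (atom ", i, ", axis ", ax, ")",
             call. = FALSE)
      }
      col <- -(t(fp) - t(fm)) / (2 * delta)   # 3 x N, coordinate-major
      H[, b] <- as.numeric(col)
    }
  }
  # zero out frozen rows too, then symmetrise
  if (length(mobile) < n) {
    frozen_ix <- as.numeric(vapply(which(frozen), function(i) 3 * (i - 1) + 1:3, numeric(3)))
    H[frozen_ix, ] <- 0
  }
  (H + t(H)) / 2
}

#' Normal modes of a mass-weighted Hessian
#'
#' Diagonalises \eqn{M^{-1/2} H M^{-1/2}}.  Eigenvalues are converted to
#' angular frequencies in rad/fs; an imaginary mode (negative eigenvalue) is
#' stored with negative `omega` as a flag.  When exactly one eigenvalue lies
#' below `-imag_tol` it is flagged as the reaction coordinate of a
#' first-order saddle; two or more is an error; none leaves the reaction
#' coordinate absent.  Modes with \eqn{|\omega^2|} below `zero_tol` are
#' classified `"free"` (rigid translations/rotations or frozen directions).
#'
#' @param hessian 3N x 3N Cartesian Hessian, eV/A^2.
#' @param masses per-atom masses, amu.
#' @param frozen logical per-atom mask; frozen coordinates are excluded from
#'   the diagonalisation and appear as zero rows of the eigenvectors.
#' @param project_tr project out rigid translations (and rotations when
#'   `positions` is given) before diagonalising; gas-phase systems only.
#' @param positions N x 3 geometry, needed to project rotations.
#' @param imag_tol threshold on \eqn{-\omega^2} (rad^2/fs^2) separating a
#'   genuine imaginary mode from numerical noise.
#' @param zero_tol threshold on \eqn{|\omega^2|} below which a mode counts
#'   as free.
#' @return object of class `normal_modes`: `omega` (rad/fs, sorted ascending
#'   by \eqn{\omega^2}, negative = imaginary), `omega2` (rad^2/fs^2),
#'   `vectors` (3N x M mass-weighted orthonormal columns),
#'   `reaction_coordinate` (index or `NA`), `mode_class`
#'   (`"reaction"`/`"vibration"`/`"free"`), `masses`, `frozen`.
#' @export
compute_normal_modes <- function(hessian, masses, frozen = NULL,
                                 project_tr = FALSE, positions = NULL,
                                 imag_tol = 1e-6, zero_tol = 1e-8) {
  n <- length(masses)
  stopifnot(nrow(hessian) == 3 * n, ncol(hessian) == 3 * n)
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  mobile_coord <- rep(!frozen, each = 3)
  m3 <- rep(masses, each = 3)
  inv_sqrt_m <- ifelse(mobile_coord, 1 / sqrt(m3), 0)
  Hm <- hessian * outer(inv_sqrt_m, inv_sqrt_m)   # eV/(A^2 amu)
  Hm <- Hm[mobile_coord, mobile_coord, drop = FALSE]

  if (project_tr) {
    P <- tr_projector(masses[!frozen], if (!is.null(positions)) positions[!frozen, , drop = FALSE])
    Hm <- P %*% Hm %*% P
    Hm <- (Hm + t(Hm)) / 2
  }

  eig <- eigen(Hm, symmetric = TRUE)
  ord <- order(eig$values)                         # ascending omega^2
  lambda <- eig$values[ord]
  vecs_m <- eig$vectors[, ord, drop = FALSE]

  omega2 <- lambda * .acc_conv   # eV/(A^2 amu) -> rad^2/fs^2 (x 9.6485e-3)
  omega <- sign(omega2) * sqrt(abs(omega2))

  imag <- which(omega2 < -imag_tol)
  if (length(imag) >= 2) {
    stop("not a first-order saddle: ", length(imag),
         " imaginary modes beyond tolerance", call. = FALSE)
  }
  rc <- if (length(imag) == 1) imag else NA_integer_

  mode_class <- ifelse(abs(omega2) <= zero_tol, "free", "vibration")
  if (!is.na(rc)) mode_class[rc] <- "reaction"

  # embed back into full 3N coordinate space (zeros on frozen coordinates)
  vectors <- matrix(0, 3 * n, ncol(vecs_m))
  vectors[mobile_coord, ] <- vecs_m

  structure(
    list(omega = omega, omega2 = omega2, vectors = vectors,
         reaction_coordinate = rc, mode_class = mode_class,
         masses = masses, frozen = frozen),
    class = "normal_modes"
  )
}

# orthogonal projector removing rigid translations (and rotations when
# positions are supplied) from mass-weighted coordinate space
tr_projector <- function(masses, positions = NULL) {
  n <- length(masses)
  sm <- sqrt(masses)
  basis <- list()
  for (ax in 1:3) {
    v <- matrix(0, n, 3); v[, ax] <- sm
    basis[[length(basis) + 1]] <- as.numeric(t(v))
  }
  if (!is.null(positions)) {
    com <- colSums(positions * masses) / sum(masses)
    rel <- sweep(positions, 2, com)
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- 1
      # mass-weighted rigid rotation about axis `ax` through the COM
      v <- t(vapply(seq_len(n), function(i) sm[i] * cross3(e, rel[i, ]), numeric(3)))
      basis[[length(basis) + 1]] <- as.numeric(t(v))
    }
  }
  B <- do.call(cbind, basis)
  # orthonormalise, dropping null vectors (e.g. rotation about a linear axis)
  q <- qr(B)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  diag(nrow(Q)) - Q %*% t(Q)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("<normal_modes> ", length(x$omega), " modes (",
      sum(x$mode_class == "vibration"), " vibrational, ",
      sum(x$mode_class == "free"), " free",
      if (!is.na(x$reaction_coordinate)) ", 1 reaction coordinate", ")\n", sep = "")
  invisible(x)
}

#' Equipartition initial velocities with random phases
#'
#' Implements transition-state equipartition sampling at temperature T: every
#' oscillatory mode carries total energy \eqn{k_B T}, split between kinetic
#' and potential parts by a uniformly random phase \eqn{\varphi}; only the
#' kinetic part \eqn{k_B T \cos^2\varphi} is realised as a mass-weighted
#' mode velocity \eqn{\dot q = \sqrt{2 k_B T}\cos\varphi} and no positional
#' displacement is applied (the system starts exactly at the sampled
#' geometry).  The reaction coordinate, a single quadratic degree of freedom,
#' receives kinetic energy exactly \eqn{k_B T / 2}, directed toward
#' desorption (positive projection of the mode on the adsorbate
#' centre-of-mass z direction).  Free modes (rigid-body directions) follow
#' the same velocity rule as oscillatory modes; their assigned energy is
#' purely kinetic.
#'
#' With `scheme = "fixed_kinetic"` each oscillatory/free mode instead gets
#' kinetic energy exactly \eqn{k_B T}, the phase contributing only the sign
#' of the velocity.
#'
#' @param modes a [compute_normal_modes()] result.
#' @param masses per-atom masses, amu.
#' @param temperature kelvin (>= 0).
#' @param seed integer RNG seed; phases are drawn in fixed mode order so a
#'   seed reproduces the sample bit-for-bit.
#' @param scheme `"total_energy_phase"` (default) or `"fixed_kinetic"`.
#' @param require_rc error when no reaction coordinate is flagged.
#' @param system optional [atomic_system()]; needed to orient the reaction
#'   coordinate (adsorbate COM z projection).
#' @return object of class `velocity_sample`: `velocities` (N x 3, A/fs),
#'   `phases`, `mode_energies` (eV; total for oscillatory modes, kinetic for
#'   free modes), `mode_kinetic` (eV), `mode_class`, `temperature`, `seed`,
#'   `scheme`.
#' @export
sample_initial_velocities <- function(modes, masses, temperature, seed,
                                      scheme = c("total_energy_phase", "fixed_kinetic"),
                                      require_rc = FALSE, system = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(modes, "normal_modes"))
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  rc <- modes$reaction_coordinate
  if (require_rc && is.na(rc)) {
    stop("no reaction coordinate flagged in the mode set", call. = FALSE)
  }
  M <- length(modes$omega)
  kT <- kBT_eV(temperature)
  kT_mech <- kT * .acc_conv                 # eV -> amu A^2/fs^2

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  phases <- stats::runif(M, 0, 2 * pi)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())

  qdot <- numeric(M)
  mode_energy <- numeric(M)
  mode_kin <- numeric(M)
  for (m in seq_len(M)) {
    if (!is.na(rc) && m == rc) next
    amp <- switch(scheme,
      total_energy_phase = sqrt(2 * kT_mech) * cos(phases[m]),
      fixed_kinetic = sqrt(2 * kT_mech) * sign(cos(phases[m]))
    )
    qdot[m] <- amp
    mode_kin[m] <- 0.5 * amp^2 * .eV_per_amuA2fs2
    mode_energy[m] <- if (modes$mode_class[m] == "vibration" &&
                          scheme == "total_energy_phase") kT else mode_kin[m]
  }
  if (!is.na(rc)) {
    phases[rc] <- NA_real_
    dir <- rc_direction_sign(modes, masses, rc, system)
    qdot[rc] <- dir * sqrt(kT_mech)         # KE = kT/2 exactly
    mode_kin[rc] <- kT / 2
    mode_energy[rc] <- kT / 2
  }

  # Cartesian velocities: v = M^(-1/2) sum_m qdot_m e_m
  m3 <- rep(masses, each = 3)
  vcart <- as.numeric(modes$vectors %*% qdot) / sqrt(m3)
  velocities <- matrix(vcart, ncol = 3, byrow = TRUE)

  structure(
    list(velocities = velocities, phases = phases,
         mode_energies = mode_energy, mode_kinetic = mode_kin,
         mode_class = modes$mode_class, temperature = temperature,
         seed = as.integer(seed), scheme = scheme),
    class = "velocity_sample"
  )
}

# sign of the reaction-coordinate mode projected on the adsorbate COM z
rc_direction_sign <- function(modes, masses, rc, system) {
  e <- modes$vectors[, rc]
  disp <- matrix(e / sqrt(rep(masses, each = 3)), ncol = 3, byrow = TRUE)
  ads <- if (!is.null(system)) system$tags == "adsorbate" else rep(TRUE, length(masses))
  proj <- sum(masses[ads] * disp[ads, 3]) / sum(masses[ads])
  if (abs(proj) < 1e-12) {
    stop("reaction coordinate has zero projection on the adsorbate z direction; ",
         "cannot orient the desorption velocity", call. = FALSE)
  }
  sign(proj)
}

#' Project Cartesian velocities back onto a mode basis
#'
#' Inverse of the expansion used by [sample_initial_velocities()]:
#' \eqn{\dot q = E^T M^{1/2} v}.  Used by the round-trip invariants.
#'
#' @param velocities N x 3 velocities, A/fs.
#' @param modes a [compute_normal_modes()] result.
#' @param masses per-atom masses, amu.
#' @return numeric vector of mass-weighted mode velocities.
#' @export
project_velocities <- function(velocities, modes, masses) {
  v <- as.numeric(t(velocities))
  as.numeric(t(modes$vectors) %*% (v * sqrt(rep(masses, each = 3))))
}

#' Add a translational kick to the adsorbate centre of mass
#'
#' Boosts every adsorbate-tagged atom by the same velocity
#' \eqn{v = \sqrt{2 E / M_\mathrm{ads}}} along `direction`, so that the
#' adsorbate COM kinetic energy increases by exactly `kick_energy` when the
#' COM was previously at rest.  Surface and transferring-H atoms are
#' untouched.  This mirrors the extra translational energy along the surface
#' normal that desorption sampling assigns on top of the thermal mode
#' energies.
#'
#' @param velocities N x 3 velocity matrix (A/fs) or a `velocity_sample`.
#' @param system the [atomic_system()] (provides masses and tags).
#' @param kick_energy energy in eV (>= 0).
#' @param direction 3-vector, normalised internally; default +z (outward
#'   surface normal).
#' @return same type as `velocities`, with the boost applied.
#' @export
apply_translational_kick <- function(velocities, system, kick_energy,
                                     direction = c(0, 0, 1)) {
  stopifnot(kick_energy >= 0)
  is_sample <- inherits(velocities, "velocity_sample")
  v <- if (is_sample) velocities$velocities else velocities
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a nonzero vector", call. = FALSE)
  direction <- direction / nrm
  ads <- system$tags == "adsorbate"
  M <- sum(system$masses[ads])
  if (M <= 0) stop("zero adsorbate mass", call. = FALSE)
  speed <- sqrt(2 * kick_energy * .acc_conv / M)   # A/fs
  v[ads, ] <- v[ads, , drop = FALSE] + rep(speed * direction, each = sum(ads))
  if (is_sample) {
    velocities$velocities <- v
    velocities$kick_energy <- kick_energy
    velocities
  } else v
}
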