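# Independent oracles and fixture builders shared across test files.

# brute-force angular momentum about the subset COM, term by term, written
# independently of the package implementation (explicit loops, no sweep/
# matrix tricks); returns a T x 3 matrix in amu A^2/fs
oracle_angular_momentum <- function(positions, velocities, masses, mask) {
  nt <- dim(positions)[3]
  out <- matrix(0, nt, 3)
  idx <- which(mask)
  M <- sum(masses[idx])
  for (k in seq_len(nt)) {
    R <- c(0, 0, 0); V <- c(0, 0, 0)
    for (i in idx) {
      R <- R + masses[i] * positions[i, , k]
      V <- V + masses[i] * velocities[i, , k]
    }
    R <- R / M; V <- V / M
    L <- c(0, 0, 0)
    for (i in idx) {
      r <- positions[i, , k] - R
      v <- velocities[i, , k] - V
      L <- L + masses[i] * c(r[2] * v[3] - r[3] * v[2],
                             r[3] * v[1] - r[1] * v[3],
                             r[1] * v[2] - r[2] * v[1])
    }
    out[k, ] <- L
  }
  out
}

# naive direct evaluation of the Cramer-von Mises sum (no vectorisation)
oracle_cvm <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  acc <- 1 / (12 * n)
  for (i in seq_len(n)) acc <- acc + (cdf(x[i]) - (2 * i - 1) / (2 * n))^2
  acc
}

# random gas-phase trajectory fixture with reproducible contents
random_trajectory <- function(n_atoms = 6, n_frames = 10, seed = 1,
                              tags = rep("adsorbate", n_atoms)) {
  set.seed(seed)
  sys <- atomic_system(
    symbols = rep("C", n_atoms),
    masses = runif(n_atoms, 1, 20),
    positions = matrix(rnorm(3 * n_atoms, sd = 2), n_atoms, 3),
    tags = tags
  )
  pos <- array(rnorm(3 * n_atoms * n_frames, sd = 2), c(n_atoms, 3, n_frames))
  vel <- array(rnorm(3 * n_atoms * n_frames, sd = 0.05), c(n_atoms, 3, n_frames))
  pos[, , 1] <- sys$positions
  trajectory(sys, times = (seq_len(n_frames) - 1) * 0.5, pos, vel,
             meta = list(seed = seed, h_m = 1, h_s = 1))
}

# symmetric full-rank mass-weighted test Hessian with a single negative
# eigenvalue whose eigenvector has a nonzero adsorbate-z projection
saddle_hessian <- function(n_atoms = 3, masses = rep(2, n_atoms), seed = 4) {
  set.seed(seed)
  n3 <- 3 * n_atoms
  Q <- qr.Q(qr(matrix(rnorm(n3 * n3), n3)))
  lambda <- c(-0.4, seq(0.5, 2, length.out = n3 - 1))
  Hm <- Q %*% diag(lambda) %*% t(Q)
  # undo the mass weighting so compute_normal_modes reapplies it
  sm <- sqrt(rep(masses, each = 3))
  H <- Hm * outer(sm, sm)
  (H + t(H)) / 2
}

# energy/unit conversion constants recomputed from CODATA values so tests
# do not depend on the package internals
kB_test <- 8.617333262e-5
eV_per_amuA2fs2_test <- 1.66053906660e-27 * 1e10 / 1.602176634e-19
au_per_amuA2fs_test <- 1.66053906660e-32 / 1.054571817e-34
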