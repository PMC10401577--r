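# Synthetic inputs with known answers: toy polar molecular crystals with
# harmonic force fields and Born charges, Langevin dynamics on them,
# two-well torsion dynamics, and Ornstein-Uhlenbeck dipole processes.

#' Build a toy polar molecular crystal with a harmonic force field
#'
#' Molecules are triangles of three beads (generic element "X") carrying
#' charges that sum to zero, arranged in a chain along the a axis with
#' periodic closure. All intramolecular bead pairs are joined by springs of
#' constant \code{springs[1]}; neighbouring molecules (including the
#' boundary-crossing closure and same-molecule images along b and c) are
#' joined by springs of constant \code{springs[2]}. Spring networks yield a
#' symmetric, positive-semidefinite, sum-rule-obeying force-constant matrix
#' whose only zero modes are the three uniform translations (molecular
#' orientations are jittered by the seed to break accidental degeneracies).
#' Born charges are isotropic per-bead charge tensors; the cell is
#' charge-neutral, so at least one optical mode is IR active.
#'
#' @param n_molecules number of molecules in the cell (>= 1).
#' @param springs numeric length-2, c(intra, inter) spring constants in
#'   eV/Angstrom^2.
#' @param charges numeric length-3 bead charges in e, summing to zero.
#' @param mass bead mass in amu (default 10).
#' @param seed integer seed for the orientation jitter.
#' @return object of class \code{toy_system}: \code{crystal},
#'   \code{force_constants} (3N x 3N, eV/A^2), \code{born} (3 x 3 x N),
#'   \code{eps_inf}, \code{masses}, \code{torsion_potential} (the default
#'   two-well coefficients), \code{seed}.
#' @export
make_toy_molecular_crystal <- function(n_molecules = 4,
                                       springs = c(intra = 20, inter = 2),
                                       charges = c(0.4, 0.4, -0.8),
                                       mass = 10, seed = 1) {
  stopifnot(n_molecules >= 1, springs[1] > 0, springs[2] >= 0,
            abs(sum(charges)) < 1e-12, length(charges) == 3)
  spacing <- 4.0
  cell <- diag(c(spacing * n_molecules, 5.0, 5.0))
  template <- rbind(c(0, 0, 0), c(1.0, 0, 0), c(0.5, sqrt(3) / 2, 0))
  cart <- NULL
  with_seed(seed, {
    for (m in seq_len(n_molecules)) {
      # small random proper rotation to break degeneracies
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- rodrigues(ax, stats::runif(1, 0.1, 0.6))
      pos <- template %*% t(R)
      pos <- sweep(pos, 2, c((m - 0.5) * spacing, 2.5, 2.5), "+")
      cart <- rbind(cart, pos)
    }
  })
  n <- 3 * n_molecules
  molecules <- split(seq_len(n), rep(seq_len(n_molecules), each = 3))
  cr <- crystal(cell, rep("X", n), cart_to_frac(cart, cell),
                molecules = molecules, provenance = "toy polar crystal")
  frac <- cr$frac

  fc <- matrix(0, 3 * n, 3 * n)
  add_spring <- function(i, j, k) {
    if (i == j || k == 0) return(invisible())
    d <- min_image_vec(frac[i, ], frac[j, ], cell)
    nh <- d / sqrt(sum(d^2))
    blk <- k * tcrossprod(nh)
    ii <- (i - 1) * 3 + 1:3; jj <- (j - 1) * 3 + 1:3
    fc[ii, ii] <<- fc[ii, ii] + blk
    fc[jj, jj] <<- fc[jj, jj] + blk
    fc[ii, jj] <<- fc[ii, jj] - blk
    fc[jj, ii] <<- fc[jj, ii] - blk
  }
  for (m in seq_len(n_molecules)) {
    b <- (m - 1) * 3
    add_spring(b + 1, b + 2, springs[1])
    add_spring(b + 2, b + 3, springs[1])
    add_spring(b + 1, b + 3, springs[1])
  }
  if (springs[2] > 0) {
    for (m in seq_len(n_molecules)) {
      b <- (m - 1) * 3
      nb <- (m %% n_molecules) * 3
      if (n_molecules > 1) {
        for (p in 1:3) add_spring(b + p, nb + p, springs[2])
        add_spring(b + 1, nb + 2, springs[2])
        add_spring(b + 2, nb + 3, springs[2])
      }
      # couplings to own images along b and c (between different beads, so
      # they survive at the Gamma point and pin rigid rotations)
      ofs_y <- frac[b + 2, ] + c(0, 1, 0)
      dy <- frac_to_cart(ofs_y - frac[b + 1, ], cell)
      nh <- as.numeric(dy) / sqrt(sum(dy^2))
      blk <- springs[2] * tcrossprod(nh)
      ii <- b * 3 + 1:3; jj <- (b + 1) * 3 + 1:3
      fc[ii, ii] <- fc[ii, ii] + blk
      fc[jj, jj] <- fc[jj, jj] + blk
      fc[ii, jj] <- fc[ii, jj] - blk
      fc[jj, ii] <- fc[jj, ii] - blk
      ofs_z <- frac[b + 3, ] + c(0, 0, 1)
      dz <- frac_to_cart(ofs_z - frac[b + 1, ], cell)
      nh <- as.numeric(dz) / sqrt(sum(dz^2))
      blk <- springs[2] * tcrossprod(nh)
      jj <- (b + 2) * 3 + 1:3
      fc[ii, ii] <- fc[ii, ii] + blk
      fc[jj, jj] <- fc[jj, jj] + blk
      fc[ii, jj] <- fc[ii, jj] - blk
      fc[jj, ii] <- fc[jj, ii] - blk
    }
  }
  born <- array(0, c(3, 3, n))
  for (m in seq_len(n_molecules)) {
    for (p in 1:3) born[, , (m - 1) * 3 + p] <- diag(3) * charges[p]
  }
  structure(list(crystal = cr, force_constants = fc, born = born,
                 eps_inf = 2.5, masses = rep(mass, n),
                 torsion_potential = two_well_coefficients(),
                 springs = springs, charges = charges, seed = seed),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy_system: %d molecules (%d beads), springs intra=%g inter=%g eV/A^2\n",
              length(x$crystal$molecules), length(x$masses),
              x$springs[1], x$springs[2]))
  invisible(x)
}

#' Gamma phonons of a toy system
#'
#' Thin wrapper handing the system's force constants, masses, Born charges
#' and dielectric baseline to \code{\link{gamma_phonons}}.
#' @param system a \code{toy_system}.
#' @param ... forwarded to \code{\link{gamma_phonons}}.
#' @return a \code{phonon_modes}.
#' @export
toy_phonons <- function(system, ...) {
  gamma_phonons(system$force_constants, system$masses,
                born_charges = system$born, eps_inf = system$eps_inf, ...)
}

#' Langevin molecular dynamics on a toy harmonic force field
#'
#' BAOAB Langevin integration of the cartesian displacements u about
#' equilibrium with forces -K u. The per-frame cell dipole is
#' sum_a Z*_a u_a. Equipartition holds: the mean kinetic energy per degree
#' of freedom converges to kB T / 2.
#'
#' @param system a \code{toy_system}.
#' @param temperature target temperature in K.
#' @param dt time step in fs; must resolve the highest mode (>= 20 steps
#'   per period) or an integration error is raised.
#' @param n_steps number of steps.
#' @param friction Langevin friction in fs^-1 (default 0.01).
#' @param seed integer seed.
#' @param store_frames also return atomic frames (default FALSE).
#' @param sample_every record every k-th step (default 1).
#' @return list with \code{dipole} (a \code{\link{dipole_trajectory}}),
#'   \code{temperature_estimate} (K, from mean kinetic energy), and
#'   optionally \code{frames}.
#' @export
simulate_harmonic_md <- function(system, temperature, dt = 0.5, n_steps = 20000,
                                 friction = 0.01, seed = 1,
                                 store_frames = FALSE, sample_every = 1L) {
  modes <- toy_phonons(system)
  fmax <- max(modes$frequency)
  period_fs <- 1 / (fmax * phys_const$c_cm_s * 1e-15)  # fs per period
  if (dt > period_fs / 20) {
    stop(sprintf("integration error: dt = %g fs does not resolve the %0.1f cm^-1 mode (need <= %.3g fs)",
                 dt, fmax, period_fs / 20))
  }
  K <- enforce_asr((system$force_constants + t(system$force_constants)) / 2)
  n <- length(system$masses)
  m3 <- rep(system$masses, each = 3)
  kT <- phys_const$kB_eV * max(temperature, 0)
  c1 <- exp(-friction * dt)
  c2 <- sqrt(1 - c1^2)
  sig_v <- sqrt(kT / (m3 * phys_const$ke_eV))
  zmat <- matrix(0, 3, n)
  for (a in seq_len(n)) zmat[, a] <- diag(system$born[, , a])
  born_full <- system$born
  nrec <- floor(n_steps / sample_every)
  dip <- matrix(0, nrec, 3)
  ke_sum <- 0
  frames <- if (store_frames) vector("list", nrec) else NULL
  eqcart <- frac_to_cart(system$crystal$frac, system$crystal$cell)
  with_seed(seed, {
    u <- numeric(3 * n)
    v <- if (temperature > 0) stats::rnorm(3 * n, 0, sig_v) else numeric(3 * n)
    rec <- 0L
    for (s in seq_len(n_steps)) {
      f <- -as.numeric(K %*% u)
      v <- v + 0.5 * dt * f / m3 * phys_const$acc_A_fs2
      u <- u + 0.5 * dt * v
      v <- c1 * v + if (temperature > 0) c2 * sig_v * stats::rnorm(3 * n) else 0
      u <- u + 0.5 * dt * v
      f <- -as.numeric(K %*% u)
      v <- v + 0.5 * dt * f / m3 * phys_const$acc_A_fs2
      ke_sum <- ke_sum + 0.5 * sum(m3 * v^2) * phys_const$ke_eV
      if (s %% sample_every == 0L) {
        rec <- rec + 1L
        um <- matrix(u, nrow = 3)
        d <- c(0, 0, 0)
        for (a in seq_len(n)) d <- d + born_full[, , a] %*% um[, a]
        dip[rec, ] <- d
        if (store_frames) {
          frames[[rec]] <- list(cell = system$crystal$cell,
                                elements = system$crystal$elements,
                                cart = eqcart + t(um),
                                time = s * dt)
        }
      }
    }
  })
  temp_est <- (ke_sum / (n_steps * 3 * n)) * 2 / phys_const$kB_eV
  traj <- dipole_trajectory(seq_len(nrec) * dt * sample_every, dip,
                            volume = cell_volume(system$crystal$cell),
                            temperature = max(temperature, 1e-12))
  out <- list(dipole = traj, temperature_estimate = temp_est)
  if (store_frames) out$frames <- frames
  out
}

#' Frozen two-well torsion potential coefficients
#'
#' Fourier coefficients (kJ/mol; angle in radians measured as the torsion
#' tau) of the package's default two-well torsion potential: minima near
#' +87 and -78 degrees, the negative-angle well about 1 kJ/mol above the
#' positive one, and along-the-path barriers of a few kJ/mol — the torsion
#' landscape typical of a thiol rotor switching between its two
#' hydrogen-bond motifs.
#'
#' @return named list with \code{a0}, \code{a} (cosine) and \code{b} (sine)
#'   coefficients; \code{a[j]}, \code{b[j]} multiply cos(j tau), sin(j tau).
#' @export
two_well_coefficients <- function() {
  # solved so that V'(87 deg) = V'(-78 deg) = 0, V(-78) - V(87) = 1.0 kJ/mol,
  # V(0) - V(87) = 6.0 kJ/mol, and min V = 0
  list(a0 = 4.2580147508,
       a = c(-1.8526928839, 3.5946781331),
       b = c(-0.6429160139, 0.5354401200))
}

#' Evaluate a Fourier torsion potential
#'
#' @param tau angle(s) in degrees.
#' @param coef coefficient list as in \code{\link{two_well_coefficients}}.
#' @return energy in kJ/mol.
#' @export
torsion_potential <- function(tau, coef) {
  x <- tau * pi / 180
  v <- rep(coef$a0, length(x))
  for (j in seq_along(coef$a)) v <- v + coef$a[j] * cos(j * x)
  for (j in seq_along(coef$b)) v <- v + coef$b[j] * sin(j * x)
  v
}

torsion_force <- function(tau_rad, coef) {
  # -dV/dtau in kJ/mol per radian
  f <- 0
  for (j in seq_along(coef$a)) f <- f + j * coef$a[j] * sin(j * tau_rad)
  for (j in seq_along(coef$b)) f <- f - j * coef$b[j] * cos(j * tau_rad)
  f
}

#' Overdamped Langevin dynamics on a torsion coordinate
#'
#' Euler-Maruyama integration of
#' d tau = -V'(tau)/gamma dt + sqrt(2 kB T / gamma) dW on the periodic
#' torsion coordinate. The stationary distribution is Boltzmann in V.
#'
#' @param coef Fourier coefficients (kJ/mol), see
#'   \code{\link{two_well_coefficients}}.
#' @param temperature temperature in K.
#' @param friction gamma in kJ/mol ps rad^-2 (default 1).
#' @param dt time step in ps (default 1e-3).
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @param init initial angle in degrees (default: the global minimum).
#' @return list with \code{times} (ps) and \code{angles} (degrees, wrapped).
#' @export
simulate_torsion_langevin <- function(coef = two_well_coefficients(),
                                      temperature = 300, friction = 1,
                                      dt = 1e-3, n_steps = 1e5, seed = 1,
                                      init = NULL) {
  kT <- phys_const$kB_kJmol * temperature
  if (is.null(init)) {
    grid <- seq(-179, 180, by = 1)
    init <- grid[which.min(torsion_potential(grid, coef))]
  }
  tau <- init * pi / 180
  noise <- sqrt(2 * kT * dt / friction)
  out <- numeric(n_steps)
  with_seed(seed, {
    xi <- stats::rnorm(n_steps)
    for (s in seq_len(n_steps)) {
      tau <- tau + torsion_force(tau, coef) / friction * dt + noise * xi[s]
      out[s] <- tau
    }
  })
  list(times = seq_len(n_steps) * dt, angles = wrap_angle(out * 180 / pi))
}

#' Ornstein-Uhlenbeck dipole trajectory
#'
#' Exact discretization per component:
#' x_{n+1} = rho x_n + amplitude sqrt(1 - rho^2) xi, rho = exp(-dt/tau_c),
#' so the sample autocorrelation decays as exp(-t/tau_c) and the stationary
#' standard deviation is \code{amplitude}.
#'
#' @param tau_c correlation time in fs.
#' @param amplitude stationary standard deviation per component (e A).
#' @param dt time step in fs (must be < tau_c / 5).
#' @param n number of frames.
#' @param seed integer seed.
#' @param volume,temperature forwarded to the \code{dipole_trajectory}.
#' @return a \code{\link{dipole_trajectory}}.
#' @export
make_ou_dipole <- function(tau_c, amplitude, dt, n, seed,
                           volume = 500, temperature = 300) {
  stopifnot(dt < tau_c / 5)
  rho <- exp(-dt / tau_c)
  dip <- with_seed(seed, {
    m <- matrix(0, n, 3)
    x <- stats::rnorm(3, 0, amplitude)
    for (i in seq_len(n)) {
      x <- rho * x + amplitude * sqrt(1 - rho^2) * stats::rnorm(3)
      m[i, ] <- x
    }
    m
  })
  dipole_trajectory((seq_len(n) - 1) * dt, dip, volume, temperature)
}
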