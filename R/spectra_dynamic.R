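# IR/THz absorption from MD cell-dipole trajectories: autocorrelation,
# window filtering, and one-sided Fourier transform to the permittivity
# with the classical linear-response prefactor.

#' Construct a dipole trajectory
#'
#' @param times uniform time grid in fs.
#' @param dipoles n x 3 matrix of cell dipole vectors in e Angstrom.
#' @param volume cell volume in Angstrom^3 (scalar for NVT, per-frame vector
#'   for NPT; the mean is used in the permittivity prefactor).
#' @param temperature simulation temperature in K.
#' @return list of class \code{dipole_trajectory}.
#' @export
dipole_trajectory <- function(times, dipoles, volume, temperature) {
  dipoles <- as.matrix(dipoles)
  stopifnot(ncol(dipoles) == 3, length(times) == nrow(dipoles),
            length(times) >= 2, temperature > 0)
  dt <- diff(times)
  if ((max(dt) - min(dt)) / mean(dt) > 1e-9) {
    stop("non-uniform time step: resample the trajectory first")
  }
  structure(list(times = times, dipoles = dipoles,
                 volume = volume, temperature = temperature,
                 dt = mean(dt)),
            class = "dipole_trajectory")
}

#' Read a dipole trajectory from CSV
#'
#' Expects columns \code{t_fs, Mx, My, Mz}.
#'
#' @param path CSV path.
#' @param volume,temperature see \code{\link{dipole_trajectory}}.
#' @return a \code{dipole_trajectory}.
#' @export
read_dipole_csv <- function(path, volume, temperature) {
  df <- utils::read.csv(path)
  need <- c("t_fs", "Mx", "My", "Mz")
  if (!all(need %in% names(df))) {
    stop("dipole CSV must have columns ", paste(need, collapse = ", "))
  }
  dipole_trajectory(df$t_fs, as.matrix(df[, c("Mx", "My", "Mz")]),
                    volume, temperature)
}

#' Dipole autocorrelation function
#'
#' C(t) = <dM(0) . dM(t)> with the mean dipole removed (fluctuation
#' convention) and the biased 1/N lag normalization, so C(0) equals the sum
#' of the per-component population variances. Computed by zero-padded FFT
#' (O(N log N)); identical to the direct lag sum.
#'
#' @param traj a \code{\link{dipole_trajectory}}.
#' @param max_lag maximum lag in fs (default: half the trajectory length);
#'   clipped with a warning if it exceeds the trajectory.
#' @return list of class \code{dipole_acf} with \code{lag} (fs), \code{acf}
#'   ((e Angstrom)^2), plus the trajectory's \code{dt}, \code{volume},
#'   \code{temperature}.
#' @export
dipole_acf <- function(traj, max_lag = NULL) {
  n <- nrow(traj$dipoles)
  span <- traj$times[n] - traj$times[1]
  if (is.null(max_lag)) max_lag <- span / 2
  if (max_lag > span) {
    warning("max_lag exceeds the trajectory span; clipped")
    max_lag <- span
  }
  nlag <- min(n - 1, floor(max_lag / traj$dt + 1e-9))
  dm <- sweep(traj$dipoles, 2, colMeans(traj$dipoles))
  npad <- 2^ceiling(log2(2 * n))
  acf <- numeric(nlag + 1)
  for (k in 1:3) {
    x <- c(dm[, k], rep(0, npad - n))
    f <- stats::fft(x)
    r <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / npad
    acf <- acf + r[1:(nlag + 1)]
  }
  acf <- acf / n
  structure(list(lag = (0:nlag) * traj$dt, acf = acf, dt = traj$dt,
                 volume = mean(traj$volume), temperature = traj$temperature,
                 window = NULL),
            class = "dipole_acf")
}

#' Window filter specification
#'
#' Taper applied to a correlation function before transforming; all families
#' evaluate to 1 at t = 0. \code{hann}: cos^2(pi t / (2 width)) for
#' t <= width, 0 beyond; \code{gaussian}: exp(-t^2 / (2 width^2));
#' \code{exponential}: exp(-t / width). The imposed width sets the spectral
#' line width, which therefore does not reflect physical phonon lifetimes.
#'
#' @param family "hann", "gaussian" or "exponential".
#' @param width width parameter in fs (> 0).
#' @return list of class \code{window_spec}.
#' @export
window_spec <- function(family = c("hann", "gaussian", "exponential"), width) {
  family <- match.arg(family)
  stopifnot(width > 0)
  structure(list(family = family, width = width), class = "window_spec")
}

window_values <- function(spec, t) {
  switch(spec$family,
         hann = ifelse(t <= spec$width, cos(pi * t / (2 * spec$width))^2, 0),
         gaussian = exp(-t^2 / (2 * spec$width^2)),
         exponential = exp(-t / spec$width))
}

#' Apply a window filter to a dipole autocorrelation function
#'
#' @param acf a \code{\link{dipole_acf}}.
#' @param spec a \code{\link{window_spec}}; its family and width are
#'   recorded in the result's provenance.
#' @return the windowed \code{dipole_acf}.
#' @export
apply_window <- function(acf, spec) {
  stopifnot(inherits(acf, "dipole_acf"), inherits(spec, "window_spec"))
  acf$acf <- acf$acf * window_values(spec, acf$lag)
  acf$window <- unclass(spec)
  acf
}

#' Absorption spectrum from a (windowed) dipole autocorrelation function
#'
#' Classical linear response: the one-sided Fourier-Laplace transform of
#' C(t) gives the dielectric susceptibility
#' chi(w) = [C(0) + i w integral_0^inf C(t) e^{i w t} dt] / (3 V eps0 kB T),
#' and eps(w) = eps_inf + chi(w). The absorption coefficient follows as in
#' the static route, alpha = 4 pi w Im sqrt(eps). An optional harmonic
#' quantum-correction factor beta hbar w / (1 - exp(-beta hbar w)) can be
#' applied to Im eps and is recorded in the provenance.
#'
#' @param acf a \code{\link{dipole_acf}} (window it first with
#'   \code{\link{apply_window}} for finite-trajectory line shapes).
#' @param grid frequency grid in cm^-1.
#' @param eps_inf electronic (high-frequency) permittivity baseline
#'   (default 1).
#' @param quantum_correction apply the harmonic quantum factor (default
#'   FALSE).
#' @return a \code{spectrum} with method tag "dynamic".
#' @export
absorption_from_acf <- function(acf, grid, eps_inf = 1,
                                quantum_correction = FALSE) {
  stopifnot(inherits(acf, "dipole_acf"), all(diff(grid) > 0))
  beta_pref <- phys_const$e2A_per_eps0_eV /
    (3 * acf$volume * phys_const$kB_eV * acf$temperature)
  w_radfs <- grid * phys_const$radfs_per_cm1
  tt <- acf$lag
  wts <- rep(acf$dt, length(tt))
  wts[c(1, length(tt))] <- acf$dt / 2  # trapezoid
  cw <- vapply(w_radfs, function(w) {
    sum(wts * acf$acf * exp(1i * w * tt))
  }, complex(1))
  chi <- beta_pref * (acf$acf[1] + 1i * w_radfs * cw)
  eps <- eps_inf + chi
  im <- Im(eps)
  if (quantum_correction) {
    x <- grid * phys_const$eV_per_cm1 /
      (phys_const$kB_eV * acf$temperature)
    im <- im * x / (1 - exp(-x))
    eps <- complex(real = Re(eps), imaginary = im)
  }
  sq <- sqrt(eps)
  flip <- Im(sq) < 0
  sq[flip] <- -sq[flip]
  alpha <- 4 * pi * grid * Im(sq)
  structure(list(frequency = grid, epsilon = eps, absorption = alpha,
                 method = "dynamic",
                 config = list(grid = grid, eps_inf = eps_inf,
                               window = acf$window,
                               quantum_correction = quantum_correction,
                               volume = acf$volume,
                               temperature = acf$temperature)),
            class = "spectrum")
}

#' Compare two spectra over a band
#'
#' Resamples both spectra (linear interpolation) onto a common grid over the
#' band and reports the integrated-absorption ratio (a / b), the difference
#' of the absorption-maximum positions, and the cosine similarity of the
#' absorption vectors.
#'
#' @param a,b \code{spectrum} objects.
#' @param band numeric length-2 wavenumber interval in cm^-1.
#' @param n number of resampling points (default 512).
#' @return list with \code{ratio}, \code{peak_delta} (cm^-1, a minus b),
#'   \code{peak_a}, \code{peak_b}, \code{cosine}, \code{band}.
#' @export
compare_spectra <- function(a, b, band = NULL, n = 512) {
  if (is.null(band)) {
    band <- c(max(min(a$frequency), min(b$frequency)),
              min(max(a$frequency), max(b$frequency)))
  }
  if (band[2] <= band[1]) stop("spectra do not overlap on the requested band")
  g <- seq(band[1], band[2], length.out = n)
  ya <- stats::approx(a$frequency, a$absorption, g)$y
  yb <- stats::approx(b$frequency, b$absorption, g)$y
  if (anyNA(ya) || anyNA(yb)) stop("band extends beyond a spectrum's grid")
  ia <- sum(ya) * (g[2] - g[1])
  ib <- sum(yb) * (g[2] - g[1])
  list(ratio = ia / ib,
       peak_a = g[which.max(ya)],
       peak_b = g[which.max(yb)],
       peak_delta = g[which.max(ya)] - g[which.max(yb)],
       cosine = sum(ya * yb) / sqrt(sum(ya^2) * sum(yb^2)),
       band = band)
}
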