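# Powder IR/THz absorption from Gamma-point phonons and Born charges:
# Lorentz oscillator dielectric function + Maxwell-Garnett effective medium.

#' Spectrum calculation configuration
#'
#' @param gamma Lorentzian line broadening in cm^-1 (default 5).
#' @param volume_fraction crystal volume fraction of the powder in the host
#'   matrix (default 0.10).
#' @param host_eps real scalar permittivity of the host matrix (default 2.0,
#'   a PTFE-like value).
#' @param grid strictly increasing frequency grid in cm^-1.
#' @return list of class \code{spectrum_config}.
#' @export
spectrum_config <- function(gamma = 5, volume_fraction = 0.10, host_eps = 2.0,
                            grid = seq(5, 300, by = 0.5)) {
  stopifnot(gamma > 0, volume_fraction >= 0, volume_fraction <= 1,
            all(diff(grid) > 0))
  structure(list(gamma = gamma, volume_fraction = volume_fraction,
                 host_eps = host_eps, grid = grid, shape = "sphere"),
            class = "spectrum_config")
}

#' Per-mode infrared oscillator strengths
#'
#' For each mode k the Born-charge-weighted mode dipole derivative
#' Z_k = sum_a Z*_a . e_{k,a} / sqrt(m_a) (units e/sqrt(amu)) gives the
#' oscillator-strength tensor S_k = C * (Z_k x Z_k) / V, where the prefactor
#' C converts to the dimensionless permittivity contribution of the Lorentz
#' sum eps(w) = eps_inf + sum_k S_k / (w_k^2 - w^2 - i gamma w) with w in
#' cm^-1 (so S_k carries units of (cm^-1)^2).
#'
#' @param modes a \code{\link{gamma_phonons}} result carrying Born charges.
#' @param volume unit-cell volume in Angstrom^3.
#' @return 3 x 3 x n_modes array of oscillator-strength tensors.
#' @export
mode_intensities <- function(modes, volume) {
  if (is.null(modes$born)) stop("modes carry no Born charges")
  n <- length(modes$masses)
  nm <- length(modes$frequency)
  S <- array(0, c(3, 3, nm))
  invsqm <- 1 / sqrt(modes$masses)
  pref <- phys_const$eps_lorentz / volume
  for (k in seq_len(nm)) {
    z <- c(0, 0, 0)
    ev <- matrix(modes$eigenvectors[, k], nrow = 3)  # 3 x N, atom columns
    for (a in seq_len(n)) {
      z <- z + modes$born[, , a] %*% ev[, a] * invsqm[a]
    }
    S[, , k] <- pref * tcrossprod(as.numeric(z))
  }
  S
}

#' Lorentz-oscillator dielectric function
#'
#' eps(w) = eps_inf + sum_k S_k / (w_k^2 - w^2 - i gamma w) on the config
#' grid; acoustic and imaginary-flagged modes are excluded from the sum.
#' The powder-average scalar is the tensor trace / 3.
#'
#' @param modes a \code{\link{gamma_phonons}} result (needs \code{eps_inf}).
#' @param strengths output of \code{\link{mode_intensities}}.
#' @param config a \code{\link{spectrum_config}}.
#' @return complex vector eps(w) over \code{config$grid} (powder average).
#' @export
dielectric_function <- function(modes, strengths, config) {
  if (is.null(modes$eps_inf)) stop("modes carry no high-frequency dielectric tensor")
  w <- config$grid
  eps <- array(rep(as.complex(modes$eps_inf), length(w)), c(3, 3, length(w)))
  use <- which(!modes$acoustic & !modes$imaginary)
  for (k in use) {
    denom <- modes$frequency[k]^2 - w^2 - 1i * config$gamma * w
    for (i in 1:3) for (j in 1:3) {
      eps[i, j, ] <- eps[i, j, ] + strengths[i, j, k] / denom
    }
  }
  (eps[1, 1, ] + eps[2, 2, ] + eps[3, 3, ]) / 3
}

#' Maxwell-Garnett effective permittivity
#'
#' Spherical inclusions of permittivity eps_i at volume fraction f in a host
#' of permittivity eps_m:
#' eps_eff = eps_m * [eps_i (1 + 2f) + 2 eps_m (1 - f)] /
#'           [eps_i (1 - f) + eps_m (2 + f)].
#'
#' @param eps_i complex inclusion permittivity (vectorized over frequency).
#' @param eps_m real scalar host permittivity.
#' @param f inclusion volume fraction in [0, 1].
#' @return complex effective permittivity.
#' @export
maxwell_garnett <- function(eps_i, eps_m, f) {
  stopifnot(f >= 0, f <= 1, length(eps_m) == 1)
  denom <- eps_i * (1 - f) + eps_m * (2 + f)
  if (any(Mod(denom) < 1e-12)) stop("singular effective-medium mixture")
  eps_m * (eps_i * (1 + 2 * f) + 2 * eps_m * (1 - f)) / denom
}

#' Powder absorption spectrum from an effective permittivity
#'
#' alpha(w) = 4 pi w kappa(w) with kappa = Im sqrt(eps_eff) on the principal
#' branch (Im sqrt >= 0 enforced) and w the wavenumber in cm^-1, so alpha is
#' an absorption coefficient per effective path length in cm^-1.
#'
#' @param eps_eff complex effective permittivity on \code{config$grid}.
#' @param config a \code{\link{spectrum_config}}.
#' @param method provenance tag, "static" or "dynamic".
#' @return object of class \code{spectrum}: \code{frequency} (cm^-1),
#'   \code{epsilon} (complex), \code{absorption} (cm^-1), \code{method},
#'   \code{config}.
#' @export
powder_absorption <- function(eps_eff, config, method = "static") {
  sq <- sqrt(as.complex(eps_eff))
  flip <- Im(sq) < 0
  sq[flip] <- -sq[flip]
  alpha <- 4 * pi * config$grid * Im(sq)
  structure(list(frequency = config$grid, epsilon = eps_eff,
                 absorption = alpha, method = method,
                 config = unclass(config)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  pk <- x$frequency[which.max(x$absorption)]
  cat(sprintf("spectrum (%s): %d points, %.1f .. %.1f cm^-1, max absorption at %.1f cm^-1\n",
              x$method, length(x$frequency), min(x$frequency),
              max(x$frequency), pk))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  plot(x$frequency, x$absorption, type = "l",
       xlab = expression(wavenumber ~ (cm^-1)),
       ylab = expression(alpha ~ (cm^-1)), ...)
}

#' Full static powder spectrum from phonon modes
#'
#' Convenience chain: \code{\link{mode_intensities}} ->
#' \code{\link{dielectric_function}} -> \code{\link{maxwell_garnett}} ->
#' \code{\link{powder_absorption}}.
#'
#' @param modes a \code{\link{gamma_phonons}} result with Born charges and
#'   eps_inf.
#' @param volume unit-cell volume in Angstrom^3.
#' @param config a \code{\link{spectrum_config}}.
#' @return a \code{spectrum}.
#' @export
static_spectrum <- function(modes, volume, config = spectrum_config()) {
  S <- mode_intensities(modes, volume)
  eps_i <- dielectric_function(modes, S, config)
  eps_eff <- maxwell_garnett(eps_i, config$host_eps, config$volume_fraction)
  powder_absorption(eps_eff, config, method = "static")
}

#' Write a spectrum to CSV (and optionally a JSON config snapshot)
#'
#' CSV columns: wavenumber_cm1, eps_re, eps_im, absorption_cm1.
#'
#' @param spectrum a \code{spectrum}.
#' @param path output CSV path.
#' @param json_path optional path for a JSON snapshot of the configuration
#'   and method tag.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(spectrum, path, json_path = NULL) {
  df <- data.frame(wavenumber_cm1 = spectrum$frequency,
                   eps_re = Re(spectrum$epsilon),
                   eps_im = Im(spectrum$epsilon),
                   absorption_cm1 = spectrum$absorption)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(json_path)) {
    snap <- spectrum$config
    snap$grid <- c(min(snap$grid), max(snap$grid), length(snap$grid))
    jsonlite::write_json(list(method = spectrum$method, config = snap),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
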