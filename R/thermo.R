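# Quasi-harmonic thermodynamics and torsion-scan profile analysis.

#' Harmonic vibrational free energy
#'
#' F_vib(T) = sum_k [ hbar w_k / 2 + kB T log(1 - exp(-hbar w_k / kB T)) ],
#' evaluated per cell in eV. At T = 0 the result equals the zero-point
#' energy exactly. Acoustic and imaginary-flagged modes are excluded when a
#' \code{phonon_modes} object is supplied; a plain frequency vector is used
#' as given.
#'
#' @param frequencies numeric vector of wavenumbers (cm^-1) or a
#'   \code{\link{gamma_phonons}} result.
#' @param temperature temperature in K (>= 0).
#' @return list with \code{f_vib} (eV), \code{zpe} (eV), \code{n_modes},
#'   and \code{n_excluded} (acoustic + imaginary modes dropped).
#' @export
vibrational_free_energy <- function(frequencies, temperature) {
  if (temperature < 0) stop("temperature must be non-negative")
  n_excluded <- 0L
  if (inherits(frequencies, "phonon_modes")) {
    keep <- !frequencies$acoustic & !frequencies$imaginary
    n_excluded <- sum(!keep)
    frequencies <- frequencies$frequency[keep]
  }
  if (length(frequencies) == 0) {
    return(list(f_vib = 0, zpe = 0, n_modes = 0L, n_excluded = n_excluded))
  }
  if (any(frequencies <= 0)) stop("frequencies must be positive wavenumbers")
  hw <- frequencies * phys_const$eV_per_cm1
  zpe <- sum(hw) / 2
  f <- zpe
  if (temperature > 0) {
    kt <- phys_const$kB_eV * temperature
    f <- f + kt * sum(log1p(-exp(-hw / kt)))
  }
  list(f_vib = f, zpe = zpe, n_modes = length(frequencies),
       n_excluded = n_excluded)
}

#' Relative polymorph stability on a pressure grid
#'
#' For each polymorph record, the per-molecule Gibbs energy
#' G(P) = [E + P V(P) + F_vib(T)] / n_molecules is evaluated on the pressure
#' grid and reported relative to a named reference (kJ/mol per molecule).
#' The PV term can be dropped (\code{include_pv = FALSE}) to compare
#' Helmholtz-style free energies of the caller's per-pressure optimized
#' geometries. Crossover pressures are sign-change brackets of each curve
#' with linear-interpolated P*.
#'
#' @param records list of polymorph records; each a list with \code{name},
#'   \code{energy} (static lattice energy, eV/cell), \code{volume} (a
#'   scalar, a vector matching the pressure grid, or a function of pressure;
#'   Angstrom^3/cell), \code{modes} (a \code{phonon_modes} object, a plain
#'   frequency vector in cm^-1, or NULL for no vibrational term), and
#'   \code{n_molecules}. An optional \code{temperature} field must match the
#'   \code{temperature} argument.
#' @param reference name of the reference polymorph.
#' @param pressures pressure grid in GPa.
#' @param temperature temperature in K.
#' @param include_pv include the P*V enthalpy term (default TRUE).
#' @param include_phonons include F_vib (default TRUE); switching this off
#'   isolates the vibrational contribution by comparison.
#' @return object of class \code{free_energy_curve}: a data.frame
#'   \code{curves} (pressure, one Delta-G column per polymorph), and
#'   \code{crossovers} (polymorph, bracket, interpolated pressure).
#' @export
relative_stability_curves <- function(records, reference, pressures,
                                      temperature, include_pv = TRUE,
                                      include_phonons = TRUE) {
  names(records) <- vapply(records, `[[`, "", "name")
  if (!reference %in% names(records)) stop("reference polymorph not found")
  for (r in records) {
    if (!is.null(r$temperature) && r$temperature != temperature) {
      stop("record '", r$name, "' carries a different temperature")
    }
  }
  gibbs <- function(r) {
    v <- if (is.function(r$volume)) r$volume(pressures)
         else if (length(r$volume) == 1) rep(r$volume, length(pressures))
         else r$volume
    if (length(v) != length(pressures)) stop("volume grid mismatch for ", r$name)
    g <- rep(r$energy, length(pressures))
    if (include_pv) g <- g + pressures * v * phys_const$GPaA3_to_eV
    if (include_phonons && !is.null(r$modes)) {
      g <- g + vibrational_free_energy(r$modes, temperature)$f_vib
    }
    g / r$n_molecules
  }
  gref <- gibbs(records[[reference]])
  curves <- data.frame(pressure = pressures)
  crossovers <- data.frame(polymorph = character(0), p_lo = numeric(0),
                           p_hi = numeric(0), p_star = numeric(0))
  for (r in records) {
    dg <- (gibbs(r) - gref) * phys_const$eV_to_kJmol
    curves[[r$name]] <- dg
    if (r$name == reference) next
    s <- sign(dg)
    for (i in seq_len(length(dg) - 1)) {
      if (s[i] != 0 && s[i + 1] != 0 && s[i] != s[i + 1]) {
        p_star <- pressures[i] - dg[i] * (pressures[i + 1] - pressures[i]) /
          (dg[i + 1] - dg[i])
        crossovers <- rbind(crossovers, data.frame(
          polymorph = r$name, p_lo = pressures[i], p_hi = pressures[i + 1],
          p_star = p_star))
      }
    }
  }
  structure(list(curves = curves, crossovers = crossovers,
                 reference = reference, temperature = temperature,
                 include_pv = include_pv),
            class = "free_energy_curve")
}

#' @export
print.free_energy_curve <- function(x, ...) {
  cat(sprintf("free_energy_curve: %d polymorphs vs '%s' at %g K (%s)\n",
              ncol(x$curves) - 1, x$reference, x$temperature,
              if (x$include_pv) "with PV term" else "no PV term"))
  if (nrow(x$crossovers) > 0) {
    for (i in seq_len(nrow(x$crossovers))) {
      cat(sprintf("  crossover: %s at %.3f GPa\n",
                  x$crossovers$polymorph[i], x$crossovers$p_star[i]))
    }
  } else cat("  no stability crossovers on the grid\n")
  invisible(x)
}

#' Analyze a periodic torsion-energy profile
#'
#' Locates all local minima on the periodic grid and, for each ordered pair
#' of adjacent minima, the along-the-path barrier: the maximum grid energy
#' on the direct arc between them, reported above the departing minimum.
#' This is a path barrier, not a transition-state height.
#'
#' @param angles grid angles in degrees, uniformly spaced, covering a full
#'   period (with or without the duplicated endpoint).
#' @param energies energies in kJ/mol on the grid. If both +180 and -180
#'   (or equivalent endpoints) appear they must agree within \code{tol}.
#' @param tol periodic-closure tolerance in kJ/mol (default 1e-6).
#' @return list with \code{minima} (data.frame: angle, energy relative to
#'   the global minimum) and \code{barriers} (data.frame: from_angle,
#'   to_angle, barrier, angle_at_max).
#' @export
analyze_torsion_profile <- function(angles, energies, tol = 1e-6) {
  stopifnot(length(angles) == length(energies), length(angles) >= 3)
  ord <- order(wrap_angle(angles))
  a <- wrap_angle(angles)[ord]
  e <- energies[ord]
  dup <- which(duplicated(round(a / 1e-9)))
  if (length(dup) > 0) {
    for (d in dup) {
      first <- which(abs(a - a[d]) < 1e-9)[1]
      if (abs(e[d] - e[first]) > tol) {
        stop("periodic closure violated: endpoint energies differ by ",
             format(e[d] - e[first]))
      }
    }
    a <- a[-dup]; e <- e[-dup]
  }
  spacing <- diff(a)
  if (max(spacing) - min(spacing) > 1e-6) {
    # allow the wrap gap; check uniformity including the periodic step
    gap <- 360 - (a[length(a)] - a[1])
    if (abs(gap - spacing[1]) > 1e-6 || max(spacing) - min(spacing) > 1e-6) {
      stop("grid spacing is not uniform")
    }
  }
  e <- e - min(e)
  n <- length(e)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  is_min <- e < e[nxt] & e < e[prv]
  if (!any(is_min)) {
    warning("flat profile: no minima found")
    return(list(minima = data.frame(angle = numeric(0), energy = numeric(0)),
                barriers = data.frame(from_angle = numeric(0),
                                      to_angle = numeric(0),
                                      barrier = numeric(0),
                                      angle_at_max = numeric(0))))
  }
  mins <- which(is_min)
  minima <- data.frame(angle = a[mins], energy = e[mins])
  barriers <- data.frame(from_angle = numeric(0), to_angle = numeric(0),
                         barrier = numeric(0), angle_at_max = numeric(0))
  k <- length(mins)
  for (i in seq_len(k)) {
    j <- if (i == k) 1 else i + 1
    # arc from mins[i] forward to mins[j]
    path <- if (mins[j] > mins[i]) mins[i]:mins[j]
            else c(mins[i]:n, 1:mins[j])
    top <- path[which.max(e[path])]
    barriers <- rbind(barriers,
      data.frame(from_angle = a[mins[i]], to_angle = a[mins[j]],
                 barrier = e[top] - e[mins[i]], angle_at_max = a[top]))
    if (k == 1) break
    barriers <- rbind(barriers,
      data.frame(from_angle = a[mins[j]], to_angle = a[mins[i]],
                 barrier = e[top] - e[mins[j]], angle_at_max = a[top]))
  }
  list(minima = minima, barriers = barriers)
}
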