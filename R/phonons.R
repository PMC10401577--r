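# Gamma-point lattice dynamics: acoustic sum rule, dynamical matrix,
# rigid-body (translation/rotation/internal) mode decomposition.

#' Enforce the translational acoustic sum rule on a force-constant matrix
#'
#' Replaces each self block K_aa by -sum_{b != a} K_ab so that uniform
#' translations carry zero force. Off-diagonal (interatomic) blocks are
#' untouched.
#'
#' @param fc 3N x 3N force-constant matrix (eV/Angstrom^2).
#' @return corrected matrix.
#' @export
enforce_asr <- function(fc) {
  n <- nrow(fc) / 3
  for (a in seq_len(n)) {
    ia <- (a - 1) * 3 + 1:3
    s <- matrix(0, 3, 3)
    for (b in seq_len(n)) {
      if (b == a) next
      s <- s + fc[ia, (b - 1) * 3 + 1:3]
    }
    fc[ia, ia] <- -s
  }
  fc
}

#' Gamma-point phonon modes from force constants
#'
#' Diagonalizes the mass-weighted dynamical matrix
#' D = M^{-1/2} K M^{-1/2}. Negative eigenvalues are reported as
#' imaginary-flagged frequencies (magnitude of sqrt(|lambda|)), never
#' dropped. Frequencies are sorted ascending with imaginary modes first.
#'
#' @param force_constants 3N x 3N symmetric matrix in eV/Angstrom^2
#'   (row-major per-site 3x3 blocks).
#' @param masses per-site masses in amu (length N).
#' @param born_charges optional 3 x 3 x N array of Born effective charge
#'   tensors (e); the acoustic sum rule (zero tensor sum) is enforced by
#'   subtracting the mean.
#' @param eps_inf optional 3x3 (or scalar) high-frequency dielectric tensor.
#' @param asr enforce the translational sum rule on \code{force_constants}
#'   first (default TRUE).
#' @param acoustic_tol modes with |frequency| below this (cm^-1) are flagged
#'   acoustic (default 0.5).
#' @param sym_tol relative symmetry tolerance on the input matrix.
#' @return object of class \code{phonon_modes}: \code{frequency} (cm^-1,
#'   non-negative magnitudes), \code{imaginary} (logical), \code{acoustic}
#'   (logical), \code{eigenvectors} (3N x 3N, one mass-weighted orthonormal
#'   column per mode), \code{masses}, \code{born}, \code{eps_inf}.
#' @export
gamma_phonons <- function(force_constants, masses, born_charges = NULL,
                          eps_inf = NULL, asr = TRUE, acoustic_tol = 0.5,
                          sym_tol = 1e-8) {
  fc <- as.matrix(force_constants)
  n3 <- nrow(fc)
  if (ncol(fc) != n3 || n3 %% 3 != 0) stop("force constants must be 3N x 3N")
  if (length(masses) != n3 / 3) stop("need one mass per site")
  scale <- max(abs(fc))
  if (scale > 0 && max(abs(fc - t(fc))) / scale > sym_tol) {
    stop("force-constant matrix is not symmetric within tolerance")
  }
  fc <- (fc + t(fc)) / 2
  if (asr) fc <- enforce_asr(fc)
  invsqm <- rep(1 / sqrt(masses), each = 3)
  D <- fc * outer(invsqm, invsqm)
  eig <- eigen((D + t(D)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  lam <- eig$values[ord]
  vec <- eig$vectors[, ord, drop = FALSE]
  freq <- sqrt(abs(lam)) * phys_const$freq_cm1
  imaginary <- lam < 0 & freq > acoustic_tol
  acoustic <- freq <= acoustic_tol
  if (!is.null(born_charges)) {
    born_charges <- as.array(born_charges)
    stopifnot(all(dim(born_charges) == c(3, 3, n3 / 3)))
    zbar <- apply(born_charges, c(1, 2), mean)
    for (a in seq_len(n3 / 3)) born_charges[, , a] <- born_charges[, , a] - zbar
  }
  if (!is.null(eps_inf) && length(eps_inf) == 1) eps_inf <- diag(3) * eps_inf
  structure(list(frequency = freq, imaginary = imaginary, acoustic = acoustic,
                 eigenvectors = vec, masses = masses, born = born_charges,
                 eps_inf = eps_inf, acoustic_tol = acoustic_tol),
            class = "phonon_modes")
}

#' @export
print.phonon_modes <- function(x, ...) {
  cat(sprintf("phonon_modes: %d modes (%d acoustic, %d imaginary)\n",
              length(x$frequency), sum(x$acoustic), sum(x$imaginary)))
  cat("  optical range:",
      paste(sprintf("%.2f", range(x$frequency[!x$acoustic])), collapse = " .. "),
      "cm^-1\n")
  invisible(x)
}

# Contiguous cartesian coordinates of one molecule: BFS over the bond graph,
# each atom placed at the minimum image of its parent. Falls back to
# minimum images of the first atom for unbonded clusters.
molecule_cart <- function(crystal, idx, bonds = NULL) {
  if (is.null(bonds)) bonds <- bond_list(crystal)
  cell <- crystal$cell
  pos <- matrix(NA_real_, length(idx), 3)
  lookup <- match(seq_len(n_sites(crystal)), idx)
  adj <- vector("list", length(idx))
  for (k in seq_len(nrow(bonds))) {
    i <- lookup[bonds[k, 1]]; j <- lookup[bonds[k, 2]]
    if (!is.na(i) && !is.na(j)) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  pos[1, ] <- frac_to_cart(crystal$frac[idx[1], ], cell)
  queue <- 1L
  placed <- c(TRUE, rep(FALSE, length(idx) - 1))
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (placed[w]) next
      pos[w, ] <- pos[v, ] + min_image_vec(crystal$frac[idx[v], ],
                                           crystal$frac[idx[w], ], cell)
      placed[w] <- TRUE
      queue <- c(queue, w)
    }
  }
  for (w in which(!placed)) {
    pos[w, ] <- pos[1, ] + min_image_vec(crystal$frac[idx[1], ],
                                         crystal$frac[idx[w], ], cell)
  }
  pos
}

#' Rigid-body basis of a crystal's molecules
#'
#' Mass-weighted, orthonormal displacement patterns spanning the per-molecule
#' rigid translations (3 per molecule) and rotations about the center of
#' mass (3, or 2 for linear molecules, 0 for single atoms).
#'
#' @param crystal a \code{\link{crystal}}.
#' @param masses optional per-site masses in amu (defaults to the element
#'   table).
#' @return list with matrices \code{translations} and \code{rotations}
#'   (3N rows, one column per basis vector).
#' @export
rigid_body_basis <- function(crystal, masses = NULL) {
  n <- n_sites(crystal)
  m <- if (is.null(masses)) site_masses(crystal) else masses
  bonds <- bond_list(crystal)
  trans <- NULL
  rots <- NULL
  for (idx in crystal$molecules) {
    pos <- molecule_cart(crystal, idx, bonds)
    mm <- m[idx]
    com <- colSums(pos * mm) / sum(mm)
    rows <- as.vector(t(outer(idx, 1:3, function(a, k) (a - 1) * 3 + k)))
    tvecs <- matrix(0, 3 * n, 3)
    for (al in 1:3) {
      v <- matrix(0, length(idx), 3); v[, al] <- sqrt(mm)
      tvecs[rows, al] <- as.vector(t(v))
      tvecs[, al] <- tvecs[, al] / sqrt(sum(tvecs[, al]^2))
    }
    rvecs <- matrix(0, 3 * n, 0)
    for (al in 1:3) {
      e <- c(0, 0, 0); e[al] <- 1
      v <- t(vapply(seq_along(idx), function(a) {
        sqrt(mm[a]) * cross3(e, pos[a, ] - com)
      }, numeric(3)))
      full <- numeric(3 * n); full[rows] <- as.vector(t(v))
      # orthogonalize against translations and earlier rotations
      for (col in seq_len(ncol(tvecs))) full <- full - sum(full * tvecs[, col]) * tvecs[, col]
      if (ncol(rvecs) > 0) {
        for (col in seq_len(ncol(rvecs))) full <- full - sum(full * rvecs[, col]) * rvecs[, col]
      }
      nrm <- sqrt(sum(full^2))
      if (nrm > 1e-8) rvecs <- cbind(rvecs, full / nrm)
    }
    trans <- cbind(trans, tvecs)
    rots <- cbind(rots, rvecs)
  }
  list(translations = trans, rotations = if (is.null(rots)) matrix(0, 3 * n, 0) else rots)
}

#' Decompose modes into translational, rotational and internal character
#'
#' Projects each mass-weighted eigenvector onto the molecular rigid-body
#' subspaces and reports squared-projection percentages. The three numbers
#' sum to 100 per mode.
#'
#' @param modes a \code{\link{gamma_phonons}} result.
#' @param crystal the \code{\link{crystal}} the force field belongs to
#'   (supplies masses and the molecular partition).
#' @return data.frame with columns \code{frequency}, \code{translational},
#'   \code{rotational}, \code{internal} (percent).
#' @export
decompose_modes <- function(modes, crystal) {
  basis <- rigid_body_basis(crystal, masses = modes$masses)
  ev <- modes$eigenvectors
  pt <- if (ncol(basis$translations) > 0) {
    colSums(crossprod(basis$translations, ev)^2) * 100
  } else rep(0, ncol(ev))
  pr <- if (ncol(basis$rotations) > 0) {
    colSums(crossprod(basis$rotations, ev)^2) * 100
  } else rep(0, ncol(ev))
  pt <- pmin(pmax(pt, 0), 100)
  pr <- pmin(pmax(pr, 0), 100)
  data.frame(frequency = ifelse(modes$imaginary, -modes$frequency, modes$frequency),
             translational = pt, rotational = pr,
             internal = pmax(100 - pt - pr, 0))
}
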