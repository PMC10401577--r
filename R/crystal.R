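# The crystal container: P1 cell, sites, molecular partition.

# Covalent radii (Angstrom, Cordero 2008) for the elements this package
# expects to meet in organic molecular crystals and toy systems.
.covalent_radii <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Br = 1.20,
  I = 1.39, X = 0.80
)

# Standard atomic weights (amu) for the same set; X is a generic toy bead.
.atomic_masses <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Br = 79.904, I = 126.90, X = 10.0
)

#' Construct a crystal
#'
#' A \code{crystal} is a P1 periodic cell: a 3x3 lattice matrix (vectors in
#' rows, Angstrom), element symbols, fractional coordinates wrapped into
#' [0, 1), and a partition of the sites into molecular units. If no partition
#' is supplied it is inferred from a covalent-radius bond graph (bond when the
#' minimum-image distance is below 1.2 times the sum of covalent radii).
#'
#' @param cell 3x3 lattice matrix or c(a, b, c, alpha, beta, gamma).
#' @param elements character vector of element symbols.
#' @param frac n x 3 matrix of fractional coordinates.
#' @param molecules optional list of integer site-index vectors partitioning
#'   the sites into molecules; inferred from bonds when NULL.
#' @param pressure_tag optional external pressure in GPa.
#' @param provenance free-text provenance string.
#' @return object of class \code{crystal} with fields \code{cell},
#'   \code{elements}, \code{frac}, \code{molecules}, \code{pressure_tag},
#'   \code{provenance}.
#' @export
crystal <- function(cell, elements, frac, molecules = NULL,
                    pressure_tag = NULL, provenance = "") {
  if (is.numeric(cell) && is.null(dim(cell)) && length(cell) == 6) {
    cell <- cell_matrix(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])
  }
  cell <- unname(as.matrix(cell))
  stopifnot(all(dim(cell) == c(3, 3)))
  if (det(cell) <= 0) stop("cell volume must be positive")
  frac <- as.matrix(frac)
  if (ncol(frac) != 3) stop("frac must have three columns")
  if (length(elements) != nrow(frac)) {
    stop("elements and frac disagree on the number of sites")
  }
  unknown <- setdiff(unique(elements), names(.covalent_radii))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  frac <- wrap_frac(frac)
  obj <- structure(
    list(cell = cell, elements = as.character(elements), frac = unname(frac),
         molecules = NULL, pressure_tag = pressure_tag,
         provenance = provenance),
    class = "crystal")
  if (is.null(molecules)) {
    molecules <- molecular_partition(obj)
  } else {
    molecules <- lapply(unname(molecules), as.integer)
    ids <- sort(unname(unlist(molecules)))
    if (!identical(ids, seq_len(nrow(frac)))) {
      stop("molecules must partition the site indices exactly once each")
    }
  }
  obj$molecules <- molecules
  obj
}

#' @export
print.crystal <- function(x, ...) {
  p <- cell_parameters(x$cell)
  cat(sprintf("crystal: %d sites, %d molecule(s)\n",
              length(x$elements), length(x$molecules)))
  cat(sprintf("  a=%.4f b=%.4f c=%.4f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.2f A^3\n",
              p[1], p[2], p[3], p[4], p[5], p[6], cell_volume(x$cell)))
  if (!is.null(x$pressure_tag)) cat(sprintf("  pressure: %g GPa\n", x$pressure_tag))
  invisible(x)
}

#' Number of sites in a crystal
#' @param crystal a \code{crystal}.
#' @return integer site count.
#' @export
n_sites <- function(crystal) length(crystal$elements)

site_masses <- function(crystal) {
  unname(.atomic_masses[crystal$elements])
}

#' Covalent bond list
#'
#' All site pairs whose minimum-image distance is below
#' \code{tol * (r_i + r_j)} with covalent radii r.
#'
#' @param crystal a \code{crystal}.
#' @param tol radius-sum multiplier (default 1.2).
#' @return two-column integer matrix of bonded site pairs (i < j).
#' @export
bond_list <- function(crystal, tol = 1.2) {
  n <- n_sites(crystal)
  r <- .covalent_radii[crystal$elements]
  out <- matrix(integer(0), ncol = 2)
  if (n < 2) return(out)
  pairs <- utils::combn(n, 2)
  keep <- logical(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- min_image_dist(crystal$frac[i, ], crystal$frac[j, ], crystal$cell)
    keep[k] <- d < tol * (r[i] + r[j])
  }
  t(pairs[, keep, drop = FALSE])
}

#' Molecular partition by bond connectivity
#'
#' Connected components of the covalent bond graph, found by breadth-first
#' search over \code{\link{bond_list}}.
#'
#' @inheritParams bond_list
#' @return list of integer site-index vectors, one per molecule.
#' @export
molecular_partition <- function(crystal, tol = 1.2) {
  n <- n_sites(crystal)
  bonds <- bond_list(crystal, tol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  split(seq_len(n), comp)
}

#' Build a supercell
#'
#' Replicates the cell n1 x n2 x n3 times. The volume is exactly
#' multiplicative and the molecular partition is replicated image by image.
#'
#' @param crystal a \code{crystal}.
#' @param multipliers integer vector of three replication factors (>= 1).
#' @return the supercell as a \code{crystal}.
#' @export
build_supercell <- function(crystal, multipliers) {
  m <- as.integer(multipliers)
  stopifnot(length(m) == 3, all(m >= 1))
  if (all(m == 1L)) return(crystal)
  n <- n_sites(crystal)
  shifts <- as.matrix(expand.grid(i = 0:(m[1] - 1), j = 0:(m[2] - 1),
                                  k = 0:(m[3] - 1)))
  nimg <- nrow(shifts)
  frac <- matrix(0, n * nimg, 3)
  elements <- character(n * nimg)
  molecules <- vector("list", length(crystal$molecules) * nimg)
  for (s in seq_len(nimg)) {
    idx <- (s - 1) * n + seq_len(n)
    frac[idx, ] <- sweep(crystal$frac, 2, shifts[s, ], "+") %*% diag(1 / m)
    elements[idx] <- crystal$elements
    for (mm in seq_along(crystal$molecules)) {
      molecules[[(s - 1) * length(crystal$molecules) + mm]] <-
        crystal$molecules[[mm]] + (s - 1L) * n
    }
  }
  newcell <- diag(m) %*% crystal$cell
  crystal(newcell, elements, frac, molecules = molecules,
          pressure_tag = crystal$pressure_tag,
          provenance = sprintf("%s [supercell %dx%dx%d]",
                               crystal$provenance, m[1], m[2], m[3]))
}
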