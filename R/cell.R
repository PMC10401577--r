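# Lattice / cell geometry helpers.
#
# A cell is stored as a 3x3 matrix with lattice vectors in the ROWS
# (Angstrom), so cartesian = fractional %*% cell.

#' Build a cell matrix from lattice parameters
#'
#' Uses the standard crystallographic convention: a along x, b in the xy
#' plane.
#'
#' @param a,b,c axis lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return 3x3 matrix with lattice vectors in rows.
#' @export
cell_matrix <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  cz2 <- 1 - cb^2 - ((ca - cb * cg) / sg)^2
  if (cz2 <= 0) stop("lattice parameters do not define a positive-volume cell")
  rbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(cz2))
  )
}

#' Lattice parameters of a cell matrix
#'
#' @param cell 3x3 matrix, lattice vectors in rows.
#' @return named numeric vector (a, b, c, alpha, beta, gamma) with lengths in
#'   Angstrom and angles in degrees.
#' @export
cell_parameters <- function(cell) {
  len <- sqrt(rowSums(cell^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  c(a = len[1], b = len[2], c = len[3],
    alpha = ang(cell[2, ], cell[3, ]),
    beta  = ang(cell[1, ], cell[3, ]),
    gamma = ang(cell[1, ], cell[2, ]))
}

#' Cell volume
#'
#' Volume of the parallelepiped spanned by the lattice vectors. For lattice
#' parameters the closed form
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma+
#'   2\cos\alpha\cos\beta\cos\gamma}} is used via the cell matrix.
#'
#' @param cell 3x3 cell matrix, or a numeric vector
#'   \code{c(a, b, c, alpha, beta, gamma)}.
#' @return volume in Angstrom^3.
#' @export
cell_volume <- function(cell) {
  if (is.numeric(cell) && is.null(dim(cell)) && length(cell) == 6) {
    cell <- cell_matrix(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])
  }
  abs(det(cell))
}

frac_to_cart <- function(frac, cell) {
  if (is.null(dim(frac))) frac <- matrix(frac, ncol = 3)
  frac %*% cell
}

cart_to_frac <- function(cart, cell) {
  if (is.null(dim(cart))) cart <- matrix(cart, ncol = 3)
  cart %*% solve(cell)
}

wrap_frac <- function(frac) {
  w <- frac - floor(frac)
  w[w >= 1] <- 0  # guard against floor(1 - eps) artefacts
  w
}

#' Minimum-image vector between two fractional coordinates
#'
#' @param f1,f2 fractional coordinate triples.
#' @param cell 3x3 cell matrix.
#' @return cartesian vector (Angstrom) from f1 to the nearest image of f2.
#' @keywords internal
min_image_vec <- function(f1, f2, cell) {
  d <- f2 - f1
  d <- d - round(d)
  as.numeric(frac_to_cart(d, cell))
}

min_image_dist <- function(f1, f2, cell) {
  sqrt(sum(min_image_vec(f1, f2, cell)^2))
}
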