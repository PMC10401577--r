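# Fixtures built in code: a hand-sized thiol-like molecule in a box, and
# small spring systems with closed-form phonons.

# A 6-atom toy "cysteine fragment": C-C-S-H chain plus two oxygens on the
# first carbon, in a roomy orthorhombic cell. Site order:
# 1 C (carboxyl-like), 2 C, 3 S, 4 H(thiol), 5 O, 6 O.
make_thiol_molecule_crystal <- function(a = 12, b = 12, c = 12) {
  cart <- rbind(
    c(5.00, 5.00, 5.00),   # C1
    c(6.50, 5.20, 5.10),   # C2
    c(7.40, 6.40, 6.20),   # S
    c(8.43, 6.80, 5.50),   # H on S
    c(4.40, 6.05, 4.60),   # O
    c(4.40, 3.90, 5.40))   # O
  cell <- diag(c(a, b, c))
  crystal(cell, c("C", "C", "S", "H", "O", "O"), cart %*% solve(cell))
}

# The C-C-S-H torsion of the fixture above.
thiol_torsion <- function() torsion_spec(1, 2, 3, 4)

# Diatomic spring pair along x: one nonzero mode at sqrt(k (1/m1 + 1/m2)).
diatomic_force_constants <- function(k) {
  blk <- matrix(0, 3, 3); blk[1, 1] <- k
  fc <- matrix(0, 6, 6)
  fc[1:3, 1:3] <- blk; fc[4:6, 4:6] <- blk
  fc[1:3, 4:6] <- -blk; fc[4:6, 1:3] <- -blk
  fc
}

# Independent force-constant oracle for an arbitrary central-force spring
# network: springs is a data.frame(i, j, k, nx, ny, nz) with unit bond
# directions. Used to cross-check the generator's matrix assembly.
spring_network_fc <- function(n, springs) {
  fc <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(springs))) {
    nh <- as.numeric(springs[r, c("nx", "ny", "nz")])
    blk <- springs$k[r] * outer(nh, nh)
    ii <- (springs$i[r] - 1) * 3 + 1:3
    jj <- (springs$j[r] - 1) * 3 + 1:3
    fc[ii, ii] <- fc[ii, ii] + blk
    fc[jj, jj] <- fc[jj, jj] + blk
    fc[ii, jj] <- fc[ii, jj] - blk
    fc[jj, ii] <- fc[jj, ii] - blk
  }
  fc
}

# Signed dihedral by an independent projection construction (cis = 0):
# project the outer bonds onto the plane perpendicular to the axis and take
# the signed angle between the A-side and D-side components.
oracle_dihedral <- function(p) {
  axis <- p[3, ] - p[2, ]; axis <- axis / sqrt(sum(axis^2))
  u <- (p[1, ] - p[2, ]) - sum((p[1, ] - p[2, ]) * axis) * axis  # toward A
  v <- (p[4, ] - p[3, ]) - sum((p[4, ] - p[3, ]) * axis) * axis  # toward D
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  atan2(sum(cr(u, v) * axis), sum(u * v)) * 180 / pi
}

# Direct O(N^2) lag-sum dipole autocorrelation (biased 1/N normalization).
oracle_acf <- function(dm, nlag) {
  n <- nrow(dm)
  vapply(0:nlag, function(l) {
    s <- 0
    for (t in seq_len(n - l)) s <- s + sum(dm[t, ] * dm[t + l, ])
    s / n
  }, numeric(1))
}

expect_close <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) <= tol,
              label = sprintf("max|diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
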