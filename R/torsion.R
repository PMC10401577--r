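# Dihedral (torsion) geometry, thiol hydrogen-bond motif classification,
# and dispersed-disorder model generation.

#' Define a torsion by four sites
#'
#' Four ordered site indices A-B-C-D; B-C is the rotation axis. The dihedral
#' follows the IUPAC right-hand-rule sign convention with cis = 0 degrees,
#' reported in (-180, 180].
#'
#' @param a,b,c,d distinct site indices.
#' @return an integer vector of class \code{torsion_spec}.
#' @export
torsion_spec <- function(a, b, c, d) {
  ids <- as.integer(c(a, b, c, d))
  if (anyDuplicated(ids)) stop("torsion sites must be four distinct ids")
  structure(ids, class = "torsion_spec")
}

as_torsion_spec <- function(x) {
  if (inherits(x, "torsion_spec")) return(x)
  torsion_spec(x[1], x[2], x[3], x[4])
}

# Place the four torsion atoms in a contiguous cartesian frame by chaining
# minimum images: B anchors, A and C are placed relative to B, D relative
# to C.
torsion_cart <- function(crystal, spec) {
  f <- crystal$frac
  cell <- crystal$cell
  B <- as.numeric(frac_to_cart(f[spec[2], ], cell))
  A <- B + min_image_vec(f[spec[2], ], f[spec[1], ], cell)
  C <- B + min_image_vec(f[spec[2], ], f[spec[3], ], cell)
  D <- C + min_image_vec(f[spec[3], ], f[spec[4], ], cell)
  rbind(A, B, C, D)
}

dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("undefined dihedral: collinear A-B-C or B-C-D")
  }
  # IUPAC right-hand-rule convention, cis (eclipsed) = 0
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Wrap an angle into (-180, 180]
#' @param x angle(s) in degrees.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * round(x / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Measure a dihedral angle
#'
#' Signed dihedral A-B-C-D in degrees, IUPAC right-hand rule with cis = 0,
#' range (-180, 180]. Atoms are assembled by chained minimum images so the
#' result is invariant under lattice translation of any site.
#'
#' @param crystal a \code{\link{crystal}}.
#' @param spec a \code{\link{torsion_spec}} or 4-vector of site indices.
#' @return angle in degrees.
#' @export
measure_torsion <- function(crystal, spec) {
  spec <- as_torsion_spec(spec)
  if (any(spec > n_sites(crystal))) stop("torsion site index out of range")
  dihedral_angle(torsion_cart(crystal, spec))
}

# Site indices on the C-side of the B-C bond within the molecule, excluding
# C itself: the atoms that move when the torsion is rotated.
distal_sites <- function(crystal, spec, bonds = NULL) {
  if (is.null(bonds)) bonds <- bond_list(crystal)
  n <- n_sites(crystal)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  b <- spec[2]; cc <- spec[3]
  seen <- logical(n)
  seen[c(b, cc)] <- TRUE
  queue <- setdiff(adj[[cc]], b)
  out <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    if (v == b) stop("topology error: rotation axis lies in a ring")
    out <- c(out, v)
    queue <- c(queue, setdiff(adj[[v]], which(seen)))
  }
  if (seen[b] && b %in% out) stop("topology error: rotation axis lies in a ring")
  sort(out)
}

rodrigues <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Set a dihedral angle
#'
#' Rotates the atoms distal to the B-C bond (identified from the covalent
#' bond graph) rigidly about the B-C axis so that the measured dihedral
#' equals \code{target}. Bond lengths and angles not involving the rotation
#' are untouched.
#'
#' @inheritParams measure_torsion
#' @param target target angle in degrees; values outside (-180, 180] are
#'   normalized with a warning.
#' @param bonds optional precomputed \code{\link{bond_list}} (saves
#'   recomputing the bond graph in batch use).
#' @return the modified \code{crystal}.
#' @export
set_torsion <- function(crystal, spec, target, bonds = NULL) {
  spec <- as_torsion_spec(spec)
  if (target <= -180 || target > 180) {
    warning("target angle normalized into (-180, 180]")
    target <- wrap_angle(target)
  }
  current <- measure_torsion(crystal, spec)
  delta <- wrap_angle(target - current) * pi / 180
  if (abs(delta) < 1e-15) return(crystal)
  moving <- distal_sites(crystal, spec, bonds)
  p <- torsion_cart(crystal, spec)
  axis <- p[3, ] - p[2, ]   # B -> C
  origin <- p[3, ]
  fC <- crystal$frac[spec[3], ]
  rotate_by <- function(theta) {
    R <- rodrigues(axis, theta)
    out <- crystal
    for (v in moving) {
      pos <- origin + min_image_vec(fC, crystal$frac[v, ], crystal$cell)
      newpos <- origin + as.numeric(R %*% (pos - origin))
      out$frac[v, ] <- wrap_frac(cart_to_frac(newpos, crystal$cell))
    }
    out
  }
  # the handedness of the stored cell decides the rotation sense; try both
  for (s in c(1, -1)) {
    cand <- rotate_by(s * delta)
    if (abs(wrap_angle(measure_torsion(cand, spec) - target)) < 1e-6) return(cand)
  }
  stop("set_torsion failed to reach the target angle")
}

#' Classify the thiol hydrogen-bond motif
#'
#' Finds the nearest hydrogen-bond acceptor (S or O) to a donor thiol
#' hydrogen over all periodic images, excluding the sulfur the hydrogen is
#' covalently bonded to, and labels the motif \code{"SH...S"},
#' \code{"SH...O"} or \code{"none"}. A tie at exactly equal distance
#' resolves to S.
#'
#' @param crystal a \code{\link{crystal}}.
#' @param donor_h site index of the thiol hydrogen.
#' @param cutoff H-to-acceptor distance cutoff in Angstrom (default 3.0).
#' @return list with \code{motif}, \code{acceptor} (site index or NA) and
#'   \code{distance} (Angstrom or NA).
#' @export
classify_sh_motif <- function(crystal, donor_h, cutoff = 3.0) {
  if (crystal$elements[donor_h] != "H") stop("invalid donor: site is not a hydrogen")
  bonds <- bond_list(crystal)
  partners <- c(bonds[bonds[, 1] == donor_h, 2], bonds[bonds[, 2] == donor_h, 1])
  donor_s <- partners[crystal$elements[partners] == "S"]
  if (length(donor_s) == 0) stop("invalid donor: hydrogen is not bonded to a sulfur")
  donor_s <- donor_s[1]
  cand <- which(crystal$elements %in% c("S", "O"))
  cand <- setdiff(cand, c(donor_s, donor_h))
  if (length(cand) == 0) return(list(motif = "none", acceptor = NA, distance = NA))
  d <- vapply(cand, function(j) {
    min_image_dist(crystal$frac[donor_h, ], crystal$frac[j, ], crystal$cell)
  }, numeric(1))
  ok <- d <= cutoff
  if (!any(ok)) return(list(motif = "none", acceptor = NA, distance = NA))
  cand <- cand[ok]; d <- d[ok]
  best <- min(d)
  at_best <- cand[abs(d - best) < 1e-12]
  # tie resolves to sulfur
  el <- crystal$elements[at_best]
  pick <- if ("S" %in% el) at_best[el == "S"][1] else at_best[1]
  list(motif = paste0("SH...", crystal$elements[pick]),
       acceptor = pick, distance = best)
}

#' Run code with a private RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded generators leave
#' the caller's random state untouched.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a dispersed-disorder model
#'
#' Assigns one of two motif angles to each listed torsion: a random subset
#' of round(fraction * N) torsions (half-up rounding) gets \code{angles[1]},
#' the remainder \code{angles[2]}. The selection is uniform over subsets and
#' reproducible for a fixed seed.
#'
#' @param crystal a \code{\link{crystal}}.
#' @param torsions list of \code{\link{torsion_spec}}s (or 4-vectors).
#' @param angles numeric length-2: the two motif angles in degrees.
#' @param fraction fraction of torsions assigned \code{angles[1]}.
#' @param seed integer seed.
#' @return list with the modified \code{crystal} and a \code{plan}
#'   data.frame (torsion index, four site ids, assigned angle, flipped flag).
#' @export
generate_disorder_model <- function(crystal, torsions, angles, fraction, seed) {
  stopifnot(length(angles) == 2, fraction >= 0, fraction <= 1)
  torsions <- lapply(torsions, as_torsion_spec)
  keys <- vapply(torsions, paste, "", collapse = ",")
  if (anyDuplicated(keys)) stop("duplicate torsion specs")
  n <- length(torsions)
  n_a <- floor(fraction * n + 0.5)
  pick <- with_seed(seed, if (n_a > 0) sort(sample.int(n, n_a)) else integer(0))
  assigned <- rep(angles[2], n)
  assigned[pick] <- angles[1]
  bonds <- bond_list(crystal)
  for (k in seq_len(n)) {
    crystal <- set_torsion(crystal, torsions[[k]], assigned[k], bonds = bonds)
  }
  plan <- data.frame(
    torsion = seq_len(n),
    a = vapply(torsions, `[`, 1L, 1), b = vapply(torsions, `[`, 1L, 2),
    c = vapply(torsions, `[`, 1L, 3), d = vapply(torsions, `[`, 1L, 4),
    angle = assigned,
    flipped = seq_len(n) %in% pick)
  attr(plan, "seed") <- seed
  attr(plan, "fraction") <- fraction
  list(crystal = crystal, plan = plan)
}
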