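test_that("planar eclipsed chain measures 0 degrees and collinear errors", {
  cell <- diag(c(20, 20, 20))
  p <- rbind(c(-1, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(2.5, 1, 0))
  cr <- crystal(cell, rep("C", 4), sweep(p, 2, 10, "+") %*% solve(cell),
                molecules = list(1:4))
  expect_equal(measure_torsion(cr, torsion_spec(1, 2, 3, 4)), 0)
  # collinear A-B-C
  p2 <- p; p2[1, ] <- c(-1, 0, 0)
  cr2 <- crystal(cell, rep("C", 4), sweep(p2, 2, 10, "+") %*% solve(cell),
                 molecules = list(1:4))
  expect_error(measure_torsion(cr2, c(1, 2, 3, 4)), "collinear")
})

test_that("a geometry constructed by explicit rotation measures that angle", {
  cell <- diag(c(20, 20, 20))
  A <- c(-1, 1, 0); B <- c(0, 0, 0); C <- c(1.5, 0, 0); D0 <- c(2.5, 1, 0)
  axis <- (C - B) / sqrt(sum((C - B)^2))
  for (target in c(77.6, -85.4, 179.5, -0.3)) {
    th <- target * pi / 180
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    D <- C + as.numeric(R %*% (D0 - C))
    cr <- crystal(cell, rep("C", 4),
                  sweep(rbind(A, B, C, D), 2, 10, "+") %*% solve(cell),
                  molecules = list(1:4))
    expect_equal(measure_torsion(cr, c(1, 2, 3, 4)), target, tolerance = 1e-6)
  }
})

test_that("random geometries agree with the projection oracle", {
  cell <- diag(c(20, 20, 20))
  set.seed(42)
  for (i in 1:50) {
    p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    p[2, ] <- 0; p[3, ] <- c(1.4, 0.2, -0.3)
    cr <- crystal(cell, rep("C", 4),
                  sweep(p, 2, 10, "+") %*% solve(cell), molecules = list(1:4))
    expect_equal(measure_torsion(cr, c(1, 2, 3, 4)), oracle_dihedral(p),
                 tolerance = 1e-9)
  }
})

test_that("torsions are invariant under lattice translation of any atom", {
  cr <- make_thiol_molecule_crystal()
  ts <- thiol_torsion()
  ref <- measure_torsion(cr, ts)
  for (i in 1:4) {
    cr2 <- cr
    cr2$frac[i, ] <- wrap_frac(cr2$frac[i, ] + c(1, -2, 3))
    expect_equal(measure_torsion(cr2, ts), ref, tolerance = 1e-10)
  }
})

test_that("set_torsion reaches targets, moves only distal atoms, and inverts", {
  cr <- make_thiol_molecule_crystal()
  ts <- thiol_torsion()
  orig <- measure_torsion(cr, ts)
  # identity set leaves coordinates untouched
  expect_equal(set_torsion(cr, ts, orig)$frac, cr$frac, tolerance = 1e-12)
  # thiol motif swap: 77.6 -> -85.4, only the thiol hydrogen displaced
  cr1 <- set_torsion(cr, ts, 77.6)
  expect_equal(measure_torsion(cr1, ts), 77.6, tolerance = 1e-6)
  cr2 <- set_torsion(cr1, ts, -85.4)
  expect_equal(measure_torsion(cr2, ts), -85.4, tolerance = 1e-6)
  moved <- which(rowSums(abs(cr2$frac - cr1$frac)) > 1e-12)
  expect_equal(moved, 4L)  # only H
  # bond lengths not involving the rotation are unchanged
  d <- function(x, i, j) min_image_dist(x$frac[i, ], x$frac[j, ], x$cell)
  for (pair in list(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(1, 6))) {
    expect_equal(d(cr2, pair[1], pair[2]), d(cr1, pair[1], pair[2]),
                 tolerance = 1e-9)
  }
  # set then set back restores coordinates
  back <- set_torsion(cr2, ts, measure_torsion(cr1, ts))
  expect_equal(back$frac, cr1$frac, tolerance = 1e-9)
  expect_warning(set_torsion(cr, ts, 270), "normalized")
})

test_that("set/measure round trip stays below 1e-6 deg for random targets", {
  cr <- make_thiol_molecule_crystal()
  ts <- thiol_torsion()
  set.seed(7)
  targets <- stats::runif(1000, -179.99, 180)
  worst <- 0
  for (t in targets) {
    got <- measure_torsion(set_torsion(cr, ts, t), ts)
    worst <- max(worst, abs(wrap_angle(got - t)))
  }
  expect_lt(worst, 1e-6)
})

test_that("motif classification picks the nearest acceptor with tie to S", {
  cell <- diag(c(14, 14, 14))
  # S-H donor, one S acceptor at 2.0 A, one O at 3.5 A from H
  cart <- rbind(c(5, 5, 5),           # S donor
                c(6.34, 5, 5),        # H (1.34 from S)
                c(8.34, 5, 5),        # S acceptor, 2.0 from H
                c(6.34, 8.5, 5))      # O, 3.5 from H
  cr <- crystal(cell, c("S", "H", "S", "O"), cart %*% solve(cell),
                molecules = list(1:2, 3, 4))
  m <- classify_sh_motif(cr, 2, cutoff = 3.0)
  expect_equal(m$motif, "SH...S")
  expect_equal(m$acceptor, 3L)
  expect_equal(m$distance, 2.0, tolerance = 1e-9)
  # no acceptor within cutoff
  expect_equal(classify_sh_motif(cr, 2, cutoff = 1.5)$motif, "none")
  # invalid donor
  expect_error(classify_sh_motif(cr, 1), "not a hydrogen")
})

test_that("motif classification matches an exhaustive periodic-image scan", {
  set.seed(11)
  cell <- diag(c(9, 10, 11))
  for (rep in 1:20) {
    cart <- rbind(c(4, 4, 4), c(5.34, 4, 4),
                  matrix(stats::runif(9, 0, 9), 3, 3))
    els <- c("S", "H", sample(c("S", "O"), 3, replace = TRUE))
    cr <- crystal(cell, els, cart %*% solve(cell),
                  molecules = list(1:2, 3, 4, 5))
    got <- classify_sh_motif(cr, 2, cutoff = 4.0)
    # brute force over all images in -2..2
    best_d <- Inf; best_el <- NA
    for (j in 3:5) {
      for (ix in -2:2) for (iy in -2:2) for (iz in -2:2) {
        img <- cart[j, ] + c(ix * 9, iy * 10, iz * 11)
        d <- sqrt(sum((img - cart[2, ])^2))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) < 1e-12 && els[j] == "S")) {
          best_d <- d; best_el <- els[j]
        }
      }
    }
    if (best_d <= 4.0) {
      expect_equal(got$motif, paste0("SH...", best_el))
      expect_equal(got$distance, best_d, tolerance = 1e-9)
    } else {
      expect_equal(got$motif, "none")
    }
  }
})

test_that("disorder generator assigns exact half/half counts reproducibly", {
  base <- make_thiol_molecule_crystal()
  sc <- build_supercell(base, c(2, 2, 2))
  specs <- lapply(0:7, function(k) torsion_spec(6 * k + 1, 6 * k + 2,
                                                6 * k + 3, 6 * k + 4))
  res <- generate_disorder_model(sc, specs, angles = c(-78.4, 87.0),
                                 fraction = 0.5, seed = 3)
  expect_equal(sum(res$plan$angle == -78.4), 4)
  expect_equal(sum(res$plan$angle == 87.0), 4)
  for (k in seq_along(specs)) {
    expect_equal(measure_torsion(res$crystal, specs[[k]]),
                 res$plan$angle[k], tolerance = 1e-6)
  }
  res2 <- generate_disorder_model(sc, specs, angles = c(-78.4, 87.0),
                                  fraction = 0.5, seed = 3)
  expect_identical(res$crystal$frac, res2$crystal$frac)
  # fraction 0: everything at angle B, no flips in the plan
  res0 <- generate_disorder_model(sc, specs, angles = c(-78.4, 87.0),
                                  fraction = 0, seed = 3)
  expect_true(all(res0$plan$angle == 87.0))
  expect_false(any(res0$plan$flipped))
  # all motifs classify identically in the single-motif cell
  expect_error(generate_disorder_model(sc, c(specs, specs[1]),
                                       c(-78.4, 87), 0.5, 1), "duplicate")
})

test_that("disorder selection is uniform over subsets across seeds", {
  base <- make_thiol_molecule_crystal()
  sc <- build_supercell(base, c(4, 1, 1))
  specs <- lapply(0:3, function(k) torsion_spec(6 * k + 1, 6 * k + 2,
                                                6 * k + 3, 6 * k + 4))
  keys <- character(1000)
  for (s in 1:1000) {
    plan <- generate_disorder_model(sc, specs, c(-78.4, 87), 0.5, seed = s)$plan
    keys[s] <- paste(which(plan$flipped), collapse = ",")
  }
  tab <- table(keys)
  expect_length(tab, choose(4, 2))
  expect_gt(stats::chisq.test(as.vector(tab))$p.value, 0.01)
})
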