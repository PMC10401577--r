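test_that("oscillator strengths: zero charges, acoustic modes, closed form", {
  sys <- make_toy_molecular_crystal(2, seed = 3)
  modes <- toy_phonons(sys)
  V <- cell_volume(sys$crystal$cell)
  # all Born charges zero -> all strengths zero
  m0 <- modes; m0$born <- array(0, dim(modes$born))
  expect_true(all(mode_intensities(m0, V) == 0))
  # acoustic (uniform translation, charge-neutral) modes have zero strength
  S <- mode_intensities(modes, V)
  smag <- apply(S, 3, function(x) sum(diag(x)) / 3)
  expect_lt(max(smag[modes$acoustic]), 1e-10 * max(smag))
  # missing Born charges -> configuration error
  m1 <- modes; m1$born <- NULL
  expect_error(mode_intensities(m1, V), "Born")
})

test_that("two-ion strength matches the reduced-mass closed form", {
  k <- 6; m1 <- 12; m2 <- 30; Z <- 0.7; V <- 400
  fc <- diatomic_force_constants(k)
  born <- array(0, c(3, 3, 2))
  born[, , 1] <- diag(3) * Z; born[, , 2] <- -diag(3) * Z
  modes <- gamma_phonons(fc, c(m1, m2), born_charges = born, eps_inf = 2)
  S <- mode_intensities(modes, V)
  stretch <- which(modes$frequency > 0.5)
  # closed form evaluated independently: |Z|^2 / mu with mu the reduced mass
  mu <- m1 * m2 / (m1 + m2)
  pref <- (1.602176634e-19^2 / 1.66053906660e-27) /
    (8.8541878128e-12 * 1e-30 * (2 * pi * 2.99792458e10)^2)
  oracle <- pref * Z^2 / mu / V
  expect_equal(S[1, 1, stretch], oracle, tolerance = 1e-10)
})

test_that("Lorentz dielectric limits: no modes, static limit, peak shape", {
  sys <- make_toy_molecular_crystal(2, seed = 3)
  modes <- toy_phonons(sys)
  V <- cell_volume(sys$crystal$cell)
  conf <- spectrum_config(gamma = 1, grid = seq(1, 120, by = 0.05))
  # no modes -> eps = eps_inf everywhere
  m0 <- modes
  m0$acoustic <- rep(TRUE, length(modes$frequency))  # mask all modes out
  eps0 <- dielectric_function(m0, mode_intensities(modes, V), conf)
  expect_true(all(abs(eps0 - 2.5) < 1e-14))
  # single synthetic mode: static limit and peak location/FWHM
  w0 <- 60; Sk <- 4000
  m1 <- modes
  m1$frequency <- w0; m1$acoustic <- FALSE; m1$imaginary <- FALSE
  S1 <- array(0, c(3, 3, 1)); S1[1, 1, 1] <- S1[2, 2, 1] <- S1[3, 3, 1] <- Sk
  eps <- dielectric_function(m1, S1, conf)
  # static limit (grid starts at 1 cm^-1, hence the 1e-6 tolerance)
  expect_equal(Re(eps[1]), 2.5 + Sk / (w0^2 - 1), tolerance = 1e-6)
  im <- Im(eps)
  pk <- conf$grid[which.max(im)]
  expect_lt(abs(pk - w0), 0.1)
  # numeric FWHM oracle against the broadening parameter
  half <- max(im) / 2
  above <- range(conf$grid[im >= half])
  expect_equal(diff(above), conf$gamma, tolerance = 0.05)
  expect_true(all(im > -1e-12))
})

test_that("Maxwell-Garnett limits are exact and the dilute expansion holds", {
  eps_i <- complex(real = c(3, 5, 2.2), imaginary = c(0.5, 2, 0))
  expect_equal(maxwell_garnett(eps_i, 2, 0), rep(2 + 0i, 3), tolerance = 1e-15)
  expect_equal(maxwell_garnett(2 + 0i, 2, 0.37), 2 + 0i, tolerance = 1e-15)
  expect_equal(maxwell_garnett(eps_i, 2, 1), eps_i, tolerance = 1e-12)
  # small-contrast dilute expansion to first order in (eps_i - eps_m)
  eps_m <- 2; f <- 0.1; d <- 0.01 + 0.004i
  got <- maxwell_garnett(eps_m + d, eps_m, f)
  first_order <- eps_m + f * d
  expect_lt(Mod(got - first_order), 1e-3 * Mod(d))
})

test_that("powder absorption uses the principal square-root branch", {
  conf <- spectrum_config(grid = seq(10, 100, by = 10))
  # real positive permittivity -> transparent, alpha = 0
  sp <- powder_absorption(rep(2.1 + 0i, 10), conf)
  expect_true(all(sp$absorption == 0))
  # tabulated complex eps vs an independent principal-branch oracle
  eps <- complex(real = c(-3, 1.5, 2, -0.2, 4), imaginary = c(1, 0.3, 2, 5, 0))
  conf2 <- spectrum_config(grid = seq(20, 100, by = 20))
  sp2 <- powder_absorption(eps, conf2)
  oracle <- vapply(seq_along(eps), function(i) {
    r <- Mod(eps[i]); th <- Arg(eps[i])
    kappa <- abs(sqrt(r) * sin(th / 2))
    4 * pi * conf2$grid[i] * kappa
  }, numeric(1))
  expect_equal(sp2$absorption, oracle, tolerance = 1e-10)
  # default configuration is recorded in the provenance
  expect_equal(sp$config$gamma, 5)
  expect_equal(sp$config$volume_fraction, 0.10)
  expect_equal(sp$method, "static")
})

test_that("integrated absorption scales linearly with oscillator strength", {
  sys <- make_toy_molecular_crystal(2, seed = 3)
  modes <- toy_phonons(sys)
  V <- cell_volume(sys$crystal$cell)
  conf <- spectrum_config(gamma = 3, grid = seq(2, 160, by = 0.2))
  S <- mode_intensities(modes, V)
  band <- conf$grid > 70 & conf$grid < 90  # isolates the 79.4 cm^-1 mode
  # work in the weak-oscillator regime where the effective-medium mixing and
  # the square root are locally linear
  area <- function(scale) {
    S2 <- S * 1e-3
    k <- which.min(abs(modes$frequency - 79.41))
    S2[, , k] <- S2[, , k] * scale
    eps <- dielectric_function(modes, S2, conf)
    al <- powder_absorption(maxwell_garnett(eps, 2, 0.1), conf)$absorption
    sum(al[band]) * 0.2
  }
  a1 <- area(1); a2 <- area(2)
  # subtract the background contributed by other modes
  a0 <- area(0)
  expect_equal((a2 - a0) / (a1 - a0), 2, tolerance = 0.01)
})

test_that("Kramers-Kronig consistency of the Lorentzian permittivity", {
  # single mode; check Re eps at several probe frequencies from Im eps
  w0 <- 300; Sk <- 5e4; gam <- 4; eps_inf <- 2
  grid <- seq(0.25, 6000, by = 0.5)
  denom <- w0^2 - grid^2 - 1i * gam * grid
  eps <- eps_inf + Sk / denom
  im <- Im(eps)
  for (wp in c(100, 250, 450)) {
    integrand <- grid * im / (grid^2 - wp^2)
    # exclude the principal-value singularity symmetrically
    keep <- abs(grid - wp) > 2
    kk <- (2 / pi) * sum(integrand[keep]) * 0.5
    re_direct <- Re(eps_inf + Sk / (w0^2 - wp^2 - 1i * gam * wp)) - eps_inf
    expect_equal(kk, re_direct, tolerance = 0.02)
  }
})

test_that("spectrum CSV/JSON output round trips", {
  sys <- make_toy_molecular_crystal(2, seed = 3)
  sp <- static_spectrum(toy_phonons(sys), cell_volume(sys$crystal$cell),
                        spectrum_config(grid = seq(5, 100, by = 1)))
  f <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_spectrum(sp, f, fj)
  df <- read.csv(f)
  expect_equal(df$absorption_cm1, sp$absorption, tolerance = 1e-6)
  js <- jsonlite::read_json(fj)
  expect_equal(js$config$gamma, 5)
  expect_equal(js$method, "static")
})
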