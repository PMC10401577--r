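test_that("dipole ACF: constant, cosine, and direct-sum oracle", {
  # constant dipole: zero after mean removal
  n <- 400
  tr <- dipole_trajectory((0:(n - 1)) * 1.0,
                          matrix(rep(c(1, 2, 3), each = n), n, 3), 500, 300)
  a <- dipole_acf(tr)
  expect_true(all(abs(a$acf) < 1e-20))
  # pure cosine: C(t) proportional to cos(w0 t) up to the (n - l)/n factor
  # of the 1/n lag normalization
  w0 <- 2 * pi / 50
  t <- (0:4999) * 1.0
  tr2 <- dipole_trajectory(t, cbind(cos(w0 * t), 0, 0), 500, 300)
  a2 <- dipole_acf(tr2, max_lag = 500)
  nfr <- 5000
  expect_equal(a2$acf / a2$acf[1],
               cos(w0 * a2$lag) * (nfr - a2$lag) / nfr, tolerance = 0.01)
  # 1000-frame random series equals the brute-force double sum
  set.seed(3)
  dm <- matrix(stats::rnorm(3000), 1000, 3)
  tr3 <- dipole_trajectory((0:999) * 2.0, dm, 500, 300)
  a3 <- dipole_acf(tr3, max_lag = 400)
  dmc <- sweep(dm, 2, colMeans(dm))
  oracle <- oracle_acf(dmc, 200)
  expect_close(a3$acf[1:201], oracle, 1e-10 * a3$acf[1])
  # C(0) equals the summed component variances
  expect_equal(a3$acf[1], sum(apply(dmc, 2, function(x) mean(x^2))),
               tolerance = 1e-12)
  # max lag clipping warns
  expect_warning(dipole_acf(tr3, max_lag = 1e9), "clipped")
})

test_that("window families evaluate to 1 at zero lag and record provenance", {
  t <- (0:999) * 1.0
  tr <- dipole_trajectory(t, cbind(sin(t / 7), 0, 0), 500, 300)
  a <- dipole_acf(tr, max_lag = 500)
  for (fam in c("hann", "gaussian", "exponential")) {
    w <- apply_window(a, window_spec(fam, 200))
    expect_equal(w$acf[1], a$acf[1])
    expect_equal(w$window$family, fam)
    expect_equal(w$window$width, 200)
  }
  # an extremely wide gaussian is the identity within 1e-9
  wide <- apply_window(a, window_spec("gaussian", 1e9))
  expect_close(wide$acf, a$acf, 1e-9 * abs(a$acf[1]))
})

test_that("Gaussian window imposes the analytic Gaussian line shape", {
  # noiseless cosine at w0: windowed transform is a Gaussian at w0 whose
  # frequency-domain sd is 1/width (analytic convolution oracle)
  w0_cm <- 100
  w0 <- w0_cm * phys_const$radfs_per_cm1    # rad/fs
  dt <- 2; n <- 40000
  t <- (0:(n - 1)) * dt
  tr <- dipole_trajectory(t, cbind(cos(w0 * t), 0, 0), 500, 300)
  a <- dipole_acf(tr, max_lag = 20000)
  width <- 3000
  aw <- apply_window(a, window_spec("gaussian", width))
  grid <- seq(80, 120, by = 0.05)
  sp <- absorption_from_acf(aw, grid)
  im <- Im(sp$epsilon) / grid   # remove the linear-response w factor
  pk <- which.max(im)
  expect_lt(abs(grid[pk] - w0_cm), 0.1)
  # fitted Gaussian sigma vs analytic width/(width in fs) -> cm^-1
  half <- im >= max(im) / 2
  fwhm_cm <- diff(range(grid[half]))
  sigma_analytic_cm <- (1 / width) / phys_const$radfs_per_cm1
  expect_equal(fwhm_cm, 2.3548 * sigma_analytic_cm, tolerance = 0.05)
})

test_that("narrow and wide windows conserve the integrated spectral area", {
  # area of Im chi / w recovers (pi/2) C(0) independent of the window
  tau <- 150; amp <- 0.3
  tr <- make_ou_dipole(tau, amp, 1.0, 60000, seed = 2)
  a <- dipole_acf(tr, max_lag = 6000)
  grid <- seq(0.4, 1200, by = 0.4)
  areas <- vapply(c(400, 1500), function(wd) {
    sp <- absorption_from_acf(apply_window(a, window_spec("gaussian", wd)),
                              grid)
    sum((Im(sp$epsilon) - 0) / grid) * 0.4
  }, numeric(1))
  expect_equal(areas[1], areas[2], tolerance = 0.01)
  # Parseval-type identity: integral of Im chi / w over frequency recovers
  # (pi/2) beta C(0) / (3 V eps0); the integral is unit-invariant
  pref <- phys_const$e2A_per_eps0_eV /
    (3 * a$volume * phys_const$kB_eV * a$temperature)
  target <- (pi / 2) * pref * a$acf[1]
  expect_equal(areas[2], target, tolerance = 0.03)
})

test_that("an exponential ACF transforms to the Debye line shape", {
  # deterministic exponential correlation, built directly
  tau <- 100; c0 <- 1.0; dt <- 1.0
  lag <- (0:5000) * dt
  acf <- structure(list(lag = lag, acf = c0 * exp(-lag / tau), dt = dt,
                        volume = 500, temperature = 300, window = NULL),
                   class = "dipole_acf")
  w_peak_cm <- (1 / tau) / phys_const$radfs_per_cm1   # ~53.1 cm^-1
  grid <- seq(1, 400, by = 0.25)
  sp <- absorption_from_acf(acf, grid)
  im <- Im(sp$epsilon)
  expect_lt(abs(grid[which.max(im)] - w_peak_cm), 0.5)
  # closed-form Debye check at several frequencies
  pref <- phys_const$e2A_per_eps0_eV / (3 * 500 * phys_const$kB_eV * 300)
  for (gi in c(40, 400, 1200)) {
    w <- grid[gi] * phys_const$radfs_per_cm1
    debye <- pref * c0 * w * tau / (1 + (w * tau)^2)
    expect_equal(im[gi], debye, tolerance = 0.01)
  }
  expect_true(all(im > -1e-12))
})

test_that("a noiseless cosine produces a single peak at its frequency", {
  w0_cm <- 100
  w0 <- w0_cm * phys_const$radfs_per_cm1
  dt <- 4; n <- 20000
  t <- (0:(n - 1)) * dt
  tr <- dipole_trajectory(t, cbind(cos(w0 * t), cos(w0 * t + 1), 0), 500, 300)
  a <- dipole_acf(tr, max_lag = n * dt / 2)
  aw <- apply_window(a, window_spec("hann", n * dt / 2))
  grid <- seq(5, 300, by = 0.25)
  sp <- absorption_from_acf(aw, grid)
  resolution_cm <- (1 / (n * dt)) / phys_const$radfs_per_cm1 * 2 * pi
  expect_lt(abs(grid[which.max(Im(sp$epsilon))] - w0_cm), resolution_cm)
})

test_that("quantum correction multiplies Im eps by the harmonic factor", {
  tr <- make_ou_dipole(100, 0.2, 1.0, 20000, seed = 4)
  a <- dipole_acf(tr, max_lag = 3000)
  grid <- seq(5, 300, by = 1)
  s0 <- absorption_from_acf(a, grid)
  s1 <- absorption_from_acf(a, grid, quantum_correction = TRUE)
  x <- grid * phys_const$eV_per_cm1 / (phys_const$kB_eV * 300)
  expect_equal(Im(s1$epsilon), Im(s0$epsilon) * x / (1 - exp(-x)),
               tolerance = 1e-10)
  expect_true(s1$config$quantum_correction)
})

test_that("compare_spectra reports identity, scaling and peak deltas", {
  sys <- make_toy_molecular_crystal(2, seed = 3)
  sp <- static_spectrum(toy_phonons(sys), cell_volume(sys$crystal$cell),
                        spectrum_config(grid = seq(5, 150, by = 0.5)))
  same <- compare_spectra(sp, sp, band = c(10, 140))
  expect_equal(same$ratio, 1)
  expect_equal(same$peak_delta, 0)
  expect_equal(same$cosine, 1)
  sp2 <- sp; sp2$absorption <- 2 * sp$absorption
  expect_equal(compare_spectra(sp, sp2, c(10, 140))$ratio, 0.5)
  # peak positions against an independent per-band argmax oracle
  cmp <- compare_spectra(sp, sp2, c(40, 90))
  g <- seq(40, 90, length.out = 512)
  y <- stats::approx(sp$frequency, sp$absorption, g)$y
  expect_equal(cmp$peak_a, g[which.max(y)])
})
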