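test_that("Gibson-Lanni phase vanishes at the design condition", {
  setup <- fx_setup_high()
  # design condition: emitter at the coverslip (t_s = 0), every actual
  # layer equal to its design counterpart -> term-by-term cancellation
  med <- layered_medium(n_s = 1.33, n_i = 1.5, n_g = 1.5,
                        t_s = 0, t_i = 130e3, t_g = 170e3,
                        t_i_star = 130e3, t_g_star = 170e3)
  st <- seq(0, 1.3 / 1.5, length.out = 41)
  w <- gibson_lanni_phase(med, setup, st)
  expect_equal(max(Mod(w)), 0, tolerance = 1e-18)
})

test_that("Gibson-Lanni phase at theta = 0 matches the hand-evaluated OPD", {
  setup <- fx_setup_high()
  med <- layered_medium(n_s = 1.3, n_i = 1.5, n_g = 1.52,
                        t_s = 1e3, t_i = 120e3, t_g = 170e3,
                        n_i_star = 1.515, n_g_star = 1.5,
                        t_i_star = 130e3, t_g_star = 165e3)
  w0 <- gibson_lanni_phase(med, setup, 0)
  expected <- 2 * pi / 632 *
    (1e3 * 1.3 + 120e3 * 1.5 - 130e3 * 1.515 + 170e3 * 1.52 - 165e3 * 1.5)
  expect_equal(Re(w0), expected, tolerance = 1e-12)
  expect_equal(Im(w0), 0, tolerance = 1e-15)
})

test_that("Gibson-Lanni phase is real below every critical angle and complex above", {
  setup <- fx_setup_high()
  med <- layered_medium(n_s = 1.33, n_i = 1.5, n_g = 1.5,
                        t_s = 2e3, t_i = 100e3, t_g = 170e3,
                        t_i_star = 100e3, t_g_star = 170e3)
  st <- seq(0, 1.3 / 1.5, length.out = 101)
  w <- gibson_lanni_phase(med, setup, st)
  sub <- st < 1.33 / 1.5   # below the sample critical angle
  expect_true(all(Mod(Im(w[sub])) < 1e-12))
  expect_true(all(Im(w[!sub & st > 1.33 / 1.5 + 0.01]) > 0))
})

test_that("the focusing condition reproduces the design immersion thickness", {
  # matched conditions must give t_i = t_i*
  m1 <- layered_medium(n_s = 1.5, n_i = 1.5, n_g = 1.5,
                       t_s = 3e3, t_g = 170e3,
                       t_i_star = 111e3, t_g_star = 170e3)
  expect_equal(immersion_thickness_from_focus(m1), 111e3, tolerance = 1e-9)

  # n_s = n_i with matched glass also cancels
  m2 <- layered_medium(n_s = 1.4, n_i = 1.4, n_g = 1.52,
                       t_s = 5e3, t_g = 170e3,
                       t_i_star = 90e3, t_g_star = 170e3)
  expect_equal(immersion_thickness_from_focus(m2), 90e3, tolerance = 1e-9)

  # mismatched stack of the high-NA gallery yields a finite positive value
  m3 <- layered_medium(n_s = 1.3, n_i = 1.5, n_g = 1.5,
                       t_s = 1e3, t_g = 170e3,
                       t_i_star = 130e3, t_g_star = 170e3)
  ti <- immersion_thickness_from_focus(m3)
  expect_equal(ti, 1e3 + 1.5 * (-1e3 / 1.3 + 130e3 / 1.5), tolerance = 1e-9)
  expect_gt(ti, 0)
})

test_that("Zernike basis is orthonormal over the unit disk", {
  n <- 512
  ax <- seq(-1, 1, length.out = n)
  rho <- sqrt(outer(ax^2, ax^2, `+`))
  phi <- atan2(matrix(ax, n, n, byrow = TRUE), matrix(ax, n, n))
  inside <- rho <= 1
  area <- 4 / n^2 / pi                     # dA / pi on the unit square
  zs <- lapply(0:9, function(j) zernike(j, rho, phi)[inside])
  gram <- sapply(zs, function(a) sapply(zs, function(b) sum(a * b) * area))
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-3)  # off-diagonals
  # diagonals reach 1 up to the pixelised disk boundary (~0.5% at 512^2)
  expect_lt(max(abs(diag(gram) - 1)), 1e-2)
})

test_that("zernike_phase assembles coefficients and custom masks", {
  setup <- fx_setup_low()
  g <- fx_grid_small()
  n <- g$pupil_size
  expect_equal(zernike_phase(aberration_spec(), setup, g), matrix(0, n, n))
  # piston is 1 everywhere on the disk
  w <- zernike_phase(aberration_spec(list(c(0, 1))), setup, g)
  pc <- pupil_coords(setup, n)
  expect_true(all(abs(w[pc$inside] - 1) < 1e-12))
  # a single coefficient is recovered by the disk inner product
  ck <- 0.8
  w5 <- zernike_phase(aberration_spec(list(c(5, ck))), setup, g)
  d <- derived_quantities(setup)
  rho <- pc$sr / d$s_max
  z5 <- zernike(5, rho, pc$phi)
  recovered <- sum(w5[pc$inside] * z5[pc$inside]) /
    sum(pc$inside) # mean over disk samples ~ (1/pi) int dA
  expect_equal(recovered, ck, tolerance = 2e-2)
  # waves toggle multiplies by 2 pi
  w5w <- zernike_phase(aberration_spec(list(c(5, ck)), unit = "waves"),
                       setup, g)
  expect_equal(w5w, 2 * pi * w5, tolerance = 1e-12)
  # custom mask adds on top
  mask <- matrix(0.25, n, n)
  wm <- zernike_phase(aberration_spec(list(c(5, ck)), custom_phase = mask),
                      setup, g)
  expect_equal(wm, w5 + 0.25, tolerance = 1e-12)
})

test_that("vortex and half-moon masks have the stated geometry", {
  setup <- fx_setup_low()
  g <- fx_grid_small()
  expect_true(all(vortex_phase(setup, g, 0L) == 0))
  w <- vortex_phase(setup, g, 1L)
  pc <- pupil_coords(setup, g$pupil_size)
  i <- which(abs(pc$phi - pi / 2) < 1e-12)  # points on the +y axis
  expect_true(length(i) > 0)
  expect_equal(unique(w[i]), pi / 2, tolerance = 1e-12)
  hm <- half_moon_phase(setup, g)
  expect_true(all(hm[pc$sx > 0] == pi) && all(hm[pc$sx <= 0] == 0))
})

test_that("apodisation and gaussian envelope behave at their anchors", {
  st <- seq(0, 0.99, length.out = 50)
  a <- apodisation(st)
  expect_equal(a[1], 1)
  expect_true(all(diff(a) < 0))
  expect_equal(apodisation(st, exponent = 0.5), sqrt(sqrt(1 - st^2)),
               tolerance = 1e-14)
  expect_equal(gaussian_envelope(0, 0.3), 1)
  expect_equal(gaussian_envelope(0.3, 0.3), exp(-1), tolerance = 1e-15)
  expect_true(all(gaussian_envelope(st, 1e6) > 1 - 1e-9))
  expect_error(gaussian_envelope(st, -1), "positive")
})

test_that("Fresnel coefficients reduce to known values", {
  # single medium: empty product
  f1 <- fresnel_coefficients(1.33, seq(0, 1, length.out = 5))
  expect_true(all(f1$q_s == 1) && all(f1$q_p == 1))
  # two equal indices: still 1
  f2 <- fresnel_coefficients(c(1.5, 1.5), 0.7)
  expect_equal(Mod(f2$q_s), 1, tolerance = 1e-14)
  expect_equal(Mod(f2$q_p), 1, tolerance = 1e-14)
  # normal incidence air -> glass: 2*1/(1+1.5) = 0.8
  f3 <- fresnel_coefficients(c(1.0, 1.5), 0)
  expect_equal(Re(f3$q_s), 0.8, tolerance = 1e-14)
  expect_equal(Re(f3$q_p), 0.8, tolerance = 1e-14)
  # supercritical glass -> air transmission turns complex (evanescent)
  f4 <- fresnel_coefficients(c(1.5, 1.0), 60 * pi / 180)
  expect_gt(Mod(Im(f4$q_s)), 0)
})

test_that("correction composition is additive in phase, multiplicative in amplitude", {
  setup <- fx_setup_low()
  g <- fx_grid_small()
  p <- uniform_pupil(setup, g)
  n <- g$pupil_size
  set.seed(7)
  w1 <- matrix(runif(n^2, -1, 1), n, n)
  w2 <- matrix(runif(n^2, -1, 1), n, n)
  a1 <- matrix(runif(n^2, 0, 2), n, n)
  both <- apply_corrections(p, amplitude = a1, phase = list(w1, w2))
  seq2 <- apply_corrections(p, amplitude = a1, phase = w1 + w2)
  expect_equal(both$values, seq2$values, tolerance = 1e-14)
  # identity when no factors are given
  expect_equal(apply_corrections(p)$values, p$values)
  # zeros propagate
  a0 <- a1; a0[3, ] <- 0
  pz <- apply_corrections(p, amplitude = a0)
  expect_true(all(pz$values[1, 3, ] == 0))
  expect_error(apply_corrections(p, amplitude = matrix(1, 3, 3)), "shape")
})
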