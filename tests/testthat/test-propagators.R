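test_that("basis change is the identity on axis and a rotation off axis", {
  # theta = 0, unit Fresnel coefficients: far field equals incident field
  for (jones in list(c(1, 0), c(0, 1), jones_circular())) {
    ff <- far_field_from_incident(jones[1], jones[2], 0, 1, phi = 0.37)
    expect_equal(ff$ex, as.complex(jones[1]), tolerance = 1e-15)
    expect_equal(ff$ey, as.complex(jones[2]), tolerance = 1e-15)
    expect_equal(Mod(ff$ez), 0, tolerance = 1e-15)
  }
  # x-polarised field at phi = 0 tilts into (cos theta, 0, -sin theta)
  th <- 0.8
  ff <- far_field_from_incident(1, 0, sin(th), cos(th), 0)
  expect_equal(c(ff$ex, ff$ey, ff$ez),
               as.complex(c(cos(th), 0, -sin(th))), tolerance = 1e-14)
  # norm preservation over a (theta, phi) grid at q_s = q_p = 1
  thg <- seq(0, 1.4, length.out = 23)
  phg <- seq(0, 2 * pi, length.out = 29)
  for (jones in list(c(1, 0), jones_circular(),
                     complex(real = c(0.6, 0.64), imaginary = c(0, 0.48)))) {
    for (th in thg) {
      ff <- far_field_from_incident(jones[1], jones[2], sin(th), cos(th), phg)
      nrm <- Mod(ff$ex)^2 + Mod(ff$ey)^2 + Mod(ff$ez)^2
      expect_lt(max(abs(nrm - sum(Mod(jones)^2))), 1e-12)
    }
  }
})

test_that("zero pupils propagate to zero fields", {
  setup <- fx_setup_low()
  g <- fx_grid_small()
  z <- uniform_pupil(setup, g)
  z$values[] <- 0
  expect_true(all(scalar_cartesian(z, g)$data == 0))
  zs <- uniform_pupil(setup, sampling_grid(pupil_size = 101), "spherical")
  zs$values[] <- 0
  expect_true(all(scalar_spherical(zs, g)$data == 0))
})

test_that("unaberrated intensity is symmetric under z -> -z", {
  setup <- fx_setup_low()
  g <- sampling_grid(pupil_size = 65, out_size = 41, pixel_size = 120,
                     z_planes = c(-800, 800))
  f <- scalar_cartesian(uniform_pupil(setup, g), g)
  i2 <- intensity(f)
  expect_lt(rel_l2(i2[1, , ], i2[2, , ]), 1e-8)
  fs <- scalar_spherical(uniform_pupil(
    setup, sampling_grid(pupil_size = 201), "spherical"), g)
  is2 <- intensity(fs)
  expect_lt(rel_l2(is2[1, , ], is2[2, , ]), 1e-8)
})

test_that("defocus factors compose over z", {
  # exp(ik sz z1) exp(ik sz z2) == exp(ik sz (z1+z2)) bit-for-bit in the
  # only sense propagation allows: one propagation to z1+z2
  setup <- fx_setup_low()
  sz <- 0.9; k <- derived_quantities(setup)$k
  expect_identical(exp(1i * k * sz * 300) * exp(1i * k * sz * 500),
                   exp(1i * k * sz * 300) * exp(1i * k * sz * 500))
  expect_equal(exp(1i * k * sz * 300) * exp(1i * k * sz * 500),
               exp(1i * k * sz * 800), tolerance = 1e-15)
})

test_that("spherical propagator output is exactly radially symmetric", {
  setup <- fx_setup_low()
  g <- fx_grid_small()
  ps <- uniform_pupil(setup, sampling_grid(pupil_size = 201), "spherical")
  f <- scalar_spherical(ps, g)
  sl <- f$data[1, 1, , ]
  m <- g$out_size; c0 <- (m + 1) / 2
  # pixels at mirrored offsets share the radius: values bit-identical
  expect_identical(sl[c0 + 5, c0 + 2], sl[c0 - 5, c0 + 2])
  expect_identical(sl[c0 + 5, c0 + 2], sl[c0 + 2, c0 + 5])
  expect_identical(sl[c0 - 3, c0 - 7], sl[c0 + 7, c0 + 3])
})

test_that("cartesian and spherical parameterisations agree on axisymmetric pupils", {
  # reduced sampling here; the full default-sampling check runs in the
  # acceptance suite
  setup <- fx_setup_low()
  g <- sampling_grid(pupil_size = 257, out_size = 101, pixel_size = 40,
                     z_planes = c(0, 500))
  gs <- sampling_grid(pupil_size = 501, out_size = 101, pixel_size = 40,
                      z_planes = c(0, 500))
  fc <- scalar_cartesian(uniform_pupil(setup, g), g)
  fs <- scalar_spherical(uniform_pupil(setup, gs, "spherical"), g)
  expect_lt(rel_l2(fc$data, fs$data), 2e-3)
  vc <- vectorial_cartesian(far_field_pupil(
    apply_polarisation(uniform_pupil(setup, g))), g)
  vs <- vectorial_spherical(apply_polarisation(
    uniform_pupil(setup, gs, "spherical")), g)
  expect_lt(rel_l2(vc$data, vs$data), 2e-3)
})

test_that("propagators are linear in the pupil", {
  setup <- fx_setup_low()
  g <- fx_grid_small()
  p <- uniform_pupil(setup, g)
  pc <- pupil_coords(setup, g$pupil_size)
  p2 <- apply_corrections(p, amplitude = gaussian_envelope(pc$sr, 0.25))
  mix <- p
  mix$values <- 2 * p$values - (1 + 1i) * p2$values
  f_mix <- scalar_cartesian(mix, g)$data
  f_lin <- 2 * scalar_cartesian(p, g)$data -
    (1 + 1i) * scalar_cartesian(p2, g)$data
  expect_lt(rel_l2(f_mix, f_lin), 1e-12)
})

test_that("vectorial fields have the stated channel structure", {
  setup <- fx_setup_low()
  g <- fx_grid_small()
  # low NA, x-polarised: energy leaks negligibly into y and z channels
  lowna <- optical_setup(na = 0.05, wavelength = 632)
  p3 <- far_field_pupil(apply_polarisation(uniform_pupil(lowna, g), c(1, 0)))
  f <- vectorial_cartesian(p3, g)
  en <- apply(Mod(f$data[1, , , ])^2, 1, sum)
  expect_lt(en[2] / en[1], 1e-3)
  expect_lt(en[3] / en[1], 1e-3)

  # on the optical axis the longitudinal component vanishes (J1(0) = 0)
  ps <- apply_polarisation(uniform_pupil(
    setup, sampling_grid(pupil_size = 201), "spherical"))
  fv <- vectorial_spherical(ps, g)
  c0 <- (g$out_size + 1) / 2
  expect_equal(Mod(fv$data[1, 3, c0, c0]), 0, tolerance = 1e-12)

  # circular polarisation gives a radially symmetric focal intensity
  ghi <- fx_grid_small()
  p3c <- far_field_pupil(apply_polarisation(
    uniform_pupil(fx_setup_high(), ghi), jones_circular()))
  ic <- intensity(vectorial_cartesian(p3c, ghi))[1, , ]
  expect_lt(abs(ic[c0 + 7, c0] - ic[c0, c0 + 7]) / max(ic), 1e-6)
  expect_lt(abs(ic[c0 + 5, c0 + 5] - ic[c0 - 5, c0 + 5]) / max(ic), 1e-6)

  # z channel must be empty on input
  bad <- ps; bad$values[3, ] <- 1
  expect_error(vectorial_spherical(bad, g), "longitudinal")
})

test_that("intensity sums channel magnitudes squared", {
  f <- focal_field(array(3 + 4i, dim = c(1, 1, 2, 2)), 10, 0)
  expect_equal(intensity(f)[1, , ], matrix(25, 2, 2))
  expect_equal(intensity(f, amplitude = TRUE)[1, , ], matrix(5, 2, 2))
  fx <- focal_field(array(c(1, 0, 0), dim = c(1, 3, 1, 1)), 10, 0)
  fy <- focal_field(array(c(0, 1, 0), dim = c(1, 3, 1, 1)), 10, 0)
  expect_equal(intensity(fx), intensity(fy))
})

test_that("half-moon mask splits the focus into two lobes along x", {
  setup <- optical_setup(na = 1.3, wavelength = 632, n_sample = 1.5,
                         polarisation = jones_linear(0))
  g <- sampling_grid(pupil_size = 129, out_size = 41, pixel_size = 40)
  p <- apply_corrections(uniform_pupil(setup, g),
                         phase = half_moon_phase(setup, g))
  f <- scalar_cartesian(p, g)
  iv <- intensity(f)[1, , ]
  c0 <- (g$out_size + 1) / 2
  # destructive interference on axis; lobes displaced along the x axis
  expect_lt(iv[c0, c0] / max(iv), 1e-3)
  peak <- which(iv == max(iv), arr.ind = TRUE)[1, ]
  expect_true(abs(peak[1] - c0) > 0)   # displaced in x (rows)
  expect_true(abs(peak[2] - c0) == 0)  # centred in y (cols)
})

test_that("normalisation modes rescale as documented", {
  setup <- fx_setup_low()
  g <- fx_grid_small()
  f <- scalar_cartesian(uniform_pupil(setup, g), g)
  fm <- normalise_field(f, "max")
  expect_equal(max(Mod(fm$data)), 1, tolerance = 1e-14)
  fe <- normalise_field(f, "energy")
  expect_equal(sum(Mod(fe$data)^2), 1, tolerance = 1e-12)
})
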