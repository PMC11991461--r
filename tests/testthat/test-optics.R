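test_that("sample-plane pixel size follows the Fraunhofer sampling relation", {
  ## beamline numbers: 705 eV, 105.4 mm, 2048 px at 11 um
  geo <- cdi_geometry(705, 0.1054, 2048, 11e-6)
  expect_equal(sample_plane_pixel_size(geo), 8.228e-9, tolerance = 1e-4)

  ## doubling N halves the pixel
  geo2 <- cdi_geometry(705, 0.1054, 4096, 11e-6)
  expect_equal(sample_plane_pixel_size(geo2),
               sample_plane_pixel_size(geo) / 2)

  ## lambda * z = N * p * (1 m)  ->  1 m
  geo3 <- cdi_geometry(1239.842, 1e7, 10, 1e-3)
  expect_equal(sample_plane_pixel_size(geo3), 1)

  expect_error(cdi_geometry(-1, 0.1, 64, 1e-5), "invalid geometry")
  expect_error(cdi_geometry(705, 0, 64, 1e-5), "invalid geometry")
})

test_that("zone-plate focal length and defocus geometry are consistent", {
  fzp <- fzp_spec(300e-6, 80e-6, 30e-9, 705)
  expect_equal(fzp$focal_length_m, 5.1176e-3, tolerance = 1e-4)
  ## defocus for a 6 um probe inverts the magnification relation
  d <- defocus_for_probe_diameter(fzp, 6e-6)
  expect_equal(300e-6 * d / fzp$focal_length_m, 6e-6)
  expect_error(fzp_spec(300e-6, 400e-6, 30e-9, 705), "central stop")
  expect_error(fzp_spec(300e-6, 80e-6, -1, 705), "zone width")
})

test_that("far-field propagator matches a direct discrete Fourier sum", {
  for (n in c(8L, 16L, 32L)) {
    x <- withr::with_seed(n, matrix(complex(real = rnorm(n * n),
                                            imaginary = rnorm(n * n)), n, n))
    wf <- wavefield(x, pixel_size = 1e-8, wavelength = 1.76e-9)
    got <- propagate_far_field(wf)$values
    want <- dft_centered_direct(x)
    expect_lt(max(Mod(got - want)), 1e-10)
  }
})

test_that("far-field propagator is unitary, centres DC, and has shift-invariant modulus", {
  n <- 32
  x <- withr::with_seed(1, matrix(complex(real = rnorm(n * n),
                                          imaginary = rnorm(n * n)), n, n))
  wf <- wavefield(x, 1e-8, 1.76e-9)
  out <- propagate_far_field(wf)$values
  expect_equal(sum(Mod(out)^2), sum(Mod(x)^2), tolerance = 1e-12)

  ## delta at the centre -> flat modulus
  d <- matrix(0 + 0i, n, n); d[n / 2 + 1, n / 2 + 1] <- 1
  fd <- propagate_far_field(wavefield(d, 1e-8, 1.76e-9))$values
  expect_lt(diff(range(Mod(fd))), 1e-12)

  ## plane wave -> delta at the DC pixel (centre)
  fo <- propagate_far_field(wavefield(matrix(1 + 0i, n, n), 1e-8,
                                      1.76e-9))$values
  peak <- which(Mod(fo) == max(Mod(fo)), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(n / 2 + 1, n / 2 + 1))

  ## circular shift leaves the modulus unchanged
  xs <- x[c(5:n, 1:4), c(9:n, 1:8)]
  ms <- Mod(propagate_far_field(wavefield(xs, 1e-8, 1.76e-9))$values)
  expect_lt(max(abs(ms - Mod(out))), 1e-10)
})

test_that("angular-spectrum propagation is unitary and invertible", {
  n <- 64
  k <- radius_grid_for_test(n)
  ## band-limited field so no evanescent/band truncation occurs
  x <- withr::with_seed(2, matrix(complex(real = rnorm(n * n),
                                          imaginary = rnorm(n * n)), n, n))
  x <- ifft_centered(fft_centered(x) * (k < n / 6))
  wf <- wavefield(x, 8.2e-9, 1.76e-9)
  expect_identical(propagate_angular_spectrum(wf, 0), wf)
  fwd <- propagate_angular_spectrum(wf, 4e-6)
  expect_equal(sum(Mod(fwd$values)^2), sum(Mod(x)^2), tolerance = 1e-10)
  back <- propagate_angular_spectrum(fwd, -4e-6)
  expect_lt(max(Mod(back$values - x)) / max(Mod(x)), 1e-10)
})

test_that("Gaussian beam width after propagation matches the closed form", {
  n <- 256; dx <- 8.2e-9; lambda <- 1.76e-9
  w0 <- 12 * dx
  cc <- (seq_len(n) - (n / 2 + 1)) * dx
  r2 <- outer(cc^2, cc^2, `+`)
  g <- wavefield(exp(-r2 / w0^2) + 0i, dx, lambda)
  zr <- pi * w0^2 / lambda
  z <- 0.75 * zr
  out <- propagate_angular_spectrum(g, z)$values
  ## beam radius from the intensity second moment: w = 2 sqrt(<x^2>)
  intens <- Mod(out)^2
  x2 <- sum(r2 / 2 * intens) / sum(intens)   # <x^2> = <r^2>/2
  w_num <- 2 * sqrt(x2)
  w_ana <- w0 * sqrt(1 + (z / zr)^2)
  expect_equal(w_num, w_ana, tolerance = 0.01)
})

test_that("defocused zone-plate probe is annular with the requested diameter", {
  geo <- default_geometry(256)
  fzp <- default_fzp(geo, probe_diameter_frac = 0.285)
  p <- make_fzp_probe(fzp, geo)
  expect_equal(sum(Mod(p$values)^2), 1, tolerance = 1e-10)
  dx <- sample_plane_pixel_size(geo)
  rr <- radius_grid_for_test(256) * dx
  a <- Mod(p$values)
  r_in <- (fzp$central_stop_m / 2) * fzp$defocus_m / fzp$focal_length_m
  r_out <- (fzp$diameter_m / 2) * fzp$defocus_m / fzp$focal_length_m
  ## hollow centre: central-stop shadow much darker than the annulus
  expect_lt(mean(a[rr < 0.7 * r_in]), 0.5 * mean(a[rr > 1.3 * r_in &
                                                     rr < 0.9 * r_out]))
  ## measured outer radius near the geometric prediction
  expect_equal(max(rr[a > 0.3 * max(a)]), r_out, tolerance = 0.1)
})

test_that("probe at focus has a spot on the outermost-zone-width scale", {
  geo <- default_geometry(256)
  fzp <- fzp_spec(300e-6, 80e-6, 30e-9, 705, defocus_m = 0)
  p <- make_fzp_probe(fzp, geo)
  a <- Mod(p$values)
  dx <- sample_plane_pixel_size(geo)
  fwhm <- sum(a[, 129] > max(a) / 2) * dx
  expect_gt(fwhm, 0.5 * fzp$outermost_zone_width_m)
  expect_lt(fwhm, 4 * fzp$outermost_zone_width_m)
})

test_that("a 6 um probe from the 300/80 um zone plate needs a wide grid", {
  fzp <- fzp_spec(300e-6, 80e-6, 30e-9, 705)
  fzp$defocus_m <- defocus_for_probe_diameter(fzp, 6e-6)
  ## on a grid whose extent it exceeds: aliasing error
  expect_error(make_fzp_probe(fzp, default_geometry(256)),
               "exceeds the grid")
  ## on a 1024 grid at the same 8.23 nm sampling: annular, ~6 um across
  geo <- cdi_geometry(705, 0.1054, 1024, 22e-6)
  p <- make_fzp_probe(fzp, geo)
  dx <- sample_plane_pixel_size(geo)
  rr <- radius_grid_for_test(1024) * dx
  a <- Mod(p$values)
  expect_equal(2 * max(rr[a > 0.3 * max(a)]), 6e-6, tolerance = 0.05)
  r_in <- (fzp$central_stop_m / 2) * fzp$defocus_m / fzp$focal_length_m
  expect_lt(mean(a[rr < 0.7 * r_in]),
            0.5 * mean(a[rr > 1.3 * r_in & rr < 2.7e-6]))
})
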