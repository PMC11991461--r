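test_that("low-frequency transfer replaces exactly the requested disk", {
  n <- 16
  set.seed(1)
  cur <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  prev <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)

  ## qlow = 0: only the DC coefficient comes from the previous frame
  out0 <- low_frequency_transfer(cur, prev, 0)
  tc <- fft_centered(cur); tp <- fft_centered(prev)
  t0 <- fft_centered(out0)
  centre <- n / 2 + 1
  expect_equal(t0[centre, centre], tp[centre, centre], tolerance = 1e-12)
  t0[centre, centre] <- tc[centre, centre]
  expect_lt(max(Mod(t0 - tc)), 1e-12)

  ## qlow = 3: coefficients outside the disk untouched
  out3 <- low_frequency_transfer(cur, prev, 3)
  t3 <- fft_centered(out3)
  disk <- radius_grid_for_test(n) <= 3
  expect_lt(max(Mod(t3[disk] - tp[disk])), 1e-12)
  expect_lt(max(Mod(t3[!disk] - tc[!disk])), 1e-12)

  ## full-plane radius: output equals the previous frame
  rmax <- max(radius_grid_for_test(n))
  expect_lt(max(Mod(low_frequency_transfer(cur, prev, rmax) - prev)), 1e-12)
  ## beyond the grid: clamped with a warning, same result
  expect_warning(outw <- low_frequency_transfer(cur, prev, n), "clamped")
  expect_lt(max(Mod(outw - prev)), 1e-12)

  ## previous = current: identity
  expect_lt(max(Mod(low_frequency_transfer(cur, cur, 4) - cur)), 1e-12)
  expect_error(low_frequency_transfer(cur, prev[1:8, 1:8], 2),
               "shape mismatch")
})

test_that("static-region transfer and save are exact inverses on the mask", {
  n <- 12
  set.seed(2)
  o <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  mask <- matrix(FALSE, n, n); mask[8:12, 3:9] <- TRUE
  s <- complex(real = rnorm(sum(mask)), imaginary = rnorm(sum(mask)))

  out <- static_region_transfer(o, s, mask)
  expect_identical(out[mask], s)
  expect_identical(out[!mask], o[!mask])
  ## idempotent
  expect_identical(static_region_transfer(out, s, mask), out)
  ## empty mask: identity
  expect_identical(static_region_transfer(o, complex(0),
                                          matrix(FALSE, n, n)), o)
  ## full mask: becomes the static function everywhere
  full <- matrix(TRUE, n, n)
  sf <- complex(real = rnorm(n * n), imaginary = rnorm(n * n))
  expect_identical(as.vector(static_region_transfer(o, sf, full)), sf)

  ## save -> transfer round trip is the identity on the mask
  expect_identical(static_region_transfer(o, save_static(o, mask), mask), o)
  expect_identical(save_static(o, matrix(FALSE, n, n)), complex(0))
  expect_identical(save_static(o, mask), o[mask])
  expect_error(static_region_transfer(o, s[-1], mask), "one value per")
})

test_that("MEP update enforces the measured probe modulus", {
  ds <- tiny_noiseless()
  p <- ds$truth$probe$values
  full <- matrix(TRUE, 64, 64)

  ## consistent probe inside its support: fixed point
  upd <- mep_probe_update(p, ds$mep_intensity, ds$support_mask)
  expect_lt(max(Mod(upd - p)), 1e-10 * max(Mod(p)))

  ## before the support step the far-field modulus equals sqrt(I) exactly
  upd2 <- mep_probe_update(p * 0.5 + 1e-3, ds$mep_intensity, full)
  expect_lt(max(abs(Mod(fft_centered(upd2)) - sqrt(ds$mep_intensity))),
            1e-10)

  ## zero MEP pattern: zero probe
  expect_true(all(mep_probe_update(p, ds$mep_intensity * 0, full) == 0))
})

test_that("Fourier modulus projection is an idempotent data constraint", {
  ds <- tiny_noisy()
  p <- ds$truth$probe$values
  psi <- ds$truth$sequence$frames[[1]] * p
  i_meas <- ds$intensities[[1]]

  ## fixed point on self-consistent intensity
  i_self <- Mod(fft_centered(psi))^2
  expect_lt(max(Mod(fourier_modulus_projection(psi, i_self) - psi)),
            1e-10 * max(Mod(psi)))

  ## idempotent, and the projected energy equals the measured total
  once <- fourier_modulus_projection(psi, i_meas)
  twice <- fourier_modulus_projection(once, i_meas)
  expect_lt(max(Mod(twice - once)), 1e-10 * max(Mod(once)))
  expect_equal(sum(Mod(fft_centered(once))^2), sum(i_meas),
               tolerance = 1e-12)
  expect_error(fourier_modulus_projection(psi, -i_meas), "non-negative")
})

test_that("ePIE update matches the hand-computed scalar example", {
  ## one-pixel grids: O = 1, P = 2, psi = 2, psi' = 4, alpha = 1
  o <- matrix(1 + 0i, 1, 1); p <- matrix(2 + 0i, 1, 1)
  psi <- matrix(2 + 0i, 1, 1); psi_p <- matrix(4 + 0i, 1, 1)
  upd <- epie_update(o, p, psi, psi_p, alpha = 1, beta = 1,
                     support_mask = matrix(TRUE, 1, 1))
  expect_identical(upd$object, matrix(2 + 0i, 1, 1))     # 1 + (2/4)*2
  expect_identical(upd$probe, matrix(3 + 0i, 1, 1))      # 2 + (2/4)*2

  ## zero residual: both unchanged inside the support
  upd0 <- epie_update(o, p, psi, psi, alpha = 1, beta = 1)
  expect_identical(upd0$object, o)
  expect_identical(upd0$probe, p)

  ## alpha = 0 leaves the object alone
  upda <- epie_update(o, p, psi, psi_p, alpha = 0, beta = 0)
  expect_identical(upda$object, o)

  ## support rule: object 1 and probe 0 outside
  n <- 8
  sup <- matrix(FALSE, n, n); sup[3:6, 3:6] <- TRUE
  set.seed(3)
  O <- matrix(complex(real = rnorm(n * n)), n, n)
  P <- matrix(complex(real = rnorm(n * n)), n, n)
  u <- epie_update(O, P, O * P, O * P * 1.1, support_mask = sup)
  expect_true(all(u$object[!sup] == 1 + 0i))
  expect_true(all(u$probe[!sup] == 0 + 0i))

  ## zero-probe degenerate input: warning, object update skipped
  expect_warning(uz <- epie_update(O, P * 0, O * 0, O, support_mask = sup),
                 "skipped")
  expect_identical(uz$object[sup], O[sup])
})

test_that("HIO pre-reconstruction recovers a field on an asymmetric support", {
  fx <- asymmetric_support_field(64, seed = 3)
  i0 <- Mod(fft_centered(fx$field))^2
  rec <- hio_prereconstruct_probe(i0, fx$support, iterations = 200,
                                  beta_hio = 0.9, seed = 1)
  expect_gt(field_correlation(rec, fx$field), 0.9)
  ## determinism
  rec2 <- hio_prereconstruct_probe(i0, fx$support, iterations = 200,
                                   beta_hio = 0.9, seed = 1)
  expect_identical(rec, rec2)
  ## final Fourier modulus is enforced exactly
  expect_lt(max(abs(Mod(fft_centered(rec)) - sqrt(i0))), 1e-9)

  ## 0 iterations with full support: inverse transform of sqrt(I), zero phase
  rec0 <- hio_prereconstruct_probe(i0, matrix(TRUE, 64, 64), iterations = 0)
  expect_lt(max(Mod(rec0 - ifft_centered(sqrt(i0) + 0i))), 1e-12)

  expect_error(hio_prereconstruct_probe(i0 * 0, fx$support), "zero")
  expect_error(hio_prereconstruct_probe(i0, fx$support & FALSE), "empty")
})

test_that("model-probe-initialised pre-reconstruction refines an annular probe", {
  ds <- tiny_noisy()
  tp <- ds$truth$probe$values
  ## the analytic model alone misses the measured probe's structure ...
  model_only <- initial_probe_guess(ds, hio_iterations = 0, seed = 1)
  ## ... and the MEP pre-reconstruction pulls the guess towards it
  guess <- initial_probe_guess(ds, hio_iterations = 200, seed = 1)
  expect_gt(field_correlation(guess, tp), field_correlation(model_only, tp))
  expect_gt(field_correlation(guess, tp), 0.6)
  ## energy pinned to the MEP total
  expect_equal(sum(Mod(guess)^2), sum(ds$mep_intensity), tolerance = 1e-10)
})
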