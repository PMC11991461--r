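test_that("truth is a fixed point of one full iteration on noiseless data", {
  ds <- tiny_noiseless()
  tr <- ds$truth
  ctl <- dyncdi_control(n_iterations = 1, use_lowfreq_transfer = FALSE,
                        hio_iterations = 0)
  fit <- dyncdi(ds, ctl, probe = tr$probe, objects = tr$sequence$frames,
                probe_support = ds$support_mask)
  for (t in 1:3) {
    drift <- max(Mod(fit$objects[[t]] - tr$sequence$frames[[t]]))
    expect_lt(drift, 1e-8 * max(Mod(tr$sequence$frames[[t]])))
  }
  expect_lt(max(Mod(fit$probe$values - tr$probe$values)),
            1e-8 * max(Mod(tr$probe$values)))
  expect_true(all(fit$errors$data < 1e-12))
})

test_that("conventional CDI equals the full method with transfers disabled", {
  ds <- tiny_noisy()
  ctl <- dyncdi_control(n_iterations = 3, hio_iterations = 10, seed = 2)
  ctl_off <- ctl
  ctl_off$use_static_transfer <- FALSE
  ctl_off$use_lowfreq_transfer <- FALSE
  a <- conventional_cdi(ds, ctl)
  b <- dyncdi(ds, ctl_off)
  expect_identical(a$objects, b$objects)
  expect_identical(a$probe$values, b$probe$values)
  expect_identical(a$errors$data, b$errors$data)
})

test_that("single-frame reconstruction reduces to plain single-pattern CDI", {
  seqc <- generate_dynamic_sequence(1, static_kind = "none", grid = 64,
                                    seed = 3)
  geo <- default_geometry(64)
  probe <- make_fzp_probe(default_fzp(geo), geo)
  ds <- build_dataset(seqc, probe, geo, photons_total = Inf)
  ctl <- dyncdi_control(n_iterations = 40, use_static_transfer = FALSE,
                        use_lowfreq_transfer = FALSE, use_mep = FALSE,
                        update_probe_epie = FALSE, hio_iterations = 0)
  fit <- dyncdi(ds, ctl, probe = ds$truth$probe,
                probe_support = ds$support_mask)
  expect_equal(ncol(fit$errors$data), 1)
  ## with the true probe and noiseless data the data error falls steadily
  expect_lt(fit$errors$data[40, 1], fit$errors$data[1, 1] / 5)
})

test_that("support rule holds exactly after a reconstruction", {
  ds <- tiny_noisy()
  fit <- dyncdi(ds, dyncdi_control(n_iterations = 2, hio_iterations = 10))
  for (o in fit$objects)
    expect_true(all(o[!ds$support_mask] == 1 + 0i))
  expect_true(all(fit$probe$values[!ds$support_mask] == 0 + 0i))
})

test_that("reconstructions are deterministic given the seed", {
  ds <- tiny_noisy()
  ctl <- dyncdi_control(n_iterations = 2, hio_iterations = 15, seed = 7)
  f1 <- dyncdi(ds, ctl)
  f2 <- dyncdi(ds, ctl)
  expect_identical(f1$objects, f2$objects)
  expect_identical(f1$probe$values, f2$probe$values)
})

test_that("a dataset without a MEP pattern is rejected when MEP is requested", {
  ds <- tiny_noisy()
  ds$mep_intensity <- NULL
  expect_error(dyncdi(ds, dyncdi_control(n_iterations = 1)),
               "MEP pattern missing")
  ## but runs fine with the constraint off and an explicit probe
  ctl <- dyncdi_control(n_iterations = 1, use_mep = FALSE,
                        hio_iterations = 0)
  expect_s3_class(dyncdi(ds, ctl, probe = tiny_noisy()$truth$probe),
                  "dyncdi")
})

test_that("non-finite state aborts with a diagnostic naming the position", {
  ds <- tiny_noisy()
  bad <- replicate(3, matrix(1 + 0i, 64, 64), simplify = FALSE)
  inside <- which(ds$support_mask, arr.ind = TRUE)[1, ]
  bad[[1]][inside[1], inside[2]] <- NaN + 0i
  expect_error(dyncdi(ds, dyncdi_control(n_iterations = 1,
                                         hio_iterations = 10),
                      objects = bad),
               "iteration 1, frame 1")
})

test_that("fit accessors expose frames, probe, residuals and summaries", {
  ds <- tiny_noisy()
  fit <- dyncdi(ds, dyncdi_control(n_iterations = 2, hio_iterations = 10))
  expect_length(fitted(fit), 3)
  expect_identical(fitted(fit, frame = 2), fit$objects[[2]])
  expect_s3_class(fitted(fit, what = "probe"), "wavefield")
  r <- residuals(fit)
  expect_length(r, 3)
  tr <- residuals(fit, type = "trace")
  expect_equal(nrow(tr), 2 * 3)
  expect_true(all(c("iteration", "frame", "data_error", "object_error")
                  %in% names(tr)))
  s <- summary(fit)
  expect_s3_class(s, "summary.dyncdi")
  expect_equal(nrow(s$table), 3)
  expect_output(print(fit), "dyncdi")
  expect_output(print(s), "iterations")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, which = "amplitude", frame = 1))
})

test_that("alignment helpers remove global scale and phase", {
  set.seed(9)
  b <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  a <- (1.7 * exp(0.4i)) * b
  expect_equal(align_scale(a, b), 1.7 * exp(0.4i), tolerance = 1e-12)
  expect_equal(field_correlation(a, b), 1, tolerance = 1e-12)
  ## orthogonal fields decorrelate
  o1 <- matrix(0 + 0i, 8, 8); o1[1, 1] <- 1
  o2 <- matrix(0 + 0i, 8, 8); o2[2, 2] <- 1
  expect_equal(field_correlation(o1, o2), 0)
})
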