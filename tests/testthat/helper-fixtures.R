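## shared fixtures, built in code and memoised per test run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## small noiseless dataset: exact fixed-point territory
tiny_noiseless <- function() fixture("tiny_noiseless",
  simulate_dataset(3, grid = 64, photons_total = Inf, seed = 5))

## small noisy dataset for behavioural tests
tiny_noisy <- function() fixture("tiny_noisy",
  simulate_dataset(3, grid = 64, photons_total = 1e7, seed = 5))

## centred radial pixel distances (test-side copy)
radius_grid_for_test <- function(n) {
  cc <- seq_len(n) - (floor(n / 2) + 1L)
  sqrt(outer(cc^2, cc^2, `+`))
}

## direct O(N^4) discrete Fourier sum with the same centred unitary
## convention as fft_centered(): the independent oracle
dft_centered_direct <- function(x) {
  n <- nrow(x)
  c0 <- floor(n / 2)
  idx <- seq_len(n) - 1L
  out <- matrix(0 + 0i, n, n)
  for (k in idx) for (l in idx) {
    w <- exp(-2i * pi * (outer(idx - c0, rep(1, n)) * (k - c0) +
                           outer(rep(1, n), idx - c0) * (l - c0)) / n)
    out[k + 1L, l + 1L] <- sum(x * w) / n
  }
  out
}

## complex field with smooth amplitude/phase on an asymmetric support:
## a recoverable single-pattern phase-retrieval fixture
asymmetric_support_field <- function(n = 64, seed = 3) {
  fixture(paste0("asym_field_", n, "_", seed), {
    withr::with_seed(seed, {
      cc <- seq_len(n) - (floor(n / 2) + 1L)
      x <- matrix(cc, n, n, byrow = TRUE)
      y <- matrix(cc, n, n)
      sup <- (sqrt((x + 8)^2 + (y + 5)^2) < 12) |
        (sqrt((x - 14)^2 + (y - 10)^2) < 6)
      k <- sqrt(outer(cc^2, cc^2, `+`))
      sm <- function(m) Re(ifft_centered(fft_centered(m + 0i) *
                                           exp(-(k / 8)^2)))
      f <- (1 + 0.5 * sm(matrix(rnorm(n * n), n, n))) *
        exp(1i * 1.5 * sm(matrix(rnorm(n * n), n, n)))
      f[!sup] <- 0 + 0i
      list(field = f, support = sup)
    })
  })
}
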