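#' Sampled complex wavefield
#'
#' A `wavefield` is a square grid of complex amplitudes together with the
#' physical sampling it lives on: the pixel size in metres, the wavelength of
#' the illumination, and the plane it is defined in (`"sample"` or
#' `"detector"`). It is the common currency of the optics, simulation and
#' reconstruction functions: probes, object transmission functions, exit
#' waves and detector-plane wavefronts are all wavefields.
#'
#' @param values Square complex (or numeric) matrix of field amplitudes.
#' @param pixel_size Physical size of one pixel (m), `> 0`.
#' @param wavelength Wavelength of the illumination (m), `> 0`.
#' @param plane Either `"sample"` or `"detector"`.
#'
#' @return An object of class `"wavefield"`: a list with elements `values`,
#'   `pixel_size`, `wavelength` and `plane`.
#' @examples
#' wf <- wavefield(matrix(1 + 0i, 8, 8), pixel_size = 1e-8,
#'                 wavelength = 1.76e-9)
#' wf
#' @export
wavefield <- function(values, pixel_size, wavelength,
                      plane = c("sample", "detector")) {
  plane <- match.arg(plane)
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (nrow(values) != ncol(values)) stop("wavefield grid must be square")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("wavefield values must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number")
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0)
    stop("'wavelength' must be a single positive number")
  storage.mode(values) <- "complex"
  structure(list(values = values, pixel_size = pixel_size,
                 wavelength = wavelength, plane = plane),
            class = "wavefield")
}

#' @export
print.wavefield <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<wavefield> %d x %d, %s plane\n", n, n, x$plane))
  cat(sprintf("  pixel size: %.4g nm, wavelength: %.4g nm\n",
              x$pixel_size * 1e9, x$wavelength * 1e9))
  cat(sprintf("  energy sum(|v|^2): %.6g\n", field_energy(x$values)))
  invisible(x)
}

#' @export
dim.wavefield <- function(x) dim(x$values)

## total field energy sum |v|^2
field_energy <- function(v) {
  if (inherits(v, "wavefield")) v <- v$values
  sum(Mod(v)^2)
}

## ---- centred 2-D FFT helpers -------------------------------------------
## Convention used throughout: DC sits at the grid centre, 0-based index N/2
## (1-based index N/2 + 1); transforms are unitary (1/N scaling each way) so
## modulus projections and energy bookkeeping are scale-consistent.

## circularly shift a matrix so that element [N/2 + 1, N/2 + 1] moves to
## [1, 1] (ifftshift) or the reverse (fftshift); for even N the two agree.
fftshift2 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  i <- c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))
  j <- c((floor(p / 2) + 1L):p, seq_len(floor(p / 2)))
  m[i, j, drop = FALSE]
}

ifftshift2 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  i <- c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))
  j <- c((ceiling(p / 2) + 1L):p, seq_len(ceiling(p / 2)))
  m[i, j, drop = FALSE]
}

#' Centred unitary 2-D Fourier transforms
#'
#' Discrete Fourier transform of a square complex matrix with the DC
#' component at the grid centre (0-based index `N/2`) and unitary `1/N`
#' normalisation, so that `sum(Mod(x)^2) == sum(Mod(fft_centered(x))^2)` to
#' machine precision and `ifft_centered(fft_centered(x))` recovers `x`.
#'
#' @param x Complex matrix (sample- or detector-plane samples).
#' @return Complex matrix of the same size.
#' @examples
#' x <- matrix(rnorm(16) + 1i * rnorm(16), 4, 4)
#' max(Mod(ifft_centered(fft_centered(x)) - x))
#' @export
fft_centered <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft_centered
#' @export
ifft_centered <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

## centred pixel coordinates: 0 at index floor(N/2)+1 (1-based)
centered_coords <- function(n) seq_len(n) - (floor(n / 2) + 1L)

## matrix of centred radial distances in pixels
radius_grid <- function(n) {
  cc <- centered_coords(n)
  sqrt(outer(cc^2, cc^2, `+`))
}
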