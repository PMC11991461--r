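#' Fourier ring correlation between two reconstructions
#'
#' Ring-wise normalised cross-correlation of the Fourier transforms of two
#' independent reconstructions of the same scene. The correlation of ring
#' `r` is `|sum(Fa * Conj(Fb))| / sqrt(sum|Fa|^2 * sum|Fb|^2)` over the
#' pixels whose centred radius falls in the ring. The resolution estimate is
#' the half-period length at the first crossing of the half-bit threshold
#' curve (the standard criterion for two half-datasets),
#' `T(r) = (0.2071 + 1.9102 / sqrt(n_r)) / (1.2071 + 0.9102 / sqrt(n_r))`
#' with `n_r` pixels in the ring. If the correlation never drops below the
#' threshold the estimate is Nyquist-limited and reported as the half-period
#' at the Nyquist ring (one pixel).
#'
#' The correlation is symmetric in its arguments and invariant to a common
#' global phase.
#'
#' @param image_a,image_b Complex (or numeric) matrices of the same size.
#' @param pixel_size Real-space pixel size (m).
#' @param n_rings Number of rings between DC and Nyquist (default: one-pixel
#'   rings).
#' @return An object of class `"frc_curve"`: list with `rings` (data frame
#'   with `radius_px`, `spatial_freq` in 1/m, `correlation`, `threshold`,
#'   `n_pixels`), `resolution_m` (half-period), `crossing_radius_px`, and
#'   `limited` (`TRUE` when no crossing occurred).
#' @export
frc <- function(image_a, image_b, pixel_size, n_rings = NULL) {
  image_a <- as_values(image_a); image_b <- as_values(image_b)
  if (!all(dim(image_a) == dim(image_b))) stop("shape mismatch")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  n <- nrow(image_a)
  nyq <- floor(n / 2)
  if (is.null(n_rings)) n_rings <- nyq
  width <- nyq / n_rings
  fa <- fft_centered(image_a)
  fb <- fft_centered(image_b)
  rr <- radius_grid(n)
  ring <- pmin(as.integer(round(rr / width)), n_rings)
  keep <- rr <= nyq + 0.5
  idx <- ring[keep] + 1L
  num <- vapply(split(fa[keep] * Conj(fb[keep]), idx), sum, complex(1))
  da <- vapply(split(Mod(fa[keep])^2, idx), sum, numeric(1))
  db <- vapply(split(Mod(fb[keep])^2, idx), sum, numeric(1))
  npx <- vapply(split(idx, idx), length, integer(1))
  corr <- Mod(num) / sqrt(pmax(da * db, .Machine$double.xmin))
  thr <- (0.2071 + 1.9102 / sqrt(npx)) / (1.2071 + 0.9102 / sqrt(npx))
  radius_px <- (seq_along(corr) - 1L) * width
  rings <- data.frame(radius_px = radius_px,
                      spatial_freq = radius_px / (n * pixel_size),
                      correlation = corr, threshold = thr, n_pixels = npx,
                      row.names = NULL)
  ## first crossing, skipping the DC ring; linear interpolation inside it
  below <- which(corr < thr & radius_px > 0)
  if (length(below) == 0) {
    res <- list(crossing_radius_px = NA_real_, limited = TRUE,
                resolution_m = pixel_size)   # half-period at Nyquist
  } else {
    j <- below[1]
    d_prev <- corr[j - 1] - thr[j - 1]
    d_here <- corr[j] - thr[j]
    fr <- if (d_prev > 0) d_prev / (d_prev - d_here) else 0
    r_cross <- radius_px[j - 1] + fr * (radius_px[j] - radius_px[j - 1])
    res <- list(crossing_radius_px = r_cross, limited = FALSE,
                resolution_m = pixel_size * n / (2 * r_cross))
  }
  structure(c(list(rings = rings, pixel_size = pixel_size, n = n), res),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("<frc_curve> %d rings to Nyquist\n", nrow(x$rings) - 1L))
  if (x$limited) {
    cat(sprintf("  no threshold crossing: resolution Nyquist-limited (%.3g nm half-period)\n",
                x$resolution_m * 1e9))
  } else {
    cat(sprintf("  half-bit crossing at %.1f px -> half-period resolution %.3g nm\n",
                x$crossing_radius_px, x$resolution_m * 1e9))
  }
  invisible(x)
}

#' @export
plot.frc_curve <- function(x, ...) {
  graphics::plot(x$rings$spatial_freq * 1e-9, x$rings$correlation,
                 type = "l", ylim = c(0, 1.05),
                 xlab = "spatial frequency (1/nm)",
                 ylab = "ring correlation", main = "Fourier ring correlation",
                 ...)
  graphics::lines(x$rings$spatial_freq * 1e-9, x$rings$threshold, lty = 2)
  if (!x$limited)
    graphics::abline(v = x$crossing_radius_px / (x$n * x$pixel_size) * 1e-9,
                     col = "grey")
  invisible(x)
}

#' Two independent reconstructions of one frame for FRC
#'
#' For a simulated dataset (with ground truth) the per-frame intensities are
#' re-drawn from the noiseless forward model with two independent noise
#' realizations and each half is reconstructed; for measured data the
#' detector pixels are split into the two checkerboard phases (missing pixels
#' filled by the 4-neighbour mean) and each half-dataset is reconstructed.
#' The two reconstructions of the chosen frame are aligned by a global
#' complex scalar and returned, ready for [frc()].
#'
#' @param dataset A [diffraction_dataset()].
#' @param control A [dyncdi_control()] used for both reconstructions.
#' @param frame Frame index to extract.
#' @param method `"noise_split"` (needs ground truth) or `"checkerboard"`.
#' @param photons_total Photon budget of each half when re-drawing noise.
#' @param ... Passed to [dyncdi()] (e.g. `probe`).
#' @return List with complex matrices `a` and `b` (aligned) and the two fits
#'   `fit_a`, `fit_b`.
#' @export
split_data_reconstructions <- function(dataset, control = dyncdi_control(),
                                       frame = 1,
                                       method = c("noise_split",
                                                  "checkerboard"),
                                       photons_total = 1e8, ...) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "diffraction_dataset"))
  if (method == "noise_split") {
    if (is.null(dataset$truth))
      stop("noise_split needs a dataset with ground truth")
    seqc <- dataset$truth$sequence
    halves <- lapply(c(101L, 202L), function(off)
      build_dataset(seqc, dataset$truth$probe, dataset$geometry,
                    photons_total = photons_total,
                    seed = control$seed + off))
  } else {
    halves <- lapply(1:2, function(ph) {
      d <- dataset
      d$intensities <- lapply(d$intensities, checkerboard_fill, phase = ph)
      if (!is.null(d$mep_intensity))
        d$mep_intensity <- checkerboard_fill(d$mep_intensity, phase = ph)
      d
    })
  }
  fit_a <- dyncdi(halves[[1]], control, ...)
  fit_b <- dyncdi(halves[[2]], control, ...)
  a <- fit_a$objects[[frame]]
  b <- fit_b$objects[[frame]]
  b <- align_scale(a, b) * b
  list(a = a, b = b, fit_a = fit_a, fit_b = fit_b, frame = frame)
}

## keep one checkerboard phase, replace the other by the 4-neighbour mean
checkerboard_fill <- function(intensity, phase = 1L) {
  n <- nrow(intensity); p <- ncol(intensity)
  chk <- (outer(seq_len(n), seq_len(p), `+`) %% 2L) == (phase %% 2L)
  up <- rbind(intensity[1, , drop = FALSE], intensity[-n, ])
  dn <- rbind(intensity[-1, ], intensity[n, , drop = FALSE])
  lf <- cbind(intensity[, 1, drop = FALSE], intensity[, -p])
  rt <- cbind(intensity[, -1], intensity[, p, drop = FALSE])
  filled <- (up + dn + lf + rt) / 4
  out <- intensity
  out[!chk] <- filled[!chk]
  out
}

#' Globally aligned difference between two complex fields
#'
#' Removes the global complex scalar (amplitude scale and phase) between two
#' fields by least squares and returns the residual amplitude map
#' `|a - c * b|` with its root-mean-square over a mask. Two fields equal up
#' to a global scalar give a zero map; orthogonal fields give an RMS of
#' `||a|| / sqrt(area)`.
#'
#' @param field_a,field_b Complex matrices or [wavefield()]s, same size.
#' @param mask Optional logical matrix over which the RMS is taken (default:
#'   everywhere).
#' @return List with `map` (numeric matrix), `rms` (scalar), and `scale`
#'   (the fitted complex scalar).
#' @export
aligned_difference <- function(field_a, field_b, mask = NULL) {
  a <- as_values(field_a); b <- as_values(field_b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (all(b == 0)) stop("field_b is identically zero")
  cc <- align_scale(a, b)
  map <- Mod(a - cc * b)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  list(map = map, rms = sqrt(mean(map[mask]^2)), scale = cc)
}
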