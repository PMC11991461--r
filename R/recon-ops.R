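## Core constraint/update operators of the dynamic-CDI iteration. All of
## them work on plain complex matrices (the hot path) and are exported both
## for testing and for building custom reconstruction loops.

as_values <- function(x) if (inherits(x, "wavefield")) x$values else x

## replace the modulus of a complex field by `target`, keeping the phase;
## below `eps` in modulus the replaced value takes zero phase
modulus_replace <- function(psi, target, epsilon_rel = 1e-12) {
  amp <- Mod(psi)
  eps <- epsilon_rel * max(amp)
  out <- psi * (target / pmax(amp, .Machine$double.xmin))
  low <- which(amp <= eps)        # which() drops NAs: non-finite input
  if (length(low)) out[low] <- target[low] + 0i    # surfaces downstream
  out
}

#' Transfer low spatial frequencies between adjacent frames
#'
#' Replaces the Fourier coefficients of `current` on the centred disk of
#' radius `qlow` (inclusive, Euclidean, in reciprocal pixels) with those of
#' `previous`, leaving all coefficients outside the disk unchanged. During
#' the early, unstable iterations this couples each frame's coarse morphology
#' to its predecessor's, exploiting the inter-frame similarity of a smoothly
#' evolving sample. `qlow = 0` transfers only the DC coefficient; a `qlow` at
#' or beyond the grid's corner radius replaces the full plane (values larger
#' than the grid supports are clamped with a warning).
#'
#' @param current,previous Complex matrices of the same size (current and
#'   previous frame transmission estimates).
#' @param qlow Transfer radius in reciprocal pixels, `>= 0`.
#' @return Complex matrix: `current` with its low frequencies replaced.
#' @export
low_frequency_transfer <- function(current, previous, qlow) {
  current <- as_values(current); previous <- as_values(previous)
  if (!all(dim(current) == dim(previous))) stop("shape mismatch")
  if (qlow < 0) stop("qlow must be >= 0")
  n <- nrow(current)
  rmax <- max(radius_grid(n))
  if (qlow > rmax) {
    warning(sprintf("qlow = %g exceeds the grid radius %.2f; clamped",
                    qlow, rmax))
    qlow <- rmax
  }
  tc <- fft_centered(current)
  tp <- fft_centered(previous)
  disk <- radius_grid(n) <= qlow
  tc[disk] <- tp[disk]
  ifft_centered(tc)
}

#' Transfer the static region into a frame estimate
#'
#' Overwrites the object values on the static mask with the running static
#' transmission function (the values saved from the previously updated
#' frame); all other pixels are untouched. Applying it twice equals applying
#' it once.
#'
#' @param object Complex matrix (frame transmission estimate).
#' @param static_function Complex vector of values on the static region, in
#'   `which(static_mask)` (column-major) order.
#' @param static_mask Logical matrix.
#' @return Complex matrix.
#' @export
static_region_transfer <- function(object, static_function, static_mask) {
  object <- as_values(object)
  if (!all(dim(object) == dim(static_mask))) stop("mask/shape mismatch")
  if (length(static_function) != sum(static_mask))
    stop("static_function must have one value per static-mask pixel")
  object[static_mask] <- static_function
  object
}

#' Save the static region of an updated frame
#'
#' Extracts the object values on the static mask as the new running static
#' transmission function, in `which(static_mask)` (column-major) order.
#'
#' @inheritParams static_region_transfer
#' @return Complex vector of length `sum(static_mask)`.
#' @export
save_static <- function(object, static_mask) {
  object <- as_values(object)
  if (!all(dim(object) == dim(static_mask))) stop("mask/shape mismatch")
  object[static_mask]
}

#' Modulus-enforced probe (MEP) update
#'
#' Propagates the probe to the detector plane, replaces the wavefront's
#' modulus by the square root of the measured probe-only diffraction
#' intensity while keeping its phase, propagates back, and applies the probe
#' support (zero outside). Where the wavefront modulus falls below the guard
#' the replaced value takes zero phase. A probe whose far field already
#' matches the MEP pattern and which lies inside the support is a fixed
#' point.
#'
#' @param probe Complex matrix or [wavefield()] (sample-plane probe).
#' @param mep_intensity Non-negative matrix: measured probe-only intensity.
#' @param probe_support Logical matrix; the probe is zeroed outside it.
#' @param epsilon_rel Relative modulus guard (fraction of the max modulus).
#' @return Updated probe, same type as the input.
#' @export
mep_probe_update <- function(probe, mep_intensity, probe_support,
                             epsilon_rel = 1e-12) {
  v <- as_values(probe)
  if (!all(dim(v) == dim(mep_intensity))) stop("shape mismatch")
  pk <- fft_centered(v)
  pk <- modulus_replace(pk, sqrt(mep_intensity), epsilon_rel)
  pr <- ifft_centered(pk)
  pr[!probe_support] <- 0 + 0i
  if (inherits(probe, "wavefield")) { probe$values <- pr; probe } else pr
}

#' Fourier modulus projection of an exit wave
#'
#' Replaces the modulus of the exit wave's far-field transform by the square
#' root of the measured intensity, keeping the phase, and transforms back.
#' This is the data constraint of the iteration: it is idempotent, and an
#' exit wave whose diffraction intensity equals the measurement is a fixed
#' point.
#'
#' @param exit_wave Complex matrix or [wavefield()].
#' @param intensity Non-negative measured intensity matrix.
#' @param epsilon_rel Relative modulus guard.
#' @return Modified exit wave, same type as the input.
#' @export
fourier_modulus_projection <- function(exit_wave, intensity,
                                       epsilon_rel = 1e-12) {
  v <- as_values(exit_wave)
  if (!all(dim(v) == dim(intensity))) stop("shape mismatch")
  if (any(intensity < 0)) stop("intensity must be non-negative")
  psi <- ifft_centered(modulus_replace(fft_centered(v), sqrt(intensity),
                                       epsilon_rel))
  if (inherits(exit_wave, "wavefield")) {
    exit_wave$values <- psi
    exit_wave
  } else psi
}

#' ePIE object/probe update
#'
#' The multiplicative gradient-style update of the extended ptychographical
#' iterative engine, driven by the exit-wave residual `psi_prime - psi`:
#' `O <- O + alpha * Conj(P) / max(|P|)^2 * (psi' - psi)`, then (optionally)
#' `P <- P + beta * Conj(O_new) / max(|O_new|)^2 * (psi' - psi)`. Outside the
#' support the object is reset to 1 and the probe to 0.
#'
#' @param object,probe Complex matrices.
#' @param psi Exit wave before the modulus projection (`object * probe`).
#' @param psi_prime Exit wave after the modulus projection.
#' @param alpha,beta Relaxation parameters of the object and probe updates.
#' @param support_mask Logical matrix (illuminated field of view).
#' @param update_probe Update the probe as well?
#' @return List with elements `object` and `probe`.
#' @export
epie_update <- function(object, probe, psi, psi_prime, alpha = 1, beta = 1,
                        support_mask = NULL, update_probe = TRUE) {
  object <- as_values(object); probe <- as_values(probe)
  psi <- as_values(psi); psi_prime <- as_values(psi_prime)
  if (is.null(support_mask))
    support_mask <- matrix(TRUE, nrow(object), ncol(object))
  dpsi <- psi_prime - psi
  pmax2 <- max(Mod(probe))^2
  if (is.finite(pmax2) && pmax2 > 0) {
    object <- object + alpha * Conj(probe) / pmax2 * dpsi
  } else {
    warning("probe is identically zero; object update skipped")
  }
  object[!support_mask] <- 1 + 0i
  if (update_probe) {
    omax2 <- max(Mod(object))^2
    if (is.finite(omax2) && omax2 > 0) {
      probe <- probe + beta * Conj(object) / omax2 * dpsi
    } else {
      warning("updated object is identically zero; probe update skipped")
    }
  }
  probe[!support_mask] <- 0 + 0i
  list(object = object, probe = probe)
}

#' Probe pre-reconstruction by hybrid input-output
#'
#' Classic complex-valued HIO phase retrieval of the probe from the
#' probe-only (MEP) diffraction pattern and a real-space support: alternates
#' the Fourier modulus replacement with the HIO feedback step (`g - beta_hio
#' * g'` outside the support), and enforces the Fourier modulus once more on
#' the final estimate. With `iterations = 0` the initial estimate — the
#' inverse transform of the measured modulus with zero phase — is returned
#' (after the final modulus enforcement, which leaves it unchanged); with
#' `iterations > 0` the Fourier phases are initialised uniformly at random
#' (seeded).
#'
#' A caveat for zone-plate probes: a centrosymmetric support (such as an
#' annulus) cannot distinguish a field from its twin (the conjugated,
#' inverted field), so a random start may stagnate between the two. Passing
#' the model probe as `init` resolves the ambiguity and turns the
#' pre-reconstruction into a refinement of the model.
#'
#' @param mep_intensity Non-negative matrix, not identically zero.
#' @param support_mask Logical matrix with at least one `TRUE` pixel.
#' @param iterations Number of HIO iterations.
#' @param beta_hio HIO feedback parameter.
#' @param seed Integer seed for the random initial phases.
#' @param init Optional complex matrix to start from (e.g. a model probe);
#'   overrides the random phase initialisation.
#' @return Complex matrix: the probe estimate (Fourier modulus enforced).
#' @export
hio_prereconstruct_probe <- function(mep_intensity, support_mask,
                                     iterations = 200, beta_hio = 0.9,
                                     seed = 1, init = NULL) {
  if (all(mep_intensity == 0)) stop("MEP intensity is identically zero")
  if (!any(support_mask)) stop("support mask is empty")
  sqrt_i <- sqrt(mep_intensity)
  n <- nrow(mep_intensity)
  if (iterations == 0) {
    g <- if (is.null(init)) ifft_centered(sqrt_i + 0i) else as_values(init)
  } else {
    if (is.null(init)) {
      ph <- withr::with_seed(seed,
                             matrix(stats::runif(n * n, -pi, pi), n, n))
      g <- ifft_centered(sqrt_i * exp(1i * ph))
    } else {
      g <- as_values(init)
    }
    for (k in seq_len(iterations)) {
      gp <- ifft_centered(modulus_replace(fft_centered(g), sqrt_i))
      gnew <- g - beta_hio * gp
      gnew[support_mask] <- gp[support_mask]
      g <- gnew
    }
  }
  ifft_centered(modulus_replace(fft_centered(g), sqrt_i))
}

## binary dilation of a logical mask by a Euclidean-disk structuring element
dilate_mask <- function(mask, radius = 2) {
  if (radius <= 0) return(mask)
  n <- nrow(mask); p <- ncol(mask)
  out <- mask
  r <- as.integer(ceiling(radius))
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    if (dy^2 + dx^2 > radius^2) next
    sy <- (seq_len(n) - dy - 1L) %% n + 1L
    sx <- (seq_len(p) - dx - 1L) %% p + 1L
    out <- out | mask[sy, sx]
  }
  out
}

#' Probe support from a probe estimate
#'
#' The default support used by the MEP constraint and the HIO
#' pre-reconstruction: pixels whose amplitude exceeds a small fraction of the
#' maximum, morphologically dilated by a couple of pixels.
#'
#' @param probe Complex matrix or [wavefield()].
#' @param threshold Amplitude threshold as a fraction of the maximum.
#' @param dilation Dilation radius in pixels.
#' @return Logical matrix.
#' @export
probe_support_from <- function(probe, threshold = 0.005, dilation = 2) {
  a <- Mod(as_values(probe))
  dilate_mask(a > threshold * max(a), dilation)
}

#' Initial probe guess for reconstructions with an unknown probe
#'
#' Blends a model zone-plate probe with the HIO pre-reconstruction of the
#' MEP pattern: the HIO estimate is aligned to the model by a global complex
#' scalar (least squares) and the two are averaged, then the result is scaled
#' so its energy matches the MEP pattern's total counts. If the dataset has
#' no MEP pattern the model probe is returned, scaled to the largest frame
#' total.
#'
#' @param dataset A [diffraction_dataset()].
#' @param model_probe A [wavefield()] or complex matrix; if `NULL`, a default
#'   zone-plate probe is synthesised from the dataset geometry with the
#'   defocus perturbed by `defocus_factor` (imperfect a-priori knowledge).
#' @param defocus_factor Multiplier on the default defocus when synthesising
#'   the model probe.
#' @param hio_iterations,hio_beta,seed HIO settings (see
#'   [hio_prereconstruct_probe()]).
#' @return Complex matrix: the initial probe.
#' @export
initial_probe_guess <- function(dataset, model_probe = NULL,
                                defocus_factor = 1.08,
                                hio_iterations = 200, hio_beta = 0.9,
                                seed = 1) {
  stopifnot(inherits(dataset, "diffraction_dataset"))
  if (is.null(model_probe)) {
    geo <- dataset$geometry
    fzp <- default_fzp(geo)
    fzp$defocus_m <- fzp$defocus_m * defocus_factor
    model_probe <- make_fzp_probe(fzp, geo)
  }
  m <- as_values(model_probe)
  m[!dataset$support_mask] <- 0 + 0i
  if (is.null(dataset$mep_intensity)) {
    target <- max(vapply(dataset$intensities, sum, numeric(1)))
    return(m / sqrt(field_energy(m)) * sqrt(target))
  }
  sup <- probe_support_from(m) & dataset$support_mask
  ## start HIO from the model: a centrosymmetric (annular) support cannot
  ## tell a probe from its twin, so a random start may stagnate
  h <- hio_prereconstruct_probe(dataset$mep_intensity, sup,
                                iterations = hio_iterations,
                                beta_hio = hio_beta, seed = seed, init = m)
  h[!dataset$support_mask] <- 0 + 0i
  cc <- sum(Conj(m) * h) / sum(Mod(m)^2)   # h ~ cc * m
  blend <- 0.5 * (h + cc * m)
  blend / sqrt(field_energy(blend)) * sqrt(sum(dataset$mep_intensity))
}
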