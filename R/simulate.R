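#' Generate a dynamic sample sequence with a static region
#'
#' Builds `n_frames` complex transmission functions sharing a bitwise
#' identical static region stitched next to a smoothly evolving dynamic
#' region, inside a disk-shaped illuminated field of view. This is the
#' ground-truth object sequence of the synthetic experiment: a time-varying
#' scene adjacent to a region that never changes, the redundancy the
#' reconstruction's static-region transfer exploits.
#'
#' The field of view is a centred disk (`support_mask`); the static region is
#' a chord at its bottom (`static_mask`), either carrying a letter-E-like
#' absorbing structure (`"structured"`), exactly unit transmission
#' (`"empty"`), or absent (`"none"`, in which case the whole disk is
#' dynamic). Transmission values satisfy `Mod(O) <= 1` with phases in
#' `[-pi, 0]` (absorbing sample); outside the support the transmission is
#' exactly `1 + 0i`.
#'
#' Scenes:
#' \describe{
#'   \item{`moving_blobs`}{absorbing Gaussian blobs drifting with constant
#'     per-blob velocities, reflected at the dynamic-region boundary.}
#'   \item{`translating_texture`}{a fixed smooth random texture rigidly
#'     translated by `step_px` pixels per frame (sub-pixel Fourier shift),
#'     emulating a sample stepped across the beam.}
#'   \item{`custom_images`}{user-supplied complex frames (list `frames` of
#'     `n_frames` matrices), masked to the dynamic region.}
#' }
#'
#' @param n_frames Number of time frames, `>= 1`.
#' @param scene One of `"translating_texture"` (the default, mirroring a
#'   sample stepped across the beam), `"moving_blobs"`, `"custom_images"`.
#' @param static_kind One of `"structured"`, `"empty"`, `"none"`.
#' @param grid Grid side length in pixels.
#' @param seed Integer seed; the sequence is deterministic given it.
#' @param support_radius Field-of-view disk radius in pixels (default
#'   `0.165 * grid`).
#' @param step_px Per-frame translation for `"translating_texture"` (pixels).
#' @param n_blobs Number of blobs for `"moving_blobs"`.
#' @param frames List of complex matrices for `"custom_images"`.
#'
#' @return An object of class `"dynamic_sequence"`: list with `frames` (list
#'   of complex matrices), `static_mask`, `dynamic_mask`, `support_mask`
#'   (logical matrices) and `n_frames`.
#' @export
generate_dynamic_sequence <- function(n_frames,
                                      scene = c("translating_texture",
                                                "moving_blobs",
                                                "custom_images"),
                                      static_kind = c("structured", "empty",
                                                      "none"),
                                      grid = 256, seed = 1,
                                      support_radius = 0.165 * grid,
                                      step_px = 0.05 * 0.285 * grid,
                                      n_blobs = 6, frames = NULL) {
  scene <- match.arg(scene)
  static_kind <- match.arg(static_kind)
  if (n_frames < 1) stop("n_frames must be >= 1")
  n <- as.integer(grid)
  rr <- radius_grid(n)
  support_mask <- rr <= support_radius
  cc <- centered_coords(n)
  ymat <- matrix(cc, n, n)                 # row coordinate, increases downward
  if (static_kind == "none") {
    static_mask <- matrix(FALSE, n, n)
  } else {
    static_mask <- support_mask & (ymat > 0.35 * support_radius)
  }
  dynamic_mask <- support_mask & !static_mask
  if (any(static_mask & dynamic_mask))
    stop("invalid configuration: static and dynamic masks overlap")

  ## static layer, built once and copied into every frame
  static_layer <- matrix(1 + 0i, n, n)
  if (static_kind == "structured") {
    e <- letter_e_mask(n, static_mask, support_radius)
    static_layer[e] <- 0.45 * exp(-0.7i)
  }

  dyn <- withr::with_seed(seed, switch(scene,
    moving_blobs = blob_frames(n, n_frames, dynamic_mask, n_blobs),
    translating_texture = texture_frames(n, n_frames, step_px),
    custom_images = {
      if (is.null(frames) || length(frames) != n_frames)
        stop("'frames' must be a list of n_frames complex matrices")
      lapply(frames, function(f) {
        if (!is.matrix(f) || !all(dim(f) == n)) stop("custom frame shape")
        f
      })
    }))

  out <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    o <- clip_transmission(dyn[[t]])
    o[!dynamic_mask] <- 1 + 0i
    o[static_mask] <- static_layer[static_mask]
    o[!support_mask] <- 1 + 0i
    out[[t]] <- o
  }
  structure(list(frames = out, static_mask = static_mask,
                 dynamic_mask = dynamic_mask, support_mask = support_mask,
                 n_frames = n_frames, scene = scene,
                 static_kind = static_kind, seed = seed),
            class = "dynamic_sequence")
}

#' @export
print.dynamic_sequence <- function(x, ...) {
  n <- nrow(x$frames[[1]])
  cat(sprintf("<dynamic_sequence> %d frames, %d x %d grid\n",
              x$n_frames, n, n))
  cat(sprintf("  scene: %s, static region: %s\n", x$scene, x$static_kind))
  cat(sprintf("  support %d px, static %d px, dynamic %d px\n",
              sum(x$support_mask), sum(x$static_mask), sum(x$dynamic_mask)))
  invisible(x)
}

## clamp |O| to [0, 1] and phases to [-pi, 0] (absorbing sample convention)
clip_transmission <- function(o) {
  a <- pmin(Mod(o), 1)
  ph <- pmax(pmin(Arg(o), 0), -pi)
  matrix(complex(modulus = a, argument = ph), nrow(o), ncol(o))
}

## blocky letter-E footprint inside the static chord
letter_e_mask <- function(n, static_mask, support_radius) {
  cc <- centered_coords(n)
  x <- matrix(cc, n, n, byrow = TRUE)      # column coordinate
  y <- matrix(cc, n, n)                    # row coordinate
  r <- support_radius
  y0 <- 0.45 * r; h <- 0.42 * r; wdt <- 0.5 * r
  stroke <- 0.12 * r
  bars <- (abs(y - y0) < h / 2) & (abs(x) < wdt / 2) &
    (abs(y - (y0 - h / 2)) < stroke | abs(y - y0) < stroke / 1.4 |
       abs(y - (y0 + h / 2)) < stroke)
  spine <- (abs(y - y0) < h / 2) & (x > -wdt / 2) & (x < -wdt / 2 + stroke)
  (bars | spine) & static_mask
}

## Gaussian absorption blobs with constant drift, reflected at the bounding
## box of the dynamic region
blob_frames <- function(n, n_frames, dynamic_mask, n_blobs) {
  idx <- which(dynamic_mask, arr.ind = TRUE)
  ylim <- range(idx[, 1]); xlim <- range(idx[, 2])
  pos <- cbind(stats::runif(n_blobs, ylim[1] + 5, ylim[2] - 5),
               stats::runif(n_blobs, xlim[1] + 5, xlim[2] - 5))
  vel <- matrix(stats::runif(2 * n_blobs, -1, 1), n_blobs, 2)
  vel <- vel / sqrt(rowSums(vel^2)) * stats::runif(n_blobs, 0.8, 2.2)
  sig <- stats::runif(n_blobs, 0.012 * n, 0.03 * n)
  amp <- stats::runif(n_blobs, 0.6, 1.3)
  rowg <- matrix(seq_len(n), n, n)
  colg <- matrix(seq_len(n), n, n, byrow = TRUE)
  out <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    g <- matrix(0, n, n)
    for (b in seq_len(n_blobs)) {
      g <- g + amp[b] * exp(-((rowg - pos[b, 1])^2 +
                                (colg - pos[b, 2])^2) / (2 * sig[b]^2))
    }
    ## optical-density field -> transmission with absorption and phase delay
    out[[t]] <- exp(-(0.9 + 0.9i) * g)
    pos <- pos + vel
    for (b in seq_len(n_blobs)) {
      if (pos[b, 1] < ylim[1] || pos[b, 1] > ylim[2]) vel[b, 1] <- -vel[b, 1]
      if (pos[b, 2] < xlim[1] || pos[b, 2] > xlim[2]) vel[b, 2] <- -vel[b, 2]
    }
  }
  out
}

## sparse particle field translated rigidly by step_px per frame: scattered
## absorbing patches on a unit-transmission background, emulating
## nanoparticles stepped across the beam (most of the field of view stays
## empty, as in real extended samples)
texture_frames <- function(n, n_frames, step_px) {
  base <- matrix(stats::rnorm(n * n), n, n)
  k <- radius_grid(n)
  lp <- exp(-(k / (0.035 * n))^2)          # correlation length ~ 1/(0.035)
  g <- Re(ifft_centered(fft_centered(base + 0i) * lp))
  g <- (g - min(g)) / diff(range(g))
  thr <- stats::quantile(g, 0.65)          # ~35% particle coverage
  od <- pmax(g - thr, 0) / (1 - thr)       # compact optical-density bumps
  cc <- centered_coords(n)
  fx <- matrix(cc, n, n, byrow = TRUE) / n
  odk <- fft_centered(od + 0i)
  out <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    shift <- (t - 1) * step_px
    ph <- exp(-2i * pi * fx * shift)       # shift along +x (columns)
    d <- pmax(Re(ifft_centered(odk * ph)), 0)
    out[[t]] <- exp(-(2.2 + 1.8i) * d)
  }
  out
}

#' Far-field diffraction intensity of one frame
#'
#' The squared modulus of the far-field transform of the exit wave
#' `object * probe`. With `object = 1` everywhere this is the probe-only
#' (MEP) diffraction pattern.
#'
#' @param object_frame Complex matrix or sample-plane [wavefield()].
#' @param probe Complex matrix or sample-plane [wavefield()] of the same
#'   size.
#' @return Non-negative numeric matrix of intensities (arbitrary units; the
#'   total equals the exit-wave energy by unitarity).
#' @export
forward_intensity <- function(object_frame, probe) {
  o <- if (inherits(object_frame, "wavefield")) object_frame$values
       else object_frame
  p <- if (inherits(probe, "wavefield")) probe$values else probe
  if (!all(dim(o) == dim(p))) stop("object and probe shapes differ")
  Mod(fft_centered(o * p))^2
}

#' Add Poisson counting noise to a diffraction pattern
#'
#' Scales the pattern so that it totals `photons_total` photons, draws
#' independent Poisson counts per pixel, and rescales back to the input
#' scale. For very large per-pixel expectations (`> 1e7`) the Poisson draw is
#' replaced by its Gaussian limit to avoid integer overflow. Deterministic
#' given `seed`.
#'
#' @param intensity Non-negative numeric matrix.
#' @param photons_total Total photon budget for the pattern; `Inf` returns
#'   the input unchanged.
#' @param seed Integer seed.
#' @return Noisy intensity matrix on the same scale as the input.
#' @export
add_noise <- function(intensity, photons_total, seed = 1) {
  if (any(intensity < 0)) stop("intensity must be non-negative")
  if (!is.numeric(photons_total) || photons_total <= 0)
    stop("photons_total must be positive")
  tot <- sum(intensity)
  if (!is.finite(photons_total) || tot == 0) return(intensity)
  s <- photons_total / tot
  lam <- as.vector(intensity) * s
  withr::with_seed(seed, {
    counts <- numeric(length(lam))
    big <- lam > 1e7
    counts[!big] <- stats::rpois(sum(!big), lam[!big])
    counts[big] <- pmax(0, stats::rnorm(sum(big), lam[big], sqrt(lam[big])))
    matrix(counts / s, nrow(intensity), ncol(intensity))
  })
}

#' Diffraction dataset container
#'
#' Bundles everything a reconstruction needs: the per-frame measured
#' intensities, the probe-only (MEP) intensity, the geometry, the
#' static/dynamic/support masks, and (for simulations) the ground truth.
#'
#' @param intensities List of `T` non-negative intensity matrices.
#' @param mep_intensity Probe-only intensity matrix, or `NULL` if not
#'   measured.
#' @param geometry A [cdi_geometry()].
#' @param static_mask,dynamic_mask,support_mask Logical matrices.
#' @param truth Optional list with elements `sequence`
#'   (a `dynamic_sequence`) and `probe` (a [wavefield()]).
#' @return An object of class `"diffraction_dataset"`.
#' @export
diffraction_dataset <- function(intensities, mep_intensity, geometry,
                                static_mask, dynamic_mask, support_mask,
                                truth = NULL) {
  if (!is.list(intensities) || length(intensities) < 1L)
    stop("need at least one intensity frame")
  for (m in intensities) {
    if (!all(is.finite(m)) || any(m < 0))
      stop("intensities must be finite and non-negative")
  }
  if (!is.null(mep_intensity) &&
      (!all(is.finite(mep_intensity)) || any(mep_intensity < 0)))
    stop("MEP intensity must be finite and non-negative")
  stopifnot(inherits(geometry, "cdi_geometry"))
  structure(list(intensities = intensities, mep_intensity = mep_intensity,
                 geometry = geometry, static_mask = static_mask,
                 dynamic_mask = dynamic_mask, support_mask = support_mask,
                 truth = truth),
            class = "diffraction_dataset")
}

#' @export
print.diffraction_dataset <- function(x, ...) {
  n <- nrow(x$intensities[[1]])
  cat(sprintf("<diffraction_dataset> %d frames, %d x %d detector\n",
              length(x$intensities), n, n))
  cat(sprintf("  MEP pattern: %s, ground truth: %s\n",
              if (is.null(x$mep_intensity)) "absent" else "present",
              if (is.null(x$truth)) "absent" else "present"))
  print(x$geometry)
  invisible(x)
}

#' Simulate the diffraction dataset of a dynamic sequence
#'
#' Forward-propagates each frame's exit wave (`object * probe`) to the
#' detector, adds Poisson noise at the given photon budget, and records the
#' probe-only MEP pattern the same way. The probe is truncated to the
#' sequence's support mask first, making the illumination exactly compatible
#' with the reconstruction's support rule (probe identically zero outside the
#' field of view), and the truncated probe is stored as the ground truth.
#'
#' @param sequence A [generate_dynamic_sequence()] result.
#' @param probe A sample-plane [wavefield()] on the same grid.
#' @param geometry A [cdi_geometry()] with matching `n_pixels`.
#' @param photons_total Photon budget per frame (`Inf` = noiseless).
#' @param seed Integer seed for the noise.
#' @param mep_photons_total Photon budget for the MEP pattern (defaults to
#'   `photons_total`).
#' @return A [diffraction_dataset()] with `truth` filled in.
#' @export
build_dataset <- function(sequence, probe, geometry,
                          photons_total = 1e8, seed = 1,
                          mep_photons_total = photons_total) {
  stopifnot(inherits(sequence, "dynamic_sequence"),
            inherits(probe, "wavefield"),
            inherits(geometry, "cdi_geometry"))
  n <- nrow(sequence$frames[[1]])
  if (!all(dim(probe$values) == n) || geometry$n_pixels != n)
    stop("sequence, probe and geometry grids are inconsistent")
  p <- probe
  p$values[!sequence$support_mask] <- 0 + 0i
  tt <- length(sequence$frames)
  intens <- vector("list", tt)
  for (t in seq_len(tt)) {
    i0 <- forward_intensity(sequence$frames[[t]], p$values)
    intens[[t]] <- add_noise(i0, photons_total, seed = seed + t)
  }
  mep0 <- forward_intensity(matrix(1 + 0i, n, n), p$values)
  mep <- add_noise(mep0, mep_photons_total, seed = seed)
  diffraction_dataset(intens, mep, geometry,
                      static_mask = sequence$static_mask,
                      dynamic_mask = sequence$dynamic_mask,
                      support_mask = sequence$support_mask,
                      truth = list(sequence = sequence, probe = p))
}

#' One-call synthetic experiment
#'
#' Convenience wrapper reproducing the reference soft X-ray configuration at
#' a chosen grid size: 705 eV photons, 105.4 mm sample-detector distance, and
#' a detector pitch of `11 um * 2048 / grid` (the full-resolution detector
#' binned down), which keeps the sample-plane pixel at 8.23 nm for every
#' grid. The probe is a defocused 300/80 um zone-plate probe scaled to
#' `probe_diameter_frac` of the field of view (so its wavefront stays
#' sampled), truncated to the field-of-view disk.
#'
#' @param n_frames Number of frames.
#' @param grid Grid side length (pixels).
#' @param scene,static_kind Passed to [generate_dynamic_sequence()].
#' @param photons_total Photon budget per frame (`Inf` = noiseless).
#' @param seed Integer seed for both scene and noise.
#' @param probe_diameter_frac Geometric probe diameter as a fraction of the
#'   field of view.
#' @param probe_structure `NULL` for the bare analytic model probe, or a list
#'   with `phase_sd` (rad), `amp_sd` (relative) and `corr_px` (pixels)
#'   describing the smooth complex speckle imprinted on the model probe. The
#'   default emulates the granularity of experimentally retrieved zone-plate
#'   probes (an idealised smooth annulus is not what a beamline delivers, and
#'   its lack of structure also ill-conditions the inversion).
#' @param ... Further arguments to [generate_dynamic_sequence()].
#' @return A [diffraction_dataset()] with ground truth.
#' @examples
#' ds <- simulate_dataset(3, grid = 64, photons_total = 1e7, seed = 42)
#' ds
#' @export
simulate_dataset <- function(n_frames = 10, grid = 256,
                             scene = "translating_texture",
                             static_kind = "structured",
                             photons_total = 1e8, seed = 1,
                             probe_diameter_frac = 0.285,
                             probe_structure = list(phase_sd = 1.5,
                                                    amp_sd = 0.3,
                                                    corr_px = 5), ...) {
  geometry <- default_geometry(grid)
  fzp <- default_fzp(geometry, probe_diameter_frac)
  probe <- make_fzp_probe(fzp, geometry)
  if (!is.null(probe_structure))
    probe <- perturb_probe(probe, seed = seed,
                           phase_sd = probe_structure$phase_sd,
                           amp_sd = probe_structure$amp_sd,
                           corr_px = probe_structure$corr_px)
  sequence <- generate_dynamic_sequence(n_frames, scene = scene,
                                        static_kind = static_kind,
                                        grid = grid, seed = seed, ...)
  build_dataset(sequence, probe, geometry, photons_total = photons_total,
                seed = seed)
}

#' Imprint measured-probe-like structure on a model probe
#'
#' Multiplies a model probe by a smooth complex speckle field (seeded):
#' Gaussian-correlated phase ripple of standard deviation `phase_sd` and
#' relative amplitude mottling `amp_sd`, with correlation length `corr_px`
#' pixels. Experimentally retrieved zone-plate probes carry this kind of
#' granularity (zone imperfections, window scattering, upstream optics), in
#' contrast to an idealised analytic annulus. The result is renormalised to
#' the input energy.
#'
#' @param probe A [wavefield()].
#' @param seed Integer seed.
#' @param phase_sd Phase ripple standard deviation (rad).
#' @param amp_sd Relative amplitude mottling standard deviation.
#' @param corr_px Speckle correlation length (pixels).
#' @return A [wavefield()] of the same energy.
#' @export
perturb_probe <- function(probe, seed = 1, phase_sd = 1.5, amp_sd = 0.3,
                          corr_px = 5) {
  stopifnot(inherits(probe, "wavefield"))
  n <- nrow(probe$values)
  k <- radius_grid(n)
  lp <- exp(-(k * corr_px / n)^2)
  out <- withr::with_seed(seed, {
    sm <- function() {
      m <- matrix(stats::rnorm(n * n), n, n)
      Re(ifft_centered(fft_centered(m + 0i) * lp))
    }
    ph <- sm(); ph <- ph / stats::sd(ph) * phase_sd
    am <- sm(); am <- pmax(1 + am / stats::sd(am) * amp_sd, 0.05)
    probe$values * am * exp(1i * ph)
  })
  e0 <- field_energy(probe$values)
  probe$values <- out / sqrt(field_energy(out)) * sqrt(e0)
  probe
}

#' @rdname simulate_dataset
#' @export
default_geometry <- function(grid = 256) {
  cdi_geometry(photon_energy_ev = 705, distance_m = 0.1054,
               n_pixels = grid, detector_pitch_m = 11e-6 * 2048 / grid)
}

#' @rdname simulate_dataset
#' @export
default_fzp <- function(geometry, probe_diameter_frac = 0.285) {
  fov <- geometry$n_pixels * sample_plane_pixel_size(geometry)
  fzp <- fzp_spec(300e-6, 80e-6, 30e-9, geometry$photon_energy_ev)
  fzp$defocus_m <- defocus_for_probe_diameter(fzp, probe_diameter_frac * fov)
  fzp
}
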