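## Planck constant times speed of light, in eV.nm
HC_EV_NM <- 1239.842

#' Photon energy to wavelength
#'
#' @param energy_ev Photon energy in eV.
#' @return Wavelength in metres, using hc = 1239.842 eV nm.
#' @examples
#' energy_to_wavelength(705)   # soft X-ray, ~1.76 nm
#' @export
energy_to_wavelength <- function(energy_ev) {
  if (!is.numeric(energy_ev) || any(energy_ev <= 0))
    stop("photon energy must be positive")
  HC_EV_NM / energy_ev * 1e-9
}

#' Experiment geometry
#'
#' Describes the far-field measurement geometry: photon energy, sample to
#' detector distance, and the detector grid. The wavelength is derived from
#' the photon energy. The sample-plane pixel size implied by this geometry is
#' the standard Fraunhofer sampling relation `lambda * z / (N * p)` (see
#' [sample_plane_pixel_size()]) and is the pixel size of every sample-plane
#' wavefield in a run.
#'
#' @param photon_energy_ev Photon energy (eV).
#' @param distance_m Sample-to-detector distance (m).
#' @param n_pixels Detector side length in pixels (square detector).
#' @param detector_pitch_m Detector pixel pitch (m).
#'
#' @return An object of class `"cdi_geometry"`.
#' @examples
#' ## soft X-ray beamline geometry, detector binned to a 256 grid
#' geo <- cdi_geometry(705, 0.1054, 256, 88e-6)
#' sample_plane_pixel_size(geo)   # ~8.23e-9 m
#' @export
cdi_geometry <- function(photon_energy_ev, distance_m, n_pixels,
                         detector_pitch_m) {
  vals <- c(photon_energy_ev, distance_m, n_pixels, detector_pitch_m)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals)) ||
      any(vals <= 0))
    stop("invalid geometry: all fields must be positive and finite")
  n_pixels <- as.integer(n_pixels)
  structure(list(photon_energy_ev = photon_energy_ev,
                 wavelength = energy_to_wavelength(photon_energy_ev),
                 distance_m = distance_m,
                 n_pixels = n_pixels,
                 detector_pitch_m = detector_pitch_m),
            class = "cdi_geometry")
}

#' @export
print.cdi_geometry <- function(x, ...) {
  cat("<cdi_geometry>\n")
  cat(sprintf("  photon energy: %g eV (lambda = %.4g nm)\n",
              x$photon_energy_ev, x$wavelength * 1e9))
  cat(sprintf("  distance: %g mm, detector: %d px @ %.3g um\n",
              x$distance_m * 1e3, x$n_pixels, x$detector_pitch_m * 1e6))
  cat(sprintf("  sample-plane pixel: %.4g nm\n",
              sample_plane_pixel_size(x) * 1e9))
  invisible(x)
}

#' Sample-plane pixel size of a far-field geometry
#'
#' For a detector of `N` pixels at pitch `p` a distance `z` downstream of the
#' sample, the discrete Fourier transform maps the detector onto a
#' sample-plane grid with pixel size `lambda * z / (N * p)`.
#'
#' @param geometry A [cdi_geometry()].
#' @return Sample-plane pixel size in metres.
#' @export
sample_plane_pixel_size <- function(geometry) {
  stopifnot(inherits(geometry, "cdi_geometry"))
  geometry$wavelength * geometry$distance_m /
    (geometry$n_pixels * geometry$detector_pitch_m)
}

#' Fresnel zone plate specification
#'
#' Geometry of the zone plate used to form the illumination: outer diameter,
#' central-stop diameter and outermost zone width, plus the photon energy it
#' is used at and the defocus (sample-plane offset from the focal plane,
#' positive downstream of focus). The first-order focal length is
#' `f = diameter * outermost_zone_width / lambda`.
#'
#' @param diameter_m Zone-plate diameter (m).
#' @param central_stop_m Central-stop diameter (m), `< diameter_m`.
#' @param outermost_zone_width_m Outermost zone width (m).
#' @param photon_energy_ev Photon energy (eV).
#' @param defocus_m Sample-plane offset from focus (m); the geometric probe
#'   diameter at the sample is `diameter_m * abs(defocus_m) / f`.
#'
#' @return An object of class `"fzp_spec"` with derived fields `wavelength`
#'   and `focal_length_m`.
#' @examples
#' ## 300 um FZP, 80 um stop, 30 nm outermost zone at 705 eV
#' fzp <- fzp_spec(300e-6, 80e-6, 30e-9, 705, defocus_m = 10.24e-6)
#' fzp$focal_length_m     # ~5.12 mm
#' @export
fzp_spec <- function(diameter_m, central_stop_m, outermost_zone_width_m,
                     photon_energy_ev, defocus_m = 0) {
  if (!(central_stop_m > 0 && central_stop_m < diameter_m))
    stop("central stop must satisfy 0 < central_stop_m < diameter_m")
  if (outermost_zone_width_m <= 0) stop("outermost zone width must be > 0")
  wavelength <- energy_to_wavelength(photon_energy_ev)
  f <- diameter_m * outermost_zone_width_m / wavelength
  if (!is.finite(f) || f <= 0) stop("derived focal length must be positive")
  structure(list(diameter_m = diameter_m,
                 central_stop_m = central_stop_m,
                 outermost_zone_width_m = outermost_zone_width_m,
                 photon_energy_ev = photon_energy_ev,
                 defocus_m = defocus_m,
                 wavelength = wavelength,
                 focal_length_m = f),
            class = "fzp_spec")
}

#' @export
print.fzp_spec <- function(x, ...) {
  cat("<fzp_spec>\n")
  cat(sprintf("  diameter %g um, stop %g um, outermost zone %g nm\n",
              x$diameter_m * 1e6, x$central_stop_m * 1e6,
              x$outermost_zone_width_m * 1e9))
  cat(sprintf("  focal length %.4g mm at %g eV, defocus %.4g um\n",
              x$focal_length_m * 1e3, x$photon_energy_ev,
              x$defocus_m * 1e6))
  cat(sprintf("  geometric probe diameter %.4g um\n",
              x$diameter_m * abs(x$defocus_m) / x$focal_length_m * 1e6))
  invisible(x)
}

#' Defocus giving a target probe diameter
#'
#' Inverts the geometric relation `D_probe = diameter * |defocus| / f` to
#' find the defocus distance that produces a probe of the requested diameter
#' at the sample plane.
#'
#' @param fzp An [fzp_spec()].
#' @param probe_diameter_m Desired geometric probe outer diameter (m).
#' @return Defocus distance (m), positive (downstream of focus).
#' @export
defocus_for_probe_diameter <- function(fzp, probe_diameter_m) {
  stopifnot(inherits(fzp, "fzp_spec"), probe_diameter_m > 0)
  probe_diameter_m * fzp$focal_length_m / fzp$diameter_m
}
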