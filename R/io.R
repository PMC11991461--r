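## Dataset container and result export. The container is a single
## schema-versioned RDS file: lossless for double/complex arrays, logical
## masks and geometry attributes, with an optional ground-truth group.

DATASET_SCHEMA <- "dyncdi-dataset"
DATASET_SCHEMA_VERSION <- 1L

#' Write / read a diffraction dataset container
#'
#' One self-describing file per experiment: the per-frame intensities, the
#' MEP pattern (if any), the geometry, the three masks, and the optional
#' simulation ground truth, stamped with a schema name and version. The round
#' trip is bit-exact. Reading fails with an explicit error on a schema or
#' version mismatch; a missing truth group loads as `NULL`.
#'
#' @param dataset A [diffraction_dataset()].
#' @param path File path (conventionally `.rds`).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the [diffraction_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "diffraction_dataset"))
  payload <- list(schema = DATASET_SCHEMA,
                  version = DATASET_SCHEMA_VERSION,
                  intensities = dataset$intensities,
                  mep_intensity = dataset$mep_intensity,
                  geometry = unclass(dataset$geometry),
                  static_mask = dataset$static_mask,
                  dynamic_mask = dataset$dynamic_mask,
                  support_mask = dataset$support_mask,
                  truth = dataset$truth)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema, DATASET_SCHEMA))
    stop("not a dyncdi dataset container: ", path)
  if (!identical(payload$version, DATASET_SCHEMA_VERSION))
    stop(sprintf("unsupported dataset schema version %s (expected %d)",
                 payload$version, DATASET_SCHEMA_VERSION))
  for (grp in c("intensities", "geometry", "static_mask", "dynamic_mask",
                "support_mask"))
    if (is.null(payload[[grp]]))
      stop("missing required group '", grp, "' in ", path)
  geo <- payload$geometry
  diffraction_dataset(payload$intensities, payload$mep_intensity,
                      cdi_geometry(geo$photon_energy_ev, geo$distance_m,
                                   geo$n_pixels, geo$detector_pitch_m),
                      payload$static_mask, payload$dynamic_mask,
                      payload$support_mask, truth = payload$truth)
}

#' Write the per-iteration error trace of a fit as CSV
#'
#' Long format with columns `iteration`, `frame`, `data_error` and (when
#' ground truth was available) `object_error`.
#'
#' @param fit A `"dyncdi"` fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_error_trace <- function(fit, path) {
  stopifnot(inherits(fit, "dyncdi"))
  utils::write.csv(residuals(fit, type = "trace"), path, row.names = FALSE)
  invisible(path)
}

#' Export reconstructed frames as 32-bit TIFF images
#'
#' Writes one amplitude and one phase image per frame. TIFF samples must lie
#' in `[0, 1]`, so amplitudes are divided by the global maximum over the
#' export and phases are mapped affinely from `[-pi, pi]`; the mapping
#' parameters are stored in `scales.csv` next to the images so values can be
#' restored to within 32-bit float precision.
#'
#' @param fit A `"dyncdi"` fit.
#' @param dir Output directory (created if needed).
#' @return Data frame of the written files and their value mappings,
#'   invisibly.
#' @export
export_frames <- function(fit, dir) {
  stopifnot(inherits(fit, "dyncdi"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  amp_scale <- max(vapply(fit$objects, function(o) max(Mod(o)), numeric(1)))
  rows <- list()
  for (t in seq_along(fit$objects)) {
    o <- fit$objects[[t]]
    fa <- file.path(dir, sprintf("frame_%03d_amplitude.tif", t))
    fp <- file.path(dir, sprintf("frame_%03d_phase.tif", t))
    tiff::writeTIFF(Mod(o) / amp_scale, fa, bits.per.sample = 32L)
    tiff::writeTIFF((Arg(o) + pi) / (2 * pi), fp, bits.per.sample = 32L)
    rows[[t]] <- data.frame(frame = t, amplitude_file = basename(fa),
                            phase_file = basename(fp),
                            amplitude_scale = amp_scale,
                            phase_offset = -pi, phase_span = 2 * pi)
  }
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(dir, "scales.csv"), row.names = FALSE)
  invisible(meta)
}

#' Export an FRC curve as CSV
#'
#' Columns: `radius_per_nm` (spatial frequency in 1/nm), `correlation`,
#' `threshold`.
#'
#' @param curve An [frc()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frc_csv <- function(curve, path) {
  stopifnot(inherits(curve, "frc_curve"))
  utils::write.csv(data.frame(radius_per_nm = curve$rings$spatial_freq * 1e-9,
                              correlation = curve$rings$correlation,
                              threshold = curve$rings$threshold),
                   path, row.names = FALSE)
  invisible(path)
}
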