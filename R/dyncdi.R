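#' Control parameters for the dynamic-CDI iteration
#'
#' @param n_iterations Total number of iterations over the frame sequence.
#' @param alpha,beta ePIE relaxation parameters of the object and probe
#'   updates (typically in `(0, 2]`).
#' @param qlow Radius (reciprocal pixels) of the low-frequency disk
#'   transferred between adjacent frames.
#' @param n_lowfreq_iterations Number of early iterations during which the
#'   low-frequency transfer is active (`<= n_iterations`).
#' @param use_mep Apply the modulus-enforced probe constraint each frame?
#' @param use_static_transfer Transfer the running static region between
#'   frames?
#' @param use_lowfreq_transfer Transfer low frequencies between adjacent
#'   frames during the early iterations?
#' @param update_probe_epie Update the probe with the ePIE step (in addition
#'   to the MEP constraint)?
#' @param epsilon_rel Relative modulus-division guard of the projections.
#' @param seed Integer seed (random initial phases of the HIO
#'   pre-reconstruction).
#' @param hio_iterations,hio_beta HIO pre-reconstruction settings.
#' @return A list of class `"dyncdi_control"`.
#' @export
dyncdi_control <- function(n_iterations = 300, alpha = 1, beta = 1,
                           qlow = 3, n_lowfreq_iterations = 20,
                           use_mep = TRUE, use_static_transfer = TRUE,
                           use_lowfreq_transfer = TRUE,
                           update_probe_epie = TRUE,
                           epsilon_rel = 1e-12, seed = 1,
                           hio_iterations = 200, hio_beta = 0.9) {
  stopifnot(n_iterations >= 1, alpha >= 0, beta >= 0, qlow >= 0,
            n_lowfreq_iterations >= 0, hio_iterations >= 0,
            epsilon_rel >= 0)
  n_lowfreq_iterations <- min(n_lowfreq_iterations, n_iterations)
  structure(list(n_iterations = as.integer(n_iterations), alpha = alpha,
                 beta = beta, qlow = qlow,
                 n_lowfreq_iterations = as.integer(n_lowfreq_iterations),
                 use_mep = isTRUE(use_mep),
                 use_static_transfer = isTRUE(use_static_transfer),
                 use_lowfreq_transfer = isTRUE(use_lowfreq_transfer),
                 update_probe_epie = isTRUE(update_probe_epie),
                 epsilon_rel = epsilon_rel, seed = as.integer(seed),
                 hio_iterations = as.integer(hio_iterations),
                 hio_beta = hio_beta),
            class = "dyncdi_control")
}

#' Dynamic coherent diffractive imaging reconstruction
#'
#' Reconstructs the full time series of complex sample transmission functions
#' and the illumination probe from per-frame far-field diffraction
#' intensities. Each iteration sweeps the frames in ascending order and
#' applies, per frame: (1) low-frequency transfer from the previous frame
#' (early iterations only, never to frame 1), (2) static-region transfer from
#' the running static function, (3) the modulus-enforced probe (MEP) update,
#' (4) exit-wave formation and the Fourier modulus projection against the
#' measured intensity, (5) the ePIE object (and optionally probe) update with
#' the support rule (object 1 and probe 0 outside the support), and (6)
#' saving the updated static region. The static function is a single running
#' variable: frame 1 of iteration `n > 1` receives the static region saved by
#' the last frame of iteration `n - 1`.
#'
#' The normalised data-space error
#' `E = sum((|A| - sqrt(I))^2) / sum(I)`
#' of each frame (with `A` the exit wave's far field before the modulus
#' replacement) is recorded at every iteration; when the dataset carries the
#' simulation ground truth, a normalised object-space error after global
#' phase alignment over the illuminated support is recorded as well.
#'
#' @param data A [diffraction_dataset()].
#' @param control A [dyncdi_control()].
#' @param probe Initial probe: a [wavefield()] or complex matrix, or `NULL`
#'   to build one with [initial_probe_guess()] (model zone-plate probe
#'   blended with the HIO pre-reconstruction of the MEP pattern).
#' @param objects Initial object estimates: list of complex matrices, or
#'   `NULL` for unit transmission everywhere.
#' @param probe_support Logical matrix used by the MEP constraint, or `NULL`
#'   to derive it from the initial probe with [probe_support_from()].
#' @return An object of class `"dyncdi"`; see [fitted.dyncdi()],
#'   [residuals.dyncdi()], [summary.dyncdi()], [plot.dyncdi()].
#' @examples
#' ds <- simulate_dataset(3, grid = 64, photons_total = Inf, seed = 2)
#' fit <- dyncdi(ds, dyncdi_control(n_iterations = 5, hio_iterations = 20))
#' fit
#' @export
dyncdi <- function(data, control = dyncdi_control(), probe = NULL,
                   objects = NULL, probe_support = NULL) {
  stopifnot(inherits(data, "diffraction_dataset"),
            inherits(control, "dyncdi_control"))
  cl <- match.call()
  n <- nrow(data$intensities[[1]])
  tt <- length(data$intensities)
  if (control$use_mep && is.null(data$mep_intensity))
    stop("MEP pattern missing: the dataset has no probe-only intensity ",
         "but use_mep = TRUE")

  if (is.null(probe)) {
    probe <- initial_probe_guess(data, hio_iterations = control$hio_iterations,
                                 hio_beta = control$hio_beta,
                                 seed = control$seed)
  }
  p <- as_values(probe)
  if (!all(dim(p) == n)) stop("probe grid does not match the data")
  if (is.null(objects)) {
    objects <- replicate(tt, matrix(1 + 0i, n, n), simplify = FALSE)
  }
  if (length(objects) != tt) stop("need one initial object per frame")
  objects <- lapply(objects, function(o) {
    o <- as_values(o)
    if (!all(dim(o) == n)) stop("object grid does not match the data")
    o
  })
  if (is.null(probe_support)) probe_support <- probe_support_from(p)

  support <- data$support_mask
  smask <- data$static_mask
  p[!support] <- 0 + 0i
  for (t in seq_len(tt)) objects[[t]][!support] <- 1 + 0i

  sqrt_i <- lapply(data$intensities, sqrt)
  sum_i <- vapply(data$intensities, sum, numeric(1))
  eps <- control$epsilon_rel

  ## ground truth (if present) for the object-space error trace
  truth <- data$truth
  obj_err <- NULL
  if (!is.null(truth)) {
    illum <- Mod(truth$probe$values) > 0.1 * max(Mod(truth$probe$values))
    obj_err <- matrix(NA_real_, control$n_iterations, tt)
  }
  data_err <- matrix(NA_real_, control$n_iterations, tt)

  s_fun <- NULL                            # running static function S(r2)
  for (it in seq_len(control$n_iterations)) {
    for (t in seq_len(tt)) {
      o <- objects[[t]]
      if (!all(is.finite(Re(o))) || !all(is.finite(Im(o))) ||
          !all(is.finite(Re(p))) || !all(is.finite(Im(p))))
        stop(sprintf("non-finite state at iteration %d, frame %d", it, t))
      if (t != 1 && control$use_lowfreq_transfer &&
          it <= control$n_lowfreq_iterations) {
        o <- low_frequency_transfer(o, objects[[t - 1]], control$qlow)
      }
      if (control$use_static_transfer && !is.null(s_fun) &&
          !(it == 1 && t == 1)) {
        o <- static_region_transfer(o, s_fun, smask)
      }
      if (control$use_mep) {
        p <- mep_probe_update(p, data$mep_intensity, probe_support, eps)
      }
      psi <- o * p
      a_mod <- Mod(fft_centered(psi))
      data_err[it, t] <- sum((a_mod - sqrt_i[[t]])^2) / sum_i[t]
      psi_p <- ifft_centered(modulus_replace(fft_centered(psi),
                                             sqrt_i[[t]], eps))
      upd <- epie_update(o, p, psi, psi_p, control$alpha, control$beta,
                         support, control$update_probe_epie)
      o <- upd$object
      p <- upd$probe
      if (control$use_static_transfer) s_fun <- save_static(o, smask)
      objects[[t]] <- o
      if (!is.null(obj_err))
        obj_err[it, t] <- object_error(o, truth$sequence$frames[[t]], illum)
      if (anyNA(o) || anyNA(p) || !all(is.finite(Mod(o))) ||
          !all(is.finite(Mod(p))))
        stop(sprintf("non-finite state at iteration %d, frame %d", it, t))
    }
  }

  px <- sample_plane_pixel_size(data$geometry)
  structure(list(objects = objects,
                 probe = wavefield(p, pixel_size = px,
                                   wavelength = data$geometry$wavelength,
                                   plane = "sample"),
                 static_function = s_fun,
                 errors = list(data = data_err, object = obj_err),
                 control = control, geometry = data$geometry,
                 masks = list(static = smask, dynamic = data$dynamic_mask,
                              support = support,
                              probe_support = probe_support),
                 truth = truth, n_frames = tt, call = cl),
            class = "dyncdi")
}

#' Conventional CDI baseline
#'
#' The same iteration with the two inter-frame constraints switched off
#' (`use_static_transfer = FALSE`, `use_lowfreq_transfer = FALSE`): each
#' frame is reconstructed as independent single-pattern CDI, sharing only the
#' probe. Used as the ablation baseline.
#'
#' @inheritParams dyncdi
#' @return A `"dyncdi"` object.
#' @export
conventional_cdi <- function(data, control = dyncdi_control(), probe = NULL,
                             objects = NULL, probe_support = NULL) {
  control$use_static_transfer <- FALSE
  control$use_lowfreq_transfer <- FALSE
  dyncdi(data, control, probe = probe, objects = objects,
         probe_support = probe_support)
}

## normalised object error after global phase alignment over a mask:
## min_phi ||O - e^{i phi} O_true|| / ||O_true||
object_error <- function(o, o_true, mask) {
  a <- o[mask]; b <- o_true[mask]
  ph <- Arg(sum(Conj(b) * a))
  sqrt(sum(Mod(a - exp(1i * ph) * b)^2) / sum(Mod(b)^2))
}

#' Global complex-scalar alignment
#'
#' Least-squares complex scalar `c` minimising `||a - c * b||`, removing the
#' global phase and amplitude-scale ambiguity between two reconstructions.
#'
#' @param a,b Complex matrices or [wavefield()]s of the same size.
#' @return The complex scalar `c`.
#' @export
align_scale <- function(a, b) {
  a <- as_values(a); b <- as_values(b)
  sum(Conj(b) * a) / sum(Mod(b)^2)
}

#' Normalised correlation between two complex fields
#'
#' `|<a, b>| / (||a|| ||b||)`: 1 when the fields agree up to a global complex
#' scalar, regardless of its phase.
#'
#' @param a,b Complex matrices or [wavefield()]s of the same size.
#' @return Real number in `[0, 1]`.
#' @export
field_correlation <- function(a, b) {
  a <- as_values(a); b <- as_values(b)
  Mod(sum(Conj(b) * a)) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
}

## ------------------------------------------------------------------- S3 --

#' @export
print.dyncdi <- function(x, ...) {
  cat(sprintf("<dyncdi> %d frames, %d iterations\n",
              x$n_frames, x$control$n_iterations))
  cat(sprintf("  constraints: MEP=%s static=%s lowfreq=%s probe-ePIE=%s\n",
              x$control$use_mep, x$control$use_static_transfer,
              x$control$use_lowfreq_transfer, x$control$update_probe_epie))
  fin <- x$errors$data[nrow(x$errors$data), ]
  cat(sprintf("  final data error: mean %.3e (range %.3e..%.3e)\n",
              mean(fin), min(fin), max(fin)))
  if (!is.null(x$errors$object)) {
    fo <- x$errors$object[nrow(x$errors$object), ]
    cat(sprintf("  final object error vs truth: mean %.3e\n", mean(fo)))
  }
  if (!is.null(x$truth)) {
    cat(sprintf("  probe correlation vs truth: %.4f\n",
                field_correlation(x$probe$values, x$truth$probe$values)))
  }
  invisible(x)
}

#' @export
summary.dyncdi <- function(object, ...) {
  nit <- nrow(object$errors$data)
  tab <- data.frame(frame = seq_len(object$n_frames),
                    data_error = object$errors$data[nit, ])
  if (!is.null(object$errors$object))
    tab$object_error <- object$errors$object[nit, ]
  out <- list(table = tab, n_iterations = nit, control = object$control,
              probe_correlation = if (!is.null(object$truth))
                field_correlation(object$probe$values,
                                  object$truth$probe$values) else NULL)
  class(out) <- "summary.dyncdi"
  out
}

#' @export
print.summary.dyncdi <- function(x, ...) {
  cat(sprintf("dynamic CDI reconstruction, %d iterations\n", x$n_iterations))
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$probe_correlation))
    cat(sprintf("probe correlation vs truth: %.4f\n", x$probe_correlation))
  invisible(x)
}

#' Extract reconstructed frames or probe
#'
#' @param object A `"dyncdi"` fit.
#' @param frame Frame index, or `NULL` for the list of all frames.
#' @param what `"object"` for transmission functions, `"probe"` for the
#'   reconstructed probe.
#' @param ... Unused.
#' @return A complex matrix, a list of them, or a [wavefield()] for the
#'   probe.
#' @export
fitted.dyncdi <- function(object, frame = NULL, what = c("object", "probe"),
                          ...) {
  what <- match.arg(what)
  if (what == "probe") return(object$probe)
  if (is.null(frame)) object$objects else object$objects[[frame]]
}

#' Data-space residual errors of a fit
#'
#' @param object A `"dyncdi"` fit.
#' @param type `"final"` for the last iteration's per-frame errors,
#'   `"trace"` for the full long-format trace.
#' @param ... Unused.
#' @return Numeric vector (`"final"`) or data frame with columns
#'   `iteration`, `frame`, `data_error` and (when ground truth was
#'   available) `object_error`.
#' @export
residuals.dyncdi <- function(object, type = c("final", "trace"), ...) {
  type <- match.arg(type)
  de <- object$errors$data
  if (type == "final") return(de[nrow(de), ])
  out <- data.frame(iteration = rep(seq_len(nrow(de)), ncol(de)),
                    frame = rep(seq_len(ncol(de)), each = nrow(de)),
                    data_error = as.vector(de))
  if (!is.null(object$errors$object))
    out$object_error <- as.vector(object$errors$object)
  out
}

#' Plot a reconstruction
#'
#' `which = "errors"` draws the per-frame data-error convergence curves on a
#' log scale; `"amplitude"` and `"phase"` draw images of one reconstructed
#' frame.
#'
#' @param x A `"dyncdi"` fit.
#' @param which One of `"errors"`, `"amplitude"`, `"phase"`.
#' @param frame Frame index for the image panels.
#' @param ... Passed to [graphics::image()] / [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.dyncdi <- function(x, which = c("errors", "amplitude", "phase"),
                        frame = 1, ...) {
  which <- match.arg(which)
  if (which == "errors") {
    graphics::matplot(x$errors$data, type = "l", log = "y", lty = 1,
                      xlab = "iteration", ylab = "normalised data error",
                      main = "dynCDI convergence", ...)
  } else {
    v <- x$objects[[frame]]
    m <- if (which == "amplitude") Mod(v) else Arg(v)
    graphics::image(t(m[nrow(m):1, ]), asp = 1, axes = FALSE,
                    col = grDevices::gray.colors(256),
                    main = sprintf("frame %d %s", frame, which), ...)
  }
  invisible(x)
}
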