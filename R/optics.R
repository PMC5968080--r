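#' Pinhole camera model for the macro imaging unit
#'
#' Describes the camera + macro lens as a central projection: a point
#' with lateral offset x (mm) at axial distance z (mm) from the
#' projection center maps to pixel offset \code{f_px * x / z} from the
#' principal point, with \code{f_px = magnification * focus_distance_mm
#' / pixel_pitch_mm}.  At the focal plane (z = focus distance) this
#' reproduces the nominal magnification.
#'
#' @param pixel_pitch_um Sensor pixel pitch in micrometers.
#' @param width_px,height_px Sensor size in pixels.
#' @param magnification Optical magnification at the focal plane.
#' @param focus_distance_mm Distance from the projection center to the
#'   in-focus object plane, in mm.
#' @param principal_point_px Principal point (x, y) in pixel
#'   coordinates; defaults to the image center.
#' @return An object of class \code{camera_model}.
#' @export
camera_model <- function(pixel_pitch_um = 5.5,
                         width_px = 2048L, height_px = 2048L,
                         magnification = 1.26,
                         focus_distance_mm = 100,
                         principal_point_px = NULL) {
  stopifnot(pixel_pitch_um > 0, magnification > 0, focus_distance_mm > 0,
            width_px >= 1, height_px >= 1)
  if (is.null(principal_point_px))
    principal_point_px <- c((width_px + 1) / 2, (height_px + 1) / 2)
  if (principal_point_px[1] < 1 || principal_point_px[1] > width_px ||
      principal_point_px[2] < 1 || principal_point_px[2] > height_px)
    stop("principal point must lie inside the image bounds")
  structure(list(pixel_pitch_um = pixel_pitch_um,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 magnification = magnification,
                 focus_distance_mm = focus_distance_mm,
                 principal_point_px = principal_point_px),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "camera_model: %dx%d px, %.2f um pitch, x%.3g, z_f = %g mm (%.2f um/px)\n",
    x$width_px, x$height_px, x$pixel_pitch_um, x$magnification,
    x$focus_distance_mm, object_pixel_size(x$pixel_pitch_um, x$magnification)))
  invisible(x)
}

# focal length in pixel units: px offset = focal_px(cam) * x_mm / z_mm
focal_px <- function(cam) {
  cam$magnification * cam$focus_distance_mm / (cam$pixel_pitch_um / 1000)
}

#' Object-side pixel size
#'
#' The digital resolution of the system: the sensor pixel pitch divided
#' by the optical magnification.  At a magnification of 1.26 with a
#' 5.5 um pitch this is 4.37 um per pixel.
#'
#' @param pitch_um Sensor pixel pitch in micrometers.
#' @param magnification Optical magnification (dimensionless).
#' @return Object-side pixel size in micrometers.
#' @export
object_pixel_size <- function(pitch_um, magnification) {
  if (!is.numeric(pitch_um) || !is.numeric(magnification) ||
      any(pitch_um <= 0) || any(magnification <= 0))
    stop("pitch_um and magnification must be positive")
  pitch_um / magnification
}

#' Focus-stack perspective calibration
#'
#' Per-slice isotropic scale factors that map every slice of a
#' moving-camera focus stack to the perspective of one reference slice,
#' following the projective law \code{s_i = 1 / (1 + beta * (i -
#' ref_index))} with \code{beta = step / focus_distance}.
#'
#' @param n_slices Number of slices in the stack.
#' @param step_um Rail step between consecutive slices, micrometers.
#' @param ref_index 1-based index of the reference slice; defaults to
#'   the middle slice.
#' @param beta Projective scale coefficient per slice (step / z_f).
#' @param residual_rms Optional RMS of the calibration fit residuals.
#' @return An object of class \code{stack_calibration} with fields
#'   \code{n_slices}, \code{step_um}, \code{ref_index}, \code{beta},
#'   \code{scales} (per-slice factors, \code{scales[ref_index] == 1})
#'   and \code{residual_rms}.
#' @export
stack_calibration <- function(n_slices, step_um, beta,
                              ref_index = middle_slice(n_slices),
                              residual_rms = NA_real_) {
  stopifnot(n_slices >= 1, ref_index >= 1, ref_index <= n_slices)
  cal <- structure(list(n_slices = as.integer(n_slices),
                        step_um = step_um,
                        ref_index = as.integer(ref_index),
                        beta = beta,
                        residual_rms = residual_rms),
                   class = "stack_calibration")
  cal$scales <- vapply(seq_len(n_slices), slice_scale, numeric(1), cal = cal)
  cal
}

middle_slice <- function(n_slices) as.integer(floor((n_slices - 1) / 2) + 1)

#' @export
print.stack_calibration <- function(x, ...) {
  cat(sprintf(
    "stack_calibration: %d slices, step %g um, ref %d, beta = %.5g (rms %.3g)\n",
    x$n_slices, x$step_um, x$ref_index, x$beta, x$residual_rms))
  invisible(x)
}

#' Perspective scale factor of one slice
#'
#' @param i 1-based slice index.
#' @param cal A \code{stack_calibration}.
#' @return The scale factor \code{1 / (1 + beta * (i - ref_index))}
#'   that maps content in focus at slice \code{i} to the reference
#'   perspective; exactly 1 at the reference slice, identically 1 when
#'   \code{beta = 0} (telecentric limit).
#' @export
slice_scale <- function(i, cal) {
  stopifnot(i >= 1, i <= cal$n_slices)
  den <- 1 + cal$beta * (i - cal$ref_index)
  if (den <= 0) stop("degenerate geometry: slice beyond the projection center")
  1 / den
}

#' Calibrate the per-slice perspective scale from a dot-grid target stack
#'
#' Measures the mean dot spacing in every slice of a stack showing a
#' flat dot-grid target, then fits the projective coefficient beta.
#' Because the camera advances one rail step per slice while the target
#' stays fixed, the measured spacing follows
#' \code{spacing_i = spacing_ref / (1 - beta * (i - ref))}; beta is
#' recovered by linear regression of \code{spacing_ref / spacing_i} on
#' \code{(i - ref)}, and the calibration stores the slice-to-reference
#' scale factors \code{s_i = 1 / (1 + beta * (i - ref))} implied by the
#' same camera geometry.
#'
#' @param target_stack A \code{focus_stack} of the dot-grid target (as
#'   rendered by \code{\link{render_target_stack}}, or acquired).
#' @param grid_pitch_mm Physical dot spacing of the target in mm
#'   (recorded; not needed for the relative fit).
#' @param ref_index Reference slice (default: middle).
#' @param min_dots Minimum number of dots that must be detected per
#'   slice (default 4).
#' @return A \code{stack_calibration} with fitted \code{beta},
#'   per-slice \code{scales} and fit \code{residual_rms}.
#' @export
calibrate_from_target <- function(target_stack, grid_pitch_mm = NA,
                                  ref_index = NULL, min_dots = 4) {
  stopifnot(inherits(target_stack, "focus_stack"))
  n <- length(target_stack$slices)
  if (is.null(ref_index)) ref_index <- middle_slice(n)
  as_gray <- function(im) if (length(dim(im)) == 3) rowMeans(im, dims = 2) else im
  dots <- lapply(target_stack$slices, function(im)
    dot_centroids(as_gray(im), min_dots = min_dots))
  d1 <- dim(as_gray(target_stack$slices[[1]]))
  pp <- if (!is.null(target_stack$camera))
    target_stack$camera$principal_point_px else (d1[2:1] + 1) / 2
  ref_dots <- dots[[ref_index]]
  spacing_ref <- mean_nn_spacing(ref_dots)
  # per-slice image scale q_i relative to the reference slice
  q <- vapply(seq_len(n), function(i) {
    if (i == ref_index) return(1)
    q0 <- mean_nn_spacing(dots[[i]]) / spacing_ref
    refine_scale(ref_dots, dots[[i]], pp, q0, tol_px = spacing_ref / 3)
  }, numeric(1))
  di <- seq_len(n) - ref_index
  # the target is fixed while the camera advances one step per slice:
  # q_i = z_f / (z_f - step * di), i.e. 1 / q_i is linear in di with
  # slope -beta
  if (n == 1 || all(di == 0)) {
    beta <- 0
    rms <- 0
  } else {
    fit <- stats::lm(I(1 / q - 1) ~ 0 + di)
    beta <- -unname(stats::coef(fit)[1])
    rms <- sqrt(mean(stats::resid(fit)^2))
  }
  if (abs(beta) < 1e-9) beta <- 0
  stack_calibration(n_slices = n,
                    step_um = target_stack$step_um %||% NA_real_,
                    beta = beta, ref_index = ref_index,
                    residual_rms = rms)
}

# least-squares isotropic scale about the principal point between two
# centroid sets, after nearest-neighbor matching at an initial guess
refine_scale <- function(ref_dots, slice_dots, pp, q0, tol_px) {
  rr <- cbind(ref_dots[, 1] - pp[2], ref_dots[, 2] - pp[1])   # (row, col)
  ss <- cbind(slice_dots[, 1] - pp[2], slice_dots[, 2] - pp[1])
  pred <- rr * q0
  d2 <- outer(pred[, 1], ss[, 1], "-")^2 + outer(pred[, 2], ss[, 2], "-")^2
  j <- max.col(-d2)
  ok <- d2[cbind(seq_len(nrow(pred)), j)] < tol_px^2
  if (sum(ok) < 3) return(q0)
  a <- rr[ok, , drop = FALSE]
  b <- ss[j[ok], , drop = FALSE]
  sum(a * b) / sum(a * a)
}

mean_nn_spacing <- function(ctr) {
  d2 <- outer(ctr[, 1], ctr[, 1], "-")^2 + outer(ctr[, 2], ctr[, 2], "-")^2
  diag(d2) <- Inf
  mean(sqrt(apply(d2, 1, min)))
}

# weighted centroids (row, col) of dark dots on bright ground; dots
# touching the image border are discarded (clipping biases centroids)
dot_centroids <- function(im, min_dots = 4) {
  thr <- EBImage::otsu(im, range = range(im))
  lab <- EBImage::bwlabel(im < thr)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  keep <- !(l %in% border)
  idx <- idx[keep, , drop = FALSE]
  w <- thr - im[lab > 0][keep]           # darker pixels weigh more
  l <- l[keep]
  if (length(unique(l)) < min_dots)
    stop("calibration failure: only ", length(unique(l)),
         " interior dots detected (need ", min_dots, ")")
  cbind(tapply(idx[, 1] * w, l, sum) / tapply(w, l, sum),
        tapply(idx[, 2] * w, l, sum) / tapply(w, l, sum))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a stack calibration as YAML
#'
#' @param cal A \code{stack_calibration}.
#' @param path YAML file path.
#' @return \code{write_calibration}: the path, invisibly;
#'   \code{read_calibration}: a \code{stack_calibration}.
#' @export
write_calibration <- function(cal, path) {
  yaml::write_yaml(list(n_slices = cal$n_slices, step_um = cal$step_um,
                        ref_index = cal$ref_index, beta = cal$beta,
                        residual_rms = cal$residual_rms), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  stack_calibration(n_slices = y$n_slices, step_um = y$step_um,
                    beta = y$beta, ref_index = y$ref_index,
                    residual_rms = y$residual_rms %||% NA_real_)
}
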