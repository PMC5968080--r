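#' Local focus measure of an image
#'
#' Smoothed-Laplacian energy: the image is Gaussian pre-smoothed
#' (sigma = 1 px), the absolute response of the 3x3 Laplacian is
#' computed, and the result is box-summed over a \code{window_px}
#' square.  The map is non-negative and identically zero on constant
#' images.
#'
#' @param image Grayscale matrix (values in \[0,1\]), or an RGB array
#'   (converted to luminance).
#' @param window_px Odd window size >= 3.
#' @return Matrix of the same size.
#' @export
focus_measure <- function(image, window_px = 9) {
  if (length(dim(image)) == 3) image <- luminance(image)
  if (window_px < 3 || window_px %% 2 != 1)
    stop("window_px must be odd and >= 3")
  if (window_px > min(dim(image)))
    stop("window larger than image")
  sm <- EBImage::gblur(image, sigma = 1, boundary = "replicate")
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- abs(EBImage::filter2(sm, lap, boundary = "replicate"))
  box <- matrix(1, window_px, window_px)
  out <- pmax(EBImage::filter2(resp, box, boundary = "replicate"), 0)
  out[out < 1e-10] <- 0               # FFT roundoff on flat regions
  out
}

luminance <- function(rgb)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]

#' Rescale a slice to the reference perspective
#'
#' Isotropic scaling about the principal point by the slice's
#' perspective factor \code{slice_scale(i, cal)}, with bilinear
#' interpolation.  The output has the same shape; areas sampled from
#' outside the input keep the nearest edge value.
#'
#' @param slice_image Matrix or H x W x C array.
#' @param i 1-based slice index.
#' @param cal A \code{stack_calibration}.
#' @param principal_point (x, y) = (column, row) of the scaling
#'   center, px.
#' @return The rescaled image.
#' @export
rescale_to_reference <- function(slice_image, i, cal, principal_point) {
  s <- slice_scale(i, cal)
  if (s == 1) return(slice_image)
  d <- dim(slice_image)
  H <- d[1]; W <- d[2]
  # output pixel q samples input at pp + (q - pp) / s
  uu <- principal_point[1] + (seq_len(W) - principal_point[1]) / s
  vv <- principal_point[2] + (seq_len(H) - principal_point[2]) / s
  bilinear_sample(slice_image, uu, vv)
}

# separable bilinear resampling on a rectilinear target grid;
# coordinates are clamped to the image (edge-value fill)
bilinear_sample <- function(img, uu, vv) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  uu <- pmin(pmax(uu, 1), W)
  vv <- pmin(pmax(vv, 1), H)
  u0 <- pmin(floor(uu), W - 1); fu <- uu - u0
  v0 <- pmin(floor(vv), H - 1); fv <- vv - v0
  sample_plane <- function(m) {
    a <- m[v0, u0, drop = FALSE]; b <- m[v0, u0 + 1, drop = FALSE]
    c2 <- m[v0 + 1, u0, drop = FALSE]; e <- m[v0 + 1, u0 + 1, drop = FALSE]
    FU <- matrix(fu, H, W, byrow = TRUE); FV <- matrix(fv, H, W)
    (1 - FV) * ((1 - FU) * a + FU * b) + FV * ((1 - FU) * c2 + FU * e)
  }
  if (length(d) == 2) return(sample_plane(img))
  out <- array(0, d)
  for (ch in seq_len(d[3])) out[, , ch] <- sample_plane(img[, , ch])
  out
}

#' Merge a focus stack into an extended-depth-of-field image
#'
#' The EDOF compositor: (1) every slice is rescaled to the reference
#' perspective using the stack calibration, so the composite complies
#' with a single pinhole camera model; (2) a per-pixel focus measure is
#' computed on each rescaled slice; (3) the per-pixel argmax over
#' slices gives the depth index, ties broken toward the camera-near
#' slice, refined to a fractional index by parabolic interpolation of
#' the focus measure; (4) the index map is median-filtered (5x5);
#' (5) the color is a linear blend of the two slices bracketing the
#' smoothed fractional index; (6) pixels whose focus confidence falls
#' below a threshold (Otsu on the confidence map, floored at 1e-4 of
#' its maximum) are flagged background and filled from the reference
#' slice.
#'
#' @param stack A \code{focus_stack}.
#' @param cal A \code{stack_calibration} with \code{n_slices} matching
#'   the stack (use \code{beta = 0} to disable perspective
#'   correction).
#' @param window_px Focus-measure window (odd, default 9).
#' @param median_radius Radius of the median filter applied to the
#'   index map (default 2, i.e. a 5x5 window).
#' @param principal_point Scaling center; defaults to the stack
#'   camera's principal point, else the image center.
#' @return An \code{edof_result}: list with \code{image} (H x W x 3 in
#'   \[0,1\]), \code{depth} (list: \code{values} fractional slice
#'   indices, \code{confidence}, \code{background} logical),
#'   \code{pose_index}, \code{calibration}.
#' @export
compose_edof <- function(stack, cal, window_px = 9, median_radius = 2,
                         principal_point = NULL) {
  stopifnot(inherits(stack, "focus_stack"), inherits(cal, "stack_calibration"))
  n <- length(stack$slices)
  if (n == 0) stop("empty stack")
  if (cal$n_slices != n) stop("calibration has ", cal$n_slices,
                              " slices but stack has ", n)
  d <- dim(stack$slices[[1]])
  if (!all(vapply(stack$slices, function(s) identical(dim(s), d), logical(1))))
    stop("stack slices differ in shape")
  H <- d[1]; W <- d[2]
  if (is.null(principal_point))
    principal_point <- if (!is.null(stack$camera))
      stack$camera$principal_point_px else c((W + 1) / 2, (H + 1) / 2)

  as_rgb <- function(s) if (length(dim(s)) == 3) s else array(s, c(H, W, 3))
  warped <- lapply(seq_len(n), function(i)
    rescale_to_reference(as_rgb(stack$slices[[i]]), i, cal, principal_point))
  fm <- array(0, c(H, W, n))
  for (i in seq_len(n)) fm[, , i] <- focus_measure(warped[[i]], window_px)

  # winner-take-all; which.max takes the first (camera-near) maximum
  flat <- matrix(fm, H * W, n)
  best <- max.col(flat, ties.method = "first")
  conf <- flat[cbind(seq_len(H * W), best)]
  # parabolic refinement of the peak position
  frac <- rep(0, H * W)
  inner <- best > 1 & best < n
  if (any(inner)) {
    ii <- which(inner)
    y0 <- flat[cbind(ii, best[ii] - 1)]
    y1 <- flat[cbind(ii, best[ii])]
    y2 <- flat[cbind(ii, best[ii] + 1)]
    den <- y0 - 2 * y1 + y2
    f <- ifelse(abs(den) > 1e-12, 0.5 * (y0 - y2) / den, 0)
    frac[ii] <- pmin(0.5, pmax(-0.5, f))
  }
  idx <- matrix(pmin(n, pmax(1, best + frac)), H, W)
  if (median_radius > 0 && min(H, W) > 2 * median_radius)
    idx <- as.matrix(EBImage::medianFilter(idx / n, median_radius)) * n
  idx <- matrix(pmin(pmax(idx, 1), n), H, W)

  conf <- matrix(conf, H, W)
  cmax <- max(conf)
  if (cmax > 0) {
    thr <- max(EBImage::otsu(conf / cmax, range = c(0, 1)) * cmax, 1e-4 * cmax)
    background <- conf < thr
  } else {
    background <- matrix(TRUE, H, W)
  }

  lo <- pmin(floor(idx), max(1, n - 1))  # floor, capped so hi exists
  hi <- pmin(lo + 1, n)
  w <- idx - lo
  arr <- array(unlist(warped, use.names = FALSE), c(H, W, 3, n))
  pix <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H))
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    a <- arr[cbind(pix, ch, as.vector(lo))]
    b <- arr[cbind(pix, ch, as.vector(hi))]
    img[, , ch] <- matrix((1 - as.vector(w)) * a + as.vector(w) * b, H, W)
  }
  if (any(background)) {
    refimg <- warped[[cal$ref_index]]
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[background] <- refimg[, , ch][background]
      img[, , ch] <- pl
    }
  }
  img <- array(pmin(pmax(img, 0), 1), c(H, W, 3))
  structure(list(image = img,
                 depth = list(values = idx, confidence = conf,
                              background = background),
                 pose_index = if (!is.null(stack$pose)) stack$pose$index else NA_integer_,
                 calibration = cal),
            class = "edof_result")
}

#' @export
print.edof_result <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("edof_result: %dx%d, %.0f%% background, depth range [%.2f, %.2f]\n",
              d[1], d[2], 100 * mean(x$depth$background),
              min(x$depth$values), max(x$depth$values)))
  invisible(x)
}

#' Write an EDOF result to disk
#'
#' The composite goes to PNG (lossless RGB); the depth-index map
#' optionally to 32-bit float TIFF (scaled to \[0,1\] by the slice
#' count).
#'
#' @param edof An \code{edof_result}.
#' @param path PNG output path.
#' @param depth_path Optional TIFF path for the depth-index map.
#' @return \code{path}, invisibly.
#' @export
write_edof <- function(edof, path, depth_path = NULL) {
  png::writePNG(edof$image, path)
  if (!is.null(depth_path))
    write_depth_tiff(edof$depth$values, edof$calibration$n_slices, depth_path)
  invisible(path)
}
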