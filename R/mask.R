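#' Segment the specimen silhouette from a back-light image
#'
#' In a back-light image the diffuse dome renders the background bright
#' and the specimen (plus support pin) as a dark silhouette.  The
#' segmentation chain is: global threshold (Otsu by default), object =
#' below-threshold pixels, morphological closing (disc, radius 2 px),
#' hole filling, and removal of connected components smaller than
#' \code{min_area_px}.
#'
#' @param back_edof Grayscale matrix in \[0,1\] (an RGB array is
#'   converted to luminance), bright background / dark object.
#' @param threshold Fixed threshold in \[0,1\]; \code{NULL} (default)
#'   uses Otsu's method.
#' @param close_radius_px Radius of the closing brush (default 2).
#' @param min_area_px Minimum component area kept (default 50).
#' @return A \code{silhouette_mask}: list with \code{mask} (logical
#'   matrix, TRUE = specimen), \code{area_px}, \code{n_components},
#'   and \code{warning} (character, e.g. for a uniform input).
#' @export
segment_backlight <- function(back_edof, threshold = NULL,
                              close_radius_px = 2, min_area_px = 50) {
  im <- if (length(dim(back_edof)) == 3) luminance(back_edof) else back_edof
  warn <- character(0)
  if (diff(range(im)) < 1e-6) {
    warn <- "uniform back-light image: empty mask"
    warning(warn)
    return(new_silhouette_mask(matrix(FALSE, nrow(im), ncol(im)), warn))
  }
  if (is.null(threshold)) threshold <- EBImage::otsu(im, range = range(im))
  obj <- im < threshold
  if (close_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * close_radius_px + 1, shape = "disc")
    obj <- EBImage::closing(obj, brush) > 0.5
  }
  obj <- EBImage::fillHull(obj) > 0.5
  lab <- EBImage::bwlabel(obj)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_area_px)
    obj <- matrix(lab %in% keep, nrow(im), ncol(im))
  }
  new_silhouette_mask(obj, warn)
}

new_silhouette_mask <- function(mask, warn = character(0)) {
  lab <- EBImage::bwlabel(mask)
  structure(list(mask = mask, area_px = sum(mask),
                 n_components = max(lab), warning = warn),
            class = "silhouette_mask")
}

#' @export
print.silhouette_mask <- function(x, ...) {
  cat(sprintf("silhouette_mask: %dx%d, area %d px, %d component(s)\n",
              nrow(x$mask), ncol(x$mask), x$area_px, x$n_components))
  invisible(x)
}

#' Attach a silhouette mask as the alpha channel
#'
#' Returns the front-light image with alpha = 1 on the specimen and 0
#' on the background; RGB values are unchanged, so the result
#' round-trips losslessly through PNG.
#'
#' @param front_edof H x W x 3 RGB array in \[0,1\].
#' @param mask A \code{silhouette_mask} (or logical matrix) of the
#'   same spatial size.
#' @return H x W x 4 RGBA array.
#' @export
apply_alpha <- function(front_edof, mask) {
  m <- if (inherits(mask, "silhouette_mask")) mask$mask else mask
  d <- dim(front_edof)
  if (length(d) != 3 || d[3] < 3) stop("front_edof must be an RGB array")
  if (!all(dim(m) == d[1:2])) stop("mask shape does not match image")
  out <- array(0, c(d[1], d[2], 4))
  out[, , 1:3] <- front_edof[, , 1:3]
  out[, , 4] <- as.numeric(m)
  out
}

#' Intersection-over-union of two masks
#'
#' @param a,b Logical matrices or \code{silhouette_mask} objects.
#' @return IoU in \[0,1\] (1 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  ma <- if (inherits(a, "silhouette_mask")) a$mask else a
  mb <- if (inherits(b, "silhouette_mask")) b$mask else b
  u <- sum(ma | mb)
  if (u == 0) return(1)
  sum(ma & mb) / u
}
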