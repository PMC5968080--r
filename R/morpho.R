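#' Surface area of a triangle mesh
#'
#' Sum of the triangle areas (cross-product formula); degenerate
#' zero-area faces contribute nothing.
#'
#' @param mesh A \code{tri_mesh} with vertices in mm.
#' @return Surface area in cm^2.
#' @export
mesh_surface_area <- function(mesh) {
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; v <- c2 - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area_mm2 <- sum(sqrt(rowSums(cr^2))) / 2
  area_mm2 / 100                     # mm^2 -> cm^2
}

#' Enclosed volume of a watertight triangle mesh
#'
#' Divergence-theorem volume: the absolute value of the sum of signed
#' origin-tetrahedron volumes over all faces, so the result is
#' independent of the global orientation.  The mesh must be watertight
#' (every edge shared by exactly two faces).
#'
#' @param mesh A \code{tri_mesh} with vertices in mm.
#' @return Volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  nbad <- count_boundary_edges(mesh)
  if (nbad > 0)
    stop("mesh is not watertight: ", nbad, " defective edge(s)")
  abs(signed_volume_mm3(mesh)) / 1000  # mm^3 -> cm^3
}

signed_volume_mm3 <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c2[, 3] - b[, 3] * c2[, 2]) -
      a[, 2] * (b[, 1] * c2[, 3] - b[, 3] * c2[, 1]) +
      a[, 3] * (b[, 1] * c2[, 2] - b[, 2] * c2[, 1])) / 6
}

#' Replicate-measurement set
#'
#' One labelled morphometric quantity measured independently by
#' several observers.
#'
#' @param label Name of the measurement.
#' @param values_mm Numeric vector of replicate values (>= 2, all
#'   positive).
#' @return An object of class \code{measurement_set}.
#' @export
measurement_set <- function(label, values_mm) {
  if (length(values_mm) < 2) stop("need at least 2 replicate values")
  if (any(values_mm <= 0)) stop("all measurements must be positive")
  structure(list(label = label, values_mm = as.numeric(values_mm)),
            class = "measurement_set")
}

#' Measurement reliability statistics
#'
#' Computes the repeatability summary used to compare observer
#' measurements: mean, sample SD (n - 1 denominator), coefficient of
#' variation CV = 100 * SD / mean, the maximum relative deviation from
#' the mean 100 * max|x - mean| / mean, and the range.  Values are
#' kept at full precision; rounding (1 d.p. for percentages, 2 d.p.
#' for mm) happens only in the printed report.
#'
#' @param set A \code{measurement_set}.
#' @return A \code{reliability_report}: list with \code{label},
#'   \code{n}, \code{mean_mm}, \code{sd_mm}, \code{cv_percent},
#'   \code{max_rel_dev_percent}, \code{range_mm}.
#' @export
reliability <- function(set) {
  stopifnot(inherits(set, "measurement_set"))
  x <- set$values_mm
  m <- mean(x)
  s <- stats::sd(x)
  structure(list(label = set$label, n = length(x), mean_mm = m, sd_mm = s,
                 cv_percent = cv_from_summary(m, s),
                 max_rel_dev_percent = max_rel_dev_from_summary(m, min(x), max(x)),
                 range_mm = range(x)),
            class = "reliability_report")
}

#' Reliability statistics from printed summaries
#'
#' When only the summary of a measurement series is available (mean,
#' SD, range), the CV and the maximum relative deviation from the mean
#' can still be recomputed.
#'
#' @param mean_mm,sd_mm,min_mm,max_mm Summary statistics.
#' @return \code{cv_from_summary}: CV in percent;
#'   \code{max_rel_dev_from_summary}: maximum relative deviation from
#'   the mean, percent.
#' @export
cv_from_summary <- function(mean_mm, sd_mm) 100 * sd_mm / mean_mm

#' @rdname cv_from_summary
#' @export
max_rel_dev_from_summary <- function(mean_mm, min_mm, max_mm)
  100 * max(abs(c(min_mm, max_mm) - mean_mm)) / mean_mm

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("%s (n = %d): mean %.2f mm, SD %.2f mm, range %.2f-%.2f mm\n",
              x$label, x$n, x$mean_mm, x$sd_mm, x$range_mm[1], x$range_mm[2]))
  cat(sprintf("  CV = %.1f%%, max deviation from mean = %.1f%%\n",
              x$cv_percent, x$max_rel_dev_percent))
  invisible(x)
}

#' Variance-ratio (F) test between two measurement sets
#'
#' F is the ratio of the larger to the smaller sample variance; the
#' two-sided p-value comes from the F distribution with (n1 - 1,
#' n2 - 1) degrees of freedom (numerator = the larger-variance set).
#'
#' @param a,b \code{measurement_set} objects (or numeric vectors).
#' @return List with \code{F}, \code{df}, \code{p_value}.
#' @export
variance_ratio_test <- function(a, b) {
  xa <- if (inherits(a, "measurement_set")) a$values_mm else a
  xb <- if (inherits(b, "measurement_set")) b$values_mm else b
  stopifnot(length(xa) >= 2, length(xb) >= 2)
  va <- stats::var(xa); vb <- stats::var(xb)
  if (min(va, vb) == 0) stop("zero variance: F statistic undefined")
  if (va >= vb) {
    f <- va / vb; df <- c(length(xa) - 1, length(xb) - 1)
  } else {
    f <- vb / va; df <- c(length(xb) - 1, length(xa) - 1)
  }
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  list(F = f, df = df, p_value = p)
}

#' Read a replicate-measurement table
#'
#' CSV with columns \code{label}, \code{observer}, \code{value_mm};
#' one \code{measurement_set} is built per label.
#'
#' @param path CSV path.
#' @return Named list of \code{measurement_set} objects.
#' @export
read_measurement_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("label", "value_mm") %in% names(d)))
  sets <- lapply(split(d$value_mm, d$label), function(v)
    measurement_set(label = "", values_mm = v))
  for (nm in names(sets)) sets[[nm]]$label <- nm
  sets
}

#' Surface-area and volume report for a mesh
#'
#' @param mesh A \code{tri_mesh} (mm coordinates).
#' @return Data frame with surface_area_cm2, volume_cm3 and their
#'   ratio (1/cm).
#' @export
measure_mesh <- function(mesh) {
  sa <- mesh_surface_area(mesh)
  vol <- mesh_volume(mesh)
  data.frame(surface_area_cm2 = sa, volume_cm3 = vol,
             sa_to_v_per_cm = sa / vol)
}
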