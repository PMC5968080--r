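#' Unit view direction for gimbal angles
#'
#' Maps gimbal tilt/rotation angles to the unit view direction
#' \code{(cos(tilt) cos(rot), cos(tilt) sin(rot), sin(tilt))} in the
#' laboratory frame (right-handed, pin axis = +Z).
#'
#' @param tilt_deg Tilt angle(s) in degrees, in \[-90, 90\].
#' @param rot_deg Rotation angle(s) in degrees, in \[0, 360).
#' @return An n x 3 matrix of unit vectors (one row per pose).
#' @export
pose_view_dir <- function(tilt_deg, rot_deg) {
  t <- tilt_deg * pi / 180
  r <- rot_deg * pi / 180
  cbind(cos(t) * cos(r), cos(t) * sin(r), sin(t))
}

#' Construct a single pose
#'
#' @param tilt_deg Tilt in degrees, \[-90, 90\].
#' @param rot_deg Rotation in degrees, \[0, 360).
#' @param index Non-negative integer pose index.
#' @param accessible Logical; whether the gimbal can reach the pose.
#' @return An object of class \code{pose}: a list with fields
#'   \code{index}, \code{tilt_deg}, \code{rot_deg}, \code{view_dir},
#'   \code{accessible}.
#' @export
pose <- function(tilt_deg, rot_deg, index = 0L, accessible = TRUE) {
  stopifnot(length(tilt_deg) == 1, length(rot_deg) == 1,
            tilt_deg >= -90, tilt_deg <= 90)
  rot_deg <- rot_deg %% 360
  structure(list(index = as.integer(index),
                 tilt_deg = tilt_deg, rot_deg = rot_deg,
                 view_dir = drop(pose_view_dir(tilt_deg, rot_deg)),
                 accessible = isTRUE(accessible)),
            class = "pose")
}

#' Generate the spherical pose program
#'
#' Builds the preassigned pose program executed by the two-axis gimbal:
#' tilt rings at every multiple of \code{spacing_deg} from -90 to +90,
#' where the ring at tilt theta holds \code{round((360/spacing_deg) *
#' cos(theta))} equally spaced rotation angles starting at 0, and each
#' pole holds exactly one pose.  For the standard spacing of 10 degrees
#' this yields 412 poses with a mean angular distance between
#' neighboring poses close to the nominal spacing.
#'
#' @param spacing_deg Nominal angular spacing delta in degrees; must
#'   satisfy \code{1 <= spacing_deg <= 90} and divide 180.
#' @return An object of class \code{pose_program}: a list with
#'   \code{spacing_deg}, \code{exclusion_cone_deg} (NA until
#'   \code{\link{apply_exclusion}} is used) and \code{poses}, a data
#'   frame with columns \code{index} (0-based), \code{tilt_deg},
#'   \code{rot_deg}, \code{vx}, \code{vy}, \code{vz},
#'   \code{accessible}.  Poses are ordered by ring from tilt -90
#'   upward, then by ascending rotation angle.
#' @examples
#' prog <- generate_pose_program(10)
#' nrow(prog$poses)  # 412
#' @export
generate_pose_program <- function(spacing_deg) {
  if (!is.numeric(spacing_deg) || length(spacing_deg) != 1 ||
      spacing_deg < 1 || spacing_deg > 90 ||
      abs(180 / spacing_deg - round(180 / spacing_deg)) > 1e-9)
    stop("spacing_deg must lie in [1, 90] and divide 180")
  tilts <- seq(-90, 90, by = spacing_deg)
  rows <- lapply(tilts, function(th) {
    if (abs(abs(th) - 90) < 1e-9) {
      data.frame(tilt_deg = th, rot_deg = 0)
    } else {
      n <- round((360 / spacing_deg) * cos(th * pi / 180))
      data.frame(tilt_deg = th, rot_deg = seq(0, 360, length.out = n + 1)[seq_len(n)])
    }
  })
  poses <- do.call(rbind, rows)
  v <- pose_view_dir(poses$tilt_deg, poses$rot_deg)
  poses <- data.frame(index = seq_len(nrow(poses)) - 1L,
                      tilt_deg = poses$tilt_deg, rot_deg = poses$rot_deg,
                      vx = v[, 1], vy = v[, 2], vz = v[, 3],
                      accessible = TRUE)
  structure(list(spacing_deg = spacing_deg,
                 exclusion_cone_deg = NA_real_,
                 poses = poses),
            class = "pose_program")
}

#' @export
print.pose_program <- function(x, ...) {
  cat(sprintf("pose_program: %d poses, spacing %g deg, %d accessible\n",
              nrow(x$poses), x$spacing_deg, sum(x$poses$accessible)))
  if (!is.na(x$exclusion_cone_deg))
    cat(sprintf("  exclusion cone: %g deg about the pin axis\n",
                x$exclusion_cone_deg))
  invisible(x)
}

view_dirs <- function(program) {
  as.matrix(program$poses[, c("vx", "vy", "vz")])
}

#' Angular distance between two poses
#'
#' Great-circle angle between the view directions of two poses,
#' \code{acos(a . b)}, clamped to \[0, 180\] degrees.
#'
#' @param a,b \code{pose} objects (or unit 3-vectors).
#' @return Angle in degrees.
#' @export
angular_distance <- function(a, b) {
  va <- if (inherits(a, "pose")) a$view_dir else a
  vb <- if (inherits(b, "pose")) b$view_dir else b
  stopifnot(length(va) == 3, length(vb) == 3)
  cr <- c(va[2] * vb[3] - va[3] * vb[2],
          va[3] * vb[1] - va[1] * vb[3],
          va[1] * vb[2] - va[2] * vb[1])
  # atan2 form: exact at 0 and 180 degrees, well-conditioned everywhere
  atan2(sqrt(sum(cr^2)), sum(va * vb)) * 180 / pi
}

#' Mean nearest-neighbor angular distance of a pose program
#'
#' For every pose, the angular distance to its nearest other pose is
#' computed from the view directions; the mean of these distances is
#' the program's realized angular spacing (nominally equal to
#' \code{spacing_deg}).
#'
#' @param program A \code{pose_program}.
#' @return Mean nearest-neighbor distance in degrees.
#' @export
mean_nn_distance <- function(program) {
  v <- view_dirs(program)
  if (nrow(v) < 2) stop("need at least 2 poses")
  g <- v %*% t(v)          # cosine of pairwise angles
  diag(g) <- -Inf          # exclude self
  g[g > 1] <- 1; g[g < -1 & is.finite(g)] <- -1
  nn <- apply(g, 1, max)
  mean(acos(nn) * 180 / pi)
}

#' Mark poses inside a double cone about an axis as inaccessible
#'
#' The specimen holder obstructs views nearly parallel to the support
#' pin: poses whose view direction lies within \code{cone_deg} of
#' either \code{+axis} or \code{-axis} are flagged inaccessible.  With
#' the standard 10-degree program and a 15-degree half-angle about the
#' pin axis this removes 14 poses, leaving 398 accessible.
#'
#' @param program A \code{pose_program}.
#' @param cone_deg Cone half-angle in degrees, in \[0, 90\].
#' @param axis Unit 3-vector; defaults to the pin axis (0, 0, 1).
#' @return The program with \code{accessible} flags updated and
#'   \code{exclusion_cone_deg} recorded.
#' @export
apply_exclusion <- function(program, cone_deg, axis = c(0, 0, 1)) {
  stopifnot(inherits(program, "pose_program"),
            cone_deg >= 0, cone_deg <= 90)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) stop("axis must be a unit vector")
  v <- view_dirs(program)
  ca <- abs(drop(v %*% axis))
  ca[ca > 1] <- 1
  excluded <- acos(ca) * 180 / pi <= cone_deg + 1e-9
  program$poses$accessible <- program$poses$accessible & !excluded
  program$exclusion_cone_deg <- cone_deg
  program
}

#' Extract one pose from a program
#'
#' @param program A \code{pose_program}.
#' @param index 0-based pose index (matching the \code{index} column).
#' @return A \code{pose} object.
#' @export
get_pose <- function(program, index) {
  row <- program$poses[program$poses$index == index, ]
  if (nrow(row) != 1) stop("no pose with index ", index)
  pose(row$tilt_deg, row$rot_deg, index = row$index,
       accessible = row$accessible)
}

#' Write a pose program manifest CSV
#'
#' Columns: index, tilt_deg, rot_deg, accessible; header row, UTF-8,
#' '.' decimal separator.
#'
#' @param program A \code{pose_program}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_pose_csv <- function(program, path) {
  utils::write.csv(program$poses[, c("index", "tilt_deg", "rot_deg", "accessible")],
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
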