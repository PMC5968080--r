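#' Voxel grid for visual-hull carving
#'
#' A cubic lattice of edge length \code{2 * half_extent_mm} centered on
#' the rotation center.
#'
#' @param n Voxels per axis.
#' @param half_extent_mm Half the grid edge length, mm.
#' @param center 3-vector, mm.
#' @return A \code{voxel_grid}: list with \code{origin_mm} (corner of
#'   the grid), \code{voxel_mm}, \code{shape}, \code{occupancy}
#'   (logical nx x ny x nz array).
#' @export
voxel_grid <- function(n = 100, half_extent_mm = 5, center = c(0, 0, 0)) {
  stopifnot(n >= 1, half_extent_mm > 0)
  voxel_mm <- 2 * half_extent_mm / n
  structure(list(origin_mm = center - half_extent_mm,
                 voxel_mm = voxel_mm,
                 shape = c(n, n, n),
                 occupancy = array(TRUE, c(n, n, n))),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %dx%dx%d, voxel %.3g mm, %d occupied (%.1f%%)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_mm,
              sum(x$occupancy), 100 * mean(x$occupancy)))
  invisible(x)
}

voxel_centers <- function(grid) {
  s <- grid$shape
  ax <- lapply(1:3, function(a)
    grid$origin_mm[a] + (seq_len(s[a]) - 0.5) * grid$voxel_mm)
  cbind(rep(ax[[1]], times = s[2] * s[3]),
        rep(rep(ax[[2]], each = s[1]), times = s[3]),
        rep(ax[[3]], each = s[1] * s[2]))
}

#' Volume of the occupied voxels
#'
#' @param grid A \code{voxel_grid}.
#' @return Volume in mm^3.
#' @export
grid_volume <- function(grid) sum(grid$occupancy) * grid$voxel_mm^3

#' Carve the visual hull from silhouette masks
#'
#' Shape-from-silhouette: the object is approximated by the visual
#' hull, the common intersection of the visual cones of all silhouette
#' views.  A voxel survives iff for every view its center projects
#' inside the image frame and inside the silhouette; a voxel that
#' projects outside any frame is carved away.  The camera geometry is
#' identical to the synthetic scanner's reference view
#' (\code{\link{camera_extrinsics}} at the focus distance), so masks
#' from EDOF images carve consistently.
#'
#' @param masks List of \code{silhouette_mask} objects (or logical
#'   matrices), one per pose.
#' @param poses List of \code{pose} objects (same length), or a
#'   \code{pose_program} whose accessible poses align with
#'   \code{masks}.
#' @param cam A \code{camera_model}.
#' @param grid A \code{voxel_grid} (carved in place and returned).
#' @param camera_distance_mm Distance from rotation center to the
#'   projection center; defaults to \code{cam$focus_distance_mm}.
#' @param rotation_center 3-vector, mm.
#' @return The carved \code{voxel_grid}.
#' @export
carve <- function(masks, poses, cam, grid = voxel_grid(),
                  camera_distance_mm = cam$focus_distance_mm,
                  rotation_center = c(0, 0, 0)) {
  if (inherits(poses, "pose_program")) {
    acc <- poses$poses[poses$poses$accessible, ]
    poses <- lapply(seq_len(nrow(acc)), function(k)
      pose(acc$tilt_deg[k], acc$rot_deg[k], index = acc$index[k]))
  }
  if (length(poses) == 0) stop("no poses to carve from")
  if (length(masks) != length(poses))
    stop("need one mask per pose (", length(masks), " vs ", length(poses), ")")
  centers <- voxel_centers(grid)
  occ <- as.vector(grid$occupancy)
  H <- cam$height_px; W <- cam$width_px
  for (k in seq_along(poses)) {
    if (!any(occ)) break
    m <- masks[[k]]
    if (inherits(m, "silhouette_mask")) m <- m$mask
    live <- which(occ)
    pr <- project_points(centers[live, , drop = FALSE],
                         camera_extrinsics(poses[[k]], camera_distance_mm,
                                           rotation_center),
                         cam)
    u <- round(pr$u); v <- round(pr$v)
    inside <- pr$z > 0 & u >= 1 & u <= W & v >= 1 & v <= H
    keep <- inside
    keep[inside] <- m[cbind(v[inside], u[inside])]
    occ[live[!keep]] <- FALSE
  }
  grid$occupancy <- array(occ, grid$shape)
  grid
}

# Fill the empty corner of diagonal 2x2 occupancy patterns in every
# axis plane so that the extracted boundary surface is edge-manifold
# (no edge shared by four faces).  Only adds voxels, so visual-hull
# containment is preserved.
fix_diagonal_contacts <- function(occ) {
  repeat {
    changed <- FALSE
    for (ax in 1:3) {
      perm <- switch(ax, c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
      a <- aperm(occ, perm)
      d <- dim(a)
      i1 <- seq_len(d[1] - 1); i2 <- seq_len(d[2] - 1)
      p00 <- a[i1, i2, , drop = FALSE];     p11 <- a[i1 + 1, i2 + 1, , drop = FALSE]
      p10 <- a[i1 + 1, i2, , drop = FALSE]; p01 <- a[i1, i2 + 1, , drop = FALSE]
      diag1 <- p00 & p11 & !p10 & !p01
      diag2 <- p10 & p01 & !p00 & !p11
      if (any(diag1) || any(diag2)) {
        changed <- TRUE
        p10[diag1] <- TRUE
        p00[diag2] <- TRUE
        a[i1 + 1, i2, ] <- a[i1 + 1, i2, , drop = FALSE] | p10
        a[i1, i2, ] <- a[i1, i2, , drop = FALSE] | p00
        occ <- aperm(a, order(perm))
      }
    }
    if (!changed) return(occ)
  }
}

#' Extract the boundary surface of an occupancy grid
#'
#' Builds the closed, outward-oriented triangle mesh bounding the
#' occupied voxels (two triangles per exposed voxel face, vertices on
#' the voxel corner lattice, welded).  Diagonal voxel contacts are
#' filled beforehand so every mesh edge is shared by exactly two
#' faces; the enclosed volume equals the occupied-voxel volume.
#'
#' @param grid A \code{voxel_grid} with at least one occupied voxel.
#' @return A \code{tri_mesh} in mm coordinates.
#' @export
extract_surface <- function(grid) {
  if (!any(grid$occupancy)) stop("empty grid: nothing to extract")
  occ <- fix_diagonal_contacts(grid$occupancy)
  s <- dim(occ)
  pad <- array(FALSE, s + 2)
  pad[2:(s[1] + 1), 2:(s[2] + 1), 2:(s[3] + 1)] <- occ
  core <- pad[2:(s[1] + 1), 2:(s[2] + 1), 2:(s[3] + 1), drop = FALSE]
  quads <- list()
  # corner offsets (rows) for the outward-oriented quad of each face
  face_corners <- list(
    xpos = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1)),
    xneg = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0)),
    ypos = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0)),
    yneg = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
    zpos = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    zneg = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  shift_of <- list(xpos = c(1, 0, 0), xneg = c(-1, 0, 0),
                   ypos = c(0, 1, 0), yneg = c(0, -1, 0),
                   zpos = c(0, 0, 1), zneg = c(0, 0, -1))
  nb <- function(dv) pad[2:(s[1] + 1) + dv[1], 2:(s[2] + 1) + dv[2],
                         2:(s[3] + 1) + dv[3], drop = FALSE]
  key_stride <- c(1, s[1] + 1, (s[1] + 1) * (s[2] + 1))
  all_keys <- list(); all_tris <- list()
  for (f in names(face_corners)) {
    exposed <- which(core & !nb(shift_of[[f]]))
    if (length(exposed) == 0) next
    ijk <- arrayInd(exposed, s) - 1L        # 0-based voxel corner base
    fc <- face_corners[[f]]
    corner_key <- matrix(0, nrow(ijk), 4)
    for (q in 1:4) {
      cc <- ijk + matrix(fc[q, ], nrow(ijk), 3, byrow = TRUE)
      corner_key[, q] <- as.numeric(cc %*% key_stride)
    }
    # two triangles per quad: (1,2,3) and (1,3,4)
    all_keys[[f]] <- corner_key
    all_tris[[f]] <- rbind(corner_key[, c(1, 2, 3), drop = FALSE],
                           corner_key[, c(1, 3, 4), drop = FALSE])
  }
  tris <- do.call(rbind, all_tris)
  ukeys <- sort(unique(as.vector(tris)))
  faces <- matrix(match(tris, ukeys), ncol = 3)
  k <- ukeys
  i <- k %% key_stride[2]
  j <- (k %/% key_stride[2]) %% (s[2] + 1)
  l <- k %/% key_stride[3]
  verts <- cbind(grid$origin_mm[1] + i * grid$voxel_mm,
                 grid$origin_mm[2] + j * grid$voxel_mm,
                 grid$origin_mm[3] + l * grid$voxel_mm)
  tri_mesh(verts, faces)
}
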