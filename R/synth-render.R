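#' Camera extrinsics for a pose
#'
#' Places the camera at \code{distance_mm} from the rotation center
#' along the pose's view direction, looking at the rotation center.
#' The in-image "up" is world +Z projected perpendicular to the view
#' (+X at the poles); the camera frame is right-handed with rows
#' (right, down, look).
#'
#' @param pose A \code{pose}.
#' @param distance_mm Distance from rotation center to the projection
#'   center, mm.
#' @param rotation_center 3-vector, mm.
#' @return List with \code{C} (camera center, world mm) and \code{R}
#'   (3x3; camera coords = \code{R \%*\% (p - C)}, third row = viewing
#'   direction).
#' @export
camera_extrinsics <- function(pose, distance_mm, rotation_center = c(0, 0, 0)) {
  v <- pose$view_dir
  C <- rotation_center + distance_mm * v
  look <- -v
  up <- if (abs(v[3]) > 1 - 1e-9) c(1, 0, 0) else c(0, 0, 1)
  up <- up - sum(up * look) * look
  up <- up / sqrt(sum(up^2))
  right <- c(look[2] * up[3] - look[3] * up[2],
             look[3] * up[1] - look[1] * up[3],
             look[1] * up[2] - look[2] * up[1])
  right <- right / sqrt(sum(right^2))
  down <- -up
  list(C = C, R = rbind(right, down, look))
}

#' Project world points through a pose camera
#'
#' @param pts N x 3 matrix of world points (mm).
#' @param ext Extrinsics from \code{\link{camera_extrinsics}}.
#' @param cam A \code{camera_model}.
#' @return List with \code{u} (column), \code{v} (row) pixel
#'   coordinates and \code{z} axial depth (mm).
#' @export
project_points <- function(pts, ext, cam) {
  pc <- (pts - matrix(ext$C, nrow(pts), 3, byrow = TRUE)) %*% t(ext$R)
  f <- focal_px(cam)
  list(u = cam$principal_point_px[1] + f * pc[, 1] / pc[, 3],
       v = cam$principal_point_px[2] + f * pc[, 2] / pc[, 3],
       z = pc[, 3])
}

# All-in-focus pinhole render of a scene from one camera position.
# Returns color (H x W x 3), depth (H x W axial mm, Inf = background),
# and the hit mask.  texture_seed_base keeps per-solid textures fixed
# across slices and poses.
render_view <- function(scn, ext, cam, lighting = c("front", "back"),
                        texture_seed_base = 1L) {
  lighting <- match.arg(lighting)
  H <- cam$height_px; W <- cam$width_px
  f <- focal_px(cam)
  px <- as.matrix(expand.grid(v = seq_len(H), u = seq_len(W)))
  dc <- cbind((px[, "u"] - cam$principal_point_px[1]) / f,
              (px[, "v"] - cam$principal_point_px[2]) / f,
              1)
  dw <- dc %*% ext$R                       # rows of R are orthonormal
  dw <- dw / sqrt(rowSums(dw^2))
  n <- nrow(dw)
  tbest <- rep(Inf, n)
  hit_id <- rep(0L, n)
  for (j in seq_along(scn$solids)) {
    tj <- ray_solid_t(scn$solids[[j]], ext$C, dw)
    closer <- tj < tbest
    tbest[closer] <- tj[closer]
    hit_id[closer] <- j
  }
  hit <- is.finite(tbest)
  # axial depth = t * (ray . look)
  zax <- tbest * as.numeric(dw %*% ext$R[3, ])
  col <- matrix(if (lighting == "front") 0.05 else 1, n, 3)
  if (lighting == "front") {
    for (j in seq_along(scn$solids)) {
      sel <- hit_id == j & hit
      if (!any(sel)) next
      s <- scn$solids[[j]]
      P <- matrix(ext$C, sum(sel), 3, byrow = TRUE) + tbest[sel] * dw[sel, , drop = FALSE]
      tex <- texture_field(P, s$texture, seed = texture_seed_base + 7L * j)
      for (ch in 1:3)
        col[sel, ch] <- pmin(1, pmax(0, s$albedo[ch] * (1 + tex)))
    }
  } else {
    col[hit, ] <- 0
  }
  list(color = array(col, c(H, W, 3)),
       depth = matrix(ifelse(hit, zax, Inf), H, W),
       silhouette = matrix(hit, H, W))
}

# Depth-dependent defocus: the sharp render is split into depth bins of
# one rail step; each bin is Gaussian-blurred with sigma = half the
# circle-of-confusion diameter at the bin's depth and composited
# nearest-first over the background (premultiplied alpha).
defocus_composite <- function(rv, z_focal_mm, step_mm, cam,
                              aperture_mm, coc_max_px, background) {
  f <- focal_px(cam)
  z <- rv$depth
  sig_of <- function(zb) {
    coc <- f * aperture_mm * abs(1 / zb - 1 / z_focal_mm)
    min(coc, coc_max_px) / 2
  }
  H <- dim(z)[1]; W <- dim(z)[2]
  out <- array(background, c(H, W, 3))
  if (any(is.finite(z))) {
    zf <- z[is.finite(z)]
    # bins centered on multiples of the rail step, so content exactly in
    # focus falls in a bin with zero blur
    bins <- sort(unique(round((zf - z_focal_mm) / step_mm)), decreasing = TRUE)
    for (b in bins) {                      # far to near
      lo <- z_focal_mm + (b - 0.5) * step_mm
      m <- is.finite(z) & z >= lo & z < lo + step_mm
      if (!any(m)) next
      sig <- sig_of(z_focal_mm + b * step_mm)
      alpha <- matrix(as.numeric(m), H, W)
      layer <- rv$color * rep(alpha, 3)
      if (sig > 0.25) {
        alpha <- EBImage::gblur(alpha, sigma = sig, boundary = 0)
        layer <- EBImage::gblur(layer, sigma = sig, boundary = 0)
      }
      out <- layer + rep(1 - alpha, 3) * out
    }
  }
  array(pmin(1, pmax(0, out)), c(H, W, 3))
}

#' Render a focus stack for one pose
#'
#' Simulates the macro-rail acquisition: slice \code{i} is imaged with
#' the projection center at distance \code{z_f + (ref - i) * step} from
#' the rotation center (the camera advances one rail step per slice, so
#' the in-focus plane sweeps from the camera-near side of the specimen
#' to the far side; the reference, middle slice focuses exactly on the
#' rotation center).  Front lighting gives flat ambient shading of the
#' textured albedo, as under a diffuse dome; back lighting gives a
#' white background with the solids in black.  Defocus is simulated per
#' depth bin from the thin-lens circle of confusion.  Rendering is
#' deterministic for a fixed seed.
#'
#' @param scn A \code{scene}.
#' @param pose A \code{pose}.
#' @param cam A \code{camera_model}; \code{cam$focus_distance_mm} is
#'   the slice focal distance z_f.
#' @param n_slices Number of slices.
#' @param step_um Rail step between slices, micrometers.
#' @param lighting "front" or "back".
#' @param seed Integer seed for the procedural textures.
#' @param aperture_mm Entrance-pupil diameter driving the circle of
#'   confusion (0 = pinhole, no defocus).
#' @param coc_max_px Clip for the circle-of-confusion diameter, px.
#' @return A \code{focus_stack}: list with \code{slices} (H x W x 3
#'   arrays in \[0,1\]), \code{rail_positions_mm} (strictly
#'   increasing), \code{lighting}, \code{step_um}, \code{ref_index},
#'   and ground truth \code{gt} (reference-perspective \code{depth} in
#'   mm from the reference camera, \code{depth_index} in fractional
#'   slice units, \code{silhouette}).
#' @export
render_pose_stack <- function(scn, pose, cam, n_slices, step_um,
                              lighting = c("front", "back"), seed = 1L,
                              aperture_mm = 10, coc_max_px = 12) {
  lighting <- match.arg(lighting)
  stopifnot(inherits(scn, "scene"), n_slices >= 1)
  step_mm <- step_um / 1000
  z_f <- cam$focus_distance_mm
  ref <- middle_slice(n_slices)
  background <- if (lighting == "front") 0.05 else 1
  slices <- vector("list", n_slices)
  gt <- NULL
  for (i in seq_len(n_slices)) {
    dist_i <- z_f + (ref - i) * step_mm
    if (dist_i <= scn$bound_radius_mm)
      stop("camera would enter the scene bound; reduce n_slices or step")
    ext <- camera_extrinsics(pose, dist_i, scn$rotation_center)
    rv <- render_view(scn, ext, cam, lighting, texture_seed_base = seed)
    if (i == ref) {
      didx <- ref - (z_f - rv$depth) / step_mm
      gt <- list(depth = rv$depth, depth_index = didx,
                 silhouette = rv$silhouette, camera_distance_mm = dist_i,
                 sharp = rv$color)
    }
    slices[[i]] <- if (aperture_mm > 0)
      defocus_composite(rv, z_focal_mm = z_f, step_mm = step_mm, cam = cam,
                        aperture_mm = aperture_mm, coc_max_px = coc_max_px,
                        background = background)
    else rv$color
  }
  structure(list(slices = slices,
                 rail_positions_mm = (seq_len(n_slices) - 1) * step_mm,
                 lighting = lighting, step_um = step_um,
                 ref_index = ref, camera = cam, pose = pose, gt = gt),
            class = "focus_stack")
}

#' @export
print.focus_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("focus_stack: %d slices of %dx%d (%s light), step %g um\n",
              length(x$slices), d[1], d[2], x$lighting, x$step_um))
  invisible(x)
}

#' Render a calibration-target stack
#'
#' Renders the focus-stack acquisition of a flat dot-grid target fixed
#' at the reference focal plane, perpendicular to the optical axis.  As
#' the camera advances along the rail the grid's projected dot spacing
#' changes slice to slice, which is what
#' \code{\link{calibrate_from_target}} measures.  Dots are rendered
#' with analytically anti-aliased edges so centroids are sub-pixel
#' accurate.
#'
#' @param cam A \code{camera_model}.
#' @param n_slices,step_um Stack geometry (rail step in micrometers).
#' @param grid_pitch_mm Dot spacing of the target, mm.
#' @param dot_radius_mm Dot radius, mm.
#' @return A \code{focus_stack} (grayscale slices, \code{lighting =
#'   "front"}) with \code{grid_pitch_mm} recorded.
#' @export
render_target_stack <- function(cam, n_slices, step_um,
                                grid_pitch_mm = 1, dot_radius_mm = 0.25) {
  step_mm <- step_um / 1000
  z_f <- cam$focus_distance_mm
  ref <- middle_slice(n_slices)
  f <- focal_px(cam)
  H <- cam$height_px; W <- cam$width_px
  u <- matrix(seq_len(W), H, W, byrow = TRUE) - cam$principal_point_px[1]
  v <- matrix(seq_len(H), H, W) - cam$principal_point_px[2]
  slices <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    dist_i <- z_f + (ref - i) * step_mm  # camera-to-target distance
    if (dist_i <= 0) stop("camera passed through the target plane")
    x <- u * dist_i / f                  # target-plane coords, mm
    y <- v * dist_i / f
    dx <- x - grid_pitch_mm * round(x / grid_pitch_mm)
    dy <- y - grid_pitch_mm * round(y / grid_pitch_mm)
    r <- sqrt(dx^2 + dy^2)
    edge_mm <- dist_i / f                # one pixel on the target plane
    dark <- pmin(pmax((dot_radius_mm - r) / edge_mm + 0.5, 0), 1)
    slices[[i]] <- matrix(0.95 - 0.9 * dark, H, W)
  }
  structure(list(slices = slices,
                 rail_positions_mm = (seq_len(n_slices) - 1) * step_mm,
                 lighting = "front", step_um = step_um, ref_index = ref,
                 camera = cam, grid_pitch_mm = grid_pitch_mm),
            class = "focus_stack")
}

#' Run a full synthetic scan
#'
#' Renders front-light and back-light focus stacks plus ground truth
#' for every accessible pose of a program, writing a scan directory
#' with one subdirectory per pose and a manifest CSV.
#'
#' @param scn A \code{scene}.
#' @param program A \code{pose_program}.
#' @param cam A \code{camera_model}.
#' @param out_dir Output directory (created if missing).
#' @param n_slices,step_um Stack geometry.
#' @param seed Integer seed.
#' @param aperture_mm Entrance-pupil diameter (mm) for defocus.
#' @param write_stacks If FALSE, stacks are returned in memory only and
#'   no TIFF files are written (ground truth and manifest still are).
#' @return Invisibly, the manifest data frame (columns pose_index,
#'   tilt_deg, rot_deg, front_path, back_path, n_slices, step_um).
#' @export
make_scan <- function(scn, program, cam, out_dir, n_slices = 7,
                      step_um = 1000, seed = 1L, aperture_mm = 10,
                      write_stacks = TRUE) {
  acc <- program$poses[program$poses$accessible, ]
  if (nrow(acc) == 0) stop("program has no accessible poses")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  rows <- vector("list", nrow(acc))
  for (k in seq_len(nrow(acc))) {
    p <- pose(acc$tilt_deg[k], acc$rot_deg[k], index = acc$index[k])
    pdir <- file.path(out_dir, sprintf("pose_%04d", p$index))
    dir.create(pdir, showWarnings = FALSE)
    fr <- render_pose_stack(scn, p, cam, n_slices, step_um, "front",
                            seed = seed, aperture_mm = aperture_mm)
    bk <- render_pose_stack(scn, p, cam, n_slices, step_um, "back",
                            seed = seed, aperture_mm = aperture_mm)
    front_path <- file.path(pdir, "front.tif")
    back_path <- file.path(pdir, "back.tif")
    if (write_stacks) {
      write_stack_tiff(fr, front_path)
      write_stack_tiff(bk, back_path)
    }
    png::writePNG(fr$gt$silhouette * 1, file.path(pdir, "gt_silhouette.png"))
    write_depth_tiff(fr$gt$depth_index, length(fr$slices),
                     file.path(pdir, "gt_depth_index.tif"))
    rows[[k]] <- data.frame(pose_index = p$index, tilt_deg = p$tilt_deg,
                            rot_deg = p$rot_deg, front_path = front_path,
                            back_path = back_path, n_slices = n_slices,
                            step_um = step_um)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(pixel_pitch_um = cam$pixel_pitch_um,
                        width_px = cam$width_px, height_px = cam$height_px,
                        magnification = cam$magnification,
                        focus_distance_mm = cam$focus_distance_mm),
                   file.path(out_dir, "camera.yaml"))
  write_calibration(
    stack_calibration(n_slices, step_um,
                      beta = (step_um / 1000) / cam$focus_distance_mm),
    file.path(out_dir, "calibration.yaml"))
  invisible(manifest)
}

#' Focus-stack TIFF I/O
#'
#' Stacks are stored as multi-page 16-bit TIFF (one page per slice,
#' RGB); depth-index maps as 32-bit float TIFF scaled to \[0,1\] by
#' the slice count.
#'
#' @param stack A \code{focus_stack}.
#' @param path TIFF path.
#' @param step_um,lighting Metadata to attach on read.
#' @return \code{read_stack_tiff} returns a \code{focus_stack}.
#' @export
write_stack_tiff <- function(stack, path) {
  tiff::writeTIFF(stack$slices, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, step_um = NA, lighting = "front") {
  pages <- tiff::readTIFF(path, all = TRUE)
  step_mm <- if (is.na(step_um)) 1 else step_um / 1000
  structure(list(slices = pages,
                 rail_positions_mm = (seq_along(pages) - 1) * step_mm,
                 lighting = lighting, step_um = step_um,
                 ref_index = middle_slice(length(pages))),
            class = "focus_stack")
}

write_depth_tiff <- function(depth_index, n_slices, path) {
  x <- depth_index / n_slices
  x[!is.finite(x)] <- 0
  x <- matrix(pmin(pmax(x, 0), 1), nrow(depth_index), ncol(depth_index))
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
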