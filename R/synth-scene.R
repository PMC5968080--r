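#' Analytic test scenes for the synthetic scanner
#'
#' A scene is a list of analytic solids (spheres, capsules, discs)
#' around a rotation center.  Solids are intersected with viewing rays
#' in closed form, so silhouette areas, depths and projections have
#' exact ground truth without any mesh rendering.
#'
#' @param solids List of solids created with \code{\link{solid_sphere}},
#'   \code{\link{solid_capsule}} or \code{\link{solid_disc}}.
#' @param rotation_center 3-vector, mm; the gimbal rotation center.
#' @param bound_radius_mm Bounding radius around the rotation center
#'   that must contain all solids.
#' @return An object of class \code{scene}.
#' @export
scene <- function(solids, rotation_center = c(0, 0, 0), bound_radius_mm = 10) {
  if (length(solids) == 0) stop("scene must contain at least one solid")
  for (s in solids) {
    r <- solid_reach(s, rotation_center)
    if (r > bound_radius_mm + 1e-9)
      stop("solid extends ", round(r, 2), " mm from the rotation center, ",
           "beyond the stated bound of ", bound_radius_mm, " mm")
  }
  structure(list(solids = solids, rotation_center = rotation_center,
                 bound_radius_mm = bound_radius_mm), class = "scene")
}

solid_reach <- function(s, center) {
  pts <- switch(s$type,
                sphere = list(s$center),
                capsule = list(s$p1, s$p2),
                disc = list(s$center))
  max(vapply(pts, function(p) sqrt(sum((p - center)^2)), numeric(1))) + s$radius
}

new_solid <- function(type, ..., albedo, texture) {
  stopifnot(all(albedo >= 0), all(albedo <= 1))
  if (length(albedo) == 1) albedo <- rep(albedo, 3)
  structure(c(list(type = type, albedo = albedo,
                   texture = texture), list(...)), class = "solid")
}

#' Scene solids
#'
#' \code{solid_sphere} is a ball; \code{solid_capsule} a sphere-swept
#' segment (also used as the support "pin"); \code{solid_disc} a flat
#' circular plate (zero thickness), used for plane phantoms and the
#' calibration target.
#'
#' @param center,p1,p2 3-vectors, mm.
#' @param radius Radius in mm.
#' @param normal Unit normal of the disc.
#' @param albedo RGB albedo in \[0,1\] (scalar = gray).
#' @param texture Procedural texture: \code{list(amplitude, length_mm)}
#'   where \code{length_mm} is the correlation length, or \code{NULL}
#'   for an untextured solid.
#' @return A \code{solid}.
#' @export
solid_sphere <- function(center, radius, albedo = 0.6,
                         texture = list(amplitude = 0.35, length_mm = 0.25)) {
  new_solid("sphere", center = center, radius = radius,
            albedo = albedo, texture = texture)
}

#' @rdname solid_sphere
#' @export
solid_capsule <- function(p1, p2, radius, albedo = 0.35,
                          texture = list(amplitude = 0.2, length_mm = 0.2)) {
  new_solid("capsule", p1 = p1, p2 = p2, radius = radius,
            albedo = albedo, texture = texture)
}

#' @rdname solid_sphere
#' @export
solid_disc <- function(center, normal, radius, albedo = 0.6,
                       texture = list(amplitude = 0.35, length_mm = 0.25)) {
  normal <- normal / sqrt(sum(normal^2))
  new_solid("disc", center = center, normal = normal, radius = radius,
            albedo = albedo, texture = texture)
}

# --- ray / solid intersection -------------------------------------------
# o: 3-vector ray origin; d: N x 3 unit directions.
# Returns t (N), Inf where missed.
ray_solid_t <- function(s, o, d) {
  n <- nrow(d)
  switch(s$type,
    sphere = {
      oc <- o - s$center
      b <- d %*% oc
      cc <- sum(oc^2) - s$radius^2
      disc <- b^2 - cc
      t <- -b - sqrt(pmax(disc, 0))
      t[disc <= 0 | t <= 0] <- Inf
      as.numeric(t)
    },
    capsule = {
      a <- s$p2 - s$p1
      L <- sqrt(sum(a^2))
      a <- a / L
      oo <- o - s$p1
      da <- as.numeric(d %*% a)
      ooa <- sum(oo * a)
      dd <- d - outer(da, a)
      oo_perp <- matrix(oo, n, 3, byrow = TRUE) - outer(rep(ooa, n), a)
      A <- rowSums(dd^2)
      B <- rowSums(dd * oo_perp)
      Cq <- rowSums(oo_perp^2) - s$radius^2
      disc <- B^2 - A * Cq
      tc <- (-B - sqrt(pmax(disc, 0))) / A
      sax <- ooa + tc * da             # axial coordinate of cylinder hit
      ok <- disc > 0 & tc > 0 & sax >= 0 & sax <= L & A > 1e-18
      tc[!ok] <- Inf
      t1 <- sphere_t(s$p1, s$radius, o, d)
      t2 <- sphere_t(s$p2, s$radius, o, d)
      pmin(tc, t1, t2)
    },
    disc = {
      dn <- as.numeric(d %*% s$normal)
      t <- as.numeric(((s$center - o) %*% s$normal)) / dn
      p <- o[1] + t * d[, 1] - s$center[1]
      q <- o[2] + t * d[, 2] - s$center[2]
      r <- o[3] + t * d[, 3] - s$center[3]
      ok <- abs(dn) > 1e-12 & t > 0 & (p^2 + q^2 + r^2) <= s$radius^2
      t[!ok] <- Inf
      t
    })
}

sphere_t <- function(ctr, radius, o, d) {
  oc <- o - ctr
  b <- as.numeric(d %*% oc)
  cc <- sum(oc^2) - radius^2
  disc <- b^2 - cc
  t <- -b - sqrt(pmax(disc, 0))
  t[disc <= 0 | t <= 0] <- Inf
  t
}

# --- procedural value-noise texture -------------------------------------
# Smooth, seeded, stationary random field on R^3: a sum of random-phase
# cosine waves with wavenumber ~ 2*pi / length_mm.  Gives the dense
# surface detail focus measures and matching need; amplitude scales the
# relative albedo modulation.
texture_field <- function(pts, texture, seed) {
  if (is.null(texture) || texture$amplitude == 0) return(rep(0, nrow(pts)))
  nwave <- 16L
  rs <- local({
    set.seed(seed)
    list(dir = matrix(stats::rnorm(3 * nwave), nwave, 3),
         mag = stats::runif(nwave, 0.6, 1.6),
         phase = stats::runif(nwave, 0, 2 * pi))
  })
  k <- rs$dir / sqrt(rowSums(rs$dir^2)) * (2 * pi / texture$length_mm * rs$mag)
  ph <- pts %*% t(k) + matrix(rs$phase, nrow(pts), nwave, byrow = TRUE)
  texture$amplitude * sqrt(2 / nwave) * rowSums(cos(ph))
}
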