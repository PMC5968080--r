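#' Triangle mesh
#'
#' @param vertices N x 3 numeric matrix, mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices,
#'   consistently oriented outward for closed meshes.
#' @return An object of class \code{tri_mesh}.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Count boundary (non-manifold) edges of a mesh
#'
#' An edge of a closed 2-manifold mesh is shared by exactly two faces.
#' Returns the number of edges for which that fails.
#'
#' @param mesh A \code{tri_mesh}.
#' @return Integer count of defective edges (0 for a watertight mesh).
#' @export
count_boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) != 2)
}

#' Is the mesh watertight?
#'
#' @param mesh A \code{tri_mesh}.
#' @return TRUE when every edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) count_boundary_edges(mesh) == 0

#' Write / read a Wavefront OBJ file
#'
#' ASCII OBJ with \code{v} and \code{f} records only.
#'
#' @param mesh A \code{tri_mesh}.
#' @param path File path.
#' @return \code{write_obj}: the path, invisibly; \code{read_obj}: a
#'   \code{tri_mesh}.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1],
                     mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  tri_mesh(verts, faces)
}

#' Reference meshes
#'
#' \code{mesh_cube} builds an axis-aligned cube of 12 triangles;
#' \code{mesh_icosphere} a subdivided icosahedron.  Both are closed
#' and outward-oriented, useful as morphometry references with known
#' area and volume.
#'
#' @param edge_mm Cube edge length.
#' @param center 3-vector, mm.
#' @param radius_mm Sphere radius.
#' @param subdivisions Number of 4-fold subdivision passes (4 gives
#'   5120 faces).
#' @return A \code{tri_mesh}.
#' @export
mesh_cube <- function(edge_mm = 10, center = c(0, 0, 0)) {
  h <- edge_mm / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- v + matrix(center, 8, 3, byrow = TRUE)
  # vertices indexed 1..8 in (x, y, z) binary order
  f <- rbind(
    c(1, 7, 3), c(1, 5, 7),   # x = -h
    c(2, 4, 8), c(2, 8, 6),   # x = +h
    c(1, 2, 6), c(1, 6, 5),   # y = -h
    c(3, 8, 4), c(3, 7, 8),   # y = +h
    c(1, 3, 4), c(1, 4, 2),   # z = -h
    c(5, 6, 8), c(5, 8, 7))   # z = +h
  tri_mesh(v, f)
}

#' @rdname mesh_cube
#' @export
mesh_icosphere <- function(radius_mm = 10, subdivisions = 3,
                           center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (iter in seq_len(subdivisions)) {
    mids <- new.env()
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mids[[key]]
      if (!is.null(id)) return(id)
      vlist[[length(vlist) + 1]] <<- (vlist[[a]] + vlist[[b]]) / 2
      mids[[key]] <- length(vlist)
      length(vlist)
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c2 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c2); ca <- midpoint(c2, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(c2, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius_mm
  v <- v + matrix(center, nrow(v), 3, byrow = TRUE)
  tri_mesh(v, f)
}

#' Rigid / similarity transform of a mesh
#'
#' @param mesh A \code{tri_mesh}.
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector, mm.
#' @param scale Uniform scale factor.
#' @return The transformed \code{tri_mesh}.
#' @export
transform_mesh <- function(mesh, rotation = diag(3),
                           translation = c(0, 0, 0), scale = 1) {
  v <- scale * (mesh$vertices %*% t(rotation))
  v <- v + matrix(translation, nrow(v), 3, byrow = TRUE)
  tri_mesh(v, mesh$faces)
}
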