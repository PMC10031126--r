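#' Triangle mesh constructor
#'
#' A minimal closed-surface triangle mesh: an `n x 3` matrix of vertex
#' coordinates in world units and an `m x 3` integer matrix of 1-based
#' triangle vertex indices.
#'
#' @param vertices numeric matrix, `n x 3`, finite coordinates.
#' @param faces integer matrix, `m x 3`, 1-based indices into `vertices`.
#' @return an object of class `stc_mesh`.
#' @export
stc_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stc_validation_error("vertices must be n x 3")
  if (ncol(faces) != 3L) stc_validation_error("faces must be m x 3")
  if (!all(is.finite(vertices))) stc_validation_error("vertex coordinates must be finite")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stc_validation_error("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "stc_mesh")
}

#' @export
print.stc_mesh <- function(x, ...) {
  cat(sprintf("<stc_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Icosphere mesh
#'
#' Sphere approximated by recursive subdivision of an icosahedron; all
#' vertices lie on the sphere of radius `radius` about `center`.
#'
#' @param subdivisions non-negative integer; each level quadruples the face
#'   count (level 0 = 20 faces, level 2 = 320, level 3 = 1280).
#' @param radius sphere radius (world units).
#' @param center length-3 numeric center.
#' @return an `stc_mesh`.
#' @export
icosphere <- function(subdivisions = 2L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- mid_cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    k <- 0L
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; c_ <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[k + 1L, ] <- c(a, ab, ca)
      nf[k + 2L, ] <- c(b, bc, ab)
      nf[k + 3L, ] <- c(c_, ca, bc)
      nf[k + 4L, ] <- c(ab, bc, ca)
      k <- k + 4L
    }
    v <- verts
    f <- nf
  }
  stc_mesh(sweep(v * radius, 2L, center, `+`), f)
}

#' Enclosed mesh volume
#'
#' Signed volume of a closed, consistently oriented triangle mesh via the
#' divergence theorem (sum of signed tetrahedra against the origin). The
#' absolute value is returned.
#'
#' @param mesh an `stc_mesh`.
#' @return volume in world units cubed.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  a <- v[mesh$faces[, 1L], , drop = FALSE]
  b <- v[mesh$faces[, 2L], , drop = FALSE]
  c_ <- v[mesh$faces[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
          a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
          a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  abs(sum(det6)) / 6
}

#' Mesh centroid (vertex mean)
#' @param mesh an `stc_mesh`.
#' @return length-3 numeric.
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Watertightness check
#'
#' A mesh is watertight (closed and consistently oriented) when every
#' undirected edge is shared by exactly two faces and every directed edge
#' appears exactly once.
#'
#' @param mesh an `stc_mesh`.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e_from <- c(f[, 1L], f[, 2L], f[, 3L])
  e_to   <- c(f[, 2L], f[, 3L], f[, 1L])
  directed <- paste(e_from, e_to)
  if (anyDuplicated(directed)) return(FALSE)
  undirected <- paste(pmin(e_from, e_to), pmax(e_from, e_to))
  all(table(undirected) == 2L)
}

# Axis-aligned bounding box of a mesh: 2 x 3 matrix (min row, max row).
mesh_bounds <- function(mesh) {
  rbind(apply(mesh$vertices, 2L, min), apply(mesh$vertices, 2L, max))
}
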