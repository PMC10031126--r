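#' Define a cutting plane
#'
#' The plane through which the 4D (x, y, z, t) dataset is projected into a
#' space-time cube. The normal is normalized, the up vector is replaced by
#' its component orthogonal to the normal (Gram-Schmidt) and the in-plane
#' basis is right-handed: `u_axis = up x normal`, `v_axis = up`, so that
#' `u_axis x v_axis = normal`.
#'
#' @param point length-3 world point on the plane.
#' @param normal length-3 nonzero vector.
#' @param up length-3 vector not parallel to the normal; fixes the image
#'   orientation.
#' @return an object of class `stc_plane` with fields `point`, `normal`,
#'   `u_axis`, `v_axis`.
#' @export
define_plane <- function(point, normal, up = c(0, 1, 0)) {
  point <- as.numeric(point)
  if (length(point) != 3L || length(normal) != 3L || length(up) != 3L)
    stc_validation_error("point, normal and up must have length 3")
  if (vnorm(normal) == 0) stc_validation_error("plane normal must be nonzero")
  n <- normalize(as.numeric(normal))
  up_orth <- as.numeric(up) - sum(up * n) * n
  if (vnorm(up_orth) < 1e-12)
    stc_validation_error("up vector is parallel to the plane normal")
  v <- normalize(up_orth)
  u <- cross3(v, n)
  structure(list(point = point, normal = n, u_axis = u, v_axis = v),
            class = "stc_plane")
}

#' @export
print.stc_plane <- function(x, ...) {
  cat(sprintf("<stc_plane: point (%s), normal (%s)>\n",
              paste(signif(x$point, 4), collapse = ", "),
              paste(signif(x$normal, 4), collapse = ", ")))
  invisible(x)
}

# Plane-local coordinates of world points `pts` (n x 3) relative to `ref`:
# columns u, v (in-plane) and w (signed distance along the normal).
plane_coords <- function(plane, pts, ref = plane$point) {
  d <- sweep(pts, 2L, ref, `-`)
  cbind(u = d %*% plane$u_axis, v = d %*% plane$v_axis, w = d %*% plane$normal)
}

# Intersection segments of a triangle mesh with the plane, as plane-local
# (u1, v1, u2, v2) rows. Vertices exactly on the plane count as positive
# side so each crossing triangle yields exactly one segment.
mesh_plane_segments <- function(mesh, plane) {
  v <- mesh$vertices
  f <- mesh$faces
  w <- as.vector((sweep(v, 2L, plane$point, `-`)) %*% plane$normal)
  s <- w >= 0
  s1 <- s[f[, 1L]]; s2 <- s[f[, 2L]]; s3 <- s[f[, 3L]]
  c12 <- s1 != s2; c23 <- s2 != s3; c31 <- s3 != s1
  keep <- which((c12 + c23 + c31) == 2L)
  if (!length(keep)) return(matrix(numeric(0), ncol = 4L))
  edge_hit <- function(ia, ib) {
    a <- v[f[keep, ia], , drop = FALSE]; b <- v[f[keep, ib], , drop = FALSE]
    wa <- w[f[keep, ia]]; wb <- w[f[keep, ib]]
    a + (b - a) * (wa / (wa - wb))
  }
  h12 <- edge_hit(1L, 2L); h23 <- edge_hit(2L, 3L); h31 <- edge_hit(3L, 1L)
  kc12 <- c12[keep]; kc31 <- c31[keep]
  # exactly two of the three edges cross; take 1-2 else 2-3 as the first
  # point and 3-1 else 2-3 as the second (covers all three patterns)
  p1 <- ifelse(matrix(kc12, length(keep), 3L), h12, h23)
  p2 <- ifelse(matrix(kc31, length(keep), 3L), h31, h23)
  uv1 <- plane_coords(plane, p1)
  uv2 <- plane_coords(plane, p2)
  cbind(u1 = uv1[, 1L], v1 = uv1[, 2L], u2 = uv2[, 1L], v2 = uv2[, 2L])
}

#' Fit the shared orthographic camera frame
#'
#' Computes the minimal field of view that contains the cross-section of
#' the dataset at every time step: the (u, v) bounding rectangle of the
#' plane intersection, unioned over all frames, expanded by
#' `margin_fraction` on each side and padded so pixels are square. The
#' same frame is used at every time step so that slices stack without
#' spatial drift.
#'
#' @param dataset an `stc_dataset`.
#' @param plane an [define_plane()] result.
#' @param resolution integer `c(n_u, n_v)` pixels.
#' @param margin_fraction fractional margin added on each side of the tight
#'   bound.
#' @param eps slab half-thickness in world units; geometry within `eps` of
#'   the plane contributes to the bound. NULL defaults to one pixel's world
#'   size (resolved after the tight bound is known).
#' @return an object of class `stc_frame` with fields `origin` (world corner),
#'   `u_axis`, `v_axis`, `normal`, `width`, `height`, `resolution`,
#'   `pixel_size`, `eps`. Pixel `(i, j)` (1-based) has world center
#'   `origin + (i - 0.5) * pixel_size * u_axis + (j - 0.5) * pixel_size * v_axis`.
#' @export
fit_frame <- function(dataset, plane, resolution = c(256L, 256L),
                      margin_fraction = 0.02, eps = NULL) {
  stopifnot(inherits(dataset, "stc_dataset"), inherits(plane, "stc_plane"))
  resolution <- as.integer(resolution)
  if (length(resolution) != 2L || any(resolution < 1L))
    stc_validation_error("resolution must be two positive integers")
  lo <- c(Inf, Inf); hi <- c(-Inf, -Inf)
  grow <- function(uv) {
    if (nrow(uv) == 0L) return()
    lo <<- pmin(lo, c(min(uv[, 1L]), min(uv[, 2L])))
    hi <<- pmax(hi, c(max(uv[, 1L]), max(uv[, 2L])))
  }
  slab <- eps %||% 0
  if (dataset$geometry == "mesh") {
    for (k in seq_along(dataset$times)) {
      for (obj in dataset$objects_by_time[[k]]) {
        seg <- mesh_plane_segments(obj$mesh, plane)
        grow(rbind(seg[, 1:2, drop = FALSE], seg[, 3:4, drop = FALSE]))
        if (slab > 0) {
          pc <- plane_coords(plane, obj$mesh$vertices)
          grow(pc[abs(pc[, 3L]) <= slab, 1:2, drop = FALSE])
        }
      }
    }
  } else {
    half_diag <- vnorm(dataset$spacing) / 2
    for (k in seq_along(dataset$times)) {
      idx <- which(dataset$volumes[[k]] != 0L, arr.ind = TRUE)
      if (!nrow(idx)) next
      centers <- sweep((idx - 0.5) * rep(dataset$spacing, each = nrow(idx)),
                       2L, dataset$origin, `+`)
      pc <- plane_coords(plane, centers)
      grow(pc[abs(pc[, 3L]) <= max(slab, half_diag), 1:2, drop = FALSE])
    }
  }
  if (!all(is.finite(c(lo, hi))))
    stc_stop("no geometry intersects the cutting plane slab at any time step",
             c("stcEmptyFrameError", "stcValidationError"))
  span <- hi - lo
  lo <- lo - margin_fraction * span
  hi <- hi + margin_fraction * span
  span <- hi - lo
  pixel <- max(span / resolution)
  if (pixel <= 0) pixel <- 1e-6
  width <- pixel * resolution[1L]
  height <- pixel * resolution[2L]
  center <- (lo + hi) / 2
  origin_uv <- center - c(width, height) / 2
  origin <- plane$point + origin_uv[1L] * plane$u_axis + origin_uv[2L] * plane$v_axis
  structure(list(
    origin = origin, u_axis = plane$u_axis, v_axis = plane$v_axis,
    normal = plane$normal, width = width, height = height,
    resolution = resolution, pixel_size = pixel,
    eps = eps %||% pixel
  ), class = "stc_frame")
}

#' @export
print.stc_frame <- function(x, ...) {
  cat(sprintf("<stc_frame: %d x %d px, %.4g x %.4g world units, eps=%.4g>\n",
              x$resolution[1L], x$resolution[2L], x$width, x$height, x$eps))
  invisible(x)
}

#' World coordinates of pixel centers
#'
#' @param frame an [fit_frame()] result.
#' @param i,j 1-based pixel indices (u column, v row); vectors are recycled
#'   against each other.
#' @return n x 3 matrix of world points.
#' @export
pixel_centers <- function(frame, i, j) {
  u <- (i - 0.5) * frame$pixel_size
  v <- (j - 0.5) * frame$pixel_size
  sweep(outer(u, frame$u_axis) + outer(v, frame$v_axis), 2L, frame$origin, `+`)
}

# Vectorized squared point-to-segment distance for paired rows.
point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  ap <- p - a
  denom <- rowSums(ab^2)
  t <- ifelse(denom > 0, rowSums(ap * ab) / denom, 0)
  t <- pmin(pmax(t, 0), 1)
  q <- a + ab * t
  rowSums((p - q)^2)
}

# Vectorized point-to-triangle distance for paired rows (p against triangle
# a, b, c). Interior projection when the barycentric foot lies inside,
# otherwise the nearest edge.
point_triangle_dist <- function(p, a, b, c_) {
  e0 <- b - a; e1 <- c_ - a
  n <- cbind(e0[, 2L] * e1[, 3L] - e0[, 3L] * e1[, 2L],
             e0[, 3L] * e1[, 1L] - e0[, 1L] * e1[, 3L],
             e0[, 1L] * e1[, 2L] - e0[, 2L] * e1[, 1L])
  nn <- rowSums(n^2)
  ap <- p - a
  dist_plane2 <- ifelse(nn > 0, rowSums(ap * n)^2 / nn, Inf)
  # barycentric coordinates of the in-plane foot
  d00 <- rowSums(e0 * e0); d01 <- rowSums(e0 * e1); d11 <- rowSums(e1 * e1)
  d20 <- rowSums(ap * e0); d21 <- rowSums(ap * e1)
  den <- d00 * d11 - d01 * d01
  vb <- ifelse(den > 0, (d11 * d20 - d01 * d21) / den, -1)
  wb <- ifelse(den > 0, (d00 * d21 - d01 * d20) / den, -1)
  inside <- vb >= 0 & wb >= 0 & (vb + wb) <= 1
  d2 <- pmin(point_segment_dist2(p, a, b),
             point_segment_dist2(p, b, c_),
             point_segment_dist2(p, c_, a))
  d2[inside] <- pmin(d2[inside], dist_plane2[inside])
  sqrt(d2)
}

# Scanline parity fill of one object's cross-section into `img` (nu x nv
# integer matrix); only background pixels are written so that iterating
# objects in increasing id order makes the smallest id win contested pixels.
fill_cross_section <- function(img, seg, id, frame) {
  if (nrow(seg) == 0L) return(img)
  px <- frame$pixel_size
  nu <- frame$resolution[1L]; nv <- frame$resolution[2L]
  jmin <- max(1L, floor(min(seg[, c(2L, 4L)]) / px + 0.5))
  jmax <- min(nv, ceiling(max(seg[, c(2L, 4L)]) / px + 0.5))
  if (jmin > jmax) return(img)
  for (j in jmin:jmax) {
    vj <- (j - 0.5) * px
    cr <- (seg[, 2L] > vj) != (seg[, 4L] > vj)
    if (!any(cr)) next
    s <- seg[cr, , drop = FALSE]
    xs <- s[, 1L] + (vj - s[, 2L]) / (s[, 4L] - s[, 2L]) * (s[, 3L] - s[, 1L])
    xs <- sort(xs)
    np <- floor(length(xs) / 2) * 2
    if (np == 0L) next
    for (q in seq(1L, np, by = 2L)) {
      i_lo <- floor(xs[q] / px + 0.5) + 1
      i_hi <- ceiling(xs[q + 1L] / px + 0.5) - 1
      i_lo <- max(i_lo, 1L); i_hi <- min(i_hi, nu)
      if (i_lo > i_hi) next
      ii <- i_lo:i_hi
      ii <- ii[img[ii, j] == 0L]
      img[ii, j] <- id
    }
  }
  img
}

# Membrane rasterization of one object: pixels whose center lies within
# `delta` (3D distance) of the surface.
membrane_cross_section <- function(img, obj, frame, delta) {
  mesh <- obj$mesh
  pc <- plane_coords_frame(frame, mesh$vertices)
  w <- pc[, 3L]
  f <- mesh$faces
  wmin <- pmin(w[f[, 1L]], w[f[, 2L]], w[f[, 3L]])
  wmax <- pmax(w[f[, 1L]], w[f[, 2L]], w[f[, 3L]])
  cand <- which(wmin <= delta & wmax >= -delta)
  if (!length(cand)) return(img)
  px <- frame$pixel_size
  nu <- frame$resolution[1L]; nv <- frame$resolution[2L]
  pair_pix <- list(); pair_tri <- list()
  for (q in seq_along(cand)) {
    tf <- f[cand[q], ]
    us <- pc[tf, 1L]; vs <- pc[tf, 2L]
    i0 <- max(1L, floor((min(us) - delta) / px + 0.5))
    i1 <- min(nu, ceiling((max(us) + delta) / px + 0.5))
    j0 <- max(1L, floor((min(vs) - delta) / px + 0.5))
    j1 <- min(nv, ceiling((max(vs) + delta) / px + 0.5))
    if (i0 > i1 || j0 > j1) next
    grid <- as.matrix(expand.grid(i = i0:i1, j = j0:j1))
    pair_pix[[length(pair_pix) + 1L]] <- grid
    pair_tri[[length(pair_tri) + 1L]] <- rep(cand[q], nrow(grid))
  }
  if (!length(pair_pix)) return(img)
  pix <- do.call(rbind, pair_pix)
  tri <- unlist(pair_tri)
  p <- pixel_centers(frame, pix[, 1L], pix[, 2L])
  a <- mesh$vertices[f[tri, 1L], , drop = FALSE]
  b <- mesh$vertices[f[tri, 2L], , drop = FALSE]
  c_ <- mesh$vertices[f[tri, 3L], , drop = FALSE]
  d <- point_triangle_dist(p, a, b, c_)
  hit <- d <= delta
  if (!any(hit)) return(img)
  lin <- unique(pix[hit, 1L] + (pix[hit, 2L] - 1L) * nu)
  lin <- lin[img[lin] == 0L]
  img[lin] <- obj$id
  img
}

# Frame-relative plane coordinates (origin at the frame corner).
plane_coords_frame <- function(frame, pts) {
  d <- sweep(pts, 2L, frame$origin, `-`)
  cbind(u = d %*% frame$u_axis, v = d %*% frame$v_axis, w = d %*% frame$normal)
}

#' Rasterize one cross-section
#'
#' Computes the label image of the dataset's intersection with the cutting
#' plane at frame `t`. In `filled` mode a pixel takes an object's id when
#' its center lies inside the object's closed mesh (parity test in the
#' cutting plane); in `membrane` mode when the object's surface passes
#' within `max(eps, half pixel diagonal)` of the pixel center. When several
#' objects claim a pixel the smallest id wins. Background is 0. For
#' label-volume datasets the label is resampled at the pixel center by
#' nearest neighbor in either mode (labels are nominal and must not be
#' interpolated).
#'
#' @param dataset an `stc_dataset`.
#' @param t frame index (0-based).
#' @param plane an `stc_plane` (used to orient the frame; geometry is read
#'   through `frame`).
#' @param frame an `stc_frame` from [fit_frame()].
#' @param mode `"membrane"` or `"filled"`.
#' @return integer matrix `n_u x n_v` of object ids (class `stc_label_image`
#'   with attributes `time` and `frame`).
#' @export
rasterize_cross_section <- function(dataset, t, plane, frame,
                                    mode = c("membrane", "filled")) {
  mode <- match.arg(mode)
  t <- as.integer(t)
  if (!(t %in% dataset$times)) stc_validation_error(sprintf("invalid time %d", t))
  nu <- frame$resolution[1L]; nv <- frame$resolution[2L]
  img <- matrix(0L, nrow = nu, ncol = nv)
  if (dataset$geometry == "labels") {
    grid <- as.matrix(expand.grid(i = seq_len(nu), j = seq_len(nv)))
    p <- pixel_centers(frame, grid[, 1L], grid[, 2L])
    vox <- floor(sweep(sweep(p, 2L, dataset$origin, `-`), 2L,
                       dataset$spacing, `/`)) + 1
    vol <- dataset$volumes[[t + 1L]]
    d <- dim(vol)
    ok <- vox[, 1L] >= 1 & vox[, 1L] <= d[1L] &
          vox[, 2L] >= 1 & vox[, 2L] <= d[2L] &
          vox[, 3L] >= 1 & vox[, 3L] <= d[3L]
    lab <- integer(nrow(grid))
    lab[ok] <- vol[vox[ok, , drop = FALSE]]
    img[grid] <- lab
  } else {
    objs <- dataset$objects_by_time[[t + 1L]]
    ids <- vapply(objs, function(o) o$id, integer(1))
    delta <- max(frame$eps, frame$pixel_size * sqrt(2) / 2)
    plane_for_frame <- list(point = frame$origin, normal = frame$normal,
                            u_axis = frame$u_axis, v_axis = frame$v_axis)
    class(plane_for_frame) <- "stc_plane"
    for (o in objs[order(ids)]) {
      if (mode == "filled") {
        if (!is_watertight(o$mesh)) {
          warning(sprintf("object %d at t=%d is not watertight; skipped in filled mode",
                          o$id, t))
          next
        }
        seg <- mesh_plane_segments(o$mesh, plane_for_frame)
        img <- fill_cross_section(img, seg, o$id, frame)
      } else {
        img <- membrane_cross_section(img, o, frame, delta)
      }
    }
  }
  structure(img, class = c("stc_label_image", class(img)),
            time = t, pixel_size = frame$pixel_size)
}

#' Build the space-time cube
#'
#' Fits one shared camera frame over all time steps, rasterizes the
#' cross-section at each frame and stacks the label images into the STC:
#' a 3D grid of object ids indexed `(u, v, k)` with `k` the time step.
#'
#' @inheritParams fit_frame
#' @param mode passed to [rasterize_cross_section()].
#' @return an object of class `stc_volume` with fields `labels` (integer
#'   array `n_u x n_v x T`), `plane`, `frame`, `mode`, `times`,
#'   `pixel_size`, `eps`.
#' @export
build_stc <- function(dataset, plane, resolution = c(256L, 256L),
                      mode = c("membrane", "filled"),
                      margin_fraction = 0.02, eps = NULL) {
  mode <- match.arg(mode)
  frame <- fit_frame(dataset, plane, resolution, margin_fraction, eps)
  T <- length(dataset$times)
  labels <- array(0L, dim = c(frame$resolution[1L], frame$resolution[2L], T))
  for (k in seq_len(T)) {
    img <- rasterize_cross_section(dataset, dataset$times[k], plane, frame, mode)
    labels[, , k] <- unclass(img)
  }
  structure(list(labels = labels, plane = plane, frame = frame, mode = mode,
                 times = dataset$times, pixel_size = frame$pixel_size,
                 eps = frame$eps),
            class = "stc_volume")
}

#' @export
print.stc_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<stc_volume: %d x %d x %d (%s mode), %d object id(s)>\n",
              d[1L], d[2L], d[3L], x$mode,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}
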