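# 1D correlation along one axis of a 3D array with edge replication.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = d)
  n <- d[axis]
  for (m in seq_along(kernel)) {
    if (kernel[m] == 0) next
    off <- m - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + kernel[m] * shifted
  }
  out
}

sobel_gradient_axis <- function(a, axis) {
  deriv <- c(-1, 0, 1)
  smooth <- c(1, 2, 1)
  g <- a
  for (ax in 1:3)
    g <- conv_axis(g, if (ax == axis) deriv else smooth, ax)
  g
}

#' Precompute the STC normal field
#'
#' Normals for shading are estimated from the binary occupancy of the STC
#' (1 where the label is nonzero): labels are nominal and must not be
#' differentiated directly. The occupancy is optionally pre-smoothed with a
#' separable Gaussian, then the gradient is taken with the 3x3x3
#' Sobel-Feldman operator along each axis (derivative kernel `[-1, 0, 1]`
#' combined with `[1, 2, 1]` smoothing on the other two axes, edges
#' replicated). The normal is the negated, normalized gradient (pointing
#' out of occupied regions); voxels with vanishing gradient get the zero
#' vector.
#'
#' @param stc an `stc_volume`.
#' @param smooth_sigma Gaussian pre-smoothing standard deviation in voxels;
#'   0 disables smoothing. Default 1.
#' @return an object of class `stc_normals`: a 4D array
#'   `n_u x n_v x T x 3` of unit (or zero) vectors.
#' @export
compute_normals <- function(stc, smooth_sigma = 1) {
  occ <- array(as.numeric(stc$labels != 0L), dim = dim(stc$labels))
  if (smooth_sigma > 0) {
    r <- max(1L, ceiling(3 * smooth_sigma))
    k <- stats::dnorm(-r:r, sd = smooth_sigma)
    k <- k / sum(k)
    for (ax in 1:3) occ <- conv_axis(occ, k, ax)
  }
  g <- array(0, dim = c(dim(occ), 3L))
  for (ax in 1:3) g[, , , ax] <- sobel_gradient_axis(occ, ax)
  len <- sqrt(g[, , , 1L]^2 + g[, , , 2L]^2 + g[, , , 3L]^2)
  nz <- len > 1e-12
  for (ax in 1:3) {
    comp <- g[, , , ax]
    comp[nz] <- -comp[nz] / len[nz]
    comp[!nz] <- 0
    g[, , , ax] <- comp
  }
  structure(g, class = "stc_normals")
}

stable_category_hash <- function(label, n) {
  codes <- utf8ToInt(as.character(label))
  h <- 0
  for (c_ in codes) h <- (h * 31 + c_) %% 1000003
  as.integer(h %% n) + 1L
}

#' Build a per-(object, time) value lookup
#'
#' The color indexing structure of the STC: a table keyed by object id and
#' time index giving each voxel's mapped value and color. Numeric
#' properties are clamped and normalized over `range` (or the observed
#' min/max) and sent through a 256-entry colormap; categorical properties
#' go through a deterministic categorical palette keyed by a stable string
#' hash so colors do not depend on level order. Missing `(id, t)` entries
#' map to the sentinel color. Switching the displayed property only
#' rebuilds this lookup; the STC and its normal field are untouched.
#'
#' @param annotations an [annotation_table()].
#' @param property property name to map.
#' @param colormap name understood by [grDevices::hcl.colors()].
#' @param range numeric `c(vmin, vmax)` or NULL for the observed range.
#' @param sentinel color for missing values.
#' @return an object of class `stc_lookup`.
#' @export
build_lookup <- function(annotations, property, colormap = "viridis",
                         range = NULL, sentinel = "#808080") {
  df <- annotation_slice(annotations, property)
  keys <- paste(df$id, df$t, sep = ":")
  if (is.numeric(df$value)) {
    vmin <- if (is.null(range)) min(df$value) else range[1L]
    vmax <- if (is.null(range)) max(df$value) else range[2L]
    pal <- grDevices::hcl.colors(256L, colormap)
    span <- vmax - vmin
    norm <- if (span > 0) pmin(pmax((df$value - vmin) / span, 0), 1)
            else rep(0.5, nrow(df))
    cols <- pal[1L + as.integer(floor(norm * 255 + 0.5))]
    kind <- "numeric"
    values <- stats::setNames(df$value, keys)
  } else {
    pal <- grDevices::hcl.colors(64L, "Dark 3")
    idx <- vapply(df$value, stable_category_hash, integer(1), n = length(pal))
    cols <- pal[idx]
    vmin <- NA_real_; vmax <- NA_real_
    kind <- "categorical"
    values <- stats::setNames(as.character(df$value), keys)
  }
  structure(list(property = property, kind = kind,
                 vmin = vmin, vmax = vmax, colormap = colormap,
                 sentinel = sentinel,
                 values = values,
                 colors = stats::setNames(cols, keys)),
            class = "stc_lookup")
}

#' @export
print.stc_lookup <- function(x, ...) {
  cat(sprintf("<stc_lookup: '%s' (%s), %d entries>\n",
              x$property, x$kind, length(x$values)))
  invisible(x)
}

#' Mapped value / color for one (id, t)
#' @param lookup an [build_lookup()] result.
#' @param id object id.
#' @param t time index.
#' @return `lookup_value`: the stored value or NA; `lookup_color`: a hex
#'   color (the sentinel when the entry is missing).
#' @export
lookup_value <- function(lookup, id, t) {
  unname(lookup$values[paste(id, t, sep = ":")])
}

#' @rdname lookup_value
#' @export
lookup_color <- function(lookup, id, t) {
  col <- lookup$colors[paste(id, t, sep = ":")]
  if (is.na(col)) lookup$sentinel else unname(col)
}

#' Render settings for the STC raycaster
#'
#' @param view_dir length-3 viewing direction (rays travel along it);
#'   orthographic camera.
#' @param up length-3 camera up vector.
#' @param image_size integer `c(nx, ny)` pixels.
#' @param light world (voxel-coordinate) position of the movable point
#'   light; NULL places it above the viewer side of the volume.
#' @param ka,kd,ks,shininess Blinn-Phong coefficients (ambient, diffuse,
#'   specular weight, specular exponent), all non-negative. `ka + kd`
#'   above 1.2 is rejected unless `override_energy = TRUE`.
#' @param background length-3 RGB in `[0, 1]`.
#' @param step ray-march step in voxels.
#' @param override_energy allow `ka + kd > 1.2`.
#' @return an object of class `stc_render_settings`.
#' @export
render_settings <- function(view_dir = c(-0.5, -0.35, -0.8), up = c(0, 1, 0),
                            image_size = c(256L, 256L), light = NULL,
                            ka = 0.2, kd = 0.7, ks = 0.3, shininess = 16,
                            background = c(0, 0, 0), step = 0.5,
                            override_energy = FALSE) {
  if (vnorm(view_dir) == 0) stc_validation_error("view direction must be nonzero")
  if (any(c(ka, kd, ks, shininess) < 0))
    stc_validation_error("Blinn-Phong coefficients must be non-negative")
  if (ka + kd > 1.2 && !override_energy)
    stc_validation_error("ka + kd > 1.2; set override_energy = TRUE to allow")
  if (step <= 0) stc_validation_error("step must be positive")
  structure(list(view_dir = normalize(as.numeric(view_dir)),
                 up = as.numeric(up), image_size = as.integer(image_size),
                 light = light, ka = ka, kd = kd, ks = ks,
                 shininess = shininess, background = as.numeric(background),
                 step = step),
            class = "stc_render_settings")
}

# Orthographic camera geometry over the STC voxel bounding box.
camera_rays <- function(stc, settings) {
  d <- settings$view_dir
  right <- cross3(d, settings$up)
  if (vnorm(right) < 1e-12)
    stc_validation_error("view direction parallel to up vector")
  right <- normalize(right)
  upv <- cross3(right, d)
  dims <- dim(stc$labels)
  corners <- as.matrix(expand.grid(x = c(0, dims[1L]), y = c(0, dims[2L]),
                                   z = c(0, dims[3L])))
  pr <- corners %*% right; pu <- corners %*% upv; pd <- corners %*% d
  nx <- settings$image_size[1L]; ny <- settings$image_size[2L]
  a <- min(pr) + (seq_len(nx) - 0.5) * (max(pr) - min(pr)) / nx
  b <- min(pu) + (seq_len(ny) - 0.5) * (max(pu) - min(pu)) / ny
  grid <- as.matrix(expand.grid(a = a, b = b))
  origins <- grid[, 1L] %o% right + grid[, 2L] %o% upv + min(pd) * rep(1, nrow(grid)) %o% d
  list(origins = origins, dir = d, right = right, up = upv,
       t_max = max(pd) - min(pd), nx = nx, ny = ny)
}

#' First-hit map of the opaque raycaster
#'
#' Marches one orthographic ray per pixel through the STC in `step`-voxel
#' increments; the first sampled voxel with a nonzero label that is not
#' suppressed by `mask` terminates the ray. This is the geometry half of
#' [render_stc()], exposed separately so the opacity contract can be
#' checked directly.
#'
#' @param stc an `stc_volume`.
#' @param settings an [render_settings()].
#' @param mask optional logical array of the STC's dimensions; FALSE voxels
#'   are skipped by the rays.
#' @return list with `id` (nx x ny integer matrix, 0 = no hit) and `voxel`
#'   (nx*ny x 3 matrix of 1-based hit voxel indices, NA where no hit).
#' @export
first_hit_map <- function(stc, settings, mask = NULL) {
  cam <- camera_rays(stc, settings)
  dims <- dim(stc$labels)
  n_ray <- nrow(cam$origins)
  hit_id <- integer(n_ray)
  hit_vox <- matrix(NA_integer_, n_ray, 3L)
  active <- rep(TRUE, n_ray)
  n_steps <- ceiling(cam$t_max / settings$step)
  for (s in seq_len(n_steps)) {
    if (!any(active)) break
    t_s <- (s - 0.5) * settings$step
    idx_active <- which(active)
    p <- cam$origins[idx_active, , drop = FALSE] +
      matrix(cam$dir, length(idx_active), 3L, byrow = TRUE) * t_s
    vox <- floor(p) + 1
    inside <- vox[, 1L] >= 1 & vox[, 1L] <= dims[1L] &
              vox[, 2L] >= 1 & vox[, 2L] <= dims[2L] &
              vox[, 3L] >= 1 & vox[, 3L] <= dims[3L]
    if (!any(inside)) next
    vin <- vox[inside, , drop = FALSE]
    storage.mode(vin) <- "integer"
    ids <- stc$labels[vin]
    ok <- ids != 0L
    if (!is.null(mask)) ok <- ok & mask[vin]
    if (!any(ok)) next
    ray_ids <- idx_active[inside][ok]
    hit_id[ray_ids] <- ids[ok]
    hit_vox[ray_ids, ] <- vin[ok, , drop = FALSE]
    active[ray_ids] <- FALSE
  }
  list(id = matrix(hit_id, cam$nx, cam$ny),
       voxel = hit_vox, cam = cam)
}

#' Render the STC with opaque Blinn-Phong shading
#'
#' Direct volume rendering with one orthographic ray per pixel and opaque
#' first-hit compositing (no semi-transparency). The hit voxel's base color
#' comes from the (id, time) lookup, overridden to pure red for highlighted
#' objects; the final color is
#' `ka*C + kd*max(N.L, 0)*C + ks*max(N.H, 0)^shininess`, clamped to
#' `[0, 1]`, with `N` the precomputed Sobel-Feldman normal, `L` the
#' direction to the movable point light and `H` the Blinn half-vector.
#' Filters and the optional cut suppress voxels at render time; the stored
#' STC is never modified.
#'
#' @param stc an `stc_volume`.
#' @param normals an [compute_normals()] result of matching dimensions.
#' @param lookup an [build_lookup()] result (NULL renders all objects with
#'   the sentinel color).
#' @param settings an [render_settings()].
#' @param filters optional [filter_state()]; hidden objects and filtered
#'   instances are skipped by rays, highlighted objects render red.
#' @param cut optional [cut_spec()]; voxels strictly on the discarded side
#'   are skipped.
#' @return RGB image array `ny x nx x 3` in `[0, 1]` (rows top to bottom),
#'   with the first-hit structure attached as attribute `"hits"`.
#' @export
render_stc <- function(stc, normals, lookup = NULL,
                       settings = render_settings(), filters = NULL,
                       cut = NULL) {
  dims <- dim(stc$labels)
  if (!identical(dim(normals)[1:3], dims))
    stc_validation_error("normal field dimensions do not match the STC")
  mask <- NULL
  if (!is.null(filters)) mask <- apply_filters(stc, lookup, filters)
  if (!is.null(cut)) {
    cm <- cut_mask(dims, cut)
    mask <- if (is.null(mask)) cm else (mask & cm)
  }
  hits <- first_hit_map(stc, settings, mask)
  nx <- hits$cam$nx; ny <- hits$cam$ny
  n_ray <- nx * ny
  img <- matrix(rep(settings$background, each = n_ray), n_ray, 3L)
  hit <- !is.na(hits$voxel[, 1L])
  if (any(hit)) {
    vox <- hits$voxel[hit, , drop = FALSE]
    ids <- stc$labels[vox]
    tt <- stc$times[vox[, 3L]]
    base <- matrix(0, length(ids), 3L)
    for (q in seq_along(ids)) {
      hl <- !is.null(filters) &&
        object_state_of(filters, ids[q]) == "highlighted"
      if (hl) {
        base[q, ] <- c(1, 0, 0)
      } else if (is.null(lookup)) {
        base[q, ] <- c(0.7, 0.7, 0.7)
      } else {
        base[q, ] <- grDevices::col2rgb(lookup_color(lookup, ids[q], tt[q]))[, 1L] / 255
      }
    }
    nmat <- cbind(normals[cbind(vox, 1L)], normals[cbind(vox, 2L)],
                  normals[cbind(vox, 3L)])
    centers <- vox - 0.5
    light <- settings$light %||% default_light(dims, settings)
    L <- normalize_rows(sweep(-centers, 2L, light, `+`))
    V <- -settings$view_dir
    H <- normalize_rows(sweep(L, 2L, V, `+`))
    ndl <- pmax(rowSums(nmat * L), 0)
    ndh <- pmax(rowSums(nmat * H), 0)
    shade <- settings$ka + settings$kd * ndl
    color <- base * shade + settings$ks * ndh^settings$shininess
    img[hit, ] <- pmin(pmax(color, 0), 1)
  }
  out <- array(0, dim = c(ny, nx, 3L))
  for (ch in 1:3) {
    m <- matrix(img[, ch], nx, ny)        # [i, j] with j increasing upward
    out[, , ch] <- t(m)[ny:1, , drop = FALSE]
  }
  attr(out, "hits") <- hits[c("id", "voxel")]
  out
}

default_light <- function(dims, settings) {
  center <- dims / 2
  center - settings$view_dir * max(dims) * 1.5 + c(0, 0, max(dims))
}

#' Cut specification for the STC
#'
#' A clipping plane in STC voxel coordinates. `keep = "positive"` retains
#' voxels whose center satisfies `(c - point) . normal >= 0`. A plane
#' perpendicular to the time axis gives time cutting, a plane containing
#' the time axis gives linear space cutting, and tilted planes give the
#' oblique cuts used to follow moving objects.
#'
#' @param point length-3 point in voxel coordinates.
#' @param normal length-3 nonzero vector.
#' @param keep `"positive"` or `"negative"` side.
#' @return an object of class `stc_cut`.
#' @export
cut_spec <- function(point, normal, keep = c("positive", "negative")) {
  keep <- match.arg(keep)
  if (vnorm(normal) == 0) stc_validation_error("cut normal must be nonzero")
  structure(list(point = as.numeric(point), normal = as.numeric(normal),
                 keep = keep),
            class = "stc_cut")
}

# Logical keep-mask of a cut over a grid of the given dimensions; voxel
# centers at (i - 0.5, j - 0.5, k - 0.5). The boundary (signed distance 0)
# belongs to the positive side, so a cut and its complement partition the
# grid.
cut_mask <- function(dims, cut) {
  di <- (seq_len(dims[1L]) - 0.5 - cut$point[1L]) * cut$normal[1L]
  dj <- (seq_len(dims[2L]) - 0.5 - cut$point[2L]) * cut$normal[2L]
  dk <- (seq_len(dims[3L]) - 0.5 - cut$point[3L]) * cut$normal[3L]
  signed <- outer(outer(di, dj, `+`), dk, `+`)
  if (cut$keep == "positive") signed >= 0 else signed < 0
}

#' Apply a cut to the STC
#'
#' Returns a copy of the STC in which voxels strictly on the discarded side
#' of the cut plane are set to background (0); voxels exactly on the plane
#' are kept.
#'
#' @param stc an `stc_volume`.
#' @param cut an [cut_spec()].
#' @return an `stc_volume`.
#' @export
cut_stc <- function(stc, cut) {
  keep <- cut_mask(dim(stc$labels), cut)
  stc$labels[!keep] <- 0L
  stc
}

#' Summarize the object under a voxel
#'
#' The detail-on-demand query behind the selection pointer: returns the
#' object id at a voxel together with its time step, mapped property value
#' and lineage context.
#'
#' @param stc an `stc_volume`.
#' @param voxel integer `c(i, j, k)` (1-based).
#' @param lookup optional [build_lookup()] for the mapped value.
#' @param lineage optional [lineage_tree()] for life interval / relatives.
#' @param annotations optional [annotation_table()]; all property values at
#'   the instance are included when given.
#' @return a list record; `background = TRUE` for background voxels.
#' @export
query_voxel <- function(stc, voxel, lookup = NULL, lineage = NULL,
                        annotations = NULL) {
  voxel <- as.integer(voxel)
  dims <- dim(stc$labels)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > dims))
    stc_validation_error("voxel index out of bounds")
  id <- stc$labels[voxel[1L], voxel[2L], voxel[3L]]
  t <- stc$times[voxel[3L]]
  if (id == 0L)
    return(list(background = TRUE, time = t, voxel = voxel))
  rec <- list(background = FALSE, id = id, time = t, voxel = voxel)
  if (!is.null(lookup)) {
    rec$property <- lookup$property
    rec$value <- lookup_value(lookup, id, t)
  }
  if (!is.null(lineage)) {
    node <- lineage_node(lineage, id)
    rec$t_birth <- node$t_birth
    rec$t_last <- node$t_last
    rec$parent <- if (is.na(node$parent_id)) NA_integer_ else node$parent_id
    rec$children <- lineage_children(lineage, id)
  }
  if (!is.null(annotations)) {
    tab <- annotations$table
    sel <- tab[tab$id == id & tab$t == t, c("property", "value")]
    rec$annotations <- stats::setNames(as.list(sel$value), sel$property)
  }
  rec
}
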