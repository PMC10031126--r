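#' Parameters for the synthetic dividing-embryo simulator
#'
#' The simulator emulates the structure of a cleavage-stage embryo time
#' lapse: sphere-like closed cells packed in an ellipsoid, binary divisions
#' every `division_period` frames with volume-conserving daughters, small
#' inter-frame motion, optional division asynchrony and an optional radial
#' cavity deformation mimicking gastrulation.
#'
#' @param n_initial_cells number of root cells at frame 0 (>= 1).
#' @param n_timesteps number of frames T (>= 1); frames run 0..T-1.
#' @param division_period frames between divisions, p (>= 1).
#' @param asynchrony integer vector of cell ids that skip exactly one
#'   division round (their division is delayed by one period).
#' @param jitter_sigma per-frame centroid motion scale in world units; each
#'   frame a cell is displaced from its base position by an independent
#'   zero-mean Gaussian vector with total standard deviation `jitter_sigma`.
#' @param cell_radius radius of a root cell in world units.
#' @param embryo_axes length-3 semi-axes of the packing ellipsoid; NULL for
#'   an automatic size that fits `n_initial_cells`.
#' @param bump_amplitude relative amplitude of the per-cell radial surface
#'   perturbation that breaks exact spherical symmetry (0 disables).
#' @param deformation NULL, or `list(amplitude =, onset =)` for a radial
#'   cavity pushing cells away from the embryo's vegetal pole from frame
#'   `onset` on; `amplitude` is in world units.
#' @param seed integer; all randomness derives from it.
#' @return an object of class `stc_sim_params`.
#' @export
simulation_params <- function(n_initial_cells = 2L, n_timesteps = 20L,
                              division_period = 7L, asynchrony = integer(),
                              jitter_sigma = 0.02, cell_radius = 1,
                              embryo_axes = NULL, bump_amplitude = 0.03,
                              deformation = NULL, seed = 1L) {
  n_initial_cells <- as.integer(n_initial_cells)
  n_timesteps <- as.integer(n_timesteps)
  division_period <- as.integer(division_period)
  if (is.na(n_initial_cells) || n_initial_cells < 1L)
    stc_validation_error("n_initial_cells must be >= 1")
  if (is.na(n_timesteps) || n_timesteps < 1L)
    stc_validation_error("n_timesteps must be >= 1")
  if (is.na(division_period) || division_period < 1L)
    stc_validation_error("division_period must be >= 1")
  if (jitter_sigma < 0) stc_validation_error("jitter_sigma must be >= 0")
  if (bump_amplitude < 0) stc_validation_error("bump_amplitude must be >= 0")
  if (!is.null(deformation)) {
    if (is.null(deformation$amplitude) || is.null(deformation$onset) ||
        deformation$amplitude < 0)
      stc_validation_error("deformation needs non-negative amplitude and an onset frame")
  }
  if (is.null(embryo_axes)) {
    a <- cell_radius * max(2.2, n_initial_cells^(1 / 3) * 1.7)
    embryo_axes <- c(a, a, 0.75 * a)
  }
  structure(list(
    n_initial_cells = n_initial_cells, n_timesteps = n_timesteps,
    division_period = division_period, asynchrony = as.integer(asynchrony),
    jitter_sigma = jitter_sigma, cell_radius = cell_radius,
    embryo_axes = as.numeric(embryo_axes), bump_amplitude = bump_amplitude,
    deformation = deformation, seed = as.integer(seed)
  ), class = "stc_sim_params")
}

# Per-cell low-frequency radial perturbation factors for unit-sphere vertex
# directions `u` (n x 3). Centered and max-normalized so that the volume of
# the perturbed cell stays within O(amp^2) of the unperturbed one.
bump_factors <- function(u, bump, amp) {
  if (amp == 0) return(rep(1, nrow(u)))
  g <- sin(u %*% bump$k1 + bump$p1) +
       sin(u %*% bump$k2 + bump$p2) +
       sin(u %*% bump$k3 + bump$p3)
  g <- g - mean(g)
  m <- max(abs(g))
  if (m > 0) g <- g / m
  1 + amp * as.vector(g)
}

cavity_displacement <- function(v, deformation, embryo_axes, t) {
  if (is.null(deformation) || t < deformation$onset) return(v)
  ramp <- min(1, (t - deformation$onset + 1) / 5)
  ccav <- c(0, 0, -embryo_axes[3L])
  sigma <- 0.6 * embryo_axes[3L]
  d <- sweep(v, 2L, ccav, `-`)
  dist <- pmax(sqrt(rowSums(d^2)), 1e-9)
  mag <- deformation$amplitude * ramp * exp(-dist^2 / (2 * sigma^2))
  v + d / dist * mag
}

#' Simulate a dividing synthetic embryo
#'
#' Generates a mesh-based temporal dataset, its ground-truth lineage and a
#' two-property annotation table (`volume` in world units cubed, measured
#' from each frame's mesh, and `remaining_lifespan` in frames until the
#' cell's scheduled division). Cells are icospheres (subdivision level 2)
#' with a small seeded radial perturbation; daughters conserve the parent's
#' volume (each daughter radius = parent radius * 2^(-1/3)) and are placed
#' astride the parent centre, separated by one daughter radius along a
#' seeded random axis, so sibling cells overlap/abut like blastomeres in a
#' real segmentation. Identical seeds produce identical output.
#'
#' @param params an [simulation_params()] object.
#' @return list with elements `dataset` (an `stc_dataset`), `lineage`
#'   (an `stc_lineage`), `annotations` (an `stc_annotations`) and `cells`
#'   (ground-truth table: id, parent_id, t_birth, t_last, divide_at,
#'   radius, base x/y/z).
#' @export
simulate_embryo <- function(params) {
  stopifnot(inherits(params, "stc_sim_params"))
  with_private_seed(params$seed, simulate_embryo_impl(params))
}

simulate_embryo_impl <- function(params) {
  p <- params$division_period
  T <- params$n_timesteps
  r0 <- params$cell_radius
  axes <- params$embryo_axes

  # -- root placement: sequential rejection sampling inside the ellipsoid
  place_roots <- function(n) {
    if (n == 1L) return(matrix(0, nrow = 1L, ncol = 3L))
    centers <- matrix(NA_real_, nrow = n, ncol = 3L)
    shrink <- pmax(axes - r0, 0.2 * axes)  # keep cells inside the hull
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        u <- stats::runif(3L, -1, 1)
        if (sum(u^2) > 1) next
        cand <- u * shrink
        if (i == 1L || all(sqrt(rowSums(sweep(
              centers[seq_len(i - 1L), , drop = FALSE], 2L, cand, `-`)^2)) >
              1.2 * r0)) { ok <- TRUE; break }
      }
      if (!ok) cand <- stats::runif(3L, -1, 1) * shrink  # dense packing fallback
      centers[i, ] <- cand
    }
    centers
  }

  divide_time <- function(id, t_birth) {
    d <- t_birth + p
    if (id %in% params$asynchrony) d <- d + p
    d
  }

  roots <- place_roots(params$n_initial_cells)
  cells <- data.frame(
    id = seq_len(params$n_initial_cells),
    parent_id = NA_integer_,
    t_birth = 0L, divide_at = NA_integer_,
    radius = r0, x = roots[, 1L], y = roots[, 2L], z = roots[, 3L])
  cells$divide_at <- vapply(cells$id, function(i) divide_time(i, 0L), integer(1))
  bumps <- list()
  new_bump <- function() list(k1 = stats::rnorm(3L), p1 = stats::runif(1L, 0, 2 * pi),
                              k2 = stats::rnorm(3L), p2 = stats::runif(1L, 0, 2 * pi),
                              k3 = stats::rnorm(3L), p3 = stats::runif(1L, 0, 2 * pi))
  for (i in seq_len(nrow(cells))) bumps[[i]] <- new_bump()

  # -- division schedule: process divisions in (time, parent id) order so
  # child ids are assigned deterministically
  repeat {
    due <- which(cells$divide_at <= T - 1L &
                   !(cells$id %in% cells$parent_id))
    if (!length(due)) break
    due <- due[order(cells$divide_at[due], cells$id[due])]
    i <- due[[1L]]
    d <- cells$divide_at[i]
    axis <- normalize(stats::rnorm(3L))
    rd <- cells$radius[i] * 2^(-1 / 3)
    parent_c <- c(cells$x[i], cells$y[i], cells$z[i])
    for (s in c(-0.5, 0.5)) {
      cid <- max(cells$id) + 1L
      cc <- parent_c + s * rd * axis
      cells <- rbind(cells, data.frame(
        id = cid, parent_id = cells$id[i], t_birth = d,
        divide_at = divide_time(cid, d), radius = rd,
        x = cc[1L], y = cc[2L], z = cc[3L]))
      bumps[[cid]] <- new_bump()
    }
  }
  divided <- cells$id %in% cells$parent_id
  cells$t_last <- ifelse(divided, cells$divide_at - 1L, T - 1L)

  # -- per-frame jitter, drawn in one deterministic block
  ncell <- nrow(cells)
  jit <- array(stats::rnorm(ncell * T * 3L, sd = params$jitter_sigma / sqrt(3)),
               dim = c(ncell, T, 3L))

  unit <- icosphere(2L, radius = 1)
  objects_by_time <- vector("list", T)
  ann_rows <- vector("list", ncell)
  for (i in seq_len(ncell)) {
    fac <- bump_factors(unit$vertices, bumps[[cells$id[i]]], params$bump_amplitude)
    base_v <- unit$vertices * fac * cells$radius[i]
    base_c <- c(cells$x[i], cells$y[i], cells$z[i])
    tt <- cells$t_birth[i]:cells$t_last[i]
    vol <- numeric(length(tt))
    for (j in seq_along(tt)) {
      t <- tt[[j]]
      ctr <- base_c + jit[i, t + 1L, ]
      v <- sweep(base_v, 2L, ctr, `+`)
      v <- cavity_displacement(v, params$deformation, axes, t)
      mesh <- stc_mesh(v, unit$faces)
      obj <- labeled_object(cells$id[i], mesh)
      objects_by_time[[t + 1L]] <- c(objects_by_time[[t + 1L]], list(obj))
      vol[[j]] <- mesh_volume(mesh)
    }
    ann_rows[[i]] <- rbind(
      data.frame(property = "volume", id = cells$id[i], t = tt, value = vol),
      data.frame(property = "remaining_lifespan", id = cells$id[i], t = tt,
                 value = cells$divide_at[i] - 1L - tt))
  }
  for (t in seq_len(T))
    if (is.null(objects_by_time[[t]])) objects_by_time[[t]] <- list()

  list(
    dataset = temporal_dataset(objects_by_time, check_watertight = FALSE),
    lineage = lineage_tree(cells[, c("id", "parent_id", "t_birth", "t_last")]),
    annotations = annotation_table(do.call(rbind, ann_rows)),
    cells = cells)
}
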