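# Independent oracles and fixture builders shared across the suite.

# Descendant closure by repeated frontier expansion over the raw edge table
# (independent of the package's traversal).
brute_descendants <- function(nodes, seed_id) {
  out <- as.integer(seed_id)
  repeat {
    kids <- nodes$id[!is.na(nodes$parent_id) & nodes$parent_id %in% out]
    grown <- sort(unique(c(out, kids)))
    if (identical(grown, out)) return(grown)
    out <- grown
  }
}

# Random lineage tree with <= n_max nodes and consistent life intervals:
# each node divides (two children) with probability p_div until the node
# budget runs out.
random_lineage <- function(n_max, p_div = 0.6) {
  nodes <- data.frame(id = 1L, parent_id = NA_integer_,
                      t_birth = 0L, t_last = sample(1:4, 1L))
  frontier <- 1L
  while (length(frontier) && nrow(nodes) + 2L <= n_max) {
    cur <- frontier[[1L]]; frontier <- frontier[-1L]
    if (stats::runif(1) > p_div) next
    b <- nodes$t_last[nodes$id == cur] + 1L
    for (q in 1:2) {
      id <- nrow(nodes) + 1L
      nodes <- rbind(nodes, data.frame(
        id = id, parent_id = cur, t_birth = b,
        t_last = b + sample(0:3, 1L)))
      frontier <- c(frontier, id)
    }
  }
  lineage_tree(nodes)
}

# One-object toy dataset: a sphere per listed frame (NULL drops the frame's
# object entirely).
sphere_dataset <- function(centers, ids, radius = 1, subdiv = 2L) {
  frames <- lapply(seq_along(centers), function(k) {
    if (is.null(centers[[k]])) return(list())
    lapply(seq_along(ids[[k]]), function(q)
      labeled_object(ids[[k]][q],
                     icosphere(subdiv, radius, centers[[k]][[q]])))
  })
  temporal_dataset(frames)
}

# Brute-force orthographic ray marcher at 0.25-voxel steps, axis-aligned
# view down -z (time axis); mirrors first_hit_map's sampling lattice but
# with a plain per-pixel loop and a 4x finer step.
brute_first_hit <- function(labels, mask = NULL) {
  d <- dim(labels)
  hits <- array(NA_integer_, dim = c(d[1L], d[2L], 3L))
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    for (s in seq_len(d[3L] * 4L)) {
      z <- d[3L] - (s - 0.5) * 0.25
      v <- c(i, j, floor(z) + 1L)
      if (v[3L] < 1L || v[3L] > d[3L]) next
      if (labels[v[1L], v[2L], v[3L]] == 0L) next
      if (!is.null(mask) && !mask[v[1L], v[2L], v[3L]]) next
      hits[i, j, ] <- as.integer(v)
      break
    }
  }
  hits
}

# Drop the label-image class/metadata, keeping the bare integer matrix.
strip_label <- function(img) {
  img <- unclass(img)
  attributes(img) <- list(dim = dim(img))
  img
}

# Small helper: a bare stc_volume around a raw label array (voxel units).
wrap_stc <- function(labels, times = seq_len(dim(labels)[3L]) - 1L) {
  structure(list(labels = labels, times = as.integer(times),
                 mode = "filled", pixel_size = 1, eps = 1,
                 plane = NULL, frame = NULL),
            class = "stc_volume")
}

# Cached small simulated embryo shared by several test files.
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_embryo(simulation_params(
        n_initial_cells = 1L, n_timesteps = 12L, division_period = 5L,
        jitter_sigma = 0.02, seed = 11L))
    cache
  }
})
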