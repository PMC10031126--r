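#' Labeled object
#'
#' One segmented object (a cell, in the embryo use case) at one time point:
#' a positive integer identifier plus its closed triangle surface.
#' ID 0 is reserved for background everywhere in the package.
#'
#' @param id positive integer object identifier.
#' @param mesh an [stc_mesh()] closed surface in world units.
#' @return an object of class `stc_labeled_object`.
#' @export
labeled_object <- function(id, mesh) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L) stc_validation_error("object id must be a positive integer")
  if (!inherits(mesh, "stc_mesh")) stc_validation_error("mesh must be an stc_mesh")
  structure(list(id = id, mesh = mesh), class = "stc_labeled_object")
}

#' Temporal dataset of labeled objects
#'
#' An ordered series of time steps (contiguous integer frames starting at 0),
#' each holding the labeled closed-surface objects present at that frame.
#' An alternative voxel-based representation is produced by
#' [label_volume_dataset()].
#'
#' @param objects_by_time list of length `T`; element `k` is a list of
#'   `stc_labeled_object`s present at frame `k - 1`.
#' @param check_watertight check each mesh for closedness (warning listing
#'   offending `(id, t)` on failure).
#' @return an object of class `stc_dataset` with fields `times`,
#'   `objects_by_time`, `world_bounds` (2 x 3 min/max matrix) and
#'   `geometry` (`"mesh"`).
#' @export
temporal_dataset <- function(objects_by_time, check_watertight = TRUE) {
  if (length(objects_by_time) < 1L)
    stc_validation_error("dataset must have at least one time step")
  lo <- Inf; hi <- -Inf
  bad <- character()
  for (k in seq_along(objects_by_time)) {
    objs <- objects_by_time[[k]]
    ids <- vapply(objs, function(o) o$id, integer(1))
    if (anyDuplicated(ids))
      stc_validation_error(sprintf("duplicate object ids at t=%d", k - 1L))
    for (o in objs) {
      b <- mesh_bounds(o$mesh)
      lo <- pmin(lo, b[1L, ]); hi <- pmax(hi, b[2L, ])
      if (check_watertight && !is_watertight(o$mesh))
        bad <- c(bad, sprintf("(id=%d, t=%d)", o$id, k - 1L))
    }
  }
  if (length(bad))
    warning("non-watertight meshes: ", paste(bad, collapse = ", "))
  structure(list(
    times = seq_along(objects_by_time) - 1L,
    objects_by_time = objects_by_time,
    world_bounds = rbind(lo, hi),
    geometry = "mesh"
  ), class = "stc_dataset")
}

#' Temporal dataset backed by labeled voxel volumes
#'
#' @param volumes list of 3D integer arrays (one per frame, equal dims);
#'   voxel value = object id, 0 = background.
#' @param origin world coordinates of the corner of voxel `[1,1,1]`.
#' @param spacing world size of one voxel along each axis (length 3).
#' @return an `stc_dataset` with `geometry = "labels"`.
#' @export
label_volume_dataset <- function(volumes, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (length(volumes) < 1L) stc_validation_error("need at least one frame")
  d <- dim(volumes[[1L]])
  if (length(d) != 3L) stc_validation_error("volumes must be 3D arrays")
  for (v in volumes)
    if (!identical(dim(v), d)) stc_validation_error("all frames must share dimensions")
  structure(list(
    times = seq_along(volumes) - 1L,
    volumes = volumes,
    origin = as.numeric(origin),
    spacing = as.numeric(spacing),
    world_bounds = rbind(origin, origin + d * spacing),
    geometry = "labels"
  ), class = "stc_dataset")
}

#' @export
print.stc_dataset <- function(x, ...) {
  cat(sprintf("<stc_dataset (%s): %d time steps>\n", x$geometry, length(x$times)))
  invisible(x)
}

# Object ids present at frame t (0-based).
dataset_ids_at <- function(dataset, t) {
  k <- t + 1L
  if (dataset$geometry == "mesh")
    vapply(dataset$objects_by_time[[k]], function(o) o$id, integer(1))
  else
    setdiff(sort(unique(as.vector(dataset$volumes[[k]]))), 0L)
}

#' Cell lineage tree
#'
#' Genealogy of object ids over time. Each node carries an inclusive life
#' interval `[t_birth, t_last]` in frames; edges link a parent to the
#' daughters created when it divides. Structural requirements (ids unique
#' and positive, at most one parent, parent must exist) are enforced here;
#' temporal ordering violations are reported by [validate_lineage()] rather
#' than rejected, so that imperfect tracking output can still be inspected.
#'
#' @param nodes data.frame with columns `id`, `parent_id` (NA for roots),
#'   `t_birth`, `t_last`.
#' @return an object of class `stc_lineage`.
#' @export
lineage_tree <- function(nodes) {
  nodes <- as.data.frame(nodes)
  req <- c("id", "parent_id", "t_birth", "t_last")
  if (!all(req %in% names(nodes)))
    stc_validation_error("nodes must have columns id, parent_id, t_birth, t_last")
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$t_birth <- as.integer(nodes$t_birth)
  nodes$t_last <- as.integer(nodes$t_last)
  if (anyDuplicated(nodes$id)) stc_validation_error("duplicate node ids")
  if (any(nodes$id < 1L)) stc_validation_error("node ids must be positive")
  known <- !is.na(nodes$parent_id)
  if (any(known & !(nodes$parent_id %in% nodes$id)))
    stc_validation_error("parent_id references an unknown node")
  if (any(known & nodes$parent_id == nodes$id))
    stc_validation_error("a node cannot be its own parent")
  structure(list(nodes = nodes[order(nodes$id), , drop = FALSE]),
            class = "stc_lineage")
}

#' @export
print.stc_lineage <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("<stc_lineage: %d nodes, %d roots, frames %d..%d>\n",
              nrow(n), sum(is.na(n$parent_id)), min(n$t_birth), max(n$t_last)))
  invisible(x)
}

lineage_node <- function(lineage, id) {
  i <- match(as.integer(id), lineage$nodes$id)
  if (is.na(i)) stc_not_found_error(sprintf("unknown object id %d in lineage", id))
  lineage$nodes[i, ]
}

lineage_children <- function(lineage, id) {
  lineage$nodes$id[!is.na(lineage$nodes$parent_id) &
                     lineage$nodes$parent_id == as.integer(id)]
}

#' Propagate a selection through the lineage
#'
#' Returns the seed object's id together with all of its descendants
#' (transitive closure over parent-to-daughter edges). A state change made
#' from this selection then applies to every temporal instance of every
#' returned id; ancestors are never affected.
#'
#' @param lineage an [lineage_tree()].
#' @param id seed object id.
#' @param t seed time index (frame); must lie inside the seed's life interval.
#' @return sorted integer vector of object ids.
#' @export
propagate_selection <- function(lineage, id, t) {
  node <- lineage_node(lineage, id)
  t <- as.integer(t)
  if (t < node$t_birth || t > node$t_last)
    stc_validation_error(sprintf(
      "time %d outside life interval [%d, %d] of object %d",
      t, node$t_birth, node$t_last, node$id))
  out <- integer(0)
  queue <- node$id
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, cur)
    queue <- c(queue, lineage_children(lineage, cur))
  }
  sort(unique(out))
}

#' Cross-check a lineage against a dataset
#'
#' Lists every inconsistency between the object instances present in a
#' dataset and the life intervals recorded in a lineage: instances outside
#' (or absent from) the lineage, lineage nodes never observed inside their
#' interval, and parent/child temporal ordering violations (a parent's
#' `t_last` must precede each child's `t_birth`).
#'
#' @param lineage an [lineage_tree()].
#' @param dataset an `stc_dataset`, or NULL to check only the lineage's
#'   internal ordering.
#' @return data.frame with columns `type`, `id`, `t`, `detail`; zero rows
#'   iff consistent.
#' @export
validate_lineage <- function(lineage, dataset = NULL) {
  rows <- list()
  add <- function(type, id, t, detail)
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, id = as.integer(id), t = as.integer(t), detail = detail)
  n <- lineage$nodes
  if (any(n$t_last < n$t_birth))
    for (i in which(n$t_last < n$t_birth))
      add("interval", n$id[i], n$t_birth[i], "t_last precedes t_birth")
  kids <- which(!is.na(n$parent_id))
  for (i in kids) {
    p <- n[match(n$parent_id[i], n$id), ]
    if (p$t_last >= n$t_birth[i])
      add("ordering", n$id[i], n$t_birth[i], sprintf(
        "parent %d t_last=%d >= child t_birth=%d", p$id, p$t_last, n$t_birth[i]))
  }
  if (!is.null(dataset)) {
    seen <- matrix(FALSE, nrow = nrow(n), ncol = length(dataset$times))
    for (t in dataset$times) {
      ids <- dataset_ids_at(dataset, t)
      for (id in ids) {
        i <- match(id, n$id)
        if (is.na(i)) {
          add("missing_node", id, t, "instance present in dataset but absent from lineage")
        } else if (t < n$t_birth[i] || t > n$t_last[i]) {
          add("outside_interval", id, t, sprintf(
            "instance at t=%d outside life interval [%d, %d]", t, n$t_birth[i], n$t_last[i]))
        } else {
          seen[i, t + 1L] <- TRUE
        }
      }
    }
    tmax <- max(dataset$times)
    for (i in seq_len(nrow(n))) {
      tt <- n$t_birth[i]:min(n$t_last[i], tmax)
      if (n$t_birth[i] > tmax) next
      missing_t <- tt[!seen[i, tt + 1L]]
      for (t in missing_t)
        add("missing_instance", n$id[i], t,
            "lineage expects an instance that the dataset lacks")
    }
  }
  if (!length(rows))
    return(data.frame(type = character(), id = integer(), t = integer(),
                      detail = character()))
  do.call(rbind, rows)
}

#' Shared filter state
#'
#' The single state object consumed by both the STC render and the
#' cross-section preview: a value range on the currently mapped property,
#' an inclusive time window, per-object display states and the current
#' time cursor.
#'
#' @param value_range numeric `c(lo, hi)` or NULL for "all".
#' @param time_window integer `c(t0, t1)` inclusive or NULL for "all".
#' @param object_states named character vector (names = ids) with values in
#'   `c("normal", "highlighted", "hidden")`; ids not present are "normal".
#' @param current_time time cursor shown on the mesh preview (frames).
#' @return an object of class `stc_filter_state`.
#' @export
filter_state <- function(value_range = NULL, time_window = NULL,
                         object_states = character(), current_time = 0L) {
  if (!is.null(value_range)) {
    if (length(value_range) != 2L || value_range[1L] > value_range[2L])
      stc_validation_error("value_range must be c(lo, hi) with lo <= hi")
  }
  if (!is.null(time_window)) {
    time_window <- as.integer(time_window)
    if (length(time_window) != 2L || time_window[1L] > time_window[2L] ||
        time_window[1L] < 0L)
      stc_validation_error("time_window must be c(t0, t1) with 0 <= t0 <= t1")
  }
  if (length(object_states) &&
      !all(object_states %in% c("normal", "highlighted", "hidden")))
    stc_validation_error("object states must be normal/highlighted/hidden")
  structure(list(value_range = value_range, time_window = time_window,
                 object_states = object_states,
                 current_time = as.integer(current_time)),
            class = "stc_filter_state")
}

#' @export
print.stc_filter_state <- function(x, ...) {
  vr <- if (is.null(x$value_range)) "all" else
    sprintf("[%g, %g]", x$value_range[1L], x$value_range[2L])
  tw <- if (is.null(x$time_window)) "all" else
    sprintf("[%d, %d]", x$time_window[1L], x$time_window[2L])
  cat(sprintf("<stc_filter_state: values %s, time %s, %d object state(s), cursor t=%d>\n",
              vr, tw, length(x$object_states), x$current_time))
  invisible(x)
}

object_state_of <- function(state, id) {
  s <- state$object_states[as.character(id)]
  if (is.na(s)) "normal" else unname(s)
}
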