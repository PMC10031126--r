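#' Value filter
#'
#' Restricts the displayed objects to those whose currently mapped value
#' lies inside `[lo, hi]`. The range is stored on the shared filter state;
#' suppression is evaluated per (id, t) instance at mask time, so a cell
#' can enter and leave the range over its life. Instances with no recorded
#' value are kept (and render with the sentinel color).
#'
#' @param state an [filter_state()].
#' @param lookup an [build_lookup()] for the mapped property (kept for
#'   interface symmetry; the range applies to whichever lookup is active
#'   when masks are computed).
#' @param lo,hi numeric bounds, `lo <= hi`.
#' @return the updated `stc_filter_state`.
#' @export
value_filter <- function(state, lookup, lo, hi) {
  if (lo > hi) stc_validation_error("value filter needs lo <= hi")
  state$value_range <- c(lo, hi)
  state
}

#' Time filter
#'
#' Constrains rendering and queries to the inclusive frame window
#' `[t0, t1]`; the preview time cursor is clamped into the window.
#'
#' @param state an [filter_state()].
#' @param t0,t1 frame indices, `0 <= t0 <= t1`.
#' @return the updated `stc_filter_state`.
#' @export
time_filter <- function(state, t0, t1) {
  t0 <- as.integer(t0); t1 <- as.integer(t1)
  if (is.na(t0) || is.na(t1) || t0 < 0L || t0 > t1)
    stc_validation_error("time filter needs 0 <= t0 <= t1")
  if (!is.null(state$time_window)) {
    t0 <- max(t0, state$time_window[1L])
    t1 <- min(t1, state$time_window[2L])
    if (t0 > t1) stc_validation_error("time windows do not overlap")
  }
  state$time_window <- c(t0, t1)
  state$current_time <- min(max(state$current_time, t0), t1)
  state
}

#' Set the display state of an object and its descendants
#'
#' Applies `new_state` to the seed object and, through
#' [propagate_selection()], to all of its descendants; the state then holds
#' for every temporal instance of each affected id (ancestors are not
#' touched). `new_state = "next"` cycles the seed's current state in the
#' order normal -> highlighted -> hidden -> normal.
#'
#' @param state an [filter_state()].
#' @param lineage an [lineage_tree()].
#' @param id,t seed object id and a frame inside its life interval.
#' @param new_state one of `"normal"`, `"highlighted"`, `"hidden"`,
#'   `"next"`.
#' @return the updated `stc_filter_state`.
#' @export
set_object_state <- function(state, lineage, id, t,
                             new_state = c("next", "normal", "highlighted",
                                           "hidden")) {
  new_state <- match.arg(new_state)
  ids <- propagate_selection(lineage, id, t)
  if (new_state == "next") {
    cycle <- c(normal = "highlighted", highlighted = "hidden",
               hidden = "normal")
    new_state <- cycle[[object_state_of(state, id)]]
  }
  st <- state$object_states
  st[as.character(ids)] <- new_state
  st <- st[st != "normal"]
  state$object_states <- st
  state
}

# Individual filter masks; each is a logical array over the STC grid.
mask_time <- function(stc, state) {
  dims <- dim(stc$labels)
  m <- array(TRUE, dims)
  if (!is.null(state$time_window)) {
    out <- !(stc$times >= state$time_window[1L] &
               stc$times <= state$time_window[2L])
    m[, , out] <- FALSE
  }
  m
}

mask_objects <- function(stc, state) {
  dims <- dim(stc$labels)
  m <- array(TRUE, dims)
  hidden <- as.integer(names(state$object_states)[state$object_states == "hidden"])
  if (length(hidden)) m[stc$labels %in% hidden] <- FALSE
  m
}

mask_value <- function(stc, lookup, state) {
  dims <- dim(stc$labels)
  m <- array(TRUE, dims)
  if (is.null(state$value_range) || is.null(lookup) ||
      lookup$kind != "numeric")
    return(m)
  lo <- state$value_range[1L]; hi <- state$value_range[2L]
  for (k in seq_len(dims[3L])) {
    slice <- stc$labels[, , k]
    ids <- setdiff(unique(as.vector(slice)), 0L)
    if (!length(ids)) next
    t <- stc$times[k]
    vals <- vapply(ids, function(id) as.numeric(lookup_value(lookup, id, t)),
                   numeric(1))
    drop_ids <- ids[!is.na(vals) & (vals < lo | vals > hi)]
    if (length(drop_ids)) {
      ms <- m[, , k]
      ms[slice %in% drop_ids] <- FALSE
      m[, , k] <- ms
    }
  }
  m
}

#' Combined filter mask
#'
#' The conjunction of the value, time and object-state masks: TRUE where a
#' voxel survives all three. The same [filter_state()] object drives both
#' the STC render and the cross-section preview, so any filtering applied
#' to one view is applied to the other. The stored STC is immutable;
#' filtering only masks it.
#'
#' @param stc an `stc_volume`.
#' @param lookup the active [build_lookup()] (may be NULL; the value filter
#'   is then inactive).
#' @param state an [filter_state()].
#' @param component `"all"` or one of `"value"`, `"time"`, `"object"` for
#'   an individual mask.
#' @return logical array with the STC's dimensions.
#' @export
filter_mask <- function(stc, lookup, state,
                        component = c("all", "value", "time", "object")) {
  component <- match.arg(component)
  switch(component,
         value = mask_value(stc, lookup, state),
         time = mask_time(stc, state),
         object = mask_objects(stc, state),
         all = mask_value(stc, lookup, state) & mask_time(stc, state) &
           mask_objects(stc, state))
}

#' @rdname filter_mask
#' @export
apply_filters <- function(stc, lookup, state) {
  filter_mask(stc, lookup, state, "all")
}

#' Read / write the shared filter state as YAML
#'
#' Keys: `value_range`, `time_window`, `current_time`, `object_states`
#' (map id -> state). Absent keys mean "no constraint".
#'
#' @param path file path.
#' @param state an [filter_state()] (writer only).
#' @return `read_filter_state`: an `stc_filter_state`.
#' @export
read_filter_state <- function(path) {
  y <- yaml::read_yaml(path)
  os <- character()
  if (!is.null(y$object_states))
    os <- stats::setNames(unlist(y$object_states), names(y$object_states))
  filter_state(value_range = if (!is.null(y$value_range)) as.numeric(y$value_range),
               time_window = if (!is.null(y$time_window)) as.integer(y$time_window),
               object_states = os,
               current_time = y$current_time %||% 0L)
}

#' @rdname read_filter_state
#' @export
write_filter_state <- function(state, path) {
  y <- list()
  if (!is.null(state$value_range)) y$value_range <- state$value_range
  if (!is.null(state$time_window)) y$time_window <- state$time_window
  y$current_time <- state$current_time
  if (length(state$object_states)) y$object_states <- as.list(state$object_states)
  yaml::write_yaml(y, path)
  invisible(path)
}
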