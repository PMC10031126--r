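# --- mesh files ------------------------------------------------------------

#' Read / write triangle meshes (ASCII PLY and OBJ)
#'
#' Minimal ASCII readers/writers for the two mesh interchange formats used
#' by segmented-embryo pipelines; vertex positions and triangular faces
#' only. Writers are deterministic (no timestamps).
#'
#' @param mesh an [stc_mesh()].
#' @param path file path; format chosen by extension (`.ply` / `.obj`).
#' @return `read_mesh`: an `stc_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(v)),
                "property float x", "property float y", "property float z",
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    writeLines(header, con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  } else if (ext == "obj") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  } else {
    stc_format_error(sprintf("unsupported mesh format '%s'", ext))
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "ply") {
    if (!length(lines) || lines[[1L]] != "ply")
      stc_format_error("not a PLY file")
    end <- match("end_header", lines)
    if (is.na(end)) stc_format_error("PLY header not terminated")
    header <- lines[seq_len(end)]
    if (!any(grepl("^format ascii", header)))
      stc_format_error("only ASCII PLY is supported")
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)))
    body <- lines[(end + 1L):length(lines)]
    vt <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                function(x) as.numeric(x[1:3])))
    ft <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                function(x) as.integer(x[2:4]) + 1L))
    stc_mesh(vt, ft)
  } else if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    vt <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                function(x) as.numeric(x[2:4])))
    ft <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
    stc_mesh(vt, ft)
  } else {
    stc_format_error(sprintf("unsupported mesh format '%s'", ext))
  }
}

# --- lineage and annotation CSV --------------------------------------------

#' Read / write lineage and annotation CSV tables
#'
#' Lineage: header `id,parent_id,t_birth,t_last`, `parent_id` empty for
#' roots. Annotations: long format, header `property,id,t,value`.
#'
#' @param lineage an [lineage_tree()].
#' @param annotations an [annotation_table()].
#' @param path file path.
#' @return readers return the corresponding object.
#' @export
write_lineage_csv <- function(lineage, path) {
  utils::write.csv(lineage$nodes, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_lineage_csv
#' @export
read_lineage_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  lineage_tree(df)
}

#' @rdname write_lineage_csv
#' @export
write_annotations_csv <- function(annotations, path) {
  df <- annotations$table
  if (is.numeric(df$value)) df$value <- sprintf("%.10g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_lineage_csv
#' @export
read_annotations_csv <- function(path) {
  annotation_table(utils::read.csv(path, na.strings = ""))
}

# --- dataset directories ---------------------------------------------------

#' Write / read a temporal dataset directory
#'
#' A dataset directory holds one mesh file per (object, time) instance plus
#' a `manifest.json` mapping each file to its `(id, t)`, or a set of
#' labeled volume files (one multi-page TIFF or NRRD per frame) with a
#' manifest mapping each file to its `t`. `write_dataset` emits PLY meshes.
#'
#' @param dataset an `stc_dataset` (mesh geometry for the writer).
#' @param dir directory path.
#' @return `read_dataset`: an `stc_dataset`. Missing frames raise a gap
#'   error listing the absent time indices; files referenced by the
#'   manifest but absent on disk raise a gap error too.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(dataset$geometry == "mesh")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  items <- list()
  for (k in seq_along(dataset$times)) {
    t <- dataset$times[k]
    for (obj in dataset$objects_by_time[[k]]) {
      fn <- sprintf("t%03d_id%05d.ply", t, obj$id)
      write_mesh(obj$mesh, file.path(dir, fn))
      items[[length(items) + 1L]] <- list(file = fn, id = obj$id, t = t)
    }
  }
  manifest <- list(type = "mesh", n_timesteps = length(dataset$times),
                   items = items)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stc_format_error("manifest.json not found")
  manifest <- jsonlite::read_json(mpath)
  items <- manifest$items
  ts <- vapply(items, function(x) as.integer(x$t), integer(1))
  T <- as.integer(manifest$n_timesteps %||% (max(ts) + 1L))
  missing_t <- setdiff(0:(T - 1L), unique(ts))
  if (length(missing_t))
    stc_stop(sprintf("missing frames in dataset: t = %s",
                     paste(missing_t, collapse = ", ")),
             c("stcGapError", "stcFormatError"))
  absent <- vapply(items, function(x) !file.exists(file.path(dir, x$file)),
                   logical(1))
  if (any(absent))
    stc_stop(sprintf("manifest references missing files: %s",
                     paste(vapply(items[absent], `[[`, "", "file"),
                           collapse = ", ")),
             c("stcGapError", "stcFormatError"))
  if (identical(manifest$type, "labels")) {
    vols <- vector("list", T)
    for (x in items)
      vols[[as.integer(x$t) + 1L]] <- read_label_volume(file.path(dir, x$file))
    return(label_volume_dataset(
      vols,
      origin = as.numeric(unlist(manifest$origin %||% c(0, 0, 0))),
      spacing = as.numeric(unlist(manifest$spacing %||% c(1, 1, 1)))))
  }
  objects_by_time <- rep(list(list()), T)
  for (x in items) {
    mesh <- read_mesh(file.path(dir, x$file))
    k <- as.integer(x$t) + 1L
    objects_by_time[[k]] <- c(objects_by_time[[k]],
                              list(labeled_object(as.integer(x$id), mesh)))
  }
  temporal_dataset(objects_by_time)
}

#' Write a full simulation to a dataset directory
#'
#' Writes per-frame PLY meshes with their manifest, the lineage CSV and
#' the annotations CSV, as produced by [simulate_embryo()].
#'
#' @param sim the list returned by [simulate_embryo()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_dataset(sim$dataset, dir)
  write_lineage_csv(sim$lineage, file.path(dir, "lineage.csv"))
  write_annotations_csv(sim$annotations, file.path(dir, "annotations.csv"))
  invisible(dir)
}

# --- label volumes (multi-page TIFF / NRRD) --------------------------------

# Labels are stored as 32-bit pages; tiff encodes integer samples on a
# [0, 1] scale, so values are divided by (2^32 - 1) on write and recovered
# exactly (as R integers) with as.is on read. Ids must stay below 2^31.
TIFF_SCALE <- 2^32 - 1

check_label_range <- function(labels) {
  if (max(labels) >= 2^31)
    stc_format_error("object ids must be < 2^31 for 32-bit label storage")
}

write_label_tiff <- function(labels, path) {
  check_label_range(labels)
  pages <- lapply(seq_len(dim(labels)[3L]),
                  function(k) t(labels[, , k]) / TIFF_SCALE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  labels <- array(0L, dim = c(d[2L], d[1L], length(pages)))
  for (k in seq_along(pages)) labels[, , k] <- t(pages[[k]])
  labels
}

write_label_nrrd <- function(labels, path) {
  check_label_range(labels)
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(labels)
  header <- c("NRRD0004", "type: int32", "dimension: 3",
              sprintf("sizes: %d %d %d", d[1L], d[2L], d[3L]),
              "encoding: raw", "endian: little", "")
  writeLines(header, con, sep = "\n")
  writeBin(as.integer(labels), con, size = 4L, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || line == "") break
    header <- c(header, line)
  }
  if (!length(header) || !startsWith(header[[1L]], "NRRD"))
    stc_format_error("not a NRRD file")
  field <- function(name) {
    x <- grep(paste0("^", name, ": "), header, value = TRUE)
    if (!length(x)) return(NULL)
    sub(paste0("^", name, ": "), "", x[[1L]])
  }
  type <- field("type")
  sizes <- as.integer(strsplit(field("sizes"), " ")[[1L]])
  if (!identical(field("encoding"), "raw"))
    stc_format_error("only raw NRRD encoding is supported")
  n <- prod(sizes)
  data <- if (type %in% c("int32", "int", "uint32"))
    readBin(con, "integer", n = n, size = 4L, endian = "little")
  else if (type %in% c("float", "float32"))
    readBin(con, "double", n = n, size = 4L, endian = "little")
  else stc_format_error(sprintf("unsupported NRRD type '%s'", type))
  array(data, dim = sizes)
}

read_label_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) read_label_tiff(path)
  else if (ext == "nrrd") {
    a <- read_nrrd(path)
    storage.mode(a) <- "integer"
    a
  } else stc_format_error(sprintf("unsupported label volume format '%s'", ext))
}

# --- the STC itself --------------------------------------------------------

#' Write / read a space-time cube
#'
#' The label grid goes to a multi-page TIFF (page = time slice, 32-bit) or
#' a raw NRRD, selected by extension; a JSON manifest with the same stem
#' records the plane, frame, slab half-thickness, mode, times and voxel
#' size. A precomputed normal field can be cached alongside as a float
#' NRRD (`<stem>_normals.nrrd`).
#'
#' @param stc an `stc_volume`.
#' @param path `.tif`/`.tiff` or `.nrrd` path.
#' @param normals optional [compute_normals()] result to cache.
#' @return `read_stc`: an `stc_volume` (with `normals` attached when a
#'   cache file is present). Grid/manifest dimension mismatches raise a
#'   format error.
#' @export
write_stc <- function(stc, path, normals = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) write_label_tiff(stc$labels, path)
  else if (ext == "nrrd") write_label_nrrd(stc$labels, path)
  else stc_format_error(sprintf("unsupported STC format '%s'", ext))
  stem <- sub(paste0("\\.", ext, "$"), "", path)
  manifest <- list(
    dims = dim(stc$labels),
    plane = list(point = stc$plane$point, normal = stc$plane$normal,
                 u_axis = stc$plane$u_axis, v_axis = stc$plane$v_axis),
    frame = list(origin = stc$frame$origin, width = stc$frame$width,
                 height = stc$frame$height,
                 resolution = stc$frame$resolution,
                 pixel_size = stc$frame$pixel_size),
    eps = stc$eps, mode = stc$mode, times = stc$times,
    voxel_size = c(stc$pixel_size, stc$pixel_size, 1))
  jsonlite::write_json(manifest, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(normals)) {
    con <- file(paste0(stem, "_normals.nrrd"), "wb")
    d <- dim(normals)
    header <- c("NRRD0004", "type: float", "dimension: 4",
                sprintf("sizes: %d %d %d %d", d[1L], d[2L], d[3L], d[4L]),
                "encoding: raw", "endian: little", "")
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(unclass(normals)), con, size = 4L, endian = "little")
    close(con)
  }
  invisible(path)
}

#' @rdname write_stc
#' @export
read_stc <- function(path) {
  ext <- tolower(tools::file_ext(path))
  labels <- read_label_volume(path)
  stem <- sub(paste0("\\.", ext, "$"), "", path)
  mpath <- paste0(stem, ".json")
  if (!file.exists(mpath)) stc_format_error("STC manifest not found")
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(as.integer(m$dims), as.integer(dim(labels))))
    stc_format_error(sprintf(
      "manifest dimensions (%s) do not match stored grid (%s)",
      paste(m$dims, collapse = "x"), paste(dim(labels), collapse = "x")))
  plane <- structure(list(point = m$plane$point, normal = m$plane$normal,
                          u_axis = m$plane$u_axis, v_axis = m$plane$v_axis),
                     class = "stc_plane")
  frame <- structure(list(origin = m$frame$origin, u_axis = m$plane$u_axis,
                          v_axis = m$plane$v_axis, normal = m$plane$normal,
                          width = m$frame$width, height = m$frame$height,
                          resolution = as.integer(m$frame$resolution),
                          pixel_size = m$frame$pixel_size, eps = m$eps),
                     class = "stc_frame")
  stc <- structure(list(labels = labels, plane = plane, frame = frame,
                        mode = m$mode, times = as.integer(m$times),
                        pixel_size = m$frame$pixel_size, eps = m$eps),
                   class = "stc_volume")
  npath <- paste0(stem, "_normals.nrrd")
  if (file.exists(npath)) {
    a <- read_nrrd(npath)
    stc$normals <- structure(a, class = "stc_normals")
  }
  stc
}

#' Write a rendered image as PNG
#'
#' @param img RGB array from [render_stc()] (attributes are dropped).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_render_png <- function(img, path) {
  a <- array(as.vector(img), dim = dim(img))
  png::writePNG(a, path)
  invisible(path)
}
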