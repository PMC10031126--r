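#' Per-(object, time) annotation table
#'
#' Long-format table of numerical or categorical measurements attached to
#' object instances: one row per `(property, id, t)`. Missing entries are
#' allowed; the color lookup machinery maps them to a sentinel color.
#'
#' @param df data.frame with columns `property`, `id`, `t`, `value`.
#' @return an object of class `stc_annotations`.
#' @export
annotation_table <- function(df) {
  df <- as.data.frame(df)
  req <- c("property", "id", "t", "value")
  if (!all(req %in% names(df)))
    stc_validation_error("annotations need columns property, id, t, value")
  df$property <- as.character(df$property)
  df$id <- as.integer(df$id)
  df$t <- as.integer(df$t)
  if (any(df$id < 1L)) stc_validation_error("annotation ids must be positive")
  if (anyDuplicated(df[, c("property", "id", "t")]))
    stc_validation_error("duplicate (property, id, t) annotation rows")
  structure(list(table = df[, req]), class = "stc_annotations")
}

#' @export
print.stc_annotations <- function(x, ...) {
  cat(sprintf("<stc_annotations: %d rows, properties: %s>\n",
              nrow(x$table), paste(annotation_properties(x), collapse = ", ")))
  invisible(x)
}

#' Property names present in an annotation table
#' @param annotations an [annotation_table()].
#' @return character vector.
#' @export
annotation_properties <- function(annotations) {
  sort(unique(annotations$table$property))
}

# Rows for one property; value coerced to numeric when every entry parses.
annotation_slice <- function(annotations, property) {
  df <- annotations$table[annotations$table$property == property, , drop = FALSE]
  if (!nrow(df))
    stc_not_found_error(sprintf("unknown annotation property '%s'", property))
  if (!is.numeric(df$value)) {
    num <- suppressWarnings(as.numeric(df$value))
    if (!anyNA(num)) df$value <- num
  }
  df
}
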