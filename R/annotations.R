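#' Annotation set for one image
#'
#' Holds the ground-truth stoma boxes of an image plus any labeled regions
#' sampled from it. Boxes are stored as data frames with 0-based half-open
#' coordinates (columns `row0, col0, height, width`, plus `label` for
#' regions).
#'
#' @param image_id Image identifier.
#' @param stomata Data frame of ground-truth boxes (may have 0 rows).
#' @param regions Data frame of labeled-region boxes with a `label` column.
#' @param window_shape The `(height, width)` used for labeled regions.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, stomata = empty_boxes(),
                           regions = empty_boxes(label = TRUE),
                           window_shape = c(151L, 258L)) {
  stomata <- as_box_df(stomata, label = FALSE)
  regions <- as_box_df(regions, label = TRUE)
  if (nrow(stomata) > 1L &&
      anyDuplicated(stomata[c("row0", "col0", "height", "width")]))
    stop("ground-truth stoma boxes must be pairwise distinct", call. = FALSE)
  structure(list(image_id = as.character(image_id),
                 window_shape = as.integer(window_shape),
                 stomata = stomata, regions = regions),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set '%s': %d stomata, %d labeled regions, window %d x %d>\n",
              x$image_id, nrow(x$stomata), nrow(x$regions),
              x$window_shape[1], x$window_shape[2]))
  invisible(x)
}

empty_boxes <- function(label = FALSE) {
  df <- data.frame(row0 = integer(0), col0 = integer(0),
                   height = integer(0), width = integer(0))
  if (label) df$label <- character(0)
  df
}

as_box_df <- function(x, label = FALSE) {
  need <- c("row0", "col0", "height", "width", if (label) "label")
  if (is.null(x) || length(x) == 0L ||
      (is.data.frame(x) && nrow(x) == 0L))
    return(empty_boxes(label))
  x <- as.data.frame(x)
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("box table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  x <- x[need]
  for (i in seq_len(nrow(x))) validate_box_record(x[i, ], i)
  for (col in c("row0", "col0", "height", "width"))
    x[[col]] <- as.integer(x[[col]])
  rownames(x) <- NULL
  x
}

validate_box_record <- function(rec, idx) {
  bad <- function(why)
    stop(sprintf("invalid box record %d: %s", idx, why), call. = FALSE)
  if (any(!is.finite(unlist(rec[c("row0", "col0", "height", "width")]))))
    bad("non-finite coordinate")
  if (rec$row0 < 0 || rec$col0 < 0) bad("negative origin")
  if (rec$height <= 0 || rec$width <= 0) bad("non-positive extent")
  if (!is.null(rec$label) && !rec$label %in% c("stoma", "non_stoma"))
    bad(sprintf("unknown label '%s'", rec$label))
  invisible(TRUE)
}

#' Read / write annotation sets
#'
#' Annotations are stored as JSON with the schema
#' `{image_id, window_shape, stomata: [{row0, col0, height, width}],
#' regions: [{row0, col0, height, width, label}]}`. Writing then reading
#' is the identity on the data model. A flat CSV export
#' ([write_annotations_csv]) carries the same columns plus a `kind` column.
#'
#' @param path Path to a `.json` annotation file.
#' @return [read_annotations] returns an [annotation_set].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    stop(sprintf("annotation file not found: '%s'", path), call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (field in c("image_id", "window_shape"))
    if (is.null(raw[[field]]))
      stop(sprintf("annotation schema violation in '%s': missing '%s'",
                   path, field), call. = FALSE)
  annotation_set(raw$image_id,
                 stomata = raw$stomata,
                 regions = raw$regions,
                 window_shape = raw$window_shape)
}

#' @rdname read_annotations
#' @param ann An [annotation_set].
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  jsonlite::write_json(
    list(image_id = ann$image_id,
         window_shape = ann$window_shape,
         stomata = ann$stomata,
         regions = ann$regions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_annotations
#' @export
write_annotations_csv <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  st <- ann$stomata
  rg <- ann$regions
  st$label <- rep("", nrow(st))
  st$kind <- rep("stoma_truth", nrow(st))
  rg$kind <- rep("region", nrow(rg))
  out <- rbind(st, rg)
  out$image_id <- rep(ann$image_id, nrow(out))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Dataset manifest
#'
#' A table of images and their annotation files; image ids must be unique and
#' every referenced file must exist.
#'
#' @param image_paths,annotation_paths Parallel character vectors.
#' @param image_ids Unique identifiers (default: file names).
#' @return A data frame of class `dataset_manifest`.
#' @export
dataset_manifest <- function(image_paths, annotation_paths,
                             image_ids = NULL) {
  if (length(image_paths) != length(annotation_paths))
    stop("image_paths and annotation_paths must have equal length",
         call. = FALSE)
  if (is.null(image_ids))
    image_ids <- tools::file_path_sans_ext(basename(image_paths))
  if (anyDuplicated(image_ids))
    stop("image_ids must be unique", call. = FALSE)
  missing <- c(image_paths, annotation_paths)
  missing <- missing[!file.exists(missing)]
  if (length(missing))
    stop(sprintf("manifest references missing file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- data.frame(image_id = image_ids, image_path = image_paths,
                    annotation_path = annotation_paths,
                    stringsAsFactors = FALSE)
  class(out) <- c("dataset_manifest", "data.frame")
  out
}
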