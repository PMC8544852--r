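# Sliding-window stomata detection: grid construction, window
# classification, occurrence-matrix accumulation, region merging, heatmaps.

#' Sliding-window grid
#'
#' Full-windows-only convention: origins are `(i*s, j*s)` for all `i, j >= 0`
#' with `i*s + h <= H` and `j*s + w <= W`, in row-major order, so the grid
#' has `floor((H-h)/s) + 1` rows and `floor((W-w)/s) + 1` columns of
#' windows. No partial or padded windows are generated.
#'
#' @param image_shape `(H, W)` of the image.
#' @param window_shape `(h, w)` of each window.
#' @param stride Stride in px, applied to both axes.
#' @return An object of class `window_grid`: list with `image_shape`,
#'   `window_shape`, `stride`, `origins` (2-column matrix of 0-based
#'   `(row0, col0)`).
#' @export
build_window_grid <- function(image_shape, window_shape = c(151L, 258L),
                              stride = 100L) {
  image_shape <- as.integer(image_shape)
  window_shape <- as.integer(window_shape)
  stride <- as.integer(stride)
  if (image_shape[1] < window_shape[1] || image_shape[2] < window_shape[2])
    stop(sprintf("image %d x %d is smaller than the window %d x %d",
                 image_shape[1], image_shape[2],
                 window_shape[1], window_shape[2]), call. = FALSE)
  if (stride < 1L) stop("stride must be positive", call. = FALSE)
  row0 <- seq.int(0L, image_shape[1] - window_shape[1], by = stride)
  col0 <- seq.int(0L, image_shape[2] - window_shape[2], by = stride)
  origins <- cbind(row0 = rep(row0, each = length(col0)),
                   col0 = rep(col0, times = length(row0)))
  structure(list(image_shape = image_shape, window_shape = window_shape,
                 stride = stride, origins = origins), class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid: %d windows (%d x %d px, stride %d) over %d x %d>\n",
              nrow(x$origins), x$window_shape[1], x$window_shape[2],
              x$stride, x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Classify every window of a grid
#'
#' Crops each window, extracts the model's descriptor and predicts; label
#' order matches the grid's origin order. A `classifier_fn` can replace the
#' model (e.g. a ground-truth oracle for pipeline tests): it receives the
#' grid and the image and must return one label per origin.
#'
#' @param image A [stoma_image].
#' @param grid A [build_window_grid] result matching the image shape.
#' @param model A [stoma_model] whose descriptor spec is set.
#' @param classifier_fn Optional `function(image, grid)` overriding the
#'   model.
#' @return Character vector of labels, one per origin.
#' @export
classify_windows <- function(image, grid, model = NULL,
                             classifier_fn = NULL) {
  stopifnot(inherits(grid, "window_grid"))
  if (!is.null(classifier_fn)) {
    labels <- classifier_fn(image, grid)
    stopifnot(length(labels) == nrow(grid$origins))
    return(labels)
  }
  stopifnot(inherits(model, "stoma_model"))
  if (is.null(model$descriptor))
    stop("model has no descriptor spec; cannot extract window features",
         call. = FALSE)
  gray <- to_grayscale(image)
  n <- nrow(grid$origins)
  dim_out <- length(model$center)
  X <- matrix(NA_real_, n, dim_out)
  for (i in seq_len(n)) {
    box <- bbox(grid$origins[i, 1], grid$origins[i, 2],
                grid$window_shape[1], grid$window_shape[2])
    X[i, ] <- compute_descriptor(crop_window(gray, box)$pixels,
                                 model$descriptor)
  }
  predict(model, X)
}

#' Accumulate the occurrence matrix
#'
#' `counts[r, c]` = number of positive (`"stoma"`) windows whose half-open
#' box contains pixel `(r, c)`; the total therefore equals
#' `#positives * h * w`.
#'
#' @param grid A [window_grid].
#' @param labels One label per grid origin.
#' @return Integer matrix of the image shape.
#' @export
accumulate_occurrence <- function(grid, labels) {
  stopifnot(inherits(grid, "window_grid"))
  if (length(labels) != nrow(grid$origins))
    stop(sprintf("%d labels for %d windows", length(labels),
                 nrow(grid$origins)), call. = FALSE)
  counts <- matrix(0L, grid$image_shape[1], grid$image_shape[2])
  h <- grid$window_shape[1]; w <- grid$window_shape[2]
  for (i in which(labels == "stoma")) {
    rows <- (grid$origins[i, 1] + 1L):(grid$origins[i, 1] + h)
    cols <- (grid$origins[i, 2] + 1L):(grid$origins[i, 2] + w)
    counts[rows, cols] <- counts[rows, cols] + 1L
  }
  counts
}

# 8-connectivity labeling: EBImage's bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over the label adjacencies.
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 4L || n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  h <- nrow(lab); w <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    r1 <- seq_len(h - 1L); c1 <- if (shift[2] > 0) seq_len(w - 1L) else 2:w
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + 1L, c1 + shift[2], drop = FALSE]
    touch <- which(a > 0L & b > 0L & a != b)
    if (length(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(pairs))) union_(pairs[k, 1], pairs[k, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Extract detection regions from an occurrence matrix
#'
#' Thresholds the counts and merges the surviving pixels into connected
#' components (8-connectivity by default); each component is one detected
#' stoma region. Regions are ordered by the `(row0, col0)` of their bounding
#' boxes.
#'
#' @param occ Occurrence count matrix.
#' @param threshold Minimum count for a pixel to be positive (>= 1).
#' @param connectivity 4 or 8.
#' @return List of class `detection_regions`: `regions` (list with `bbox`,
#'   `area`, `peak_count` each) and `label_matrix` (0 = background).
#' @export
extract_regions <- function(occ, threshold = 1L, connectivity = 8L) {
  if (threshold < 1L) stop("threshold must be >= 1", call. = FALSE)
  stopifnot(connectivity %in% c(4L, 8L))
  mask <- occ >= threshold
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  regions <- vector("list", n)
  if (n > 0L) {
    for (id in seq_len(n)) {
      px <- which(lab == id, arr.ind = TRUE)
      r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
      regions[[id]] <- list(
        bbox = bbox(r0, c0, max(px[, 1]) - r0, max(px[, 2]) - c0),
        area = nrow(px),
        peak_count = max(occ[px]))
    }
    ord <- order(vapply(regions, function(r) r$bbox$row0, integer(1)),
                 vapply(regions, function(r) r$bbox$col0, integer(1)))
    regions <- regions[ord]
    out_lab <- lab
    for (new_id in seq_along(ord)) out_lab[lab == ord[new_id]] <- new_id
    lab <- out_lab
  }
  structure(list(regions = regions, label_matrix = lab),
            class = "detection_regions")
}

#' Detect stomata in a full image
#'
#' Composition of [build_window_grid], [classify_windows],
#' [accumulate_occurrence] and [extract_regions]; deterministic given the
#' model.
#'
#' @param image A [stoma_image] at least as large as the window.
#' @param model A [stoma_model] (or `classifier_fn`, see
#'   [classify_windows]).
#' @param window_shape,stride,threshold,connectivity Detection parameters.
#' @param classifier_fn Optional classifier override.
#' @return An object of class `detection_result` with the grid, per-window
#'   labels, occurrence matrix, regions and model provenance.
#' @export
detect <- function(image, model = NULL, window_shape = c(151L, 258L),
                   stride = 100L, threshold = 1L, connectivity = 8L,
                   classifier_fn = NULL) {
  stopifnot(inherits(image, "stoma_image"))
  grid <- build_window_grid(dim(image$pixels)[1:2], window_shape, stride)
  labels <- classify_windows(image, grid, model, classifier_fn)
  occ <- accumulate_occurrence(grid, labels)
  reg <- extract_regions(occ, threshold, connectivity)
  structure(list(image_id = image$image_id, grid = grid,
                 window_labels = labels, occurrence = occ,
                 regions = reg,
                 provenance = list(
                   model = if (!is.null(model))
                     list(classifier = model$classifier,
                          descriptor = model$descriptor)
                   else "classifier_fn",
                   threshold = threshold, connectivity = connectivity)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result '%s': %d windows, %d positive, %d regions>\n",
              x$image_id, length(x$window_labels),
              sum(x$window_labels == "stoma"), length(x$regions$regions)))
  invisible(x)
}

#' Render an occurrence heatmap overlay
#'
#' Normalised counts are mapped through a monotone black-to-red ramp and
#' alpha-blended onto the grayscale image; pixels with zero count keep the
#' grayscale value exactly. A binary mask of positive pixels is attached as
#' attribute `"mask"`.
#'
#' @param image The [stoma_image] the occurrence was computed on.
#' @param occ Occurrence matrix of the same shape.
#' @param alpha Maximum blend weight of the ramp.
#' @return `H x W x 3` RGB array in `[0, 255]` with attribute `"mask"`.
#' @export
render_heatmap <- function(image, occ, alpha = 0.6) {
  stopifnot(inherits(image, "stoma_image"))
  gray <- to_grayscale(image)$pixels
  if (!all(dim(gray) == dim(occ)))
    stop("image and occurrence matrix shapes differ", call. = FALSE)
  norm <- if (max(occ) > 0) occ / max(occ) else occ * 0
  a <- alpha * norm
  out <- array(0, dim = c(dim(gray), 3L))
  out[, , 1] <- gray * (1 - a) + 255 * a   # red ramp
  out[, , 2] <- gray * (1 - a)
  out[, , 3] <- gray * (1 - a)
  attr(out, "mask") <- (occ >= 1L) * 1L
  out
}
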