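# Detection scoring against ground truth: region/window matching, detection
# rates, per-fold and mean reports.

#' Match criterion for region-to-truth scoring
#'
#' `center_in_region`: a ground-truth stoma counts as detected iff its box
#' centre pixel lies inside some detected region's pixel set (robust to
#' merged regions). `iou_threshold`: region and truth bounding boxes must
#' overlap with IoU at least `iou`. The criterion is recorded in every
#' report.
#'
#' @param mode `"center_in_region"` or `"iou_threshold"`.
#' @param iou IoU threshold in (0, 1\] (only for `iou_threshold`).
#' @return An object of class `match_criterion`.
#' @export
match_criterion <- function(mode = c("center_in_region", "iou_threshold"),
                            iou = 0.5) {
  mode <- match.arg(mode)
  if (mode == "iou_threshold" && (iou <= 0 || iou > 1))
    stop("iou must lie in (0, 1]", call. = FALSE)
  structure(list(mode = mode, iou = if (mode == "iou_threshold") iou else NULL),
            class = "match_criterion")
}

bbox_iou <- function(b1, b2df) {
  inter <- bbox_intersection_area(b1, b2df)
  union <- b1$height * b1$width + b2df$height * b2df$width - inter
  ifelse(union > 0, inter / union, 0)
}

#' Match detected regions against ground truth
#'
#' Under `center_in_region`, each truth stoma is detected iff its centre
#' lies in some region; one region may cover several truths (each truth is
#' counted once), and regions covering no truth are unmatched
#' (false-positive regions). Under `iou_threshold`, truth and regions are
#' matched greedily by decreasing IoU.
#'
#' @param detections A `detection_regions` object (from [extract_regions] or
#'   inside a [detect] result).
#' @param truth An [annotation_set] (its `stomata` table) for the same
#'   image.
#' @param criterion A [match_criterion].
#' @return List: `matched_truth` (count), `unmatched_regions` (count),
#'   `truth_matched` (logical per truth box), `criterion`.
#' @export
match_regions <- function(detections, truth,
                          criterion = match_criterion()) {
  stopifnot(inherits(criterion, "match_criterion"))
  if (inherits(detections, "detection_result"))
    detections <- detections$regions
  stopifnot(inherits(detections, "detection_regions"))
  boxes <- if (inherits(truth, "annotation_set")) truth$stomata
           else as_box_df(truth)
  n_truth <- nrow(boxes); n_reg <- length(detections$regions)
  if (n_truth == 0L)
    return(list(matched_truth = 0L, unmatched_regions = n_reg,
                truth_matched = logical(0), criterion = criterion))
  if (criterion$mode == "center_in_region") {
    centers <- bbox_center(boxes)
    lab <- detections$label_matrix
    hits <- lab[cbind(centers$row + 1L, centers$col + 1L)]
    truth_matched <- hits > 0L
    covering <- unique(hits[hits > 0L])
    unmatched <- n_reg - length(covering)
  } else {
    truth_matched <- logical(n_truth)
    used_regions <- logical(n_reg)
    if (n_reg > 0L) {
      iou_mat <- sapply(detections$regions, function(r)
        bbox_iou(r$bbox, boxes))
      iou_mat <- matrix(iou_mat, n_truth, n_reg)
      repeat {
        best <- which.max(iou_mat)
        if (iou_mat[best] < criterion$iou) break
        idx <- arrayInd(best, dim(iou_mat))
        truth_matched[idx[1]] <- TRUE
        used_regions[idx[2]] <- TRUE
        iou_mat[idx[1], ] <- -1; iou_mat[, idx[2]] <- -1
      }
    }
    unmatched <- sum(!used_regions)
  }
  list(matched_truth = sum(truth_matched), unmatched_regions = unmatched,
       truth_matched = truth_matched, criterion = criterion)
}

#' Window-level true/false positives
#'
#' A positive window is a true positive iff its box has positive-area
#' intersection with some ground-truth box, else a false positive. (Window
#' counts are the paper-style accounting where several overlapping windows
#' may hit one stoma.)
#'
#' @param grid A [window_grid].
#' @param labels One label per origin.
#' @param truth An [annotation_set] or truth-box data frame.
#' @return List `window_TP`, `window_FP`.
#' @export
count_window_hits <- function(grid, labels, truth) {
  stopifnot(inherits(grid, "window_grid"))
  if (length(labels) != nrow(grid$origins))
    stop(sprintf("%d labels for %d windows", length(labels),
                 nrow(grid$origins)), call. = FALSE)
  boxes <- if (inherits(truth, "annotation_set")) truth$stomata
           else as_box_df(truth)
  pos <- which(labels == "stoma")
  tp <- 0L
  for (i in pos) {
    b <- bbox(grid$origins[i, 1], grid$origins[i, 2],
              grid$window_shape[1], grid$window_shape[2])
    if (nrow(boxes) && any(bbox_intersection_area(b, boxes) > 0))
      tp <- tp + 1L
  }
  list(window_TP = tp, window_FP = length(pos) - tp)
}

#' Detection rate
#'
#' `100 * detected / manual`, the percentage of manually counted stomata
#' recovered as detected regions. Display convention is one decimal.
#'
#' @param detected Number of detected stoma regions.
#' @param manual Manually counted stomata (> 0).
#' @return Numeric percentage (full precision).
#' @export
detection_rate <- function(detected, manual) {
  if (manual <= 0)
    stop("detection rate is undefined for a zero manual count",
         call. = FALSE)
  100 * detected / manual
}

#' Per-fold detection report
#'
#' @param fold Fold index.
#' @param manual_count Ground-truth stomata in the fold's test images.
#' @param detected_regions Detected stoma regions matched or not.
#' @param total_windows Windows classified in the fold.
#' @param window_TP,window_FP Window-level positives.
#' @return A one-row data frame of class `detection_report`.
#' @export
detection_report <- function(fold, manual_count, detected_regions,
                             total_windows, window_TP, window_FP) {
  out <- data.frame(fold = fold, manual_count = manual_count,
                    detected_regions = detected_regions,
                    detection_rate = detection_rate(detected_regions,
                                                    manual_count),
                    total_windows = total_windows,
                    window_TP = window_TP, window_FP = window_FP)
  class(out) <- c("detection_report", "data.frame")
  out
}

#' Summarise fold reports
#'
#' Appends a `Mean` row (arithmetic means of the detected counts, rates and
#' window counts) and an `Overall` row (totals, with the overall rate
#' recomputed from the summed counts).
#'
#' @param reports List of [detection_report] rows (or a stacked data
#'   frame).
#' @return Data frame with the fold rows plus `Mean` and `Overall`.
#' @export
summarize_folds <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (!length(reports)) stop("no fold reports to summarise", call. = FALSE)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  mean_row <- data.frame(
    fold = "Mean", manual_count = NA_real_,
    detected_regions = mean(df$detected_regions),
    detection_rate = mean(df$detection_rate),
    total_windows = NA_real_,
    window_TP = mean(df$window_TP), window_FP = mean(df$window_FP))
  overall_row <- data.frame(
    fold = "Overall", manual_count = sum(df$manual_count),
    detected_regions = sum(df$detected_regions),
    detection_rate = detection_rate(sum(df$detected_regions),
                                    sum(df$manual_count)),
    total_windows = sum(df$total_windows),
    window_TP = sum(df$window_TP), window_FP = sum(df$window_FP))
  df$fold <- as.character(df$fold)
  rbind(df, mean_row, overall_row)
}
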