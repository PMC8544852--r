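# Orchestration: one-command reproduction of the classification and
# detection benchmarks on synthetic scenes.

#' Benchmark scene conditions
#'
#' The separable, artifact-light imaging condition used by the synthetic
#' benchmarks: strong stoma-background contrast, low additive noise, no
#' artifacts. Scene `i` gets seed `seed + i`, so a benchmark is fully
#' reproducible from one seed.
#'
#' @param n_scenes Number of scenes.
#' @param n_stomata Stomata per scene.
#' @param seed Base seed.
#' @param contrast,noise_sd Imaging condition (defaults: high contrast).
#' @param image_shape Scene size in px.
#' @return List of [scene_spec].
#' @export
benchmark_scene_specs <- function(n_scenes, n_stomata = 12L, seed = 0L,
                                  contrast = 0.85, noise_sd = 4,
                                  image_shape = c(1200L, 1600L)) {
  lapply(seq_len(n_scenes), function(i)
    scene_spec(image_shape = image_shape, n_stomata = n_stomata,
               contrast = contrast, noise_sd = noise_sd, seed = seed + i))
}

scene_dataset <- function(specs, n_per_class, region_seed = 1000L) {
  scenes <- lapply(specs, generate_scene)
  names(scenes) <- vapply(scenes, function(s) s$image$image_id, "")
  regions <- list()
  for (i in seq_along(scenes))
    regions <- c(regions,
                 sample_balanced_regions(scenes[[i]], n_per_class,
                                         seed = region_seed + i))
  images <- lapply(scenes, function(s) s$image)
  list(scenes = scenes, images = images, regions = regions)
}

#' Run the stomata classification benchmark
#'
#' Generates synthetic scenes, samples balanced stoma/non-stoma windows,
#' extracts every configured descriptor, cross-validates every (descriptor,
#' classifier) tuple with image-level folds, and assembles the accuracy
#' table and best tuple. Optionally writes the table (CSV + text) and the
#' resolved configuration to `out_dir`.
#'
#' @param n_scenes Number of synthetic images.
#' @param n_per_class Stoma and non-stoma windows per image.
#' @param descriptors Character vector of descriptor names.
#' @param classifiers Character vector of classifier names.
#' @param k Folds.
#' @param seed Base seed for scenes, sampling, folds and classifiers.
#' @param scene_args Extra arguments passed to [benchmark_scene_specs].
#' @param out_dir Optional output directory.
#' @return List: `table` ([build_accuracy_table]), `best`
#'   ([select_best_tuple]), `per_fold` (data frame), `folds`, plus the
#'   dataset (`scenes`, `regions`) for reuse.
#' @export
run_classification_benchmark <- function(n_scenes = 50L, n_per_class = 5L,
                                         descriptors = c("HOG", "DAISY",
                                                         "LBP", "HARALICK",
                                                         "GIST"),
                                         classifiers = c("LinearSVM", "MLP",
                                                         "AdaBoost"),
                                         k = 5L, seed = 0L,
                                         scene_args = list(),
                                         out_dir = NULL) {
  specs <- do.call(benchmark_scene_specs,
                   c(list(n_scenes = n_scenes, seed = seed), scene_args))
  data <- scene_dataset(specs, n_per_class, region_seed = seed + 1000L)
  labels <- vapply(data$regions, function(r) r$label, "")
  image_ids <- vapply(data$regions, function(r) r$image_id, "")
  folds <- make_folds(names(data$images), k = k, seed = seed)
  per_fold <- list(); cells <- list()
  for (dname in descriptors) {
    dspec <- descriptor_spec(dname)
    X <- extract_features(data$regions, data$images, dspec)
    for (cname in classifiers) {
      cspec <- classifier_spec(cname, seed = seed)
      acc <- cross_validate(X, labels, image_ids, folds, cspec, dspec)
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(descriptor = dname, classifier = cname,
                   fold = seq_len(k), accuracy = acc)
      cells[[length(cells) + 1L]] <-
        data.frame(descriptor = dname, classifier = cname,
                   accuracy = mean(acc))
    }
  }
  table <- build_accuracy_table(do.call(rbind, cells))
  best <- select_best_tuple(table)
  per_fold <- do.call(rbind, per_fold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cbind(classifier = rownames(table$cells),
                           as.data.frame(rbind(table$cells))),
                     file.path(out_dir, "accuracy_table.csv"),
                     row.names = FALSE)
    utils::write.csv(per_fold, file.path(out_dir, "per_fold_accuracy.csv"),
                     row.names = FALSE)
    writeLines(c(utils::capture.output(print(table)),
                 sprintf("best tuple: %s + %s (%.2f%%)", best$descriptor,
                         best$classifier, best$accuracy)),
               file.path(out_dir, "accuracy_table.txt"))
    jsonlite::write_json(
      list(n_scenes = n_scenes, n_per_class = n_per_class,
           descriptors = descriptors, classifiers = classifiers,
           k = k, seed = seed, best = best),
      file.path(out_dir, "benchmark_config.json"), auto_unbox = TRUE)
  }
  list(table = table, best = best, per_fold = per_fold, folds = folds,
       scenes = data$scenes, regions = data$regions)
}

#' Run the stomata detection benchmark
#'
#' Trains the chosen (descriptor, classifier) tuple on the balanced windows
#' of the training scenes, slides the detector over each held-out scene,
#' matches detected regions against ground truth and assembles a fold
#' report.
#'
#' @param train_scenes,test_scenes Lists of [synthetic_scene].
#' @param descriptor,classifier Tuple to train (names or specs).
#' @param n_per_class Training windows per class per scene.
#' @param center_jitter Training-window jitter (px); the default, half the
#'   stride, exposes the classifier to the stoma offsets that sliding
#'   windows produce (see [sample_balanced_regions]).
#' @param stride,threshold Detection parameters.
#' @param seed Seed for sampling and fitting.
#' @param fold Fold index recorded in the report.
#' @param criterion A [match_criterion].
#' @return List: `report` ([detection_report] row), `per_scene` data frame,
#'   `model`, `detections` (list of [detect] results).
#' @export
run_detection_benchmark <- function(train_scenes, test_scenes,
                                    descriptor = "HOG",
                                    classifier = "LinearSVM",
                                    n_per_class = 5L, center_jitter = NULL,
                                    stride = 100L,
                                    threshold = 1L, seed = 0L, fold = 1L,
                                    criterion = match_criterion()) {
  if (is.null(center_jitter)) center_jitter <- stride %/% 2L
  dspec <- if (inherits(descriptor, "descriptor_spec")) descriptor
           else descriptor_spec(descriptor)
  cspec <- if (inherits(classifier, "classifier_spec")) classifier
           else classifier_spec(classifier, seed = seed)
  regions <- list()
  for (i in seq_along(train_scenes))
    regions <- c(regions,
                 sample_balanced_regions(train_scenes[[i]], n_per_class,
                                         seed = seed + 2000L + i,
                                         center_jitter = center_jitter))
  images <- lapply(train_scenes, function(s) s$image)
  names(images) <- vapply(train_scenes, function(s) s$image$image_id, "")
  X <- extract_features(regions, images, dspec)
  model <- train_model(X, attr(X, "labels"), cspec, dspec)
  ws <- train_scenes[[1]]$truth$window_shape
  per_scene <- list(); detections <- list()
  for (s in test_scenes) {
    det <- detect(s$image, model, window_shape = ws, stride = stride,
                  threshold = threshold)
    m <- match_regions(det, s$truth, criterion)
    hits <- count_window_hits(det$grid, det$window_labels, s$truth)
    per_scene[[length(per_scene) + 1L]] <- data.frame(
      image_id = s$image$image_id,
      manual_count = nrow(s$truth$stomata),
      detected_regions = length(det$regions$regions),
      matched_truth = m$matched_truth,
      unmatched_regions = m$unmatched_regions,
      total_windows = length(det$window_labels),
      window_TP = hits$window_TP, window_FP = hits$window_FP)
    detections[[length(detections) + 1L]] <- det
  }
  per_scene <- do.call(rbind, per_scene)
  report <- detection_report(
    fold = fold,
    manual_count = sum(per_scene$manual_count),
    detected_regions = sum(per_scene$matched_truth),
    total_windows = sum(per_scene$total_windows),
    window_TP = sum(per_scene$window_TP),
    window_FP = sum(per_scene$window_FP))
  list(report = report, per_scene = per_scene, model = model,
       detections = detections)
}
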