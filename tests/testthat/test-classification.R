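toy_features <- function(n, p = 2, sep = 3, seed = 50) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("stoma", "non_stoma"), length.out = n)
  X[y == "stoma", 1] <- X[y == "stoma", 1] + sep
  list(X = X, y = y)
}

test_that("image-level folds partition evenly and by seed", {
  f <- make_folds(sprintf("img%03d", 1:200), k = 5, seed = 1)
  expect_equal(unname(table(f$assignment)), rep(40L, 5), ignore_attr = TRUE)
  expect_setequal(names(f$assignment), sprintf("img%03d", 1:200))
  # 7 images, 5 folds -> sizes {2,2,1,1,1}
  f7 <- make_folds(letters[1:7], k = 5, seed = 2)
  expect_equal(sort(unname(table(f7$assignment)), decreasing = TRUE),
               c(2L, 2L, 1L, 1L, 1L), ignore_attr = TRUE)
  # same seed reproduces, different seed shuffles
  expect_identical(make_folds(letters[1:7], 5, 2)$assignment, f7$assignment)
})

test_that("degenerate fold requests are config errors", {
  expect_error(make_folds(letters[1:5], k = 1), "k must be")
  expect_error(make_folds(letters[1:3], k = 5), "exceeds")
  expect_error(make_folds(c("a", "a", "b"), k = 2), "unique")
})

test_that("all three classifiers separate a wide-margin toy problem", {
  d <- toy_features(60, sep = 8)
  for (cn in c("LinearSVM", "MLP", "AdaBoost")) {
    m <- train_model(d$X, d$y, classifier_spec(cn, seed = 3))
    expect_equal(unname(mean(predict(m, d$X) == d$y)), 1,
                 label = paste(cn, "training accuracy"))
  }
})

test_that("fitting is deterministic given the spec seed", {
  d <- toy_features(40, p = 5, sep = 1, seed = 51)
  probe <- matrix(rnorm(50 * 5), 50, 5)
  for (cn in c("LinearSVM", "MLP", "AdaBoost")) {
    m1 <- train_model(d$X, d$y, classifier_spec(cn, seed = 7))
    m2 <- train_model(d$X, d$y, classifier_spec(cn, seed = 7))
    expect_identical(predict(m1, probe), predict(m2, probe))
  }
})

test_that("single-class training sets are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(train_model(X, rep("stoma", 5), classifier_spec("LinearSVM")),
               "single class")
})

test_that("standardisation uses training statistics only", {
  X <- matrix(c(1, 3, 10, 14), 2, 2)  # per-column mean (2, 12), sd by hand
  y <- c("stoma", "non_stoma")
  m <- train_model(X, y, classifier_spec("LinearSVM"))
  expect_equal(m$center, c(2, 12))
  expect_equal(m$scale, apply(X, 2, sd))
})

test_that("prediction validates feature width and handles zero rows", {
  d <- toy_features(20)
  m <- train_model(d$X, d$y, classifier_spec("LinearSVM"))
  expect_error(predict(m, matrix(0, 2, 5)), "width")
  expect_identical(predict(m, matrix(0, 0, 2)), character(0))
})

test_that("cross-validation never leaks regions of a test image", {
  set.seed(52)
  n_img <- 12
  ids <- rep(sprintf("im%02d", 1:n_img), each = 4)
  X <- matrix(rnorm(length(ids) * 3), ncol = 3)
  y <- rep(c("stoma", "non_stoma"), length.out = length(ids))
  folds <- make_folds(unique(ids), k = 4, seed = 5)
  acc <- cross_validate(X, y, ids, folds, classifier_spec("LinearSVM"))
  expect_length(acc, 4)
  expect_true(all(acc >= 0 & acc <= 100))
  # a fold with no test regions is a config error
  keep <- folds$assignment[ids] != 2
  expect_error(
    cross_validate(X[keep, ], y[keep], ids[keep], folds,
                   classifier_spec("LinearSVM")),
    "no test regions")
  # unknown image id is an error
  expect_error(cross_validate(X, y, c("zz", ids[-1]), folds,
                              classifier_spec("LinearSVM")), "absent")
})

test_that("perfectly separable synthetic features score 100 in every fold", {
  n_img <- 10
  ids <- rep(sprintf("s%02d", 1:n_img), each = 6)
  d <- toy_features(length(ids), sep = 6, seed = 53)
  folds <- make_folds(unique(ids), k = 5, seed = 6)
  acc <- cross_validate(d$X, d$y, ids, folds, classifier_spec("LinearSVM"))
  expect_equal(acc, rep(100, 5))
})

test_that("reported accuracy equals hand-computed confusion arithmetic", {
  d <- toy_features(30, sep = 1.2, seed = 54)
  m <- train_model(d$X[1:20, ], d$y[1:20], classifier_spec("LinearSVM"))
  probe_X <- d$X[21:30, ]; probe_y <- d$y[21:30]
  pred <- predict(m, probe_X)
  tp <- sum(pred == "stoma" & probe_y == "stoma")
  tn <- sum(pred == "non_stoma" & probe_y == "non_stoma")
  expect_equal(mean(pred == probe_y), (tp + tn) / 10)
})

test_that("shuffled labels on noise features stay near chance", {
  set.seed(55)
  n_img <- 40
  ids <- rep(sprintf("n%02d", 1:n_img), each = 5)
  n <- length(ids)
  X <- matrix(rnorm(n * 8), n, 8)
  y <- sample(rep(c("stoma", "non_stoma"), n / 2))
  folds <- make_folds(unique(ids), k = 5, seed = 8)
  acc <- cross_validate(X, y, ids, folds, classifier_spec("LinearSVM"))
  # overall proportion correct within the 99% binomial interval around 0.5
  p_hat <- mean(acc) / 100
  half_width <- qnorm(0.995) * sqrt(0.25 / n)
  expect_lt(abs(p_hat - 0.5), half_width + 1e-9)
})

test_that("accuracy tables reproduce the printed column means", {
  res <- expand.grid(classifier = c("AdaBoost", "MLP", "LinearSVM"),
                     descriptor = c("HOG", "VGG16"),
                     stringsAsFactors = FALSE)
  res$accuracy <- c(93, 96, 95, 99, 100, 100)
  tab <- build_accuracy_table(res)
  expect_equal(round(tab$column_means[["HOG"]], 1), 94.7)
  expect_equal(round(tab$column_means[["VGG16"]], 1), 99.7)
  # all-identical cells give that constant everywhere
  res$accuracy <- 88
  expect_equal(unname(build_accuracy_table(res)$column_means), c(88, 88))
})

test_that("incomplete or invalid grids are rejected", {
  res <- data.frame(descriptor = c("HOG", "HOG"),
                    classifier = c("MLP", "LinearSVM"),
                    accuracy = c(96, 95))
  tab <- build_accuracy_table(res)  # single column is fine
  expect_equal(dim(tab$cells), c(2L, 1L))
  bad <- data.frame(descriptor = c("HOG", "LBP"),
                    classifier = c("MLP", "LinearSVM"),
                    accuracy = c(96, 95))
  expect_error(build_accuracy_table(bad), "incomplete")
  res$accuracy <- c(105, 95)
  expect_error(build_accuracy_table(res), "0, 100")
})

test_that("best-tuple selection follows argmax then the declared tie-breaks", {
  # deep-feature benchmark layout: SVM and MLP both reach 100 on VGG16;
  # the SVM-first preference selects (VGG16, LinearSVM)
  res <- expand.grid(classifier = c("AdaBoost", "MLP", "LinearSVM"),
                     descriptor = c("DenseNet", "IResNet", "Inception",
                                    "MobileNet", "NasNet", "VGG16"),
                     stringsAsFactors = FALSE)
  res$accuracy <- c(95, 98, 80,   96, 94, 94,   90, 88, 91,
                    96, 98, 98,   91, 95, 95,   99, 100, 100)
  best <- select_best_tuple(build_accuracy_table(res))
  expect_equal(best$descriptor, "VGG16")
  expect_equal(best$classifier, "LinearSVM")
  # single cell
  one <- build_accuracy_table(data.frame(descriptor = "LBP",
                                         classifier = "MLP", accuracy = 90))
  expect_equal(select_best_tuple(one)$descriptor, "LBP")
  # equal maxima across descriptors resolved by the column mean
  res2 <- expand.grid(classifier = c("LinearSVM", "MLP"),
                      descriptor = c("A", "B"), stringsAsFactors = FALSE)
  res2$accuracy <- c(99, 50, 99, 98)
  best2 <- select_best_tuple(build_accuracy_table(res2))
  expect_equal(best2$descriptor, "B")
})

test_that("CV accuracy does not decrease with scene contrast", {
  accs <- vapply(c(0.08, 0.35, 0.85), function(ct) {
    specs <- lapply(1:10, function(i)
      scene_spec(image_shape = c(700L, 900L), n_stomata = 3, contrast = ct,
                 noise_sd = 25, row_spacing = 120, seed = 600 + i))
    scenes <- lapply(specs, generate_scene)
    names(scenes) <- vapply(scenes, function(s) s$image$image_id, "")
    regions <- list()
    for (i in seq_along(scenes))
      regions <- c(regions, sample_balanced_regions(scenes[[i]], 3,
                                                    seed = 700 + i))
    imgs <- lapply(scenes, function(s) s$image)
    X <- extract_features(regions, imgs, descriptor_spec("HARALICK"))
    folds <- make_folds(names(imgs), k = 5, seed = 9)
    mean(cross_validate(X, attr(X, "labels"),
                        vapply(regions, function(r) r$image_id, ""),
                        folds, classifier_spec("LinearSVM", seed = 9)))
  }, numeric(1))
  expect_true(all(diff(accs) >= -1))   # tolerate 1% noise violations
  expect_gt(accs[3], accs[1])
})
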