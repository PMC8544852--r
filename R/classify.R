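# Stomata classification: (descriptor x classifier) tuples benchmarked under
# image-level k-fold cross-validation, accuracy tables and best-tuple
# selection.

.classifier_defaults <- list(
  LinearSVM = list(cost = 1),
  MLP = list(size = 16L, maxit = 200L, decay = 1e-4,
             pca_var = 0.95, max_pc = 64L),
  AdaBoost = list(n_rounds = 100L)
)

#' Classifier specification
#'
#' Declares one of the three classifiers with its hyperparameters and seed.
#' Defaults: linear SVM with cost 1; MLP = train-fold PCA compression
#' (components covering `pca_var` of the variance, capped at `max_pc`)
#' followed by a single 16-unit hidden layer trained for up to 200
#' iterations; AdaBoost.M1 with 100 exact weighted decision stumps. Identical
#' spec + data give identical fitted predictions.
#'
#' @param name `"LinearSVM"`, `"MLP"` or `"AdaBoost"`.
#' @param hyperparams Named list overriding the defaults.
#' @param seed Integer seed recorded in the spec and used for fitting.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("LinearSVM", "MLP", "AdaBoost"),
                            hyperparams = list(), seed = 0L) {
  name <- match.arg(name)
  structure(list(name = name,
                 hyperparams = utils::modifyList(.classifier_defaults[[name]],
                                                 hyperparams),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Image-level fold assignment
#'
#' Partitions image ids into `k` folds whose sizes differ by at most one,
#' shuffled by `seed`. All regions of one image inherit its fold, which is
#' the leakage guard for window-level data.
#'
#' @param image_ids Character vector of unique image ids (or a
#'   `dataset_manifest`).
#' @param k Number of folds (>= 2).
#' @param seed Integer shuffle seed.
#' @return An object of class `fold_assignment`: list with `k`, `seed`, and
#'   `assignment` (named integer vector, image id -> fold).
#' @export
make_folds <- function(image_ids, k = 5L, seed = 0L) {
  if (inherits(image_ids, "dataset_manifest")) image_ids <- image_ids$image_id
  image_ids <- as.character(image_ids)
  if (anyDuplicated(image_ids)) stop("image ids must be unique", call. = FALSE)
  n <- length(image_ids)
  if (k < 2L) stop("k must be at least 2 (k = 1 leaves no held-out data)",
                   call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the number of images (%d)", k, n),
                  call. = FALSE)
  with_seed(seed, {
    shuffled <- sample(image_ids)
    fold <- rep(seq_len(k), length.out = n)
    assignment <- stats::setNames(fold, shuffled)[image_ids]
    structure(list(k = as.integer(k), seed = as.integer(seed),
                   assignment = assignment), class = "fold_assignment")
  })
}

# --- AdaBoost.M1 with exact weighted decision stumps ------------------------

stump_predict <- function(stump, x) {
  s <- ifelse(x[, stump$feature] <= stump$threshold, -1, 1)
  stump$polarity * s
}

adaboost_fit <- function(x, y, n_rounds) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  ord <- apply(x, 2L, order)
  xs <- matrix(x[cbind(as.vector(ord), rep(seq_len(ncol(x)), each = n))],
               n, ncol(x))
  stumps <- list(); alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    st <- stump_search(xs, ord, w, y)
    if (st$feature == 0L) break             # no admissible split
    pred <- stump_predict(st, x)
    err <- sum(w[pred != y])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[r]] <- st; alphas[r] <- alpha
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  list(stumps = stumps, alphas = alphas)
}

adaboost_decision <- function(fit, x) {
  score <- numeric(nrow(x))
  for (r in seq_along(fit$stumps))
    score <- score + fit$alphas[r] * stump_predict(fit$stumps[[r]], x)
  score
}

# --- model fitting -----------------------------------------------------------

.class_levels <- c("stoma", "non_stoma")

#' Train a stomata window classifier
#'
#' Standardises features to zero mean / unit variance using training rows
#' only (constant features get scale 1), then fits the classifier named in
#' `classifier_spec`. Fitting is deterministic given the spec's seed. The
#' returned model carries the descriptor and classifier specs and the
#' standardisation parameters, so prediction is self-contained.
#'
#' @param features Numeric matrix, one row per training window.
#' @param labels Character vector (`"stoma"` / `"non_stoma"`) or factor;
#'   both classes must be present.
#' @param classifier_spec A [classifier_spec].
#' @param descriptor_spec The [descriptor_spec] (or [backbone_spec]) that
#'   produced `features`; stored for provenance.
#' @param training_folds Optional fold ids used for training (provenance).
#' @return An object of class `stoma_model`.
#' @export
train_model <- function(features, labels, classifier_spec,
                        descriptor_spec = NULL, training_folds = NULL) {
  stopifnot(inherits(classifier_spec, "classifier_spec"))
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (!all(labels %in% .class_levels))
    stop("labels must be 'stoma' or 'non_stoma'", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length", call. = FALSE)
  if (!all(is.finite(features)))
    stop("features contain non-finite values", call. = FALSE)
  center <- colMeans(features)
  scale_ <- apply(features, 2L, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  X <- sweep(sweep(features, 2L, center), 2L, scale_, "/")
  y <- factor(labels, levels = .class_levels)
  hp <- classifier_spec$hyperparams
  pca <- NULL
  fit <- NULL
  with_seed(classifier_spec$seed, {
    if (classifier_spec$name == "LinearSVM") {
      fit <- e1071::svm(X, y, kernel = "linear", cost = hp$cost,
                        scale = FALSE)
    } else if (classifier_spec$name == "MLP") {
      pr <- stats::prcomp(X, center = FALSE, scale. = FALSE)
      cum <- cumsum(pr$sdev^2) / sum(pr$sdev^2)
      npc <- min(which(cum >= hp$pca_var), hp$max_pc, ncol(pr$rotation))
      pca <- pr$rotation[, seq_len(npc), drop = FALSE]
      Z <- X %*% pca
      fit <- nnet::nnet(Z, cbind(as.numeric(y == "stoma")),
                        size = hp$size, decay = hp$decay, maxit = hp$maxit,
                        entropy = TRUE, trace = FALSE,
                        MaxNWts = (npc + 2L) * hp$size + hp$size + 10L)
    } else {
      fit <- adaboost_fit(X, ifelse(y == "stoma", 1, -1), hp$n_rounds)
    }
  })
  structure(list(classifier = classifier_spec, descriptor = descriptor_spec,
                 center = center, scale = scale_, pca = pca, fit = fit,
                 training_folds = training_folds, levels = .class_levels),
            class = "stoma_model")
}

#' @export
print.stoma_model <- function(x, ...) {
  dsc <- if (is.null(x$descriptor)) "unspecified descriptor"
         else x$descriptor$name
  cat(sprintf("<stoma_model: %s on %s features (%d dims)>\n",
              x$classifier$name, dsc, length(x$center)))
  invisible(x)
}

#' Predict window labels
#'
#' Applies the stored train-set standardisation `(x - mean) / sd` and the
#' fitted classifier; returns one label per row.
#'
#' @param object A [stoma_model] from [train_model].
#' @param features Numeric matrix with the model's feature width.
#' @param ... Unused.
#' @return Character vector of `"stoma"` / `"non_stoma"`.
#' @export
predict.stoma_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) return(character(0))
  if (ncol(features) != length(object$center))
    stop(sprintf("feature width %d does not match the model's %d",
                 ncol(features), length(object$center)), call. = FALSE)
  X <- sweep(sweep(features, 2L, object$center), 2L, object$scale, "/")
  out <- switch(object$classifier$name,
    LinearSVM = as.character(stats::predict(object$fit, X)),
    MLP = {
      p <- stats::predict(object$fit, X %*% object$pca)
      ifelse(p[, 1] >= 0.5, "stoma", "non_stoma")
    },
    AdaBoost = ifelse(adaboost_decision(object$fit, X) >= 0,
                      "stoma", "non_stoma")
  )
  unname(out)
}

# --- cross-validation --------------------------------------------------------

#' Image-level cross-validated accuracy
#'
#' For each fold: trains on all regions whose images lie in other folds and
#' tests on the fold's own regions; accuracy is `correct / total * 100`. An
#' internal assertion re-checks that no region of a test image ever enters
#' its training set.
#'
#' @param features Feature matrix, rows aligned with `labels`/`image_ids`.
#' @param labels Region labels.
#' @param image_ids Parent image of each region.
#' @param folds A [make_folds] assignment covering every `image_id`.
#' @param classifier_spec A [classifier_spec].
#' @param descriptor_spec Stored in the fold models (provenance).
#' @return Numeric vector of `k` fold accuracies (percent).
#' @export
cross_validate <- function(features, labels, image_ids, folds,
                           classifier_spec, descriptor_spec = NULL) {
  stopifnot(inherits(folds, "fold_assignment"))
  image_ids <- as.character(image_ids)
  unknown <- setdiff(image_ids, names(folds$assignment))
  if (length(unknown))
    stop(sprintf("regions reference images absent from the folds: %s",
                 paste(unique(unknown), collapse = ", ")), call. = FALSE)
  region_fold <- folds$assignment[image_ids]
  acc <- numeric(folds$k)
  for (f in seq_len(folds$k)) {
    test_idx <- which(region_fold == f)
    train_idx <- which(region_fold != f)
    if (!length(test_idx))
      stop(sprintf("fold %d has no test regions", f), call. = FALSE)
    # leakage guard: no test image contributes training regions
    stopifnot(!any(image_ids[train_idx] %in% image_ids[test_idx]))
    model <- train_model(features[train_idx, , drop = FALSE],
                         labels[train_idx], classifier_spec, descriptor_spec,
                         training_folds = setdiff(seq_len(folds$k), f))
    pred <- predict(model, features[test_idx, , drop = FALSE])
    acc[f] <- 100 * mean(pred == labels[test_idx])
  }
  acc
}

# --- accuracy tables ---------------------------------------------------------

#' Build a classifier x descriptor accuracy table
#'
#' @param results Data frame with columns `descriptor`, `classifier`,
#'   `accuracy` (mean CV accuracy, percent); the (descriptor, classifier)
#'   grid must be complete.
#' @return An object of class `accuracy_table`: list with `cells` (matrix,
#'   rows = classifiers, cols = descriptors, full precision) and
#'   `column_means`. Printing rounds to one decimal.
#' @export
build_accuracy_table <- function(results) {
  results <- as.data.frame(results)
  stopifnot(all(c("descriptor", "classifier", "accuracy") %in% names(results)))
  descriptors <- unique(results$descriptor)
  classifiers <- unique(results$classifier)
  cells <- matrix(NA_real_, length(classifiers), length(descriptors),
                  dimnames = list(classifiers, descriptors))
  for (i in seq_len(nrow(results)))
    cells[results$classifier[i], results$descriptor[i]] <- results$accuracy[i]
  if (anyNA(cells)) {
    miss <- which(is.na(cells), arr.ind = TRUE)
    stop(sprintf("accuracy grid is incomplete (e.g. missing %s x %s)",
                 rownames(cells)[miss[1, 1]], colnames(cells)[miss[1, 2]]),
         call. = FALSE)
  }
  if (any(cells < 0 | cells > 100))
    stop("accuracies must lie in [0, 100]", call. = FALSE)
  structure(list(cells = cells, column_means = colMeans(cells)),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  disp <- rbind(round(x$cells, 1), Mean = round(x$column_means, 1))
  print(disp)
  invisible(x)
}

.classifier_preference <- c("LinearSVM", "MLP", "AdaBoost")

#' Select the best (descriptor, classifier) tuple
#'
#' Argmax over the full-precision cells; ties are broken by the declared
#' classifier preference order (SVM, then MLP, then AdaBoost), then by the
#' descriptor's column mean.
#'
#' @param table An [build_accuracy_table] result.
#' @return List with `descriptor`, `classifier`, `accuracy`.
#' @export
select_best_tuple <- function(table) {
  stopifnot(inherits(table, "accuracy_table"))
  cells <- table$cells
  best <- max(cells)
  cand <- which(cells == best, arr.ind = TRUE)
  cand <- data.frame(classifier = rownames(cells)[cand[, 1]],
                     descriptor = colnames(cells)[cand[, 2]])
  cand$clf_rank <- match(cand$classifier, .classifier_preference)
  cand$col_mean <- table$column_means[cand$descriptor]
  cand <- cand[order(cand$clf_rank, -cand$col_mean), ]
  list(descriptor = cand$descriptor[1], classifier = cand$classifier[1],
       accuracy = best)
}
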