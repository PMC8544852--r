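test_that("the window-grid closed form matches exhaustive enumeration", {
  set.seed(60)
  for (i in 1:200) {
    h <- sample(5:40, 1); w <- sample(5:40, 1)
    H <- h + sample(0:80, 1); W <- w + sample(0:80, 1)
    s <- sample(1:20, 1)
    grid <- build_window_grid(c(H, W), c(h, w), s)
    oracle <- grid_oracle(H, W, h, w, s)
    expect_equal(unname(grid$origins), unname(oracle))
  }
})

test_that("paper-scale image geometry yields a 26 x 36 grid", {
  grid <- build_window_grid(c(2748L, 3840L))
  expect_equal(nrow(grid$origins), 936L)
  expect_equal(grid$origins[1, ], c(row0 = 0L, col0 = 0L))
  expect_equal(unname(grid$origins[936, ]), c(2500L, 3500L))
})

test_that("minimal geometries produce single-window grids", {
  expect_equal(nrow(build_window_grid(c(151L, 258L))$origins), 1L)
  expect_equal(nrow(build_window_grid(c(151L, 357L))$origins), 1L)
  expect_error(build_window_grid(c(150L, 258L)), "smaller")
})

test_that("occurrence accumulation is conservative and correctly placed", {
  grid <- build_window_grid(c(400L, 500L))
  labels <- rep("non_stoma", nrow(grid$origins))
  expect_equal(sum(accumulate_occurrence(grid, labels)), 0)
  # one positive window at the origin
  labels1 <- labels; labels1[1] <- "stoma"
  occ <- accumulate_occurrence(grid, labels1)
  expect_equal(sum(occ > 0), 38958L)
  expect_true(all(occ[occ > 0] == 1L))
  # two positives in the same row, 100 px apart: 158-wide band counts 2
  i2 <- which(grid$origins[, 1] == 0 & grid$origins[, 2] == 100)
  labels2 <- labels1; labels2[i2] <- "stoma"
  occ2 <- accumulate_occurrence(grid, labels2)
  expect_equal(sum(occ2), 2L * 38958L)
  expect_equal(sum(occ2 == 2L), 151L * 158L)
  expect_error(accumulate_occurrence(grid, labels[-1]), "labels")
})

test_that("occurrence totals equal positives times window area under fuzzing", {
  set.seed(61)
  for (i in 1:20) {
    h <- sample(3:10, 1); w <- sample(3:10, 1)
    H <- h + sample(0:30, 1); W <- w + sample(0:30, 1)
    grid <- build_window_grid(c(H, W), c(h, w), sample(1:6, 1))
    labels <- sample(c("stoma", "non_stoma"), nrow(grid$origins),
                     replace = TRUE)
    occ <- accumulate_occurrence(grid, labels)
    expect_equal(sum(occ), sum(labels == "stoma") * h * w)
  }
})

test_that("region extraction matches a flood-fill oracle on random masks", {
  set.seed(62)
  for (i in 1:100) {
    h <- sample(4:64, 1); w <- sample(4:64, 1)
    mask <- matrix(runif(h * w) < 0.35, h, w)
    occ <- mask * 1L
    for (conn in c(8L, 4L)) {
      got <- extract_regions(occ, threshold = 1, connectivity = conn)
      oracle <- flood_fill_components(mask, conn)
      expect_equal(max(got$label_matrix), max(oracle))
      # identical partition: component ids must map one-to-one
      if (max(oracle) > 0) {
        pairs <- unique(cbind(as.vector(got$label_matrix),
                              as.vector(oracle)))
        pairs <- pairs[pairs[, 1] > 0 | pairs[, 2] > 0, , drop = FALSE]
        expect_equal(nrow(pairs), max(oracle))
      }
    }
  }
})

test_that("region bookkeeping covers the analytic window layouts", {
  expect_length(extract_regions(matrix(0L, 300, 400))$regions, 0L)
  grid <- build_window_grid(c(400L, 700L))
  labels <- rep("non_stoma", nrow(grid$origins))
  labels[1] <- "stoma"
  reg1 <- extract_regions(accumulate_occurrence(grid, labels))
  expect_length(reg1$regions, 1L)
  b <- reg1$regions[[1]]$bbox
  expect_equal(c(b$row0, b$col0, b$height, b$width), c(0L, 0L, 151L, 258L))
  expect_equal(reg1$regions[[1]]$area, 38958L)
  # disjoint pair: col0 = 0 and col0 = 400 (gap > window width)
  i2 <- which(grid$origins[, 1] == 0 & grid$origins[, 2] == 400)
  labels2 <- labels; labels2[i2] <- "stoma"
  expect_length(extract_regions(accumulate_occurrence(grid, labels2))$regions,
                2L)
  # overlapping pair: col0 = 0 and 100 merge into one 358-wide region
  i3 <- which(grid$origins[, 1] == 0 & grid$origins[, 2] == 100)
  labels3 <- labels; labels3[i3] <- "stoma"
  reg3 <- extract_regions(accumulate_occurrence(grid, labels3))
  expect_length(reg3$regions, 1L)
  expect_equal(reg3$regions[[1]]$bbox$width, 358L)
  expect_error(extract_regions(matrix(0L, 5, 5), threshold = 0), ">= 1")
})

test_that("classify_windows matches the grid order and supports oracles", {
  sc <- small_scene(seed = 63)
  grid <- build_window_grid(dim(sc$image$pixels))
  labels <- classify_windows(sc$image, grid,
                             classifier_fn = oracle_classifier(sc$truth$stomata))
  expect_length(labels, nrow(grid$origins))
  # the oracle flags exactly the windows that overlap some truth box
  for (i in seq_len(nrow(grid$origins))) {
    b <- bbox(grid$origins[i, 1], grid$origins[i, 2], 151, 258)
    overlap <- any(stomadetect:::bbox_intersection_area(b, sc$truth$stomata) > 0)
    expect_equal(labels[i] == "stoma", overlap)
  }
})

test_that("detection on blank scenes yields no regions with a real model", {
  train <- lapply(101:103, function(s) small_scene(seed = s, n = 3))
  regions <- list()
  for (i in seq_along(train))
    regions <- c(regions, sample_balanced_regions(train[[i]], 3,
                                                  seed = 200 + i))
  imgs <- lapply(train, function(s) s$image)
  names(imgs) <- vapply(train, function(s) s$image$image_id, "")
  dspec <- descriptor_spec("HARALICK")
  X <- extract_features(regions, imgs, dspec)
  model <- train_model(X, attr(X, "labels"),
                       classifier_spec("LinearSVM", seed = 1), dspec)
  blank <- generate_scene(scene_spec(image_shape = c(700L, 900L),
                                     n_stomata = 0, contrast = 0.85,
                                     noise_sd = 4, seed = 999))
  det <- detect(blank$image, model)
  expect_length(det$regions$regions, 0L)
  expect_true(all(det$window_labels == "non_stoma"))
  # determinism: bit-equal occurrence on a repeat run
  det2 <- detect(blank$image, model)
  expect_identical(det$occurrence, det2$occurrence)
})

test_that("well-separated stomata give one region per stoma with an oracle", {
  sp <- scene_spec(image_shape = c(2400L, 3400L), n_stomata = 10,
                   placement_pad = c(310L, 520L), contrast = 0.85,
                   noise_sd = 4, seed = 64)
  sc <- generate_scene(sp)
  det <- detect(sc$image, classifier_fn = oracle_classifier(sc$truth$stomata))
  expect_length(det$regions$regions, 10L)
  m <- match_regions(det, sc$truth)
  expect_equal(m$matched_truth, 10L)
  expect_equal(m$unmatched_regions, 0L)
})

test_that("heatmap rendering preserves zero-count pixels and is monotone", {
  img <- rand_image(200, 300, seed = 65)
  occ <- matrix(0L, 200, 300)
  hm0 <- render_heatmap(img, occ)
  for (ch in 1:3) expect_equal(hm0[, , ch], img$pixels)
  occ[10:60, 10:60] <- 1L; occ[20:40, 20:40] <- 2L; occ[25:30, 25:30] <- 3L
  hm <- render_heatmap(img, occ)
  expect_equal(sum(attr(hm, "mask")), sum(occ >= 1))
  # fix the underlying gray, probe increasing counts -> increasing red
  gray <- to_grayscale(img)$pixels
  reds <- vapply(1:3, function(k) {
    idx <- which(occ == k & gray < 100)[1]
    (hm[, , 1])[idx] - gray[idx]
  }, numeric(1))
  expect_true(all(diff(reds) > 0))
  expect_error(render_heatmap(img, matrix(0L, 5, 5)), "shapes differ")
})
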