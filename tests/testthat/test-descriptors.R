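const_win <- function(v = 128) matrix(v, 151, 258)

test_that("constant windows map to the analytic degenerate outputs", {
  w <- const_win()
  expect_equal(compute_hog(w), rep(0, 4320))
  expect_equal(compute_daisy(w), rep(0, 5600))
  expect_equal(compute_gist(w), rep(0, 512), tolerance = 1e-10)
  lbp <- compute_lbp(w)
  expect_equal(sum(lbp), 1)
  # >= convention: every bit set -> all-ones uniform pattern carries all mass
  all_ones_bin <- which(lbp > 0)
  expect_length(all_ones_bin, 1L)
  expect_equal(lbp[all_ones_bin], 1)
  har <- haralick_features(w)
  expect_equal(unname(har["asm"]), 1)
  expect_equal(unname(har["entropy"]), 0)
  expect_equal(unname(har["contrast"]), 0)
})

test_that("descriptor output lengths match their declared dimensions", {
  w <- rand_image(151, 258, seed = 30)$pixels
  for (d in c("HOG", "DAISY", "LBP", "HARALICK", "GIST")) {
    spec <- descriptor_spec(d)
    expect_length(compute_descriptor(w, spec),
                  descriptor_output_dim(spec, c(151L, 258L)))
  }
  expect_equal(descriptor_output_dim(descriptor_spec("HOG")), 8 * 15 * 4 * 9)
  expect_equal(descriptor_output_dim(descriptor_spec("GIST")), 4 * 8 * 16)
  expect_equal(descriptor_output_dim(descriptor_spec("LBP")), 59)
})

test_that("a vertical step edge concentrates HOG mass in the 0-degree bin", {
  w <- cbind(matrix(0, 151, 129), matrix(255, 151, 129))
  v <- compute_hog(w)
  # block vectors are (cell_r, cell_c, bin) column-major, 36 per block
  m <- matrix(v, nrow = 36)
  bin_mass <- vapply(1:9, function(b) sum(m[((b - 1) * 4 + 1):(b * 4), ]),
                     numeric(1))
  expect_gt(bin_mass[1] / sum(bin_mass), 0.95)
})

test_that("HOG is invariant to 180-degree rotation up to cell permutation", {
  w <- rand_image(151, 258, seed = 31)$pixels
  rot <- w[rev(seq_len(nrow(w))), rev(seq_len(ncol(w)))]
  expect_equal(sort(compute_hog(w)), sort(compute_hog(rot)),
               tolerance = 1e-10)
})

test_that("DAISY length follows the grid-point count formula", {
  # 0-based grid: seq(radius, extent-1-radius, step)
  n_r <- length(seq(24, 151 - 1 - 24, by = 32))
  n_c <- length(seq(24, 258 - 1 - 24, by = 32))
  expect_equal(descriptor_output_dim(descriptor_spec("DAISY"),
                                     c(151L, 258L)),
               n_r * n_c * (3 * 8 + 1) * 8)
})

test_that("shifting by one DAISY grid step shifts the descriptor blocks", {
  set.seed(32)
  base <- matrix(runif(151 * 322, 0, 255), 151, 322)
  shifted <- base[, 33:322]                      # shift left by one step
  orig <- base[, 1:290]
  d1 <- compute_daisy(orig); d2 <- compute_daisy(shifted)
  n_c <- length(seq(24, 290 - 1 - 24, by = 32)) # 8 grid cols in both
  n_r <- length(seq(24, 151 - 1 - 24, by = 32)) # 4 grid rows
  a1 <- array(d1, dim = c(200, n_c, n_r))       # point-major: col fastest
  a2 <- array(d2, dim = c(200, n_c, n_r))
  # descriptor at grid col j of the shifted image = grid col j+1 of the
  # original, for interior columns whose blur support avoids the borders
  for (r in seq_len(n_r)) for (j in 3:5)
    expect_equal(a2[, j, r], a1[, j + 1, r], tolerance = 1e-8)
})

test_that("LBP matches a brute-force per-pixel oracle on a toy window", {
  set.seed(33)
  m <- matrix(sample(0:255, 36), 6, 6)
  got <- compute_lbp(m)
  # independent oracle: loop over interior pixels, bilinear neighbours
  P <- 8; R <- 1
  codes <- c()
  for (r in 2:5) for (c in 2:5) {
    code <- 0
    for (k in 0:(P - 1)) {
      ang <- 2 * pi * k / P
      rr <- r - R * sin(ang); cc <- c + R * cos(ang)
      fr <- floor(rr); fc <- floor(cc)
      tr <- rr - fr; tc <- cc - fc
      val <- (1 - tr) * (1 - tc) * m[fr, fc] +
             (1 - tr) * tc * m[fr, min(fc + 1, 6)] +
             tr * (1 - tc) * m[min(fr + 1, 6), fc] +
             tr * tc * m[min(fr + 1, 6), min(fc + 1, 6)]
      if (round(val, 6) >= m[r, c]) code <- code + 2^k
    }
    codes <- c(codes, code)
  }
  # map codes through the same uniform binning definition (<= 2 transitions)
  bits <- function(x) as.integer(intToBits(x)[1:8])
  is_uniform <- function(x) {
    b <- bits(x); sum(b != b[c(2:8, 1)]) <= 2
  }
  uniform_codes <- Filter(is_uniform, 0:255)
  bin_of <- function(x) {
    i <- match(x, uniform_codes)
    if (is.na(i)) 59L else i
  }
  oracle_hist <- tabulate(vapply(codes, bin_of, 1L), nbins = 59) / 16
  expect_equal(got, oracle_hist)
})

test_that("LBP histograms always sum to one", {
  set.seed(34)
  for (i in 1:10) {
    m <- matrix(sample(0:255, 30 * 40, replace = TRUE), 30, 40)
    expect_equal(sum(compute_lbp(m)), 1)
  }
})

test_that("GLCM reproduces the analytic checkerboard and constant cases", {
  g <- compute_glcm(matrix(c(0, 255, 255, 0), 2, 2), distance = 1,
                    angle = 0, levels = 2)
  expect_equal(g$matrix[1, 2], 0.5)
  expect_equal(g$matrix[2, 1], 0.5)
  expect_equal(g$matrix[1, 1] + g$matrix[2, 2], 0)
  gc <- compute_glcm(const_win(100), levels = 64)
  expect_equal(sum(gc$matrix != 0), 1L)
  expect_equal(sum(gc$matrix), 1)
})

test_that("GLCM equals the brute-force pair-enumeration oracle", {
  set.seed(35)
  for (i in 1:20) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    m <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    lv <- sample(2:4, 1)
    d <- sample(1:min(h, w, 2), 1)
    for (ang in c(0, 45, 90, 135)) {
      skip_small <- (ang != 90 && d >= w) || (ang != 0 && d >= h)
      if (skip_small) next
      got <- compute_glcm(m, distance = d, angle = ang, levels = lv)$matrix
      expect_equal(got, glcm_oracle(m, d, ang, lv), tolerance = 1e-12)
    }
  }
})

test_that("GLCM conservation: normalised entries sum to one", {
  set.seed(36)
  for (i in 1:5) {
    m <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
    expect_equal(sum(compute_glcm(m)$matrix), 1)
  }
})

test_that("Haralick contrast of the checkerboard GLCM is exactly 1", {
  m <- matrix(c(0, 255, 255, 0), 2, 2)
  har <- haralick_features(m, distance = 1, angles = 0, levels = 2)
  expect_equal(unname(har["contrast"]), 1.0)
})

test_that("Haralick features ignore shifts within one quantisation bin", {
  set.seed(37)
  # values on the 64-level bin lattice (width 4), shifted by less than 4
  m <- matrix(sample(seq(0, 252, by = 4), 30 * 30, replace = TRUE), 30, 30)
  expect_equal(haralick_features(m), haralick_features(m + 2))
})

test_that("GIST separates orthogonal gratings by orientation band", {
  n <- 128
  xs <- matrix(rep(0:(n - 1), each = n), n, n)   # column index
  ys <- matrix(rep(0:(n - 1), times = n), n, n)  # row index
  f0 <- 0.25                                     # scale-1 centre frequency
  vert <- 127.5 + 100 * sin(2 * pi * f0 * xs)    # varies along columns
  horiz <- 127.5 + 100 * sin(2 * pi * f0 * ys)   # varies along rows
  gv <- compute_gist(vert); gh <- compute_gist(horiz)
  # scale 1 occupies the first 8 orientation blocks of 16 values each
  band_energy <- function(g) vapply(1:8, function(o)
    sum(g[((o - 1) * 16 + 1):(o * 16)]), numeric(1))
  ov <- which.max(band_energy(gv)); oh <- which.max(band_energy(gh))
  expect_equal(abs(ov - oh), 4L)                 # 90 degrees apart
})

test_that("descriptors are finite on degenerate and extreme inputs", {
  extremes <- list(const_win(0), const_win(255),
                   { set.seed(38); matrix(sample(c(0, 255), 151 * 258,
                                                 replace = TRUE), 151, 258) })
  for (w in extremes)
    for (d in c("HOG", "DAISY", "LBP", "HARALICK", "GIST"))
      expect_true(all(is.finite(compute_descriptor(w, descriptor_spec(d)))))
})

test_that("windows too small for a descriptor raise shape errors", {
  tiny <- matrix(0, 10, 10)
  expect_error(compute_daisy(tiny), "small")
  expect_error(compute_lbp(matrix(0, 2, 2), R = 2), "small")
  expect_error(compute_glcm(matrix(0, 2, 2), distance = 5), "displacement")
})

test_that("extract_features aligns rows with regions and is deterministic", {
  sc <- small_scene(seed = 39)
  imgs <- list(); imgs[[sc$image$image_id]] <- sc$image
  regs <- sample_balanced_regions(sc, 2, seed = 40)
  spec <- descriptor_spec("HARALICK")
  X <- extract_features(regs, imgs, spec)
  expect_equal(dim(X), c(4L, 13L))
  expect_equal(attr(X, "labels"), vapply(regs, function(r) r$label, ""))
  # duplicated region -> identical rows
  X2 <- extract_features(c(regs[1], regs[1]), imgs, spec)
  expect_equal(X2[1, ], X2[2, ])
  # empty input -> 0-row matrix with the right width
  X0 <- extract_features(list(), imgs, spec)
  expect_equal(dim(X0), c(0L, 13L))
  # unknown image id -> indexed error
  bad <- regs[[1]]; bad$image_id <- "nope"
  expect_error(extract_features(list(bad), imgs, spec), "region 1")
})
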