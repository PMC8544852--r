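# Handcrafted window descriptors: HOG, DAISY, LBP, GLCM/Haralick, GIST.
# Every descriptor is a pure function of the window pixels and returns a
# fixed-length finite vector for the configured window shape.

.pkg_cache <- new.env(parent = emptyenv())

# --- small numeric helpers ---------------------------------------------------

# accept a stoma_image (grayscale or RGB) or a plain matrix; return a
# grayscale matrix on the 8-bit scale
as_gray_matrix <- function(window) {
  if (inherits(window, "stoma_image")) {
    window <- to_grayscale(window)
    return(window$pixels)
  }
  if (is.matrix(window)) return(window)
  stop("window must be a stoma_image or a numeric matrix", call. = FALSE)
}

# bilinear resize through EBImage (whose first array dimension matches our
# row dimension, so target sizes are passed straight through)
resize_gray <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = h, h = w))
}

# one-dimensional Gaussian blur operator with replicated borders (rows sum
# to 1, so constants are preserved); cached per (n, sigma)
blur_operator <- function(n, sigma) {
  key <- sprintf("blur_op_%d_%g", n, sigma)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + seq(-r, r), 1L), n)   # replicate border
    for (t in seq_along(j)) B[i, j[t]] <- B[i, j[t]] + k[t]
  }
  B <- B / rowSums(B)
  .pkg_cache[[key]] <- B
  B
}

# separable Gaussian blur via the cached operators (BLAS matmuls)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Br <- blur_operator(nrow(m), sigma)
  Bc <- blur_operator(ncol(m), sigma)
  Br %*% m %*% t(Bc)
}

# central-difference gradients with replicated borders, on any numeric matrix
image_gradients <- function(m) {
  h <- nrow(m); w <- ncol(m)
  left  <- m[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- m[, c(seq_len(w)[-1L], w), drop = FALSE]
  up    <- m[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(h)[-1L], h), , drop = FALSE]
  list(gx = (right - left) / 2, gy = (down - up) / 2)
}

l2_normalize <- function(v, eps = 1e-6) v / sqrt(sum(v^2) + eps^2)

# --- descriptor specification ------------------------------------------------

.descriptor_defaults <- list(
  HOG = list(orientations = 9L, cell = c(16L, 16L), block = c(2L, 2L),
             resize_to = c(144L, 256L)),
  DAISY = list(step = 32L, radius = 24L, rings = 3L, histograms = 8L,
               orientations = 8L),
  LBP = list(P = 8L, R = 1),
  HARALICK = list(distance = 1L, angles = c(0, 45, 90, 135), levels = 64L),
  GIST = list(resize_to = c(128L, 128L), scales = 4L,
              orientations_per_scale = 8L, grid = c(4L, 4L))
)

#' Descriptor specification
#'
#' Names one of the five handcrafted descriptors and its parameters. The
#' defaults are standard-literature values and are recorded here (and
#' serialised with every learned model) because reproducibility of the
#' feature extraction depends on them. `output_dim` is fixed for a given
#' window shape.
#'
#' @param name One of `"HOG"`, `"DAISY"`, `"LBP"`, `"HARALICK"`, `"GIST"`.
#' @param params Named list overriding the defaults.
#' @return An object of class `descriptor_spec`.
#' @export
descriptor_spec <- function(name = c("HOG", "DAISY", "LBP", "HARALICK", "GIST"),
                            params = list()) {
  name <- match.arg(name)
  p <- utils::modifyList(.descriptor_defaults[[name]], params)
  structure(list(name = name, params = p), class = "descriptor_spec")
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat(sprintf("<descriptor_spec %s: %s>\n", x$name,
              paste(names(x$params), vapply(x$params, function(v)
                paste(v, collapse = "x"), ""), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Fixed output length of a descriptor for a window shape
#'
#' @param spec A [descriptor_spec].
#' @param window_shape `(height, width)` of the windows to be described.
#' @return Integer vector length of the descriptor.
#' @export
descriptor_output_dim <- function(spec, window_shape = c(151L, 258L)) {
  p <- spec$params
  switch(spec$name,
    HOG = {
      ncr <- p$resize_to[1] %/% p$cell[1]
      ncc <- p$resize_to[2] %/% p$cell[2]
      (ncr - p$block[1] + 1L) * (ncc - p$block[2] + 1L) *
        p$block[1] * p$block[2] * p$orientations
    },
    DAISY = {
      gr <- daisy_grid(window_shape[1], p$radius, p$step)
      gc <- daisy_grid(window_shape[2], p$radius, p$step)
      length(gr) * length(gc) * (p$rings * p$histograms + 1L) * p$orientations
    },
    LBP = lbp_n_bins(p$P),
    HARALICK = 13L,
    GIST = p$scales * p$orientations_per_scale * prod(p$grid)
  )
}

#' Compute a descriptor for one window
#'
#' Dispatches to the descriptor named in the spec. See [compute_hog],
#' [compute_daisy], [compute_lbp], [haralick_features], [compute_gist].
#'
#' @param window Grayscale window ([stoma_image] or matrix, 8-bit scale).
#' @param spec A [descriptor_spec].
#' @return Numeric feature vector of length `descriptor_output_dim(spec)`.
#' @export
compute_descriptor <- function(window, spec) {
  stopifnot(inherits(spec, "descriptor_spec"))
  p <- spec$params
  switch(spec$name,
    HOG = compute_hog(window, orientations = p$orientations, cell = p$cell,
                      block = p$block, resize_to = p$resize_to),
    DAISY = compute_daisy(window, step = p$step, radius = p$radius,
                          rings = p$rings, histograms = p$histograms,
                          orientations = p$orientations),
    LBP = compute_lbp(window, P = p$P, R = p$R),
    HARALICK = haralick_features(window, distance = p$distance,
                                 angles = p$angles, levels = p$levels),
    GIST = compute_gist(window, resize_to = p$resize_to, scales = p$scales,
                        orientations_per_scale = p$orientations_per_scale,
                        grid = p$grid)
  )
}

# --- HOG ---------------------------------------------------------------------

#' Histogram of oriented gradients
#'
#' The window is resized so its sides divide the cell size, unsigned gradient
#' orientations (\[0, 180) degrees) are histogrammed per cell weighted by
#' gradient magnitude, and overlapping blocks of cells are L2-normalised with
#' an epsilon guard (a constant window therefore maps to the all-zero
#' vector). With the defaults the output has
#' `8 * 15 * 4 * 9 = 4320` entries.
#'
#' @param window Grayscale window (matrix or [stoma_image]).
#' @param orientations Number of unsigned orientation bins.
#' @param cell Cell size `(rows, cols)` in px.
#' @param block Block size in cells; blocks slide with stride one cell.
#' @param resize_to Target size before extraction; must divide by `cell`.
#' @return Numeric vector.
#' @export
compute_hog <- function(window, orientations = 9L, cell = c(16L, 16L),
                        block = c(2L, 2L), resize_to = c(144L, 256L)) {
  m <- as_gray_matrix(window) / 255
  m <- resize_gray(m, resize_to[1], resize_to[2])
  ncr <- nrow(m) %/% cell[1]; ncc <- ncol(m) %/% cell[2]
  if (ncr < block[1] || ncc < block[2])
    stop("window too small for the configured HOG cell/block sizes",
         call. = FALSE)
  g <- image_gradients(m)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ang <- atan2(g$gy, g$gx) %% pi
  bin <- pmin(floor(ang / pi * orientations), orientations - 1L)
  ci <- (row(m) - 1L) %/% cell[1]          # 0-based cell row
  cj <- (col(m) - 1L) %/% cell[2]
  idx <- 1L + ci + ncr * (cj + ncc * bin)  # column-major (ci, cj, bin)
  hist <- numeric(ncr * ncc * orientations)
  acc <- rowsum(as.vector(mag), group = as.vector(idx))
  hist[as.integer(rownames(acc))] <- acc
  cells <- array(hist, dim = c(ncr, ncc, orientations))
  out <- vector("list", (ncr - block[1] + 1L) * (ncc - block[2] + 1L))
  k <- 0L
  for (bi in seq_len(ncr - block[1] + 1L)) {
    for (bj in seq_len(ncc - block[2] + 1L)) {
      k <- k + 1L
      v <- as.vector(cells[bi:(bi + block[1] - 1L),
                           bj:(bj + block[2] - 1L), ])
      out[[k]] <- l2_normalize(v)
    }
  }
  unlist(out, use.names = FALSE)
}

# --- DAISY -------------------------------------------------------------------

# 0-based grid coordinates along one axis
daisy_grid <- function(extent, radius, step) {
  if (extent <= 2L * radius)
    stop("window too small for the configured DAISY radius", call. = FALSE)
  seq.int(radius, extent - 1L - radius, by = step)
}

#' DAISY dense descriptor
#'
#' Quantised gradient-orientation maps (half-wave rectified directional
#' derivatives) are convolved with Gaussians of increasing size; each grid
#' point concatenates the centre sample with samples on `rings` concentric
#' circles (`histograms` points per ring), giving
#' `(rings * histograms + 1) * orientations` values per point, L2-normalised
#' per point with an epsilon guard. Descriptors of all grid points are
#' concatenated in row-major grid order.
#'
#' @param window Grayscale window.
#' @param step Grid spacing in px.
#' @param radius Outer ring radius in px (also the border margin).
#' @param rings Number of concentric rings.
#' @param histograms Sample points per ring.
#' @param orientations Number of gradient orientation maps.
#' @return Numeric vector.
#' @export
compute_daisy <- function(window, step = 32L, radius = 24L, rings = 3L,
                          histograms = 8L, orientations = 8L) {
  m <- as_gray_matrix(window) / 255
  h <- nrow(m); w <- ncol(m)
  gr <- daisy_grid(h, radius, step)
  gc <- daisy_grid(w, radius, step)
  g <- image_gradients(m)
  sigma_c <- radius / (2 * rings)
  sigmas <- sigma_c * seq_len(rings + 1L)         # centre + one per ring
  ring_radii <- radius * seq_len(rings) / rings
  # blurred orientation maps: [[level]][[orientation]]
  maps <- lapply(seq_len(rings + 1L), function(l) {
    lapply(seq_len(orientations), function(o) {
      th <- 2 * pi * (o - 1L) / orientations
      gmap <- cos(th) * g$gx + sin(th) * g$gy
      gmap[gmap < 0] <- 0   # half-wave rectification, dim preserved
      gaussian_blur(gmap, sigmas[l])
    })
  })
  pts <- expand.grid(col = gc, row = gr)          # row-major over (gr, gc)
  pts <- pts[order(rep(seq_along(gr), each = length(gc))), , drop = FALSE]
  pr <- rep(gr, each = length(gc)); pc <- rep(gc, times = length(gr))
  n_pts <- length(pr)
  dlen <- (rings * histograms + 1L) * orientations
  desc <- matrix(0, n_pts, dlen)
  col_at <- 0L
  for (o in seq_len(orientations)) {
    col_at <- col_at + 1L
    desc[, col_at] <- maps[[1L]][[o]][cbind(pr + 1L, pc + 1L)]
  }
  for (ri in seq_len(rings)) {
    for (hj in seq_len(histograms)) {
      phi <- 2 * pi * (hj - 1L) / histograms
      sr <- pmin(pmax(pr + round(ring_radii[ri] * sin(phi)), 0L), h - 1L)
      sc <- pmin(pmax(pc + round(ring_radii[ri] * cos(phi)), 0L), w - 1L)
      for (o in seq_len(orientations)) {
        col_at <- col_at + 1L
        desc[, col_at] <- maps[[ri + 1L]][[o]][cbind(sr + 1L, sc + 1L)]
      }
    }
  }
  desc <- t(apply(desc, 1L, l2_normalize))
  as.vector(t(desc))
}

# --- LBP ---------------------------------------------------------------------

lbp_n_bins <- function(P) P * (P - 1L) + 3L

# uniform-pattern lookup: code -> bin (1-based); non-uniform codes share the
# last bin
lbp_uniform_table <- function(P) {
  key <- sprintf("lbp_table_%d", P)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  n_codes <- 2L^P
  codes <- 0:(n_codes - 1L)
  bits <- t(sapply(codes, function(x) as.integer(intToBits(x)[1:P])))
  trans <- rowSums(bits != bits[, c(2:P, 1L), drop = FALSE])
  uniform <- which(trans <= 2L) # includes all-0 and all-1
  table <- integer(n_codes)
  table[uniform] <- seq_along(uniform)
  table[-uniform] <- length(uniform) + 1L
  stopifnot(length(uniform) + 1L == lbp_n_bins(P))
  .pkg_cache[[key]] <- table
  table
}

#' Uniform local binary pattern histogram
#'
#' Each interior pixel is compared with `P` neighbours on a circle of radius
#' `R` (bilinear interpolation off-grid; neighbour >= centre sets the bit).
#' Codes are mapped to the `P*(P-1)+3` uniform bins (59 for `P = 8`) and the
#' histogram is normalised to sum 1.
#'
#' @param window Grayscale window.
#' @param P Number of circular neighbours.
#' @param R Circle radius in px.
#' @return Numeric probability vector of length `P*(P-1)+3`.
#' @export
compute_lbp <- function(window, P = 8L, R = 1) {
  m <- as_gray_matrix(window)
  h <- nrow(m); w <- ncol(m)
  pad <- ceiling(R)
  if (2 * pad + 1 > min(h, w))
    stop("window too small for the configured LBP radius", call. = FALSE)
  # replicate-pad so the weight-0 corner of an exactly-integer offset is
  # still addressable
  pp <- pad + 1L
  mp <- m[c(rep(1L, pp), seq_len(h), rep(h, pp)),
          c(rep(1L, pp), seq_len(w), rep(w, pp)), drop = FALSE]
  rows <- (pad + 1L):(h - pad) + pp; cols <- (pad + 1L):(w - pad) + pp
  center <- mp[rows, cols, drop = FALSE]
  code <- matrix(0L, nrow(center), ncol(center))
  for (k in 0:(P - 1L)) {
    ang <- 2 * pi * k / P
    dr <- -R * sin(ang); dc <- R * cos(ang)
    fr <- floor(dr); fc <- floor(dc)
    tr <- dr - fr; tc <- dc - fc
    sub <- function(er, ec)
      mp[rows + fr + er, cols + fc + ec, drop = FALSE]
    nbr <- (1 - tr) * (1 - tc) * sub(0L, 0L) +
           (1 - tr) * tc       * sub(0L, 1L) +
           tr       * (1 - tc) * sub(1L, 0L) +
           tr       * tc       * sub(1L, 1L)
    nbr <- round(nbr, 6)  # stabilise interpolation ties
    code <- code + bitwShiftL(1L, k) * (nbr >= center)
  }
  table <- lbp_uniform_table(P)
  bins <- table[code + 1L]
  tabulate(bins, nbins = lbp_n_bins(P)) / length(bins)
}

# --- GLCM / Haralick ---------------------------------------------------------

glcm_offset <- function(distance, angle) {
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    stop(sprintf("unsupported GLCM angle %s (use 0, 45, 90 or 135)", angle),
         call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Intensities are quantised to `levels` equal-width bins of the 8-bit range;
#' pairs of quantised values at the displacement given by `(distance, angle)`
#' are counted, symmetrised, and normalised to sum 1.
#'
#' @param window Grayscale window (8-bit scale).
#' @param distance Displacement in px.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param levels Number of gray levels after quantisation.
#' @param symmetric Count each pair in both directions.
#' @param normalize Normalise entries to sum 1.
#' @return An object of class `glcm`: list with `matrix`, `distance`,
#'   `angle`, `levels`.
#' @export
compute_glcm <- function(window, distance = 1L, angle = 0, levels = 64L,
                         symmetric = TRUE, normalize = TRUE) {
  m <- as_gray_matrix(window)
  q <- pmin(floor(m * levels / 256), levels - 1L)
  off <- glcm_offset(distance, angle)
  h <- nrow(q); w <- ncol(q)
  r_src <- seq_len(h); c_src <- seq_len(w)
  r_src <- r_src[r_src + off[1] >= 1L & r_src + off[1] <= h]
  c_src <- c_src[c_src + off[2] >= 1L & c_src + off[2] <= w]
  if (!length(r_src) || !length(c_src))
    stop("GLCM displacement larger than the window", call. = FALSE)
  a <- q[r_src, c_src, drop = FALSE]
  b <- q[r_src + off[1], c_src + off[2], drop = FALSE]
  counts <- tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                     nbins = levels^2)
  M <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) M <- M + t(M)
  if (normalize && sum(M) > 0) M <- M / sum(M)
  structure(list(matrix = M, distance = distance, angle = angle,
                 levels = levels), class = "glcm")
}

# the 13 classic co-occurrence statistics for one normalised symmetric GLCM;
# natural logs, 0*log(0) = 0, degenerate denominators map to 0
haralick_stats <- function(P) {
  N <- nrow(P)
  i <- 0:(N - 1L)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * px); muy <- sum(i * py)
  sx <- sqrt(sum((i - mux)^2 * px)); sy <- sqrt(sum((i - muy)^2 * py))
  ij <- outer(i, i)
  sum_idx <- as.vector(outer(i, i, "+"))
  diff_idx <- as.vector(abs(outer(i, i, "-")))
  pv <- as.vector(P)
  psum <- numeric(2L * N - 1L)
  acc <- rowsum(pv, sum_idx); psum[as.integer(rownames(acc)) + 1L] <- acc
  pdiff <- numeric(N)
  acc <- rowsum(pv, diff_idx); pdiff[as.integer(rownames(acc)) + 1L] <- acc
  ks <- 0:(2L * N - 2L); kd <- 0:(N - 1L)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  f1 <- sum(P^2)
  f2 <- sum(kd^2 * pdiff)
  f3 <- if (sx > 0 && sy > 0) (sum(ij * P) - mux * muy) / (sx * sy) else 0
  f4 <- sum((i - mux)^2 * px)
  f5 <- sum(P / (1 + outer(i, i, "-")^2))
  f6 <- sum(ks * psum)
  f7 <- sum((ks - f6)^2 * psum)
  f8 <- -sum(xlogx(psum))
  f9 <- -sum(xlogx(P))
  mu_d <- sum(kd * pdiff)
  f10 <- sum((kd - mu_d)^2 * pdiff)
  f11 <- -sum(xlogx(pdiff))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(ifelse(P > 0 & pxy > 0, P * log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  c(asm = f1, contrast = f2, correlation = f3, variance = f4, idm = f5,
    sum_average = f6, sum_variance = f7, sum_entropy = f8, entropy = f9,
    diff_variance = f10, diff_entropy = f11, imc1 = f12, imc2 = f13)
}

#' Haralick texture features
#'
#' The 13 classic co-occurrence statistics (angular second moment, contrast,
#' correlation, variance, inverse difference moment, sum average,
#' sum variance, sum entropy, entropy, difference variance, difference
#' entropy, and the two information measures of correlation), computed per
#' angle from symmetric normalised GLCMs and averaged over angles. Natural
#' logarithms with `0 log 0 = 0`; statistics with vanishing denominators
#' (correlation, IMC1 on degenerate windows) are defined as 0.
#'
#' @inheritParams compute_glcm
#' @param angles Angles (degrees) to average over.
#' @return Named numeric vector of length 13.
#' @export
haralick_features <- function(window, distance = 1L,
                              angles = c(0, 45, 90, 135), levels = 64L) {
  stats_per_angle <- vapply(angles, function(a) {
    g <- compute_glcm(window, distance = distance, angle = a, levels = levels)
    haralick_stats(g$matrix)
  }, numeric(13))
  rowMeans(stats_per_angle)
}

# --- GIST --------------------------------------------------------------------

# frequency grid in cycles/pixel for an n x n image (rows = f_r, cols = f_c)
fft_freq <- function(n) {
  f <- c(seq(0, floor(n / 2) - 1), seq(-ceiling(n / 2), -1)) / n
  f
}

gist_filter_bank <- function(n, scales, orientations) {
  key <- sprintf("gist_bank_%d_%d_%d", n, scales, orientations)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  fr_ <- fft_freq(n)
  FR <- matrix(rep(fr_, times = n), n, n)          # row frequency
  FC <- matrix(rep(fr_, each = n), n, n)           # col frequency
  rad <- sqrt(FR^2 + FC^2)
  th <- atan2(FR, FC)
  f0s <- 0.25 / 2^(0:(scales - 1L))
  sigma_th <- pi / orientations
  bank <- vector("list", scales * orientations)
  k <- 0L
  for (s in seq_len(scales)) {
    f0 <- f0s[s]
    for (o in seq_len(orientations)) {
      th0 <- pi * (o - 1L) / orientations
      dth <- ((th - th0 + pi) %% (2 * pi)) - pi    # wrapped, one-sided
      G <- exp(-(rad - f0)^2 / (2 * (0.4 * f0)^2) - dth^2 / (2 * sigma_th^2))
      G[1, 1] <- 0                                 # kill DC
      k <- k + 1L
      bank[[k]] <- G
    }
  }
  out <- list(bank = bank, f0s = f0s)
  .pkg_cache[[key]] <- out
  out
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Gaussian low-pass in the frequency domain with cutoff fc (cycles/image)
lowpass <- function(m, fc) {
  n <- nrow(m)
  f <- fft_freq(n) * n                             # cycles/image
  H <- exp(-(outer(f^2, f^2, "+")) / (fc^2))
  Re(ifft2(fft2(m) * H))
}

#' GIST scene descriptor
#'
#' Oliva–Torralba pipeline: the window is resized to a square, passed through
#' a local-contrast prefilter (log intensity, Gaussian high-pass whitening,
#' divisive normalisation with an epsilon guard), filtered with a bank of
#' `scales * orientations_per_scale` Gabor-like transfer functions built in
#' the frequency domain, and the response magnitudes are averaged over a
#' coarse spatial grid. Defaults give `4 * 8 * 16 = 512` values. A constant
#' window maps exactly to the zero vector.
#'
#' @param window Grayscale window.
#' @param resize_to Square working size `(n, n)`.
#' @param scales Number of frequency scales (centre frequencies
#'   `0.25 / 2^(s-1)` cycles/px).
#' @param orientations_per_scale Orientation bands per scale.
#' @param grid Spatial pooling grid `(rows, cols)`.
#' @return Numeric vector.
#' @export
compute_gist <- function(window, resize_to = c(128L, 128L), scales = 4L,
                         orientations_per_scale = 8L, grid = c(4L, 4L)) {
  m <- as_gray_matrix(window)
  n <- resize_to[1]
  m <- resize_gray(m, n, resize_to[2])
  L <- log(1 + m)
  W <- L - lowpass(L, fc = 4)
  V <- lowpass(W^2, fc = 4)
  V[V < 0] <- 0
  C <- W / (0.2 + sqrt(V))
  bank <- gist_filter_bank(n, scales, orientations_per_scale)$bank
  Fc <- fft2(C)
  block_r <- n %/% grid[1]; block_c <- resize_to[2] %/% grid[2]
  br <- (seq_len(n) - 1L) %/% block_r
  bc <- (seq_len(resize_to[2]) - 1L) %/% block_c
  pool_idx <- 1L + outer(pmin(br, grid[1] - 1L), pmin(bc, grid[2] - 1L) * grid[1], "+")
  out <- numeric(length(bank) * prod(grid))
  at <- 0L
  for (G in bank) {
    E <- Mod(ifft2(Fc * G))
    acc <- rowsum(as.vector(E), group = as.vector(pool_idx))
    sizes <- tabulate(as.vector(pool_idx), nbins = prod(grid))
    means <- numeric(prod(grid))
    means[as.integer(rownames(acc))] <- acc / sizes[as.integer(rownames(acc))]
    out[at + seq_len(prod(grid))] <- means
    at <- at + prod(grid)
  }
  out
}

# --- batch extraction --------------------------------------------------------

#' Extract a feature matrix from labeled regions
#'
#' Row `i` holds the descriptor of region `i`, in input order; the label
#' vector is attached as attribute `"labels"` and the spec as
#' `"descriptor"`.
#'
#' @param regions List of [labeled_region].
#' @param images Named list of [stoma_image], indexed by `image_id`.
#' @param spec A [descriptor_spec].
#' @return Numeric matrix with one row per region.
#' @export
extract_features <- function(regions, images, spec) {
  stopifnot(inherits(spec, "descriptor_spec"))
  ws <- if (length(regions))
    c(regions[[1]]$box$height, regions[[1]]$box$width) else c(151L, 258L)
  dim_out <- descriptor_output_dim(spec, ws)
  X <- matrix(NA_real_, length(regions), dim_out)
  labels <- character(length(regions))
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    img <- images[[reg$image_id]]
    if (is.null(img))
      stop(sprintf("region %d references unknown image '%s'",
                   i, reg$image_id), call. = FALSE)
    v <- tryCatch(
      compute_descriptor(to_grayscale(crop_window(img, reg$box)), spec),
      error = function(e)
        stop(sprintf("feature extraction failed at region %d: %s",
                     i, conditionMessage(e)), call. = FALSE))
    X[i, ] <- v
    labels[i] <- reg$label
  }
  attr(X, "labels") <- labels
  attr(X, "descriptor") <- spec
  X
}
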