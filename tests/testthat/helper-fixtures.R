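# Shared fixtures and independent oracles, all built in code.

# small random 8-bit grayscale image
rand_image <- function(h, w, seed = 1, id = "img") {
  set.seed(seed)
  stoma_image(matrix(sample(0:255, h * w, replace = TRUE), h, w),
              image_id = id)
}

# quick small scene (fast to generate, 3 stomata)
small_scene <- function(seed = 1, contrast = 0.85, noise_sd = 4, n = 3,
                        ...) {
  generate_scene(scene_spec(image_shape = c(700L, 900L), n_stomata = n,
                            row_spacing = 120, contrast = contrast,
                            noise_sd = noise_sd, seed = seed, ...))
}

# ground-truth window classifier: positive iff the window overlaps any
# truth box
oracle_classifier <- function(truth_boxes) {
  function(image, grid) {
    vapply(seq_len(nrow(grid$origins)), function(i) {
      b <- bbox(grid$origins[i, 1], grid$origins[i, 2],
                grid$window_shape[1], grid$window_shape[2])
      inter <- pmax(0, pmin(b$row0 + b$height,
                            truth_boxes$row0 + truth_boxes$height) -
                      pmax(b$row0, truth_boxes$row0)) *
               pmax(0, pmin(b$col0 + b$width,
                            truth_boxes$col0 + truth_boxes$width) -
                      pmax(b$col0, truth_boxes$col0))
      if (length(inter) && any(inter > 0)) "stoma" else "non_stoma"
    }, "")
  }
}

# brute-force flood fill connected components (BFS), independent of the
# package's labeling path
flood_fill_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8L)
    rbind(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),c(1,-1),c(1,0),c(1,1))
  else rbind(c(-1,0),c(0,-1),c(0,1),c(1,0))
  cur <- 0L
  for (sr in seq_len(h)) for (sc in seq_len(w)) {
    if (!mask[sr, sc] || lab[sr, sc] > 0L) next
    cur <- cur + 1L
    queue <- list(c(sr, sc)); lab[sr, sc] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# brute-force GLCM by explicit pair enumeration over every pixel
glcm_oracle <- function(m, distance, angle, levels, symmetric = TRUE) {
  q <- pmin(floor(m * levels / 256), levels - 1)
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  M <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q))
      M[q[r, c] + 1, q[r2, c2] + 1] <- M[q[r, c] + 1, q[r2, c2] + 1] + 1
  }
  if (symmetric) M <- M + t(M)
  if (sum(M) > 0) M <- M / sum(M)
  M
}

# enumeration oracle for sliding-window origins (full windows only)
grid_oracle <- function(H, W, h, w, s) {
  out <- NULL
  r <- 0L
  while (r + h <= H) {
    c <- 0L
    while (c + w <= W) {
      out <- rbind(out, c(r, c))
      c <- c + s
    }
    r <- r + s
  }
  out
}
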