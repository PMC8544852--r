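#' Synthetic maize-epidermis scene specification
#'
#' Parameterises the generator that stands in for real cyanoacrylate-
#' impression micrographs: dark dumbbell-shaped stomata (two guard-cell
#' lobes joined by a narrow pore slit) arranged in longitudinal cell files
#' on a lighter, faintly textured epidermis background, with optional
#' imaging artifacts (air bubbles, leaf residuals, grooves, degraded
#' stomata, low image quality).
#'
#' All linear units are pixels; intensities are on the 8-bit scale.
#'
#' @param image_shape `(height, width)` of the generated image.
#' @param n_stomata Number of stomata to place.
#' @param stoma_length `(mean, sd)` of the stoma long axis (along the leaf,
#'   horizontal) in px.
#' @param stoma_width `(mean, sd)` of the stoma short axis in px.
#' @param row_spacing Vertical spacing between longitudinal stomatal files.
#' @param orientation_jitter SD (degrees) of per-stoma rotation about the
#'   horizontal file axis.
#' @param contrast Stoma-vs-background intensity gap as a fraction of the
#'   8-bit range, in \[0, 1\].
#' @param artifact_config Named list enabling artifact types; see
#'   [add_artifacts].
#' @param noise_sd SD of additive Gaussian pixel noise (8-bit units).
#' @param background_level Mean epidermis intensity (8-bit).
#' @param texture_amp Amplitude of the background cell-wall texture.
#' @param window_shape Classification window `(height, width)`; stomata are
#'   kept at least half a window away from the borders so centred windows
#'   always fit.
#' @param placement_pad `(rows, cols)` padding added around each truth box
#'   when rejecting overlapping placements; the default keeps a small gap
#'   between stomata, large values produce well-separated stomata whose
#'   sliding-window detections cannot merge.
#' @param seed Integer seed; the scene is a pure function of the spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(1200L, 1600L),
                       n_stomata = 12L,
                       stoma_length = c(90, 8),
                       stoma_width = c(42, 5),
                       row_spacing = 150,
                       orientation_jitter = 6,
                       contrast = 0.6,
                       artifact_config = list(),
                       noise_sd = 8,
                       background_level = 200,
                       texture_amp = 10,
                       window_shape = c(151L, 258L),
                       placement_pad = c(8L, 8L),
                       seed = 1L) {
  if (contrast < 0 || contrast > 1)
    stop("contrast must lie in [0, 1]", call. = FALSE)
  if (n_stomata < 0) stop("n_stomata must be >= 0", call. = FALSE)
  structure(list(
    image_shape = as.integer(image_shape), n_stomata = as.integer(n_stomata),
    stoma_length = stoma_length, stoma_width = stoma_width,
    row_spacing = row_spacing, orientation_jitter = orientation_jitter,
    contrast = contrast, artifact_config = artifact_config,
    noise_sd = noise_sd, background_level = background_level,
    texture_amp = texture_amp, window_shape = as.integer(window_shape),
    placement_pad = as.integer(placement_pad),
    seed = as.integer(seed)), class = "scene_spec")
}

# clamp to the 8-bit range preserving dim
clamp8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Run code under a seeded, restored RNG so generators never disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Epidermis background: light base, longitudinal file shading, faint
# transverse cell walls, slow illumination gradient.
render_background <- function(h, w, level, amp, row_spacing) {
  rows <- seq_len(h); cols <- seq_len(w)
  file_phase <- stats::runif(1, 0, 2 * pi)
  shading <- amp * 0.5 * sin(2 * pi * rows / row_spacing + file_phase)
  grad_r <- stats::runif(1, -4, 4); grad_c <- stats::runif(1, -4, 4)
  illum <- outer((rows / h - 0.5) * grad_r, (cols / w - 0.5) * grad_c, "+")
  img <- matrix(level, h, w) + shading + illum
  # transverse (vertical) cell walls: dark 2 px lines at jittered spacing
  wall_cols <- cumsum(stats::runif(ceiling(w / 60) + 2, 50, 130))
  wall_cols <- wall_cols[wall_cols < w - 1]
  for (wc in wall_cols) {
    wc <- round(wc)
    img[, wc:(wc + 1)] <- img[, wc:(wc + 1)] - amp * stats::runif(1, 0.5, 1)
  }
  img
}

# Render one dumbbell stoma into the image, clipped to its truth box.
# Returns the modified image; `drop_mask_env`, if given, accumulates the
# pixel mask actually darkened.
render_stoma <- function(img, center, len, wid, theta, depth, box,
                         drop_mask_env = NULL) {
  rows <- (box$row0 + 1L):(box$row0 + box$height)
  cols <- (box$col0 + 1L):(box$col0 + box$width)
  rr <- outer(rows - 1 - center[1], rep(1, length(cols)))
  cc <- outer(rep(1, length(rows)), cols - 1 - center[2])
  ct <- cos(theta); st <- sin(theta)
  u <- cc * ct + rr * st      # along the long axis
  v <- -cc * st + rr * ct     # across
  u0 <- 0.32 * len
  lobe_su <- 0.11 * len; lobe_sv <- 0.26 * wid
  lobes <- exp(-((u - u0)^2) / (2 * lobe_su^2) - v^2 / (2 * lobe_sv^2)) +
           exp(-((u + u0)^2) / (2 * lobe_su^2) - v^2 / (2 * lobe_sv^2))
  slit <- exp(-v^2 / (2 * (0.09 * wid)^2)) *
          exp(-u^2 / (2 * (0.28 * len)^2))
  drop <- depth * pmin(1, lobes + 0.85 * slit)
  img[rows, cols] <- img[rows, cols] - drop
  if (!is.null(drop_mask_env)) {
    m <- drop > 1
    drop_mask_env$mask[rows, cols] <- drop_mask_env$mask[rows, cols] | m
  }
  img
}

# Truth box of a rotated stoma: rotated footprint of the len x wid ellipse
# plus a small pad, clamped to integers.
stoma_truth_box <- function(center, len, wid, theta) {
  hr <- 0.5 * (len * abs(sin(theta)) + wid * abs(cos(theta))) + 3
  hc <- 0.5 * (len * abs(cos(theta)) + wid * abs(sin(theta))) + 3
  r0 <- floor(center[1] - hr); c0 <- floor(center[2] - hc)
  bbox(r0, c0, ceiling(2 * hr), ceiling(2 * hc))
}

#' Generate a synthetic epidermis scene
#'
#' Deterministic given the spec (including its seed). Stomata are placed in
#' horizontal files with jittered spacing; each is rendered as a dark
#' dumbbell and recorded as a tight ground-truth box. Artifacts (if
#' configured) and additive Gaussian noise are applied afterwards; ground
#' truth is unaffected by artifacts.
#'
#' @param spec A [scene_spec].
#' @param keep_mask If `TRUE`, the rendered stoma pixel mask is kept in
#'   `$provenance$stoma_mask` (for consistency checks).
#' @return An object of class `synthetic_scene`: list with `image`
#'   ([stoma_image]), `truth` ([annotation_set]), `spec`, `provenance`.
#' @export
generate_scene <- function(spec, keep_mask = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$image_shape[1]; w <- spec$image_shape[2]
    margin_r <- ceiling(spec$window_shape[1] / 2)
    margin_c <- ceiling(spec$window_shape[2] / 2)
    img <- render_background(h, w, spec$background_level, spec$texture_amp,
                             spec$row_spacing)
    mask_env <- if (keep_mask) {
      e <- new.env(); e$mask <- matrix(FALSE, h, w); e
    } else NULL

    # placement: candidate slots along horizontal files
    boxes <- empty_boxes()
    placed <- list()
    if (spec$n_stomata > 0L) {
      file_rows <- seq(margin_r + 20, h - margin_r - 20, by = spec$row_spacing)
      if (!length(file_rows))
        stop("image too small for the window margin", call. = FALSE)
      tries <- 0L; max_tries <- 400L * spec$n_stomata
      while (nrow(boxes) < spec$n_stomata && tries < max_tries) {
        tries <- tries + 1L
        len <- max(20, stats::rnorm(1, spec$stoma_length[1], spec$stoma_length[2]))
        wid <- max(10, stats::rnorm(1, spec$stoma_width[1], spec$stoma_width[2]))
        theta <- stats::rnorm(1, 0, spec$orientation_jitter) * pi / 180
        fr <- sample(file_rows, 1L) + stats::rnorm(1, 0, spec$row_spacing / 12)
        fc <- stats::runif(1, margin_c + len, w - margin_c - len)
        box <- stoma_truth_box(c(fr, fc), len, wid, theta)
        if (box$row0 < margin_r || box$col0 < margin_c ||
            box$row0 + box$height > h - margin_r ||
            box$col0 + box$width > w - margin_c) next
        # a gap between truth boxes keeps regions unambiguous
        pad <- spec$placement_pad
        grown <- bbox(max(0L, box$row0 - pad[1]), max(0L, box$col0 - pad[2]),
                      box$height + 2L * pad[1], box$width + 2L * pad[2])
        if (nrow(boxes) && any(bbox_intersection_area(grown, boxes) > 0)) next
        img <- render_stoma(img, c(fr, fc), len, wid, theta,
                            depth = spec$contrast * 255, box = box,
                            drop_mask_env = mask_env)
        boxes <- rbind(boxes, data.frame(row0 = box$row0, col0 = box$col0,
                                         height = box$height, width = box$width))
        placed[[length(placed) + 1L]] <-
          list(center = c(fr, fc), length = len, width = wid, theta = theta)
      }
      if (nrow(boxes) < spec$n_stomata)
        stop(sprintf(
          "could not place %d non-overlapping stomata (placed %d) within the retry budget",
          spec$n_stomata, nrow(boxes)), call. = FALSE)
    }

    image_id <- sprintf("synthetic_seed%d", spec$seed)
    image <- stoma_image(clamp8(img), image_id = image_id)
    artifact_log <- NULL
    if (length(spec$artifact_config)) {
      image <- add_artifacts(image, spec$artifact_config,
                             seed = spec$seed + 1L, truth = boxes)
      artifact_log <- attr(image, "artifact_log")
    }
    if (spec$noise_sd > 0) {
      px <- image$pixels + stats::rnorm(h * w, 0, spec$noise_sd)
      image <- stoma_image(clamp8(px), image_id = image_id)
    }
    truth <- annotation_set(image_id, stomata = boxes,
                            window_shape = spec$window_shape)
    structure(list(
      image = image, truth = truth, spec = spec,
      provenance = list(stomata = placed, artifact_log = artifact_log,
                        stoma_mask = if (keep_mask) mask_env$mask else NULL)),
      class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene '%s': %d x %d px, %d stomata, contrast %.2f, noise sd %.1f>\n",
              x$image$image_id, dim(x$image$pixels)[1], dim(x$image$pixels)[2],
              nrow(x$truth$stomata), x$spec$contrast, x$spec$noise_sd))
  invisible(x)
}

.artifact_types <- c("bubbles", "residuals", "grooves", "degradation", "blur")

#' Add imaging artifacts to an image
#'
#' Emulates the recurring noise sources of impression micrographs:
#' `bubbles` (bright rings from trapped air), `residuals` (irregular dark
#' leaf debris), `grooves` (elongated dark bands from leaf bending),
#' `degradation` (attenuates a random subset of the rendered stomata —
#' requires `truth`), and `blur` (Gaussian blur plus intensity quantisation,
#' i.e. low image quality). An empty config is the identity. The artifact
#' provenance (e.g. bubble centres) is attached as attribute
#' `"artifact_log"`. Ground truth is never modified.
#'
#' @param image A grayscale [stoma_image].
#' @param artifact_config Named list; allowed names are `bubbles`
#'   (`list(k, intensity)`), `residuals` (`list(k, intensity)`), `grooves`
#'   (`list(k, intensity)`), `degradation` (`list(fraction)`), `blur`
#'   (`list(sigma, levels)`).
#' @param seed Integer seed.
#' @param truth Data frame of ground-truth boxes (needed by `degradation`).
#' @return The modified [stoma_image] with an `"artifact_log"` attribute.
#' @export
add_artifacts <- function(image, artifact_config, seed = 1L, truth = NULL) {
  stopifnot(inherits(image, "stoma_image"))
  if (!length(artifact_config)) return(image)
  unknown <- setdiff(names(artifact_config), .artifact_types)
  if (length(unknown))
    stop(sprintf("unknown artifact type(s): %s (allowed: %s)",
                 paste(unknown, collapse = ", "),
                 paste(.artifact_types, collapse = ", ")), call. = FALSE)
  with_seed(seed, {
    px <- image$pixels
    h <- nrow(px); w <- ncol(px)
    log <- list()
    cfg <- artifact_config

    if (!is.null(cfg$bubbles)) {
      k <- cfg$bubbles$k %||% 3L
      intensity <- cfg$bubbles$intensity %||% 40
      centers <- cbind(stats::runif(k, 40, h - 40), stats::runif(k, 40, w - 40))
      radii <- stats::runif(k, 25, 70)
      for (i in seq_len(k)) {
        d <- sqrt(outer((seq_len(h) - centers[i, 1])^2,
                        (seq_len(w) - centers[i, 2])^2, "+"))
        ring <- exp(-((d - radii[i])^2) / (2 * 2.5^2)) +
                0.25 * (d < radii[i])
        px <- px + intensity * ring
      }
      log$bubbles <- list(centers = centers, radii = radii)
    }
    if (!is.null(cfg$residuals)) {
      k <- cfg$residuals$k %||% 2L
      intensity <- cfg$residuals$intensity %||% 35
      centers <- cbind(stats::runif(k, 30, h - 30), stats::runif(k, 30, w - 30))
      for (i in seq_len(k)) {
        # irregular blob: a few overlapping anisotropic gaussians
        n_sub <- sample(3:6, 1)
        for (j in seq_len(n_sub)) {
          cr <- centers[i, 1] + stats::rnorm(1, 0, 15)
          cc <- centers[i, 2] + stats::rnorm(1, 0, 15)
          sr <- stats::runif(1, 6, 20); sc <- stats::runif(1, 6, 20)
          g <- exp(-outer((seq_len(h) - cr)^2 / (2 * sr^2),
                          (seq_len(w) - cc)^2 / (2 * sc^2), "+"))
          px <- px - intensity * g
        }
      }
      log$residuals <- list(centers = centers)
    }
    if (!is.null(cfg$grooves)) {
      k <- cfg$grooves$k %||% 1L
      intensity <- cfg$grooves$intensity %||% 25
      params <- matrix(NA_real_, k, 3)
      for (i in seq_len(k)) {
        theta <- stats::runif(1, -0.3, 0.3)
        offset <- stats::runif(1, 0.2 * h, 0.8 * h)
        width_ <- stats::runif(1, 15, 40)
        dist <- outer(seq_len(h), seq_len(w),
                      function(r, c) r - offset - tan(theta) * c)
        px <- px - intensity * exp(-dist^2 / (2 * width_^2))
        params[i, ] <- c(theta, offset, width_)
      }
      log$grooves <- list(params = params)
    }
    if (!is.null(cfg$degradation)) {
      if (is.null(truth) || nrow(truth) == 0L) {
        log$degradation <- list(attenuated = integer(0))
      } else {
        fraction <- cfg$degradation$fraction %||% 0.3
        n_deg <- round(fraction * nrow(truth))
        idx <- if (n_deg > 0) sample(nrow(truth), n_deg) else integer(0)
        for (i in idx) {
          rows <- (truth$row0[i] + 1L):(truth$row0[i] + truth$height[i])
          cols <- (truth$col0[i] + 1L):(truth$col0[i] + truth$width[i])
          patch <- px[rows, cols]
          bg <- stats::median(px)  # pull toward overall background
          blend <- stats::runif(1, 0.4, 0.8)
          px[rows, cols] <- blend * bg + (1 - blend) * patch
        }
        log$degradation <- list(attenuated = idx)
      }
    }
    if (!is.null(cfg$blur)) {
      sigma <- cfg$blur$sigma %||% 2
      levels <- cfg$blur$levels %||% 32L
      px <- gaussian_blur(px, sigma)
      step <- 256 / levels
      px <- floor(px / step) * step + step / 2
      log$blur <- list(sigma = sigma, levels = levels)
    }
    out <- stoma_image(clamp8(px), image_id = image$image_id)
    attr(out, "artifact_log") <- log
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample balanced labeled regions from a scene
#'
#' Draws `n_per_class` stoma windows, each centred on a distinct ground-truth
#' stoma, and `n_per_class` non-stoma windows with zero-area intersection
#' against every truth box, all of the scene's window shape.
#'
#' @param scene A [synthetic_scene].
#' @param n_per_class Windows per class.
#' @param seed Integer seed.
#' @param center_jitter Maximum absolute offset (px, per axis) of a stoma
#'   window from the stoma centre, drawn uniformly. 0 (the default) centres
#'   every stoma window exactly; a positive value emulates the arbitrary
#'   stoma positions that sliding windows see at detection time. The stoma
#'   box always stays fully inside its window.
#' @return List of [labeled_region].
#' @export
sample_balanced_regions <- function(scene, n_per_class, seed = 1L,
                                    center_jitter = 0L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  truth <- scene$truth$stomata
  ws <- scene$truth$window_shape
  h <- img_height(scene$image); w <- img_width(scene$image)
  if (nrow(truth) < n_per_class)
    stop(sprintf("scene has %d stomata but %d stoma regions were requested",
                 nrow(truth), n_per_class), call. = FALSE)
  with_seed(seed, {
    centers <- bbox_center(truth)
    pick <- sample(nrow(truth), n_per_class)
    regions <- vector("list", 2L * n_per_class)
    for (i in seq_len(n_per_class)) {
      jr <- jc <- 0L
      if (center_jitter > 0L) {
        # keep the stoma box inside the window: the admissible offset range
        # is +/- (window - stoma)/2 per axis
        max_jr <- min(center_jitter, (ws[1] - truth$height[pick[i]]) %/% 2L)
        max_jc <- min(center_jitter, (ws[2] - truth$width[pick[i]]) %/% 2L)
        jr <- sample.int(2L * max_jr + 1L, 1L) - max_jr - 1L
        jc <- sample.int(2L * max_jc + 1L, 1L) - max_jc - 1L
      }
      r0 <- min(max(0L, centers$row[pick[i]] - ws[1] %/% 2L + jr), h - ws[1])
      c0 <- min(max(0L, centers$col[pick[i]] - ws[2] %/% 2L + jc), w - ws[2])
      regions[[i]] <- labeled_region(bbox(r0, c0, ws[1], ws[2]), "stoma",
                                     scene$image$image_id, ws)
    }
    n_placed <- 0L; tries <- 0L; budget <- 2000L * n_per_class
    while (n_placed < n_per_class && tries < budget) {
      tries <- tries + 1L
      r0 <- sample.int(h - ws[1] + 1L, 1L) - 1L
      c0 <- sample.int(w - ws[2] + 1L, 1L) - 1L
      cand <- bbox(r0, c0, ws[1], ws[2])
      if (nrow(truth) && any(bbox_intersection_area(cand, truth) > 0)) next
      n_placed <- n_placed + 1L
      regions[[n_per_class + n_placed]] <-
        labeled_region(cand, "non_stoma", scene$image$image_id, ws)
    }
    if (n_placed < n_per_class)
      stop(sprintf(
        "could not place %d truth-disjoint non-stoma windows (placed %d)",
        n_per_class, n_placed), call. = FALSE)
    regions
  })
}
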