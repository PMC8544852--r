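# Transfer-learning window descriptors: frozen ImageNet-pretrained CNN
# backbones used as feature extractors. This is an optional capability: the
# package carries the backbone contracts (names, input shapes, tap points,
# output dims) but delegates the actual forward pass to a user-registered
# provider (e.g. a wrapper around a local keras/torch installation). The
# rest of the pipeline runs descriptor-only when no provider is available.

.backbone_table <- list(
  DenseNet121       = list(input_shape = c(224L, 224L, 3L),
                           feature_layer = "global_average_pool",
                           output_dim = 1024L),
  InceptionV3       = list(input_shape = c(299L, 299L, 3L),
                           feature_layer = "global_average_pool",
                           output_dim = 2048L),
  InceptionResNetV2 = list(input_shape = c(299L, 299L, 3L),
                           feature_layer = "global_average_pool",
                           output_dim = 1536L),
  MobileNet         = list(input_shape = c(224L, 224L, 3L),
                           feature_layer = "global_average_pool",
                           output_dim = 1024L),
  NasNetMobile      = list(input_shape = c(224L, 224L, 3L),
                           feature_layer = "global_average_pool",
                           output_dim = 1056L),
  VGG16             = list(input_shape = c(224L, 224L, 3L),
                           feature_layer = "fc2",
                           output_dim = 4096L)
)

#' Pretrained backbone specification
#'
#' Declares one of the six supported ImageNet-pretrained backbones together
#' with its input shape, the layer tapped for features (global average pool
#' for the convolutional backbones; the second 4096-unit fully-connected
#' layer for VGG16) and the resulting fixed output dimension. The spec is
#' recorded with every learned model so experiments are reproducible.
#'
#' @param name Backbone name; one of `DenseNet121`, `InceptionV3`,
#'   `InceptionResNetV2`, `MobileNet`, `NasNetMobile`, `VGG16`.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(name) {
  if (!name %in% names(.backbone_table))
    stop(sprintf(
      "unknown backbone '%s'; supported backbones are: %s",
      name, paste(names(.backbone_table), collapse = ", ")), call. = FALSE)
  info <- .backbone_table[[name]]
  structure(c(list(name = name), info), class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone_spec %s: input %s, tap %s, output_dim %d>\n",
              x$name, paste(x$input_shape, collapse = "x"),
              x$feature_layer, x$output_dim))
  invisible(x)
}

capability_error <- function(msg) {
  stop(structure(class = c("stomadetect_capability_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Register or query a deep-feature provider
#'
#' A provider is a function `function(backbone_spec, windows)` returning an
#' `n x output_dim` matrix for a list of RGB window arrays. Registering one
#' (typically a thin wrapper around a local keras/torch installation with
#' cached ImageNet weights) enables [load_backbone] and
#' [extract_deep_features]; without one those functions raise a capability
#' error of class `stomadetect_capability_error`, distinct from I/O errors.
#'
#' @param provider A function, or `NULL` to unregister.
#' @return The previously registered provider, invisibly.
#' @export
register_backbone_provider <- function(provider) {
  old <- .pkg_cache$backbone_provider
  stopifnot(is.null(provider) || is.function(provider))
  .pkg_cache$backbone_provider <- provider
  invisible(old)
}

#' Load a frozen pretrained backbone
#'
#' @param spec A [backbone_spec] (or backbone name).
#' @return A backbone handle (list with the spec and the provider).
#' @export
load_backbone <- function(spec) {
  if (is.character(spec)) spec <- backbone_spec(spec)
  stopifnot(inherits(spec, "backbone_spec"))
  provider <- .pkg_cache$backbone_provider
  if (is.null(provider))
    capability_error(paste0(
      "no deep-feature provider is registered, so pretrained backbone '",
      spec$name, "' cannot be loaded. Install a CNN runtime with cached ",
      "ImageNet weights and register it with register_backbone_provider(); ",
      "the rest of the pipeline runs with handcrafted descriptors only."))
  structure(list(spec = spec, provider = provider), class = "backbone_handle")
}

#' Extract deep features for a list of windows
#'
#' Grayscale windows are replicated to three channels and resized to the
#' backbone's input shape (bilinear, aspect ratio not preserved) before the
#' provider's forward pass. Deterministic for fixed weights and inputs.
#'
#' @param windows List of [stoma_image] windows.
#' @param backbone A handle from [load_backbone].
#' @return Numeric matrix `length(windows) x output_dim`.
#' @export
extract_deep_features <- function(windows, backbone) {
  stopifnot(inherits(backbone, "backbone_handle"))
  spec <- backbone$spec
  prepped <- lapply(windows, function(wimg) {
    px <- wimg$pixels
    if (is.matrix(px)) {
      g <- resize_gray(px, spec$input_shape[1], spec$input_shape[2])
      array(rep(g, 3L), dim = spec$input_shape)
    } else {
      out <- array(0, dim = spec$input_shape)
      for (ch in 1:3)
        out[, , ch] <- resize_gray(px[, , ch],
                                   spec$input_shape[1], spec$input_shape[2])
      out
    }
  })
  X <- backbone$provider(spec, prepped)
  X <- matrix(as.numeric(X), nrow = length(prepped))
  if (length(prepped) && ncol(X) != spec$output_dim)
    stop(sprintf("provider returned %d features per window; %s declares %d",
                 ncol(X), spec$name, spec$output_dim), call. = FALSE)
  if (!length(prepped)) X <- matrix(numeric(0), 0L, spec$output_dim)
  X
}
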