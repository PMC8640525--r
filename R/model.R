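#' Low-level classifier constructor
#'
#' Builds a feed-forward classifier from an explicit layer plan and a named
#' weight list. Normally called via [build_model()]; exposed so toy models
#' (e.g. a single hand-set dense layer) can be assembled directly in
#' analyses and tests.
#'
#' Layer descriptors are lists with a `type` field:
#' * `conv`: fields `name`, `filters`, `kernel` (odd, default 3),
#'   `activation` (`"relu"`); stride 1, zero-padded "same".
#' * `maxpool`: 2x2, stride 2 (odd trailing rows/columns dropped).
#' * `flatten`: tensor to feature matrix (row-major over H, then W, then C
#'   in column-major R order: H fastest).
#' * `dense`: fields `name`, `units`, `activation` (`"relu"`, `"linear"` or
#'   `"softmax"`), `dropout` (training-only rate, default 0).
#'
#' Weight tensors are named `"<layer>/kernel"` and `"<layer>/bias"`; conv
#' kernels are `[k, k, C_in, filters]` arrays, dense kernels `[in, out]`
#' matrices. The final layer must be a `dense` layer with softmax
#' activation whose width equals the number of classes.
#'
#' @param layers List of layer descriptors (see Details).
#' @param weights Named list of weight arrays.
#' @param input_shape Integer `c(H, W, channels)`.
#' @param n_classes Output dimension.
#' @param penultimate Name of the designated penultimate layer whose
#'   post-activation outputs feed representational analyses.
#' @param profile Optional profile tag.
#' @param meta Optional list of metadata (seed, training metrics, ...).
#' @return A `classifier_model` object.
#' @export
classifier_model <- function(layers, weights, input_shape, n_classes,
                             penultimate = "dense_2", profile = "custom",
                             meta = list()) {
  nms <- vapply(layers, function(l) l$name %||% l$type, character(1))
  wn <- names(weights)
  if (length(wn) != length(unique(wn))) {
    abort("Weight tensor names must be unique.", class = "degensim_invalid_argument")
  }
  last <- layers[[length(layers)]]
  if (!identical(last$type, "dense") || !identical(last$activation, "softmax")) {
    abort("Final layer must be a softmax dense layer.",
          class = "degensim_invalid_argument")
  }
  structure(list(layers = layers, weights = weights,
                 input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 penultimate = penultimate, profile = profile, meta = meta,
                 layer_names = nms),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("<classifier_model:%s> input %s, %d classes, %d parameters\n",
              x$profile, paste(x$input_shape, collapse = "x"),
              x$n_classes, np))
  invisible(x)
}

# Layer plans ------------------------------------------------------------

profile_layers <- function(profile, n_classes) {
  switch(profile,
    "small-cnn" = list(
      list(type = "conv", name = "conv_1", filters = 8L, kernel = 3L,
           activation = "relu"),
      list(type = "maxpool", name = "pool_1"),
      list(type = "conv", name = "conv_2", filters = 16L, kernel = 3L,
           activation = "relu"),
      list(type = "maxpool", name = "pool_2"),
      list(type = "flatten", name = "flatten"),
      list(type = "dense", name = "dense_1", units = 64L,
           activation = "relu", dropout = 0.3),
      list(type = "dense", name = "dense_2", units = 32L,
           activation = "relu", dropout = 0.3),
      list(type = "dense", name = "output", units = as.integer(n_classes),
           activation = "softmax", dropout = 0)
    ),
    "vgg19-cifar100" = {
      plan <- list()
      filt <- list(c(64L, 64L), c(128L, 128L), rep(256L, 4L),
                   rep(512L, 4L), rep(512L, 4L))
      ci <- 0L
      for (b in seq_along(filt)) {
        for (f in filt[[b]]) {
          ci <- ci + 1L
          plan[[length(plan) + 1L]] <-
            list(type = "conv", name = sprintf("conv_%d", ci), filters = f,
                 kernel = 3L, activation = "relu")
        }
        plan[[length(plan) + 1L]] <- list(type = "maxpool",
                                          name = sprintf("pool_%d", b))
      }
      c(plan, list(
        list(type = "flatten", name = "flatten"),
        list(type = "dense", name = "dense_1", units = 1000L,
             activation = "relu", dropout = 0.3),
        list(type = "dense", name = "dense_2", units = 1000L,
             activation = "relu", dropout = 0.3),
        list(type = "dense", name = "output", units = as.integer(n_classes),
             activation = "softmax", dropout = 0)
      ))
    },
    abort(sprintf("Unknown model profile `%s`.", profile),
          class = "degensim_invalid_argument")
  )
}

profile_input_shape <- function(profile, image_size = NULL, channels = NULL) {
  if (profile == "vgg19-cifar100") {
    # 32x32 inputs upscaled 4x, RGB
    c(128L, 128L, 3L)
  } else {
    c(image_size %||% 16L, image_size %||% 16L, channels %||% 1L)
  }
}

# Walk the layer plan computing the shape entering each layer.
layer_input_shapes <- function(layers, input_shape) {
  shapes <- vector("list", length(layers))
  cur <- input_shape # c(H, W, C) or scalar feature count
  for (i in seq_along(layers)) {
    shapes[[i]] <- cur
    l <- layers[[i]]
    cur <- switch(l$type,
      conv = c(cur[1], cur[2], l$filters),
      maxpool = c(cur[1] %/% 2L, cur[2] %/% 2L, cur[3]),
      flatten = prod(cur),
      dense = l$units,
      abort(sprintf("Unknown layer type `%s`.", l$type)))
  }
  shapes
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

init_layer_weights <- function(layers, input_shape, skip = character(0)) {
  shapes <- layer_input_shapes(layers, input_shape)
  w <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv" && !(l$name %in% skip)) {
      cin <- shapes[[i]][3]
      k <- l$kernel
      w[[paste0(l$name, "/kernel")]] <-
        glorot_uniform(k * k * cin, k * k * l$filters, c(k, k, cin, l$filters))
      w[[paste0(l$name, "/bias")]] <- rep(0, l$filters)
    } else if (l$type == "dense" && !(l$name %in% skip)) {
      cin <- shapes[[i]]
      w[[paste0(l$name, "/kernel")]] <- glorot_uniform(cin, l$units,
                                                       c(cin, l$units))
      w[[paste0(l$name, "/bias")]] <- rep(0, l$units)
    }
  }
  w
}

#' Build a classifier for a training profile
#'
#' Two profiles are provided. `"small-cnn"` is the desk-scale reference
#' network: two 3x3 convolution layers (8 and 16 filters, each followed by
#' 2x2 max-pooling), a 64-unit dense layer and a 32-unit penultimate dense
#' layer (each with 30% training-time dropout), and a softmax output sized
#' by the hierarchy; all layers are seed-initialised (Glorot uniform
#' kernels, zero biases). `"vgg19-cifar100"` is the full replication
#' profile: the VGG-19 topology (16 convolution layers) followed by two
#' 1000-unit dense layers and a C-way softmax, for 128x128 RGB inputs
#' (32x32 images upscaled 4x); its convolutional weights must be supplied
#' from a pretrained weight file — they are never silently random — while
#' dense and output layers are seed-initialised.
#'
#' @param profile `"small-cnn"` or `"vgg19-cifar100"`.
#' @param hierarchy A `class_hierarchy`; its class count sets the output width.
#' @param seed Integer seed for weight initialisation.
#' @param image_size,channels Input geometry for `"small-cnn"` (ignored by
#'   the vgg19 profile, which is fixed at 128x128x3).
#' @param pretrained_conv Path to a weight directory (as written by
#'   [save_model()]) providing the convolutional tensors for the vgg19
#'   profile.
#' @return A `classifier_model`.
#' @examples
#' m <- build_model("small-cnn", make_hierarchy(5, 4), seed = 1)
#' m
#' @export
build_model <- function(profile, hierarchy, seed,
                        image_size = 16, channels = 1,
                        pretrained_conv = NULL) {
  validate_hierarchy(hierarchy)
  seed <- check_count(seed, "seed", min = 0L)
  C <- n_classes(hierarchy)
  layers <- profile_layers(profile, C)
  input_shape <- profile_input_shape(profile, image_size, channels)

  if (profile == "vgg19-cifar100") {
    if (is.null(pretrained_conv)) {
      abort(paste("The vgg19-cifar100 profile requires `pretrained_conv`:",
                  "a path to pretrained convolutional weights.",
                  "Convolutional layers are never silently random-initialised."),
            class = "degensim_missing_resource")
    }
    conv_names <- vapply(Filter(function(l) l$type == "conv", layers),
                         `[[`, character(1), "name")
    pre <- load_model(pretrained_conv)
    weights <- withr::with_seed(seed,
      init_layer_weights(layers, input_shape, skip = conv_names))
    for (nm in conv_names) {
      for (part in c("/kernel", "/bias")) {
        key <- paste0(nm, part)
        if (is.null(pre$weights[[key]])) {
          abort(sprintf("Pretrained weights lack tensor `%s`.", key),
                class = "degensim_missing_resource")
        }
        weights[[key]] <- pre$weights[[key]]
      }
    }
  } else {
    weights <- withr::with_seed(seed, init_layer_weights(layers, input_shape))
  }
  # keep catalog order = layer order
  ord <- unlist(lapply(layers, function(l)
    if (l$type %in% c("conv", "dense")) paste0(l$name, c("/kernel", "/bias"))))
  weights <- weights[ord]
  classifier_model(layers, weights, input_shape, C,
                   penultimate = "dense_2", profile = profile,
                   meta = list(seed = seed))
}

# Forward pass -----------------------------------------------------------

# images: [n, H, W, C] stimulus tensor or an already-flat [n, features]
# matrix for dense-only models. Returns class probabilities and, when
# `capture` names a layer, its post-activation output (pre-dropout).
model_forward <- function(model, images, training = FALSE, capture = NULL,
                          keep_caches = FALSE) {
  if (length(dim(images)) == 4L) {
    x <- aperm(images, c(2, 3, 4, 1))
  } else {
    x <- images
  }
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  captured <- NULL
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    r <- switch(l$type,
      conv = conv_forward(x, model$weights[[paste0(l$name, "/kernel")]],
                          model$weights[[paste0(l$name, "/bias")]],
                          l$activation),
      maxpool = maxpool_forward(x),
      flatten = flatten_forward(x),
      dense = dense_forward(x, model$weights[[paste0(l$name, "/kernel")]],
                            model$weights[[paste0(l$name, "/bias")]],
                            l$activation, l$dropout %||% 0, training))
    x <- r$out
    if (keep_caches) caches[[i]] <- r$cache
    if (!is.null(capture) && identical(l$name, capture)) {
      captured <- r$activations %||% r$out
    }
  }
  list(probs = x, captured = captured, caches = caches)
}

#' Class probabilities for a stimulus set
#'
#' Inference-mode forward pass (dropout inactive): softmax probabilities,
#' one row per stimulus.
#'
#' @param model A `classifier_model`.
#' @param stimuli A `stimulus_set` or a `[n, H, W, C]` image array.
#' @return Numeric matrix `[n, n_classes]`; rows sum to 1.
#' @export
predict_proba <- function(model, stimuli) {
  images <- if (inherits(stimuli, "stimulus_set")) stimuli$images else stimuli
  model_forward(model, images, training = FALSE)$probs
}

# Serialisation ----------------------------------------------------------

#' Save / load a classifier
#'
#' Writes the model as a directory: `weights.bin` (all weight tensors as
#' little-endian float64, concatenated in catalog order) plus a
#' `manifest.json` sidecar with the layer plan, tensor names and shapes,
#' the penultimate-layer designation, profile and metadata. The round trip
#' is bit-exact.
#'
#' @param model A `classifier_model`.
#' @param path Directory to write to / read from.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `classifier_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  shapes <- lapply(model$weights, function(w) dim(w) %||% length(w))
  manifest <- list(format = "degensim-model", version = 1L,
                   profile = model$profile, layers = model$layers,
                   input_shape = model$input_shape,
                   n_classes = model$n_classes,
                   penultimate = model$penultimate,
                   weight_order = names(model$weights),
                   weight_shapes = shapes,
                   meta = model$meta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "weights.bin"), "wb")
  for (nm in names(model$weights)) {
    writeBin(as.double(model$weights[[nm]]), con, size = 8, endian = "little")
  }
  close(con)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("No model manifest found at `%s`.", path),
          class = "degensim_missing_file")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (!identical(manifest$format, "degensim-model")) {
    abort("Not a degensim model directory (bad `format` field).",
          class = "degensim_format_error")
  }
  order <- unlist(manifest$weight_order)
  shapes <- manifest$weight_shapes
  wfile <- file.path(path, "weights.bin")
  if (!file.exists(wfile)) {
    abort("Model directory is missing weights.bin.",
          class = "degensim_format_error")
  }
  total <- sum(vapply(shapes, function(s) prod(unlist(s)), numeric(1)))
  con <- file(wfile, "rb")
  vals <- readBin(con, "double", n = total, size = 8, endian = "little")
  close(con)
  if (length(vals) != total) {
    abort("weights.bin is truncated relative to the manifest.",
          class = "degensim_format_error")
  }
  weights <- list()
  off <- 0L
  for (nm in order) {
    s <- unlist(shapes[[nm]])
    n <- prod(s)
    w <- vals[(off + 1):(off + n)]
    if (length(s) > 1L) dim(w) <- s
    weights[[nm]] <- w
    off <- off + n
  }
  layers <- lapply(manifest$layers, function(l) lapply(l, function(v)
    if (is.list(v)) unlist(v) else v))
  classifier_model(layers, weights,
                   unlist(manifest$input_shape), manifest$n_classes,
                   penultimate = manifest$penultimate,
                   profile = manifest$profile,
                   meta = manifest$meta)
}
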