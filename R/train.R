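#' Training configuration
#'
#' Profile defaults follow the replication recipe for
#' `"vgg19-cifar100"` (fixed learning rate 3e-5, RMSprop, 40 epochs, 30%
#' dropout, inputs upscaled 4x) and desk-scale choices for `"small-cnn"`
#' (RMSprop at 1e-3 for 30 epochs, 30% dropout, native input size). Batch
#' size and the categorical cross-entropy loss are package choices exposed
#' here. Dropout applies only during training; the final trained model
#' retains every neuron and weight.
#'
#' @param profile `"small-cnn"` or `"vgg19-cifar100"`.
#' @param learning_rate,optimizer,epochs,dropout_rate,input_upscale,batch_size
#'   Override the profile defaults. `optimizer` is `"rmsprop"` or `"sgd"`.
#' @param seed Integer seed driving initial weights, shuffling and dropout
#'   masks; with single-threaded numerics this makes training deterministic.
#' @return A `training_config` list.
#' @export
training_config <- function(profile = "small-cnn",
                            learning_rate = NULL, optimizer = NULL,
                            epochs = NULL, dropout_rate = NULL,
                            input_upscale = NULL, batch_size = 64,
                            seed = 1) {
  defaults <- switch(profile,
    "small-cnn" = list(learning_rate = 1e-3, optimizer = "rmsprop",
                       epochs = 30L, dropout_rate = 0.3, input_upscale = 1L),
    "vgg19-cifar100" = list(learning_rate = 3e-5, optimizer = "rmsprop",
                            epochs = 40L, dropout_rate = 0.3,
                            input_upscale = 4L),
    abort(sprintf("Unknown training profile `%s`.", profile),
          class = "degensim_invalid_argument"))
  cfg <- list(
    profile = profile,
    learning_rate = check_scalar_number(learning_rate %||% defaults$learning_rate,
                                        "learning_rate", min = 0),
    optimizer = match.arg(optimizer %||% defaults$optimizer,
                          c("rmsprop", "sgd")),
    epochs = check_count(epochs %||% defaults$epochs, "epochs", min = 0L),
    dropout_rate = check_fraction(dropout_rate %||% defaults$dropout_rate,
                                  "dropout_rate"),
    input_upscale = check_count(input_upscale %||% defaults$input_upscale,
                                "input_upscale"),
    batch_size = check_count(batch_size, "batch_size"),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "training_config")
}

upscale_images <- function(images, factor) {
  if (factor <= 1L) return(images)
  d <- dim(images)
  images[, rep(seq_len(d[2]), each = factor),
         rep(seq_len(d[3]), each = factor), , drop = FALSE]
}

#' Train a classifier end-to-end
#'
#' Minimises categorical cross-entropy by mini-batch gradient descent
#' (RMSprop or plain SGD), updating every layer. Training consumes only the
#' fine class labels of `train`; the class/superclass structure is never
#' visible to the optimiser, so any superclass organisation in the learned
#' representation is emergent. All stochastic elements (shuffling, dropout
#' masks) derive from `cfg$seed`.
#'
#' @param model A `classifier_model`.
#' @param train A `stimulus_set` whose labels match the model's output width.
#' @param cfg A [training_config()].
#' @return The trained `classifier_model`, with an epoch-loss history and
#'   the training config recorded in `$meta`.
#' @export
train_model <- function(model, train, cfg) {
  stopifnot(inherits(model, "classifier_model"),
            inherits(train, "stimulus_set"),
            inherits(cfg, "training_config"))
  labels <- train$labels
  if (max(labels) >= model$n_classes || min(labels) < 0L) {
    abort("Labels are out of range for the model's output dimension.",
          class = "degensim_invalid_argument")
  }
  # dropout rate is a training property; apply it to the hidden dense layers
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "dense" && !identical(l$activation, "softmax") &&
        (l$dropout %||% 0) > 0) {
      model$layers[[i]]$dropout <- cfg$dropout_rate
    }
  }
  images <- upscale_images(train$images, cfg$input_upscale)
  n <- dim(images)[1]
  opt_state <- new.env(parent = emptyenv())
  history <- numeric(0)

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        b <- ord[start:min(start + cfg$batch_size - 1L, n)]
        res <- sgd_step(model, images[b, , , , drop = FALSE], labels[b],
                        cfg, opt_state)
        model <- res$model
        losses <- c(losses, res$loss)
      }
      history <- c(history, mean(losses))
    }
  })
  model$meta$training <- unclass(cfg)
  model$meta$epoch_loss <- history
  model
}

# One mini-batch forward/backward/update.
sgd_step <- function(model, images, labels, cfg, opt_state) {
  nb <- length(labels)
  fwd <- model_forward(model, images, training = TRUE, keep_caches = TRUE)
  probs <- fwd$probs
  target_idx <- cbind(seq_len(nb), labels + 1L)
  loss <- -mean(log(pmax(probs[target_idx], 1e-12)))

  onehot <- matrix(0, nb, model$n_classes)
  onehot[target_idx] <- 1
  grads <- list()
  d <- (probs - onehot) / nb   # dL/dlogits of the softmax output
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cache <- fwd$caches[[i]]
    if (l$type == "dense") {
      bk <- if (identical(l$activation, "softmax")) {
        dense_backward(NULL, cache, dZ_direct = d)
      } else {
        dense_backward(d, cache)
      }
      grads[[paste0(l$name, "/kernel")]] <- bk$dW
      grads[[paste0(l$name, "/bias")]] <- bk$db
      d <- bk$dX
    } else if (l$type == "flatten") {
      d <- flatten_backward(d, cache)
    } else if (l$type == "maxpool") {
      d <- maxpool_backward(d, cache)
    } else if (l$type == "conv") {
      bk <- conv_backward(d, cache)
      grads[[paste0(l$name, "/kernel")]] <- bk$dkernel
      grads[[paste0(l$name, "/bias")]] <- bk$dbias
      d <- bk$dX
    }
  }

  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (cfg$optimizer == "rmsprop") {
      c_old <- opt_state[[nm]] %||% (g * 0)
      c_new <- 0.9 * c_old + 0.1 * g * g
      assign(nm, c_new, envir = opt_state)
      step <- cfg$learning_rate * g / (sqrt(c_new) + 1e-8)
    } else {
      step <- cfg$learning_rate * g
    }
    model$weights[[nm]] <- model$weights[[nm]] - step
  }
  list(model = model, loss = loss)
}

#' Train replicate networks
#'
#' Repeats build-and-train with distinct derived seeds (`cfg$seed + r` for
#' replicate `r`) to produce unique uninjured networks, mirroring the
#' 25-replicate protocol at configurable count. Every trained replicate is
#' retained — no post-training exclusion is applied.
#'
#' @param n Number of replicates (>= 1).
#' @param train Training `stimulus_set`.
#' @param cfg A [training_config()].
#' @param test Optional test `stimulus_set`; when given, each replicate's
#'   final test accuracy is recorded.
#' @param pretrained_conv Passed to [build_model()] for the vgg19 profile.
#' @return A `replicate_set`: list with `models`, `seeds`, and a `metadata`
#'   tibble (replicate id, seed, final test accuracy when available).
#' @export
train_replicates <- function(n, train, cfg, test = NULL,
                             pretrained_conv = NULL) {
  n <- check_count(n, "n")
  stopifnot(inherits(train, "stimulus_set"), inherits(cfg, "training_config"))
  d <- dim(train$images)
  seeds <- vapply(seq_len(n), function(r) derive_seed(cfg$seed, r),
                  integer(1))
  models <- vector("list", n)
  accs <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    rcfg <- cfg
    rcfg$seed <- seeds[r]
    m <- build_model(cfg$profile, train$hierarchy, seed = seeds[r],
                     image_size = d[2], channels = d[4],
                     pretrained_conv = pretrained_conv)
    m <- train_model(m, train, rcfg)
    if (!is.null(test)) {
      accs[r] <- accuracy(predict_labels(m, test))
    }
    m$meta$replicate_id <- r
    models[[r]] <- m
  }
  structure(list(models = models, seeds = seeds,
                 metadata = tibble::tibble(replicate_id = seq_len(n),
                                           seed = seeds,
                                           test_accuracy = accs)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %d trained networks\n", length(x$models)))
  print(x$metadata)
  invisible(x)
}
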