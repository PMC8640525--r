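# Shared fixtures, built in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

# Small hierarchical dataset: 5x4 classes, 20 train / 10 test per class.
tiny_dataset <- function() {
  cache_fixture("tiny_dataset", function() {
    generate_dataset(generator_config(images_per_class_train = 20,
                                      images_per_class_test = 10, seed = 42))
  })
}

# A briefly trained small-cnn on the tiny dataset (clearly above chance,
# far from converged - enough for behavioural and RSA plumbing tests).
tiny_model <- function() {
  cache_fixture("tiny_model", function() {
    ds <- tiny_dataset()
    m <- build_model("small-cnn", ds$hierarchy, seed = 7)
    train_model(m, ds$train, training_config("small-cnn", epochs = 5, seed = 7))
  })
}

# Dense-only toy model: flatten(4 pixels) -> softmax over n_out classes.
# Weights are supplied by the caller, so forward passes are hand-checkable.
toy_dense_model <- function(W, b, input_shape = c(2, 2, 1)) {
  layers <- list(
    list(type = "flatten", name = "flatten"),
    list(type = "dense", name = "output", units = ncol(W),
         activation = "softmax", dropout = 0)
  )
  classifier_model(layers, list(`output/kernel` = W, `output/bias` = b),
                   input_shape = input_shape, n_classes = ncol(W),
                   penultimate = "flatten")
}

# Toy two-hidden-neuron network for node-ablation geometry checks.
toy_hidden_model <- function(seed = 1) {
  withr::with_seed(seed, {
    W1 <- matrix(rnorm(4 * 2), 4, 2)
    W2 <- matrix(rnorm(2 * 3), 2, 3)
  })
  layers <- list(
    list(type = "flatten", name = "flatten"),
    list(type = "dense", name = "dense_1", units = 2L,
         activation = "relu", dropout = 0),
    list(type = "dense", name = "output", units = 3L,
         activation = "softmax", dropout = 0)
  )
  classifier_model(layers,
                   list(`dense_1/kernel` = W1, `dense_1/bias` = rep(0, 2),
                        `output/kernel` = W2, `output/bias` = rep(0, 3)),
                   input_shape = c(2, 2, 1), n_classes = 3L,
                   penultimate = "dense_1")
}

# Catalog stub for count/selection tests that need only a size.
stub_catalog <- function(N) {
  structure(list(tensors = "w/kernel", sizes = as.double(N),
                 offsets = 0, N = N), class = "weight_catalog")
}

# Independent O(n^2) tau-a oracle, written against the definition:
# every unordered pair in the denominator, sign products in the numerator.
tau_a_oracle <- function(x, y) {
  n <- length(x)
  num <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- num + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  num / (n * (n - 1) / 2)
}

# Independent per-pair Pearson correlation from the textbook formula.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# The desk-scale degeneration study: 5x4 synthetic hierarchy, small-cnn,
# 5 replicates, cumulative ablation by 0.005 to 0.5 with 7 RSA checkpoints.
# Expensive (~6 min); computed once and shared across acceptance checks.
desk_experiment <- function() {
  cache_fixture("desk_experiment", function() {
    run_experiment(experiment_config(seed = 1))
  })
}
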