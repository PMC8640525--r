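test_that("build_model sizes the output by the hierarchy and is seed-deterministic", {
  h <- make_hierarchy(5, 4)
  m <- build_model("small-cnn", h, seed = 1)
  expect_equal(m$n_classes, 20L)
  expect_equal(dim(m$weights[["output/kernel"]])[2], 20L)
  expect_equal(m$penultimate, "dense_2")

  m2 <- build_model("small-cnn", h, seed = 1)
  expect_identical(m$weights, m2$weights)
  m3 <- build_model("small-cnn", h, seed = 2)
  expect_false(identical(m$weights, m3$weights))

  expect_error(build_model("resnet", h, seed = 1),
               class = "degensim_invalid_argument")
})

test_that("vgg19 profile has the replication topology and demands pretrained convs", {
  h <- make_hierarchy(20, 5)
  plan <- degensim:::profile_layers("vgg19-cifar100", 100)
  convs <- Filter(function(l) l$type == "conv", plan)
  dense <- Filter(function(l) l$type == "dense" && l$activation == "relu", plan)
  out <- plan[[length(plan)]]
  expect_length(convs, 16)
  expect_equal(vapply(dense, `[[`, integer(1), "units"), c(1000L, 1000L))
  expect_equal(out$units, 100L)
  expect_equal(out$activation, "softmax")
  expect_equal(degensim:::profile_input_shape("vgg19-cifar100"),
               c(128L, 128L, 3L))

  expect_error(build_model("vgg19-cifar100", h, seed = 1),
               class = "degensim_missing_resource")
})

test_that("inference is deterministic with dropout inactive and softmax normalised", {
  m <- tiny_model()
  ds <- tiny_dataset()
  x <- ds$test$images[1:16, , , , drop = FALSE]
  p1 <- predict_proba(m, x)
  p2 <- predict_proba(m, x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
  expect_equal(rowSums(p1), rep(1, 16), tolerance = 1e-6)
})

test_that("zero training epochs leave the model at initialisation", {
  ds <- tiny_dataset()
  m <- build_model("small-cnn", ds$hierarchy, seed = 3)
  m0 <- train_model(m, ds$train, training_config("small-cnn", epochs = 0,
                                                 seed = 3))
  expect_identical(m0$weights, m$weights)
})

test_that("training is deterministic given seed and data", {
  ds <- tiny_dataset()
  cfg <- training_config("small-cnn", epochs = 2, seed = 9)
  m1 <- train_model(build_model("small-cnn", ds$hierarchy, seed = 9),
                    ds$train, cfg)
  m2 <- train_model(build_model("small-cnn", ds$hierarchy, seed = 9),
                    ds$train, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(accuracy(predict_labels(m1, ds$test)),
                   accuracy(predict_labels(m2, ds$test)))
})

test_that("training rejects label/output mismatches and never sees the hierarchy", {
  ds <- tiny_dataset()
  m <- build_model("small-cnn", make_hierarchy(2, 2), seed = 1)
  expect_error(train_model(m, ds$train, training_config("small-cnn", epochs = 1)),
               class = "degensim_invalid_argument")
  expect_false("hierarchy" %in% names(formals(train_model)))
})

test_that("backpropagated gradients match finite differences", {
  h <- make_hierarchy(2, 2)
  layers <- list(
    list(type = "conv", name = "conv_1", filters = 3L, kernel = 3L,
         activation = "relu"),
    list(type = "maxpool", name = "pool_1"),
    list(type = "flatten", name = "flatten"),
    list(type = "dense", name = "dense_1", units = 5L, activation = "relu",
         dropout = 0),
    list(type = "dense", name = "output", units = 4L, activation = "softmax",
         dropout = 0)
  )
  weights <- withr::with_seed(21, {
    w <- degensim:::init_layer_weights(layers, c(6L, 6L, 1L))
    lapply(w, function(wi) wi + rnorm(length(wi), sd = 0.05))
  })
  m <- classifier_model(layers, weights, c(6L, 6L, 1L), 4L,
                        penultimate = "dense_1")
  withr::with_seed(22, {
    x <- array(runif(7 * 6 * 6 * 1), c(7, 6, 6, 1))
    y <- sample(0:3, 7, replace = TRUE)
  })
  loss_at <- function(model) {
    p <- degensim:::model_forward(model, x)$probs
    -mean(log(p[cbind(seq_along(y), y + 1L)]))
  }
  # plain SGD with lr 1 turns the update into the raw gradient
  cfg <- training_config("small-cnn", optimizer = "sgd", learning_rate = 1,
                         epochs = 1)
  stepped <- degensim:::sgd_step(m, x, y, cfg,
                                 new.env(parent = emptyenv()))$model
  eps <- 1e-6
  for (nm in names(m$weights)) {
    g_bp <- m$weights[[nm]] - stepped$weights[[nm]]
    pos <- withr::with_seed(30 + match(nm, names(m$weights)),
                            sample(length(g_bp), min(4, length(g_bp))))
    for (p in pos) {
      mp <- m; mp$weights[[nm]][p] <- mp$weights[[nm]][p] + eps
      mm <- m; mm$weights[[nm]][p] <- mm$weights[[nm]][p] - eps
      g_num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_lt(abs(g_bp[p] - g_num), 1e-5)
    }
  }
})

test_that("the small-cnn learns the synthetic task well above chance", {
  ds <- cache_fixture("learn_dataset", function() {
    generate_dataset(generator_config(images_per_class_train = 30,
                                      images_per_class_test = 10, seed = 2))
  })
  m <- build_model("small-cnn", ds$hierarchy, seed = 2)
  m <- train_model(m, ds$train, training_config("small-cnn", epochs = 10,
                                                seed = 2))
  acc <- accuracy(predict_labels(m, ds$test))
  chance <- chance_accuracy(table(ds$test$labels))
  expect_gte(acc, 3 * chance)
})

test_that("model serialisation round-trips weights, names and designation", {
  m <- tiny_model()
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  back <- load_model(dir)
  expect_identical(back$weights, m$weights)
  expect_identical(names(back$weights), names(m$weights))
  expect_identical(back$penultimate, m$penultimate)
  x <- ds$test$images[1:8, , , , drop = FALSE]
  expect_identical(predict_proba(back, x), predict_proba(m, x))

  expect_error(load_model(file.path(dir, "nope")),
               class = "degensim_missing_file")
})

test_that("replicate training yields distinct retained networks", {
  ds <- tiny_dataset()
  cfg <- training_config("small-cnn", epochs = 1, seed = 5)
  reps <- train_replicates(2, ds$train, cfg, test = ds$test)
  expect_length(reps$models, 2)
  expect_equal(nrow(reps$metadata), 2)
  expect_false(identical(reps$models[[1]]$weights[["dense_1/kernel"]],
                         reps$models[[2]]$weights[["dense_1/kernel"]]))
  expect_equal(length(unique(reps$seeds)), 2)
  expect_error(train_replicates(0, ds$train, cfg),
               class = "degensim_invalid_argument")
})
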