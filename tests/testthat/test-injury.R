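test_that("the weight catalog counts connection weights elementwise, biases excluded", {
  # single dense layer, 3 inputs x 2 outputs (+2 biases)
  m <- toy_dense_model(matrix(1, 3, 2), c(0.5, -0.5), input_shape = 3L)
  cat1 <- build_catalog(m)
  expect_equal(cat1$N, 6)

  # conv: 8 kernels of 3x3x1 (72) plus dense 10x4 (40)
  layers <- list(
    list(type = "conv", name = "conv_1", filters = 8L, kernel = 3L,
         activation = "relu"),
    list(type = "flatten", name = "flatten"),
    list(type = "dense", name = "output", units = 4L, activation = "softmax",
         dropout = 0)
  )
  w <- list(`conv_1/kernel` = array(1, c(3, 3, 1, 8)), `conv_1/bias` = rep(0, 8),
            `output/kernel` = matrix(1, 10, 4), `output/bias` = rep(0, 4))
  m2 <- classifier_model(layers, w, c(4L, 4L, 1L), 4L, penultimate = "flatten")
  cat2 <- build_catalog(m2)
  expect_equal(cat2$N, 112)
  expect_identical(build_catalog(m2)$tensors, cat2$tensors)
})

test_that("target_count rounds half away from zero and is monotone", {
  expect_equal(target_count(0.001, 10000), 10L)
  expect_equal(target_count(0.30, 1000), 300L)
  expect_equal(target_count(0, 123), 0L)
  expect_equal(target_count(1, 123), 123L)
  # 0.5 * 7 = 3.5 -> 4 under half-away-from-zero (reference oracle: floor(x+0.5))
  expect_equal(target_count(0.5, 7), floor(0.5 * 7 + 0.5))
  expect_equal(target_count(0.5, 7), 4L)
  fs <- seq(0, 1, by = 0.01)
  counts <- vapply(fs, target_count, integer(1), N = 997)
  expect_true(all(diff(counts) >= 0))
  expect_error(target_count(-0.1, 10), class = "degensim_invalid_argument")
  expect_error(target_count(1.1, 10), class = "degensim_invalid_argument")
})

test_that("advance selects exact counts and is idempotent at equal fractions", {
  cat10 <- stub_catalog(10)
  st <- injury_state(cat10, seed = 1)
  st <- advance_injury(st, 0.1, cat10)
  expect_length(st$injured, 1)
  st_same <- advance_injury(st, 0.1, cat10)
  expect_identical(st_same$injured, st$injured)
  expect_error(advance_injury(st, 0.05, cat10),
               class = "degensim_invalid_argument")
})

test_that("stepwise and direct advances reach identical counts", {
  catN <- stub_catalog(10000)
  st <- injury_state(catN, seed = 4)
  for (k in 1:300) st <- advance_injury(st, k * 0.001, catN)
  direct <- advance_injury(injury_state(catN, seed = 99), 0.30, catN)
  expect_length(st$injured, 3000)
  expect_length(direct$injured, 3000)
  expect_equal(length(st$injured), target_count(0.30, catN$N))
})

test_that("injury is cumulative: injured sets are nested along a schedule", {
  catN <- stub_catalog(2000)
  st <- injury_state(catN, seed = 8)
  prev <- integer(0)
  for (f in seq(0.01, 0.5, by = 0.01)) {
    st <- advance_injury(st, f, catN)
    expect_true(all(prev %in% st$injured))
    expect_equal(length(st$injured), target_count(f, catN$N))
    prev <- st$injured
  }
})

test_that("selection is uniform over the catalog", {
  cat10 <- stub_catalog(10)
  picks <- vapply(seq_len(2000), function(r) {
    advance_injury(injury_state(cat10, seed = 5000 + r), 0.1, cat10)$injured
  }, integer(1))
  freq <- tabulate(picks, nbins = 10) / 2000
  expect_true(all(abs(freq - 0.1) <= 0.02))
  expect_gt(stats::chisq.test(tabulate(picks, nbins = 10))$p.value, 0.001)
})

test_that("identical seeds reproduce the injured-index sequence", {
  catN <- stub_catalog(500)
  seq1 <- injury_state(catN, seed = 77)
  seq2 <- injury_state(catN, seed = 77)
  for (f in c(0.1, 0.2, 0.4)) {
    seq1 <- advance_injury(seq1, f, catN)
    seq2 <- advance_injury(seq2, f, catN)
  }
  expect_identical(seq1$injured, seq2$injured)
})

test_that("apply_injury zeroes exactly the selected weights and nothing else", {
  m <- toy_dense_model(matrix(c(1, 2), 1, 2), c(0, 0), input_shape = 1L)
  cat2 <- build_catalog(m)
  expect_equal(cat2$N, 2)

  st0 <- injury_state(cat2, seed = 1)
  expect_identical(apply_injury(m, st0, cat2)$weights, m$weights)

  st <- advance_injury(st0, 0.5, cat2)
  inj <- apply_injury(m, st, cat2)
  expect_equal(sum(inj$weights[["output/kernel"]] == 0), 1)
  expect_equal(sum(inj$weights[["output/kernel"]] != 0), 1)
  # source model untouched
  expect_identical(m$weights[["output/kernel"]], matrix(c(1, 2), 1, 2))

  st1 <- advance_injury(st, 1, cat2)
  inj1 <- apply_injury(m, st1, cat2)
  expect_true(all(inj1$weights[["output/kernel"]] == 0))
  expect_identical(inj1$weights[["output/bias"]], m$weights[["output/bias"]])
})

test_that("full ablation forces constant predictions at chance accuracy", {
  ds <- tiny_dataset()
  m <- tiny_model()
  catm <- build_catalog(m)
  st <- advance_injury(injury_state(catm, seed = 2), 1, catm)
  inj <- apply_injury(m, st, catm)
  batch <- predict_labels(inj, ds$test)
  expect_equal(length(unique(batch$predicted)), 1L)
  expect_equal(accuracy(batch), 1 / 20)
})

test_that("node ablation lesions whole units (row and column of a hidden neuron)", {
  m <- toy_hidden_model()
  ucat <- build_unit_catalog(m)
  wcat <- build_catalog(m)
  expect_equal(ucat$N, 2)  # two hidden neurons; output units are not lesioned

  st <- injury_state(ucat, seed = 3, mode = "ablate-node")
  st <- advance_variant(st, 0.5, ucat, mode = "ablate-node")
  inj <- apply_injury(m, st, wcat)
  u <- st$injured_units
  expect_length(u, 1)
  expect_true(all(inj$weights[["dense_1/kernel"]][, u] == 0))
  expect_true(all(inj$weights[["output/kernel"]][u, ] == 0))
  other <- setdiff(1:2, u)
  expect_identical(inj$weights[["dense_1/kernel"]][, other],
                   m$weights[["dense_1/kernel"]][, other])
  expect_identical(inj$weights[["output/kernel"]][other, ],
                   m$weights[["output/kernel"]][other, ])

  st1 <- advance_variant(st, 1, ucat, mode = "ablate-node")
  inj1 <- apply_injury(m, st1, wcat)
  expect_true(all(inj1$weights[["dense_1/kernel"]] == 0))
  expect_true(all(inj1$weights[["output/kernel"]] == 0))
})

test_that("node ablation covers conv channels including the flatten boundary", {
  m <- tiny_model()
  ucat <- build_unit_catalog(m)
  wcat <- build_catalog(m)
  # 8 conv_1 + 16 conv_2 + 64 dense_1 + 32 dense_2 units
  expect_equal(ucat$N, 120)
  st <- advance_variant(injury_state(ucat, seed = 6, mode = "ablate-node"),
                        1, ucat, mode = "ablate-node")
  inj <- apply_injury(m, st, wcat)
  for (nm in wcat$tensors) expect_true(all(inj$weights[[nm]] == 0))
})

test_that("randomize mode rescales selected weights instead of zeroing", {
  m <- tiny_model()
  wcat <- build_catalog(m)
  st0 <- injury_state(wcat, seed = 9, mode = "randomize")
  expect_identical(apply_injury(m, st0, wcat)$weights, m$weights)

  expect_error(advance_variant(st0, 0.2, wcat, mode = "randomize"),
               class = "degensim_invalid_argument")  # needs model
  st <- advance_variant(st0, 0.2, wcat, mode = "randomize", model = m)
  inj <- apply_injury(m, st, wcat)
  changed <- unlist(inj$weights[wcat$tensors]) !=
    unlist(m$weights[wcat$tensors])
  expect_equal(sum(changed), length(st$injured))
  # replacements are draws, not zeros
  expect_gt(sd(st$replacements), 0)

  expect_error(advance_variant(st0, 0.1, wcat, mode = "sever"),
               class = "degensim_invalid_argument")
})

test_that("catalog/model mismatches are rejected", {
  m <- tiny_model()
  other <- toy_hidden_model()
  st <- advance_injury(injury_state(build_catalog(other), seed = 1), 0.5,
                       build_catalog(other))
  expect_error(apply_injury(m, st, build_catalog(other)),
               class = "degensim_invalid_argument")
})
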