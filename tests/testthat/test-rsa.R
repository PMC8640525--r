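test_that("RDM entries follow 1 - Pearson on worked examples", {
  r <- build_rdm(rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1)))
  expect_equal(r$D[1, 2], 0)            # perfect positive correlation
  expect_equal(r$D[1, 3], 2)            # perfect anticorrelation
  r2 <- build_rdm(rbind(c(1, 0, 1, 0), c(1, 1, 0, 0)))
  expect_equal(r2$D[1, 2], 1)           # r = 0
})

test_that("RDMs match an independent per-pair Pearson computation", {
  for (rep in 1:100) {
    acts <- withr::with_seed(rep, matrix(rnorm(6 * 8), 6, 8))
    r <- build_rdm(acts)
    for (i in 1:5) {
      for (j in (i + 1):6) {
        expect_equal(r$D[i, j], 1 - pearson_oracle(acts[i, ], acts[j, ]),
                     tolerance = 1e-9)
      }
    }
    expect_true(isSymmetric(r$D))
    expect_true(all(diag(r$D) == 0))
    expect_true(all(r$D >= 0 & r$D <= 2))
  }
})

test_that("degenerate zero-variance rows get dissimilarity 1 with a message", {
  acts <- rbind(c(1, 1, 1, 1), c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_message(r <- build_rdm(acts), "zero-variance")
  expect_equal(r$D[1, 2], 1)
  expect_equal(r$D[1, 3], 1)
  expect_equal(r$D[1, 1], 0)
})

test_that("duplicated stimuli have exactly zero dissimilarity", {
  acts <- rbind(c(0.3, 1.2, -0.5, 2), c(0.3, 1.2, -0.5, 2), rnorm(4))
  r <- build_rdm(acts)
  expect_identical(r$D[1, 2], 0)
})

test_that("RDM size guards fire", {
  expect_error(build_rdm(matrix(1:4, 1, 4)), class = "degensim_invalid_argument")
  expect_error(build_rdm(matrix(1:4, 4, 1)), class = "degensim_invalid_argument")
})

test_that("utv extracts the strict upper triangle in row-major order", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 12
  D[1, 3] <- D[3, 1] <- 13
  D[2, 3] <- D[3, 2] <- 23
  expect_equal(utv(D), c(12, 13, 23))
  expect_length(utv(matrix(0, 2, 2)), 1)
  # inverse consistency: rebuilding a symmetric matrix reproduces D
  v <- utv(D)
  R <- matrix(0, 3, 3)
  R[lower.tri(R)] <- v
  R <- t(R); R[lower.tri(R)] <- v
  expect_equal(t(R), D)
})

test_that("tau-a worked examples and tie handling are exact", {
  for (meth in c("brute", "fast")) {
    expect_equal(kendall_tau_a(1:3, 1:3, method = meth), 1)
    expect_equal(kendall_tau_a(1:3, 3:1, method = meth), -1)
    expect_equal(kendall_tau_a(c(1, 2, 3, 4), c(1, 3, 2, 4), method = meth),
                 2 / 3)
    expect_equal(kendall_tau_a(c(1, 2, 3, 4), c(1, 1, 2, 3), method = meth),
                 5 / 6)
  }
  expect_error(kendall_tau_a(1:3, 1:4), class = "degensim_invalid_argument")
  expect_error(kendall_tau_a(1, 1), class = "degensim_invalid_argument")
})

test_that("fast and brute tau-a agree with the enumeration oracle under ties", {
  withr::with_seed(17, {
    for (rep in 1:200) {
      n <- sample(3:50, 1)
      x <- sample(1:8, n, replace = TRUE)   # heavy ties
      y <- rnorm(n) + 0.3 * x
      o <- tau_a_oracle(x, y)
      expect_equal(kendall_tau_a(x, y, method = "brute"), o, tolerance = 1e-12)
      expect_equal(kendall_tau_a(x, y, method = "fast"), o, tolerance = 1e-12)
    }
  })
})

test_that("tau-a is invariant under strictly increasing transforms", {
  withr::with_seed(23, {
    x <- rnorm(40)
    y <- rnorm(40)
  })
  base <- kendall_tau_a(x, y)
  expect_equal(kendall_tau_a(exp(x), y), base)
  expect_equal(kendall_tau_a(x, 3 * y + 7), base)
  expect_equal(kendall_tau_a(rank(x), y), base)
})

test_that("compare_rdms is a rank statistic over matched condition sets", {
  acts <- withr::with_seed(3, matrix(rnorm(10 * 6), 10, 6))
  r <- build_rdm(acts)
  expect_equal(compare_rdms(r, r)$tau_a, 1)
  # strictly increasing transform of the entries leaves tau-a at 1
  r2 <- r
  r2$D <- r$D^3 + 0.1 * r$D
  diag(r2$D) <- 0
  expect_equal(compare_rdms(r, r2)$tau_a, 1)
  expect_equal(compare_rdms(r, r2)$n_pairs, 45)

  r3 <- build_rdm(acts[1:5, ])
  expect_error(compare_rdms(r, r3), class = "degensim_invalid_argument")
})

test_that("scrambling a constant RDM yields tau-a exactly 0 (all ties)", {
  D <- matrix(0.7, 5, 5); diag(D) <- 0
  nf <- scrambled_noise_floor(degensim:::new_rdm(D, 1:5), n_reps = 10, seed = 2)
  expect_true(all(nf$tau_a == 0))
  expect_equal(nf$mean_tau_a, 0)
})

test_that("noise-floor preconditions and determinism hold", {
  r <- build_rdm(withr::with_seed(5, matrix(rnorm(20 * 4), 20, 4)))
  a <- scrambled_noise_floor(r, n_reps = 5, seed = 9)
  b <- scrambled_noise_floor(r, n_reps = 5, seed = 9)
  expect_identical(a$tau_a, b$tau_a)
  expect_gte(a$mean_abs_tau_a, abs(a$mean_tau_a))

  two <- degensim:::new_rdm(matrix(c(0, 1, 1, 0), 2, 2), 1:2)
  expect_error(scrambled_noise_floor(two, n_reps = 3),
               class = "degensim_invalid_argument")
  expect_error(scrambled_noise_floor(r, n_reps = 0),
               class = "degensim_invalid_argument")
})

test_that("superclass RDMs are block means of the stimulus RDM", {
  h <- make_hierarchy(2, 1)
  # 4 stimuli: conditions 1,2 in superclass 0; 3,4 in superclass 1
  D <- matrix(c(0, 1, 2, 3,
                1, 0, 4, 5,
                2, 4, 0, 6,
                3, 5, 6, 0), 4, 4, byrow = TRUE)
  r <- degensim:::new_rdm(D, 1:4)
  s <- superclass_rdm(r, labels = c(0L, 0L, 1L, 1L), h)
  expect_equal(s$D[1, 1], 1)                 # mean of the single within pair
  expect_equal(s$D[2, 2], 6)
  expect_equal(s$D[1, 2], mean(c(2, 3, 4, 5)))
  expect_true(isSymmetric(s$D))

  # constant dissimilarity propagates to every block mean
  Dc <- matrix(0.4, 4, 4)
  sc <- superclass_rdm(degensim:::new_rdm(Dc, 1:4), c(0L, 0L, 1L, 1L), h)
  expect_true(all(sc$D == 0.4))

  # permuting stimuli within a superclass changes nothing
  p <- c(2, 1, 4, 3)
  sp <- superclass_rdm(degensim:::new_rdm(D[p, p], 1:4), c(0L, 0L, 1L, 1L), h)
  expect_equal(sp$D, s$D)

  expect_error(superclass_rdm(r, labels = c(0L, 0L, 0L, 1L), h),
               class = "degensim_invalid_argument")
})

test_that("average_rdms is the elementwise mean preserving RDM structure", {
  acts <- withr::with_seed(8, matrix(rnorm(8 * 5), 8, 5))
  r <- build_rdm(acts)
  expect_equal(average_rdms(list(r))$D, r$D)
  r2 <- r; r2$D <- 2 * r$D
  avg <- average_rdms(list(r, r2))
  expect_equal(avg$D, 1.5 * r$D)
  expect_true(isSymmetric(avg$D))
  expect_true(all(diag(avg$D) == 0))

  r3 <- r; r3$condition_ids <- 101:108
  expect_error(average_rdms(list(r, r3)), class = "degensim_invalid_argument")
  expect_error(average_rdms(list()), class = "degensim_invalid_argument")
})

test_that("penultimate activations are deterministic and sized by the layer", {
  m <- tiny_model()
  ds <- tiny_dataset()
  x <- ds$test$images[1:12, , , , drop = FALSE]
  a1 <- penultimate_activations(m, x)
  expect_identical(a1, penultimate_activations(m, x))
  expect_equal(dim(a1), c(12L, 32L))

  # fully injured model: every row of activations identical
  catm <- build_catalog(m)
  st <- advance_injury(injury_state(catm, seed = 1), 1, catm)
  a_dead <- penultimate_activations(apply_injury(m, st, catm), x)
  expect_equal(max(apply(a_dead, 2, function(col) diff(range(col)))), 0)

  m_bad <- m
  m_bad$penultimate <- "nonexistent"
  expect_error(penultimate_activations(m_bad, x),
               class = "degensim_invalid_argument")
})
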