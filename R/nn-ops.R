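# Low-level tensor ops for the feed-forward classifier.
#
# Batches are held as arrays [H, W, C, n] in the convolutional stage and as
# [n, features] matrices after flattening. Convolution is 3x3 (odd k), stride
# 1, zero-padded "same", implemented by im2col with index maps cached per
# input shape; the col2im accumulation in the backward pass loops over the
# k*k*C kernel positions only, each step vectorised over space and batch.

.im2col_cache <- new.env(parent = emptyenv())

im2col_map <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  di <- rep(seq_len(k), times = k * C)
  dj <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  # linear index into the padded single-image tensor [Hp, Wp, C]
  idx <- outer(di - 1L, i, "+") + Hp * outer(dj - 2L, j, "+") +
    Hp * Wp * (cc - 1L)
  map <- list(idx = idx, di = di, dj = dj, cc = cc,
              Hp = Hp, Wp = Wp, pad = pad)
  assign(key, map, envir = .im2col_cache)
  map
}

conv_forward <- function(X, kernel, bias, activation = "relu") {
  d <- dim(X)
  H <- d[1]; W <- d[2]; C <- d[3]; n <- d[4]
  k <- dim(kernel)[1]
  nf <- dim(kernel)[4]
  im <- im2col_map(H, W, C, k)
  Xp <- array(0, c(im$Hp, im$Wp, C, n))
  Xp[im$pad + seq_len(H), im$pad + seq_len(W), , ] <- X
  M <- matrix(Xp, nrow = im$Hp * im$Wp * C, ncol = n)
  P <- M[as.vector(im$idx), , drop = FALSE]
  dim(P) <- c(nrow(im$idx), H * W * n)
  Wm <- t(matrix(kernel, nrow = k * k * C, ncol = nf))
  Z <- Wm %*% P + bias
  A <- if (activation == "relu") pmax(Z, 0) else Z
  out <- aperm(array(A, c(nf, H, W, n)), c(2, 3, 1, 4))
  list(out = out,
       cache = list(P = P, Z = Z, Wm = Wm, im = im, dims = d, k = k, nf = nf,
                    kernel_dim = dim(kernel), activation = activation))
}

conv_backward <- function(dY, cache) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; C <- d[3]; n <- d[4]
  nf <- cache$nf
  im <- cache$im
  dA <- aperm(dY, c(3, 1, 2, 4))
  dim(dA) <- c(nf, H * W * n)
  dZ <- if (cache$activation == "relu") dA * (cache$Z > 0) else dA
  dkernel <- array(t(dZ %*% t(cache$P)), cache$kernel_dim)
  dbias <- rowSums(dZ)
  dP <- crossprod(cache$Wm, dZ)
  dXp <- array(0, c(im$Hp, im$Wp, C, n))
  for (p in seq_len(nrow(dP))) {
    rows <- im$di[p] + 0:(H - 1L)
    cols <- im$dj[p] + 0:(W - 1L)
    ch <- im$cc[p]
    dXp[rows, cols, ch, ] <- dXp[rows, cols, ch, ] + array(dP[p, ], c(H, W, n))
  }
  dX <- dXp[im$pad + seq_len(H), im$pad + seq_len(W), , , drop = FALSE]
  dim(dX) <- d
  list(dX = dX, dkernel = dkernel, dbias = dbias)
}

maxpool_forward <- function(X) {
  d <- dim(X)
  H2 <- (d[1] %/% 2L) * 2L
  W2 <- (d[2] %/% 2L) * 2L
  ro <- seq(1L, H2, 2L); re <- seq(2L, H2, 2L)
  co <- seq(1L, W2, 2L); ce <- seq(2L, W2, 2L)
  s1 <- X[ro, co, , , drop = FALSE]
  s2 <- X[re, co, , , drop = FALSE]
  s3 <- X[ro, ce, , , drop = FALSE]
  s4 <- X[re, ce, , , drop = FALSE]
  Y <- pmax(s1, s2, s3, s4)
  list(out = Y, cache = list(s = list(s1, s2, s3, s4), Y = Y, dims = d,
                             ro = ro, re = re, co = co, ce = ce))
}

maxpool_backward <- function(dY, cache) {
  dX <- array(0, cache$dims)
  claimed <- array(FALSE, dim(cache$Y))
  sl <- list(list(cache$ro, cache$co), list(cache$re, cache$co),
             list(cache$ro, cache$ce), list(cache$re, cache$ce))
  for (q in 1:4) {
    m <- (cache$s[[q]] == cache$Y) & !claimed
    dX[sl[[q]][[1]], sl[[q]][[2]], , ] <- dY * m
    claimed <- claimed | m
  }
  dX
}

flatten_forward <- function(X) {
  d <- dim(X)
  nfeat <- prod(d[1:3])
  out <- t(matrix(X, nrow = nfeat, ncol = d[4]))
  list(out = out, cache = list(dims = d))
}

flatten_backward <- function(dY, cache) {
  array(t(dY), cache$dims)
}

dense_forward <- function(X, W, b, activation = "relu",
                          dropout = 0, training = FALSE) {
  Z <- X %*% W
  Z <- Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
  A <- switch(activation,
              relu = pmax(Z, 0),
              softmax = softmax_rows(Z),
              linear = Z,
              abort(sprintf("Unknown activation `%s`.", activation)))
  mask <- NULL
  out <- A
  if (training && dropout > 0) {
    mask <- (matrix(runif(length(A)), nrow(A), ncol(A)) >= dropout) / (1 - dropout)
    out <- A * mask
  }
  list(out = out, activations = A,
       cache = list(X = X, Z = Z, W = W, mask = mask, activation = activation))
}

dense_backward <- function(dOut, cache, dZ_direct = NULL) {
  if (is.null(dZ_direct)) {
    dA <- if (is.null(cache$mask)) dOut else dOut * cache$mask
    dZ <- switch(cache$activation,
                 relu = dA * (cache$Z > 0),
                 linear = dA,
                 abort("Softmax backward must come through the loss."))
  } else {
    dZ <- dZ_direct
  }
  list(dX = dZ %*% t(cache$W),
       dW = crossprod(cache$X, dZ),
       db = colSums(dZ))
}

softmax_rows <- function(Z) {
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  E / rowSums(E)
}
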