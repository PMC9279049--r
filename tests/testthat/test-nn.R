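# Layer-level checks of the network primitives against direct enumeration
# oracles and finite differences.

test_that("convolution layer matches identity, constant and enumeration oracles", {
  x <- matrix(stats::rnorm(16), 4, 4)
  k_id <- array(1, c(1, 1, 1, 1))
  expect_equal(conv_forward(x, k_id, 0, "identity"), array(x, c(4, 4, 1)))
  k0 <- array(0, c(3, 3, 1, 2))
  out <- conv_forward(x, k0, c(2, -1), "identity")
  expect_equal(out[, , 1], matrix(2, 2, 2))
  expect_equal(out[, , 2], matrix(-1, 2, 2))
  # ReLU of a negative constant map
  expect_equal(conv_forward(x, k0, c(-1, -1), "relu")[, , 1], matrix(0, 2, 2))
  k <- array(stats::rnorm(9), c(3, 3, 1, 1))
  expect_equal(conv_forward(x, k, 0, "identity")[, , 1],
               oracle_conv_valid(x, k[, , 1, 1]))
  expect_error(conv_forward(matrix(0, 2, 2), k), "dimension")
})

test_that("same padding preserves spatial dimensions", {
  x <- matrix(stats::rnorm(35), 5, 7)
  k <- array(stats::rnorm(18), c(3, 3, 1, 2))
  out <- conv_forward(x, k, 0, "identity", padding = "same")
  expect_equal(dim(out), c(5L, 7L, 2L))
  # interior agrees with valid convolution
  vld <- conv_forward(x, k, 0, "identity", padding = "valid")
  expect_equal(out[2:4, 2:6, ], vld)
})

test_that("pooling layer computes weighted block means and handles padding", {
  c4 <- matrix(3.7, 4, 4)
  expect_equal(pool_forward(c4, 1, 0, "identity")[, , 1], matrix(3.7, 2, 2))
  expect_equal(pool_forward(c4, 0, -2.5, "identity")[, , 1], matrix(-2.5, 2, 2))
  x <- matrix(1:16, 4, 4)
  blocks <- pool_forward(x, 1, 0, "identity")[, , 1]
  expect_equal(blocks, rbind(c(mean(c(1, 2, 5, 6)), mean(c(9, 10, 13, 14))),
                             c(mean(c(3, 4, 7, 8)), mean(c(11, 12, 15, 16)))))
  # odd dims are zero-padded on the right/bottom
  x5 <- matrix(1, 5, 5)
  p <- pool_forward(x5, 1, 0, "identity")[, , 1]
  expect_equal(dim(p), c(3L, 3L))
  expect_equal(p[3, 3], 1 / 4)
  # max pooling option
  expect_equal(pool_forward(x, 1, 0, "identity", pooling = "max")[, , 1],
               rbind(c(6, 14), c(8, 16)))
  expect_error(pool_forward(matrix(numeric(0), 0, 0)), "dimension")
})

test_that("batched plan-based conv/pool agree with the single-grid path", {
  set.seed(4)
  H <- 5L; W <- 6L; S <- 3L
  grids <- array(stats::rnorm(S * H * W), c(H, W, S))
  K <- array(stats::rnorm(9 * 2), c(3, 3, 1, 2))
  b <- c(0.3, -0.2)
  A <- matrix(as.vector(grids), ncol = 1)          # (S*H*W, 1), sample-major
  plan <- deeppsy:::.conv_plan(H, W, S, "same")
  out <- deeppsy:::.conv_fwd(A, K, b, plan)$out
  for (s in seq_len(S)) {
    ref <- conv_forward(grids[, , s], K, b, "identity", "same")
    got <- array(out[((s - 1) * H * W + 1):(s * H * W), ], c(H, W, 2))
    expect_equal(got, ref, tolerance = 1e-12)
  }
  pplan <- deeppsy:::.pool_plan(H, W, S)
  pooled <- deeppsy:::.meanpool_fwd(A, pplan)
  for (s in seq_len(S)) {
    ref <- pool_forward(grids[, , s], 1, 0, "identity")
    got <- array(pooled[((s - 1) * 9 + 1):(s * 9), 1], c(3, 3, 1))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("conv and pool gradients match central finite differences", {
  set.seed(5)
  H <- 5L; W <- 5L; S <- 2L
  plan <- deeppsy:::.conv_plan(H, W, S, "same")
  pplan <- deeppsy:::.pool_plan(H, W, S)
  A <- matrix(stats::rnorm(S * H * W), ncol = 1)
  K <- array(stats::rnorm(9 * 3), c(3, 3, 1, 3))
  b <- stats::rnorm(3)
  w_out <- stats::rnorm(3)                     # scalar head: loss = sum(out %*% w)
  loss_of <- function(Avec, Karr, bvec) {
    fw <- deeppsy:::.conv_fwd(matrix(Avec, ncol = 1), Karr, bvec, plan)
    pooled <- deeppsy:::.meanpool_fwd(fw$out, pplan)
    sum(pooled %*% w_out)
  }
  fw <- deeppsy:::.conv_fwd(A, K, b, plan)
  pooled <- deeppsy:::.meanpool_fwd(fw$out, pplan)
  dpool <- matrix(rep(w_out, each = nrow(pooled)), nrow(pooled))
  dconv <- deeppsy:::.meanpool_bwd(dpool, pplan, 3L)
  grads <- deeppsy:::.conv_bwd(dconv, fw$Pcat, K, plan)
  gA <- numeric_grad(function(v) loss_of(v, K, b), as.vector(A))
  expect_equal(as.vector(grads$dA), gA, tolerance = 1e-4)
  gK <- numeric_grad(function(v) loss_of(A, array(v, dim(K)), b), as.vector(K))
  expect_equal(as.vector(grads$dK), gK, tolerance = 1e-4)
  gb <- numeric_grad(function(v) loss_of(A, K, v), b)
  expect_equal(as.vector(grads$db), gb, tolerance = 1e-4)
})

test_that("batchnorm, dense and lstm gradients match finite differences", {
  set.seed(6)
  X <- matrix(stats::rnorm(40), 10, 4)
  gamma <- stats::runif(4, 0.5, 1.5); beta <- stats::rnorm(4)
  wsum <- matrix(stats::rnorm(40), 10, 4)
  bn_loss <- function(Xv, g, be) {
    fw <- deeppsy:::.bn_fwd(matrix(Xv, 10, 4), g, be, training = TRUE)
    sum(fw$out * wsum)
  }
  fw <- deeppsy:::.bn_fwd(X, gamma, beta, training = TRUE)
  bb <- deeppsy:::.bn_bwd(wsum, fw, gamma)
  expect_equal(as.vector(bb$dX), numeric_grad(function(v) bn_loss(v, gamma, beta),
                                              as.vector(X)), tolerance = 1e-4)
  expect_equal(as.vector(bb$dgamma),
               numeric_grad(function(v) bn_loss(as.vector(X), v, beta), gamma),
               tolerance = 1e-4)
  # lstm over a short sequence, loss on the last hidden state
  B <- 3L; Tn <- 4L; Din <- 5L; U <- 2L
  E <- matrix(stats::rnorm(B * Tn * Din), B * Tn, Din)
  Wx <- matrix(stats::rnorm(Din * 4 * U), Din) * 0.5
  Wh <- matrix(stats::rnorm(U * 4 * U), U) * 0.5
  bl <- stats::rnorm(4 * U) * 0.1
  wh <- matrix(stats::rnorm(B * U), B, U)
  lstm_loss <- function(Ev, Wxv, Whv, blv) {
    f <- deeppsy:::.lstm_fwd(matrix(Ev, B * Tn, Din), B, Tn,
                             matrix(Wxv, Din), matrix(Whv, U), blv)
    sum(f$h * wh)
  }
  f <- deeppsy:::.lstm_fwd(E, B, Tn, Wx, Wh, bl)
  bw <- deeppsy:::.lstm_bwd(wh, f$caches, Wx, Wh)
  expect_equal(as.vector(bw$dWx),
               numeric_grad(function(v) lstm_loss(as.vector(E), v, Wh, bl),
                            as.vector(Wx)), tolerance = 1e-4)
  expect_equal(as.vector(bw$dWh),
               numeric_grad(function(v) lstm_loss(as.vector(E), Wx, v, bl),
                            as.vector(Wh)), tolerance = 1e-4)
  expect_equal(as.vector(bw$db),
               numeric_grad(function(v) lstm_loss(as.vector(E), Wx, Wh, v), bl),
               tolerance = 1e-4)
})
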