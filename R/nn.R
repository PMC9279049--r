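# Minimal dense neural-network kernels used by the trajectory models.
#
# Feature maps are stored as "channel matrices": a stack of S grids of size
# H x W with C channels is the matrix A of dim (S*H*W, C), rows ordered
# sample-major, then grid column, then grid row (each H x W plane is in R's
# column-major order). Convolution and pooling are expressed as 9 (resp. 4)
# gathered matrix products over precomputed row-index plans, which keeps
# both the forward and the backward pass fully vectorized.

.conv_plan <- function(H, W, S, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  if (padding == "same") {
    Hp <- H + 2L; Wp <- W + 2L
    Ho <- H; Wo <- W
    y <- rep(seq_len(Ho), times = Wo * S)
    x <- rep(rep(seq_len(Wo), each = Ho), times = S)
    s <- rep(seq_len(S), each = Ho * Wo)
    sel <- vector("list", 9L)
    for (kb in 1:3) for (ka in 1:3) {
      sel[[(kb - 1L) * 3L + ka]] <-
        (s - 1L) * (Hp * Wp) + (x + kb - 2L) * Hp + (y + ka - 1L)
    }
    interior <- (s - 1L) * (Hp * Wp) + x * Hp + y + 1L
    selcat <- as.integer(unlist(sel, use.names = FALSE))
    list(sel = lapply(sel, as.integer), selcat = selcat,
         interior = interior, pad_rows = S * Hp * Wp,
         NHW = S * Ho * Wo, Ho = Ho, Wo = Wo, S = S)
  } else {
    if (H < 3L || W < 3L) stop("dimension error: input smaller than kernel", call. = FALSE)
    Ho <- H - 2L; Wo <- W - 2L
    y <- rep(seq_len(Ho), times = Wo * S)
    x <- rep(rep(seq_len(Wo), each = Ho), times = S)
    s <- rep(seq_len(S), each = Ho * Wo)
    sel <- vector("list", 9L)
    for (kb in 1:3) for (ka in 1:3) {
      sel[[(kb - 1L) * 3L + ka]] <-
        (s - 1L) * (H * W) + (x + kb - 2L) * H + (y + ka - 1L)
    }
    selcat <- as.integer(unlist(sel, use.names = FALSE))
    list(sel = lapply(sel, as.integer), selcat = selcat,
         interior = NULL, pad_rows = S * H * W,
         NHW = S * Ho * Wo, Ho = Ho, Wo = Wo, S = S)
  }
}

.pool_plan <- function(H, W, S) {
  He <- H + H %% 2L; We <- W + W %% 2L
  Ho <- He %/% 2L; Wo <- We %/% 2L
  y <- rep(seq_len(Ho), times = Wo * S)
  x <- rep(rep(seq_len(Wo), each = Ho), times = S)
  s <- rep(seq_len(S), each = Ho * Wo)
  sel <- vector("list", 4L)
  j <- 0L
  for (dx in 0:1) for (dy in 0:1) {
    j <- j + 1L
    sel[[j]] <- (s - 1L) * (He * We) + (2L * x - 2L + dx) * He + (2L * y - 1L + dy)
  }
  padded <- (He != H) || (We != W)
  interior <- NULL
  if (padded) {
    yi <- rep(seq_len(H), times = W * S)
    xi <- rep(rep(seq_len(W), each = H), times = S)
    si <- rep(seq_len(S), each = H * W)
    interior <- (si - 1L) * (He * We) + (xi - 1L) * He + yi
  }
  list(sel = lapply(sel, as.integer), interior = interior,
       pad_rows = S * He * We, Ho = Ho, Wo = Wo, S = S)
}

.pad_rows <- function(A, plan) {
  if (is.null(plan$interior)) return(A)
  P <- matrix(0, plan$pad_rows, ncol(A))
  P[plan$interior, ] <- A
  P
}

.unpad_rows <- function(P, plan) {
  if (is.null(plan$interior)) return(P)
  P[plan$interior, , drop = FALSE]
}

.add_bias <- function(O, b) cpp_scale_shift(O, rep(1, length(b)), b)

# K: array (3, 3, C_in, C_out). The gathered patch matrix (NHW, 9*C) and
# the kernel matrix (9*C, F) share R's column-major layout with the 3x3
# offset index running fastest, so both reshapes are free and one matrix
# product computes the whole layer.
.conv_fwd <- function(A, K, b, plan) {
  P <- .pad_rows(A, plan)
  Cin <- ncol(P); Fk <- dim(K)[4]
  Pcat <- cpp_gather(P, plan$selcat, plan$NHW)
  # gather is patch-major (offset outer, channel inner), matching the
  # column-major layout of the kernel array reshaped to (9*C, F)
  O <- Pcat %*% matrix(aperm(K, c(3, 1, 2, 4)), 9L * Cin, Fk)
  list(out = .add_bias(O, b), Pcat = Pcat)
}

.conv_bwd <- function(dO, Pcat, K, plan) {
  Cin <- dim(K)[3]; Fk <- dim(K)[4]
  dKm <- crossprod(Pcat, dO)                     # (9*C, F), patch-major
  dK <- aperm(array(dKm, c(Cin, 3L, 3L, Fk)), c(2, 3, 1, 4))
  Km <- matrix(aperm(K, c(3, 1, 2, 4)), 9L * Cin, Fk)
  dPg <- dO %*% t(Km)                            # (NHW, 9*C)
  # columns grouped per offset k as (k-1)*C + j, matching cpp_gather
  dPg2 <- matrix(0, 9L * plan$NHW, Cin)
  for (k in 1:9) {
    dPg2[((k - 1L) * plan$NHW + 1L):(k * plan$NHW), ] <-
      dPg[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
  }
  dP <- cpp_scatter_add(dPg2, plan$selcat, plan$NHW, plan$pad_rows)
  list(dA = .unpad_rows(dP, plan), dK = dK, db = colSums(dO))
}

.meanpool_fwd <- function(A, plan) {
  P <- .pad_rows(A, plan)
  cpp_pool4_mean(P, plan$sel[[1]], plan$sel[[2]], plan$sel[[3]], plan$sel[[4]])
}

.meanpool_bwd <- function(dO, plan, Cin) {
  dP <- cpp_pool4_bwd(dO, plan$sel[[1]], plan$sel[[2]], plan$sel[[3]],
                      plan$sel[[4]], plan$pad_rows)
  .unpad_rows(dP, plan)
}

# flatten a channel matrix (S*P rows, C cols) to per-sample vectors (S, P*C)
.flatten_fwd <- function(A, P, S) {
  t(matrix(aperm(array(A, c(P, S, ncol(A))), c(1, 3, 2)), P * ncol(A), S))
}

.flatten_bwd <- function(dX, P, S, C) {
  matrix(aperm(array(t(dX), c(P, C, S)), c(1, 3, 2)), P * S, C)
}

.dense_fwd <- function(X, W, b) .add_bias(X %*% W, b)

.dense_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

.relu_fwd <- function(X) {
  if (is.matrix(X)) cpp_relu(X) else X * (X > 0)
}
.relu_bwd <- function(dY, X) {
  if (is.matrix(X)) cpp_relu_bwd(dY, X) else dY * (X > 0)
}

.bn_fwd <- function(X, gamma, beta, running = NULL, training = TRUE,
                    momentum = 0.9, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu     # biased batch variance
    v[v < 0] <- 0
    if (!is.null(running)) {
      running$mean <- momentum * running$mean + (1 - momentum) * mu
      running$var <- momentum * running$var + (1 - momentum) * v
    }
  } else {
    mu <- running$mean
    v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  a <- gamma * invstd
  out <- cpp_scale_shift(X, a, beta - mu * a)
  list(out = out, X = X, mu = mu, invstd = invstd, running = running)
}

.bn_bwd <- function(dY, cache, gamma) {
  cpp_bn_bwd(dY, cache$X, cache$mu, cache$invstd, gamma)
}

.dropout_fwd <- function(X, rate, training = TRUE) {
  if (!training || rate == 0) return(list(out = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= rate) / (1 - rate), nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# E: (B*Tn, Din) with timestep fastest within sample; returns last hidden
# state and BPTT caches
.lstm_fwd <- function(E, B, Tn, Wx, Wh, b) {
  U <- nrow(Wh)
  h <- matrix(0, B, U); cc <- matrix(0, B, U)
  caches <- vector("list", Tn)
  step_rows <- (seq_len(B) - 1L) * Tn
  for (t in seq_len(Tn)) {
    Xt <- E[step_rows + t, , drop = FALSE]
    z <- .add_bias(Xt %*% Wx + h %*% Wh, b)
    i <- .sigmoid(z[, 1:U, drop = FALSE])
    f <- .sigmoid(z[, U + 1:U, drop = FALSE])
    o <- .sigmoid(z[, 2L * U + 1:U, drop = FALSE])
    g <- tanh(z[, 3L * U + 1:U, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    caches[[t]] <- list(X = Xt, h_prev = h, c_prev = c_prev,
                        i = i, f = f, o = o, g = g, tc = tc)
    h <- o * tc
  }
  list(h = h, caches = caches)
}

.lstm_bwd <- function(dH, caches, Wx, Wh) {
  Tn <- length(caches)
  U <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, U, 4L * U)
  db <- numeric(4L * U)
  dc <- matrix(0, nrow(dH), U)
  dXseq <- vector("list", Tn)
  dh <- dH
  for (t in rev(seq_len(Tn))) {
    cc <- caches[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$X, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dXseq[[t]] <- dz %*% t(Wx)
    dh <- dz %*% t(Wh)
    dc <- dc * cc$f
  }
  list(dXseq = dXseq, dWx = dWx, dWh = dWh, db = db)
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# weighted cross-entropy; y integer labels in 1..K, w per-class weights
.softmax_xent <- function(logits, y, w = rep(1, ncol(logits))) {
  p <- .softmax(logits)
  B <- nrow(logits)
  wy <- w[y]
  pi_y <- pmax(p[cbind(seq_len(B), y)], 1e-12)
  loss <- sum(wy * (-log(pi_y))) / sum(wy)
  dY <- p
  dY[cbind(seq_len(B), y)] <- dY[cbind(seq_len(B), y)] - 1
  dY <- dY * (wy / sum(wy))
  list(loss = loss, p = p, dlogits = dY)
}

# fan-in scaled uniform initialization
.init_uniform <- function(dims, fan_in) {
  r <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -r, r), dims)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - c(lr * mhat / (sqrt(vhat) + eps))
  }
  list(params = params, state = state)
}

# total number of scalar parameters in a (possibly nested) parameter list
.param_count <- function(params) {
  sum(vapply(params, function(p) length(p), numeric(1)))
}
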