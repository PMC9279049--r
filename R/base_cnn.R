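# Five-layer CNN for internet-usage pattern extraction:
# conv -> pool -> conv -> pool -> fully connected embedding.

.act_get <- function(activation) {
  if (is.function(activation)) return(activation)
  switch(activation,
         relu = function(x) x * (x > 0),
         identity = ,
         linear = function(x) x,
         sigmoid = .sigmoid,
         tanh = tanh,
         stop("unknown activation: ", activation, call. = FALSE))
}

.as_3d <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

#' Convolution layer forward pass
#'
#' Computes one convolution layer on a single grid: each output map `j` is
#' `f(sum_i x_i * k_ij + b_j)` over the input maps `i`, with `valid`
#' (default) or `same` zero padding.
#'
#' @param input `H x W` matrix or `H x W x C` array.
#' @param kernels array `(kh, kw, C, F)` of `F` kernels.
#' @param biases length-`F` bias vector (recycled if scalar).
#' @param activation activation name (`"relu"`, `"identity"`, `"sigmoid"`,
#'   `"tanh"`) or a function.
#' @param padding `"valid"` or `"same"` (odd kernel sizes only for same).
#' @return `Ho x Wo x F` array of feature maps.
#' @export
conv_forward <- function(input, kernels, biases = 0,
                         activation = "relu", padding = c("valid", "same")) {
  padding <- match.arg(padding)
  f <- .act_get(activation)
  x <- .as_3d(input)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(kernels)[1]; kw <- dim(kernels)[2]
  if (dim(kernels)[3] != C) {
    stop("dimension error: kernel input channels (", dim(kernels)[3],
         ") do not match input (", C, ")", call. = FALSE)
  }
  nf <- dim(kernels)[4]
  biases <- rep_len(biases, nf)
  if (padding == "same") {
    ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
    xp <- array(0, c(H + 2L * ph, W + 2L * pw, C))
    xp[ph + seq_len(H), pw + seq_len(W), ] <- x
    x <- xp
    H <- dim(x)[1]; W <- dim(x)[2]
  }
  Ho <- H - kh + 1L; Wo <- W - kw + 1L
  if (Ho < 1L || Wo < 1L) {
    stop("dimension error: kernel larger than input", call. = FALSE)
  }
  out <- array(0, c(Ho, Wo, nf))
  for (j in seq_len(nf)) {
    acc <- matrix(biases[j], Ho, Wo)
    for (a in seq_len(kh)) for (b in seq_len(kw)) for (ci in seq_len(C)) {
      acc <- acc + x[a:(a + Ho - 1L), b:(b + Wo - 1L), ci] * kernels[a, b, ci, j]
    }
    out[, , j] <- acc
  }
  f(out)
}

#' Pooling layer forward pass
#'
#' 2x2 downsampling followed by a learned per-map scalar weight and bias:
#' `f(w * down(x) + b)` with `down` either the block mean (default) or the
#' block max. Maps with odd extent are zero-padded on the right/bottom.
#'
#' @param map `H x W` matrix or `H x W x C` array.
#' @param w per-map scalar weight(s), recycled over maps.
#' @param b per-map bias(es), recycled.
#' @param activation as in [conv_forward()].
#' @param pooling `"mean"` or `"max"`.
#' @return Pooled array with halved (rounded-up) spatial dims.
#' @export
pool_forward <- function(map, w = 1, b = 0, activation = "relu",
                         pooling = c("mean", "max")) {
  pooling <- match.arg(pooling)
  f <- .act_get(activation)
  x <- .as_3d(map)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  if (H < 1L || W < 1L) stop("dimension error: empty map", call. = FALSE)
  He <- H + H %% 2L; We <- W + W %% 2L
  if (He != H || We != W) {
    pad_fill <- if (pooling == "max") -Inf else 0
    xp <- array(pad_fill, c(He, We, C))
    xp[seq_len(H), seq_len(W), ] <- x
    x <- xp
  }
  w <- rep_len(w, C); b <- rep_len(b, C)
  Ho <- He %/% 2L; Wo <- We %/% 2L
  out <- array(0, c(Ho, Wo, C))
  oy <- 2L * seq_len(Ho) - 1L
  ox <- 2L * seq_len(Wo) - 1L
  for (ci in seq_len(C)) {
    blocks <- if (pooling == "mean") {
      (x[oy, ox, ci] + x[oy + 1L, ox, ci] + x[oy, ox + 1L, ci] + x[oy + 1L, ox + 1L, ci]) / 4
    } else {
      pmax(x[oy, ox, ci], x[oy + 1L, ox, ci], x[oy, ox + 1L, ci], x[oy + 1L, ox + 1L, ci])
    }
    out[, , ci] <- blocks * w[ci] + b[ci]
  }
  f(out)
}

#' Specification of the five-layer base CNN
#'
#' conv (`conv1_kernels` 3x3, valid) -> pool 2x2 -> conv (`conv2_kernels`
#' 3x3, valid) -> pool 2x2 -> fully connected embedding of width
#' `fc_width`. Hidden activations default to ReLU; the embedding output is
#' linear.
#'
#' @param conv1_kernels,conv2_kernels kernel counts of the two conv layers.
#' @param fc_width embedding width.
#' @param activation hidden activation name.
#' @param pooling `"mean"` or `"max"`.
#' @param seed seed for parameter initialization.
#' @return A `base_cnn_spec` object.
#' @export
base_cnn_spec <- function(conv1_kernels = 4L, conv2_kernels = 32L,
                          fc_width = 16L, activation = "relu",
                          pooling = c("mean", "max"), seed = 1L) {
  pooling <- match.arg(pooling)
  stopifnot(conv1_kernels >= 1, conv2_kernels >= 1, fc_width >= 1)
  structure(list(conv1_kernels = as.integer(conv1_kernels),
                 conv2_kernels = as.integer(conv2_kernels),
                 fc_width = as.integer(fc_width),
                 activation = activation, pooling = pooling,
                 seed = as.integer(seed)),
            class = "base_cnn_spec")
}

.half_up <- function(x) (x + x %% 2L) %/% 2L

#' Initialize base CNN parameters
#'
#' Draws kernels and fully connected weights from a fan-in scaled uniform
#' distribution under the spec's seed; pooling weights start at 1 and all
#' biases at 0.
#'
#' @param spec a [base_cnn_spec()].
#' @param grid_dim input grid dimensions, e.g. `c(7, 24)`.
#' @return Named parameter list with a `dims` attribute describing the
#'   layer shapes.
#' @export
init_base_cnn <- function(spec, grid_dim = c(7L, 24L)) {
  stopifnot(inherits(spec, "base_cnn_spec"))
  set.seed(spec$seed)
  H1 <- grid_dim[1] - 2L; W1 <- grid_dim[2] - 2L          # conv1 valid
  H2 <- .half_up(H1); W2 <- .half_up(W1)                  # pool1
  H3 <- H2 - 2L; W3 <- W2 - 2L                            # conv2 valid
  H4 <- .half_up(H3); W4 <- .half_up(W3)                  # pool2
  if (H3 < 1L || W3 < 1L) stop("dimension error: grid too small", call. = FALSE)
  flat <- H4 * W4 * spec$conv2_kernels
  params <- list(
    K1 = .init_uniform(c(3L, 3L, 1L, spec$conv1_kernels), 9),
    b1 = numeric(spec$conv1_kernels),
    pw1 = rep(1, spec$conv1_kernels),
    pb1 = numeric(spec$conv1_kernels),
    K2 = .init_uniform(c(3L, 3L, spec$conv1_kernels, spec$conv2_kernels),
                       9 * spec$conv1_kernels),
    b2 = numeric(spec$conv2_kernels),
    pw2 = rep(1, spec$conv2_kernels),
    pb2 = numeric(spec$conv2_kernels),
    W5 = .init_uniform(c(flat, spec$fc_width), flat),
    b5 = numeric(spec$fc_width))
  attr(params, "dims") <- list(grid = grid_dim,
                               conv1 = c(H1, W1), pool1 = c(H2, W2),
                               conv2 = c(H3, W3), pool2 = c(H4, W4),
                               flat = flat)
  params
}

#' Embed an activity grid with the base CNN
#'
#' Runs the five layers and returns the fixed-length embedding
#' `s = w5 * x4 + b5` (linear output over the flattened last pooled maps).
#' Deterministic given the parameters.
#'
#' @param grid `H x W` activity matrix with entries in \[0, 1\].
#' @param spec a [base_cnn_spec()].
#' @param params parameters from [init_base_cnn()] (must match the spec).
#' @return Numeric embedding of length `spec$fc_width`.
#' @export
cnn_embed <- function(grid, spec, params) {
  stopifnot(inherits(spec, "base_cnn_spec"))
  dims <- attr(params, "dims")
  if (is.null(dims) || dim(params$K1)[4] != spec$conv1_kernels ||
      dim(params$K2)[4] != spec$conv2_kernels ||
      ncol(params$W5) != spec$fc_width) {
    stop("configuration error: params do not match spec", call. = FALSE)
  }
  if (!all(dim(grid) == dims$grid)) {
    stop("configuration error: grid dims ", paste(dim(grid), collapse = "x"),
         " do not match initialized dims ", paste(dims$grid, collapse = "x"),
         call. = FALSE)
  }
  x <- conv_forward(grid, params$K1, params$b1, spec$activation, "valid")
  x <- pool_forward(x, params$pw1, params$pb1, spec$activation, spec$pooling)
  x <- conv_forward(x, params$K2, params$b2, spec$activation, "valid")
  x <- pool_forward(x, params$pw2, params$pb2, spec$activation, spec$pooling)
  as.vector(params$b5 + as.vector(x) %*% params$W5)
}

#' Number of scalar parameters of a model or parameter list
#'
#' @param x a parameter list (e.g. from [init_base_cnn()]) or a
#'   `deeppsy_model`.
#' @return Integer count of scalar parameters.
#' @export
n_params <- function(x) {
  if (inherits(x, "deeppsy_model")) x <- x$params
  .param_count(x)
}
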