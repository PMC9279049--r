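#' DeepPsy architecture and training hyperparameters
#'
#' The fusion model has two branches. The trajectory branch processes each
#' weekly day-by-hour activity grid through
#' conv(`conv1_kernels`, 3x3, same) -> batchnorm -> 2x2 mean pool ->
#' conv(`conv2_kernels`, 3x3, same) -> batchnorm -> 2x2 mean pool ->
#' fully connected (`fc_width`) -> dropout, projects each weekly vector to
#' `lstm_input` dimensions and feeds the week sequence to an LSTM with
#' `lstm_units` units. The basic branch maps the tabular feature vector
#' through two fully connected layers (`basic_widths`). The branch outputs
#' are concatenated, passed through a fully connected fusion layer
#' (`fusion_width`) and a softmax over `n_classes`. Training uses Adam with
#' class-weighted cross-entropy.
#'
#' @param conv1_kernels,conv2_kernels 3x3 kernel counts of the two
#'   convolution layers (defaults 4 and 32).
#' @param fc_width width of the per-week fully connected layer (default 16).
#' @param dropout dropout rate after it (default 0.5).
#' @param lstm_input width the weekly vectors are projected to before the
#'   LSTM (default 64).
#' @param lstm_units LSTM hidden units (default 4).
#' @param basic_widths widths of the two basic-branch layers (default 8, 4).
#' @param fusion_width width of the fusion layer (default 4).
#' @param n_classes output classes: 2 (MD vs none, default) or 4 (severity).
#' @param epochs training epochs (default 60).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 4).
#' @param seed seed for initialization and training randomness.
#' @return A `deeppsy_spec` object.
#' @export
deeppsy_spec <- function(conv1_kernels = 4L, conv2_kernels = 32L,
                         fc_width = 16L, dropout = 0.5,
                         lstm_input = 64L, lstm_units = 4L,
                         basic_widths = c(8L, 4L), fusion_width = 4L,
                         n_classes = 2L, epochs = 60L,
                         learning_rate = 1e-3, batch_size = 4L, seed = 1L) {
  if (dropout < 0 || dropout >= 1) {
    stop("configuration error: dropout must lie in [0, 1)", call. = FALSE)
  }
  widths <- c(conv1_kernels, conv2_kernels, fc_width, lstm_input, lstm_units,
              basic_widths, fusion_width, n_classes, batch_size)
  if (any(widths < 1)) {
    stop("configuration error: widths must be positive", call. = FALSE)
  }
  structure(list(conv1_kernels = as.integer(conv1_kernels),
                 conv2_kernels = as.integer(conv2_kernels),
                 fc_width = as.integer(fc_width), dropout = dropout,
                 lstm_input = as.integer(lstm_input),
                 lstm_units = as.integer(lstm_units),
                 basic_widths = as.integer(basic_widths),
                 fusion_width = as.integer(fusion_width),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "deeppsy_spec")
}

#' Build an untrained DeepPsy model
#'
#' Allocates and initializes all parameters for the given spec and input
#' shapes. Weights use fan-in scaled uniform initialization under the
#' spec's seed; batch-normalization scales start at 1 and running statistics
#' at (0, 1). With `use_trajectory = FALSE` the model reduces to the basic
#' (tabular) branch plus the fusion head, which is how channel-ablation
#' variants without network data are built.
#'
#' @param spec a [deeppsy_spec()].
#' @param n_basic number of tabular input features.
#' @param n_weeks number of weekly grids per student (ignored without
#'   trajectory branch).
#' @param grid_dim weekly grid dimensions (default `c(7, 24)`).
#' @param use_trajectory include the CNN+LSTM branch?
#' @return A `deeppsy_model` object.
#' @export
build_deeppsy <- function(spec, n_basic, n_weeks = NULL,
                          grid_dim = c(7L, 24L), use_trajectory = TRUE) {
  stopifnot(inherits(spec, "deeppsy_spec"))
  if (use_trajectory && is.null(n_weeks)) {
    stop("configuration error: n_weeks required for the trajectory branch",
         call. = FALSE)
  }
  set.seed(spec$seed)
  F1 <- spec$conv1_kernels; F2 <- spec$conv2_kernels
  H <- as.integer(grid_dim[1]); W <- as.integer(grid_dim[2])
  H1 <- .half_up(H); W1 <- .half_up(W)        # after pool1 (same conv keeps dims)
  H2 <- .half_up(H1); W2 <- .half_up(W1)      # after pool2
  flat <- H2 * W2 * F2
  U <- spec$lstm_units
  params <- list()
  bn <- list()
  if (use_trajectory) {
    params$K1 <- .init_uniform(c(3L, 3L, 1L, F1), 9)
    params$c1b <- numeric(F1)
    params$g1 <- rep(1, F1); params$be1 <- numeric(F1)
    params$K2 <- .init_uniform(c(3L, 3L, F1, F2), 9 * F1)
    params$c2b <- numeric(F2)
    params$g2 <- rep(1, F2); params$be2 <- numeric(F2)
    params$Wf <- .init_uniform(c(flat, spec$fc_width), flat)
    params$bf <- numeric(spec$fc_width)
    params$Wp <- .init_uniform(c(spec$fc_width, spec$lstm_input), spec$fc_width)
    params$bp <- numeric(spec$lstm_input)
    params$Wx <- .init_uniform(c(spec$lstm_input, 4L * U), spec$lstm_input)
    params$Wh <- .init_uniform(c(U, 4L * U), U)
    params$bl <- numeric(4L * U)
    bn$bn1 <- list(mean = numeric(F1), var = rep(1, F1))
    bn$bn2 <- list(mean = numeric(F2), var = rep(1, F2))
  }
  w1 <- spec$basic_widths[1]; w2 <- spec$basic_widths[2]
  params$Wb1 <- .init_uniform(c(n_basic, w1), max(n_basic, 1L))
  params$bb1 <- numeric(w1)
  params$Wb2 <- .init_uniform(c(w1, w2), w1)
  params$bb2 <- numeric(w2)
  z_in <- w2 + if (use_trajectory) U else 0L
  params$Wz <- .init_uniform(c(z_in, spec$fusion_width), z_in)
  params$bz <- numeric(spec$fusion_width)
  params$Wo <- .init_uniform(c(spec$fusion_width, spec$n_classes), spec$fusion_width)
  params$bo <- numeric(spec$n_classes)
  structure(list(spec = spec, params = params, bn = bn,
                 grid_dim = c(H, W), n_weeks = n_weeks, n_basic = n_basic,
                 use_trajectory = use_trajectory,
                 dims = list(pool1 = c(H1, W1), pool2 = c(H2, W2), flat = flat),
                 tab_center = NULL, tab_scale = NULL,
                 plans = new.env(parent = emptyenv()),
                 trained = FALSE),
            class = "deeppsy_model")
}

#' @export
print.deeppsy_model <- function(x, ...) {
  cat("DeepPsy model:",
      if (x$use_trajectory) "CNN+LSTM trajectory branch +" else "(no trajectory branch)",
      "FCNN basic branch |", n_params(x), "parameters |",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

.dp_plans <- function(model, S) {
  key <- paste0("s", S)
  if (!is.null(model$plans[[key]])) return(model$plans[[key]])
  H <- model$grid_dim[1]; W <- model$grid_dim[2]
  H1 <- model$dims$pool1[1]; W1 <- model$dims$pool1[2]
  cplan <- function(pl, in_rows) {
    list(selcat = pl$selcat, pos = pl$NHW, interior = pl$interior,
         pad_rows = pl$pad_rows, in_rows = as.integer(in_rows))
  }
  pplan <- function(pl) {
    list(sel1 = pl$sel[[1]], sel2 = pl$sel[[2]], sel3 = pl$sel[[3]],
         sel4 = pl$sel[[4]], interior = pl$interior, pad_rows = pl$pad_rows)
  }
  p <- list(conv1 = cplan(.conv_plan(H, W, S, "same"), S * H * W),
            pool1 = pplan(.pool_plan(H, W, S)),
            conv2 = cplan(.conv_plan(H1, W1, S, "same"), S * H1 * W1),
            pool2 = pplan(.pool_plan(H1, W1, S)))
  model$plans[[key]] <- p
  p
}

# stack a grid array (B, n_weeks, H, W) into the (B*n_weeks*H*W, 1)
# channel-matrix layout; sample rows are contiguous per student
.grids_to_channels <- function(grids) {
  matrix(as.vector(aperm(grids, c(3, 4, 2, 1))), ncol = 1)
}

# row block of the full-cohort channel matrix for a student subset
.channel_rows <- function(idx, n_weeks, HW) {
  blk <- n_weeks * HW
  rep((idx - 1L) * blk, each = blk) + seq_len(blk)
}

# forward pass; traj = list(A1 = channel matrix of the batch, Wk = weeks)
# or NULL, tab (B, n_basic) already standardized, y integer labels or NULL
.dp_forward <- function(model, traj, tab, y = NULL, training = FALSE,
                        class_weights = NULL, zero_trajectory = FALSE) {
  sp <- model$spec
  B <- nrow(tab)
  cache <- list()
  if (model$use_trajectory) {
    Wk <- traj$Wk
    S <- B * Wk
    pl <- .dp_plans(model, S)
    F1 <- sp$conv1_kernels; F2 <- sp$conv2_kernels
    K1m <- matrix(aperm(model$params$K1, c(3, 1, 2, 4)), 9L, F1)
    K2m <- matrix(aperm(model$params$K2, c(3, 1, 2, 4)), 9L * F1, F2)
    st <- cpp_stem_fwd(traj$A1, pl$conv1, pl$pool1, pl$conv2, pl$pool2,
                       K1m, model$params$c1b, model$params$g1, model$params$be1,
                       K2m, model$params$c2b, model$params$g2, model$params$be2,
                       training,
                       model$bn$bn1$mean, model$bn$bn1$var,
                       model$bn$bn2$mean, model$bn$bn2$var, 0.9, 1e-5)
    if (training) {
      model$bn$bn1 <- list(mean = st$rmean1, var = st$rvar1)
      model$bn$bn2 <- list(mean = st$rmean2, var = st$rvar2)
    }
    Pn <- prod(model$dims$pool2)
    Xfc <- .flatten_fwd(st$out, Pn, S)
    h1_pre <- .dense_fwd(Xfc, model$params$Wf, model$params$bf)
    h1 <- .relu_fwd(h1_pre)
    dp <- .dropout_fwd(h1, sp$dropout, training = training)
    E <- .dense_fwd(dp$out, model$params$Wp, model$params$bp)
    lstm <- .lstm_fwd(E, B, Wk, model$params$Wx, model$params$Wh, model$params$bl)
    hT <- lstm$h
    if (zero_trajectory) hT[] <- 0
    cache <- list(pl = pl, st = st, K1m = K1m, K2m = K2m, Xfc = Xfc,
                  h1_pre = h1_pre, dp = dp, lstm = lstm,
                  B = B, Wk = Wk, S = S, Pn = Pn)
  } else {
    hT <- NULL
  }
  hb1_pre <- .dense_fwd(tab, model$params$Wb1, model$params$bb1)
  hb1 <- .relu_fwd(hb1_pre)
  hb2_pre <- .dense_fwd(hb1, model$params$Wb2, model$params$bb2)
  hb2 <- .relu_fwd(hb2_pre)
  z <- if (is.null(hT)) hb2 else cbind(hT, hb2)
  fz_pre <- .dense_fwd(z, model$params$Wz, model$params$bz)
  fz <- .relu_fwd(fz_pre)
  logits <- .dense_fwd(fz, model$params$Wo, model$params$bo)
  out <- list(model = model, cache = cache, tab = tab,
              hb1_pre = hb1_pre, hb1 = hb1, hb2_pre = hb2_pre, hb2 = hb2,
              z = z, fz_pre = fz_pre, fz = fz, logits = logits,
              probs = .softmax(logits))
  if (!is.null(y)) {
    sx <- .softmax_xent(logits, y, class_weights %||% rep(1, sp$n_classes))
    out$loss <- sx$loss
    out$dlogits <- sx$dlogits
  }
  out
}

.dp_backward <- function(model, fwd) {
  pr <- model$params
  g <- list()
  d_out <- .dense_bwd(fwd$dlogits, fwd$fz, pr$Wo)
  g$Wo <- d_out$dW; g$bo <- d_out$db
  dfz_pre <- .relu_bwd(d_out$dX, fwd$fz_pre)
  d_z <- .dense_bwd(dfz_pre, fwd$z, pr$Wz)
  g$Wz <- d_z$dW; g$bz <- d_z$db
  U <- model$spec$lstm_units
  if (model$use_trajectory) {
    dhT <- d_z$dX[, seq_len(U), drop = FALSE]
    dhb2 <- d_z$dX[, -seq_len(U), drop = FALSE]
  } else {
    dhb2 <- d_z$dX
  }
  dhb2_pre <- .relu_bwd(dhb2, fwd$hb2_pre)
  d_b2 <- .dense_bwd(dhb2_pre, fwd$hb1, pr$Wb2)
  g$Wb2 <- d_b2$dW; g$bb2 <- d_b2$db
  dhb1_pre <- .relu_bwd(d_b2$dX, fwd$hb1_pre)
  d_b1 <- .dense_bwd(dhb1_pre, fwd$tab, pr$Wb1)
  g$Wb1 <- d_b1$dW; g$bb1 <- d_b1$db

  if (model$use_trajectory) {
    ca <- fwd$cache
    lb <- .lstm_bwd(dhT, ca$lstm$caches, pr$Wx, pr$Wh)
    g$Wx <- lb$dWx; g$Wh <- lb$dWh; g$bl <- lb$db
    dE <- matrix(0, ca$S, model$spec$lstm_input)
    for (t in seq_len(ca$Wk)) {
      dE[(seq_len(ca$B) - 1L) * ca$Wk + t, ] <- lb$dXseq[[t]]
    }
    d_p <- .dense_bwd(dE, ca$dp$out, pr$Wp)
    g$Wp <- d_p$dW; g$bp <- d_p$db
    ddp <- d_p$dX
    if (!is.null(ca$dp$mask)) ddp <- ddp * ca$dp$mask
    dh1_pre <- .relu_bwd(ddp, ca$h1_pre)
    d_f <- .dense_bwd(dh1_pre, ca$Xfc, pr$Wf)
    g$Wf <- d_f$dW; g$bf <- d_f$db
    dp2 <- .flatten_bwd(d_f$dX, ca$Pn, ca$S, model$spec$conv2_kernels)
    sg <- cpp_stem_bwd(dp2, ca$st, ca$pl$conv1, ca$pl$pool1,
                       ca$pl$conv2, ca$pl$pool2,
                       ca$K1m, pr$g1, ca$K2m, pr$g2)
    F1 <- model$spec$conv1_kernels; F2 <- model$spec$conv2_kernels
    g$K1 <- aperm(array(sg$dK1m, c(1L, 3L, 3L, F1)), c(2, 3, 1, 4))
    g$c1b <- sg$dc1b; g$g1 <- sg$dg1; g$be1 <- sg$dbe1
    g$K2 <- aperm(array(sg$dK2m, c(F1, 3L, 3L, F2)), c(2, 3, 1, 4))
    g$c2b <- sg$dc2b; g$g2 <- sg$dg2; g$be2 <- sg$dbe2
  }
  g[names(pr)]
}

.dp_standardize <- function(tab, center, scale_) {
  sweep(sweep(as.matrix(tab), 2L, center), 2L, scale_, "/")
}

#' Train a DeepPsy model
#'
#' Runs `spec$epochs` passes of minibatch Adam (`spec$batch_size`,
#' `spec$learning_rate`) over the training rows, with class-weighted
#' cross-entropy (weights inversely proportional to training class
#' frequency), dropout and per-batch batch-normalization statistics active
#' during training only. Both branches are updated jointly by the same
#' backward pass. All randomness (batch order, dropout masks) derives from
#' `spec$seed`, so a fixed seed reproduces the run bit for bit.
#'
#' Tabular features are standardized with training-set statistics, which
#' are stored in the model and reused at prediction time.
#'
#' @param model a [build_deeppsy()] model.
#' @param grids activity-grid array `(n, n_weeks, H, W)` (or `NULL` for a
#'   basic-branch-only model).
#' @param tab numeric matrix of tabular features, `n` rows.
#' @param y integer class labels in `1..n_classes`.
#' @param train_idx,val_idx row indices of the training and (optional)
#'   validation split.
#' @return List with `model` (trained) and `log` (a `deeppsy_trainlog` data
#'   frame: epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_deeppsy <- function(model, grids, tab, y, train_idx,
                          val_idx = integer(0)) {
  stopifnot(inherits(model, "deeppsy_model"))
  sp <- model$spec
  tab <- as.matrix(tab)
  y <- as.integer(y)
  if (length(unique(y[train_idx])) < 2L) {
    stop("training error: training split must contain both classes", call. = FALSE)
  }
  center <- colMeans(tab[train_idx, , drop = FALSE])
  scale_ <- apply(tab[train_idx, , drop = FALSE], 2L, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  model$tab_center <- center; model$tab_scale <- scale_
  tabz <- .dp_standardize(tab, center, scale_)
  counts <- tabulate(y[train_idx], nbins = sp$n_classes)
  cw <- length(train_idx) / (sp$n_classes * pmax(counts, 1L))
  adam <- .adam_init(model$params)
  A1full <- NULL; Wk <- NULL; HW <- NULL
  if (model$use_trajectory) {
    Wk <- dim(grids)[2]
    HW <- prod(model$grid_dim)
    A1full <- .grids_to_channels(grids)
  }
  traj_of <- function(idx) {
    if (!model$use_trajectory) return(NULL)
    list(A1 = A1full[.channel_rows(idx, Wk, HW), , drop = FALSE], Wk = Wk)
  }
  set.seed(sp$seed)
  log_rows <- vector("list", sp$epochs)
  eval_split <- function(idx) {
    if (length(idx) == 0) return(c(NA_real_, NA_real_))
    fw <- .dp_forward(model, traj_of(idx), tabz[idx, , drop = FALSE],
                      y = y[idx], training = FALSE, class_weights = cw)
    c(fw$loss, mean(max.col(fw$probs) == y[idx]))
  }
  for (ep in seq_len(sp$epochs)) {
    order_ <- sample(train_idx)
    nb <- ceiling(length(order_) / sp$batch_size)
    ep_loss <- 0; ep_hits <- 0L
    for (b in seq_len(nb)) {
      idx <- order_[((b - 1L) * sp$batch_size + 1L):min(b * sp$batch_size, length(order_))]
      fw <- .dp_forward(model, traj_of(idx), tabz[idx, , drop = FALSE],
                        y = y[idx], training = TRUE, class_weights = cw)
      model$bn <- fw$model$bn
      if (!is.finite(fw$loss)) {
        stop("training error: non-finite loss at epoch ", ep, ", batch ", b,
             call. = FALSE)
      }
      ep_loss <- ep_loss + fw$loss * length(idx)
      ep_hits <- ep_hits + sum(max.col(fw$probs) == y[idx])
      grads <- .dp_backward(model, fw)
      st <- .adam_step(model$params, grads, adam, lr = sp$learning_rate)
      model$params <- st$params
      adam <- st$state
    }
    va <- eval_split(val_idx)
    log_rows[[ep]] <- data.frame(epoch = ep,
                                 train_loss = ep_loss / length(order_),
                                 train_acc = ep_hits / length(order_),
                                 val_loss = va[1], val_acc = va[2])
  }
  log <- do.call(rbind, log_rows)
  model$trained <- TRUE
  class(log) <- c("deeppsy_trainlog", "data.frame")
  attr(log, "seed") <- sp$seed
  attr(log, "spec_hash") <- .spec_hash(sp)
  list(model = model, log = log)
}

.spec_hash <- function(spec) {
  s <- paste(names(spec), vapply(spec, function(v) paste(v, collapse = ","),
                                 character(1)), sep = "=", collapse = ";")
  # small rolling hash; only used to tag logs with their configuration
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Predict class probabilities with a trained DeepPsy model
#'
#' Inference path: dropout disabled, batch normalization uses the running
#' averages accumulated during training. Deterministic.
#'
#' @param object a trained `deeppsy_model`.
#' @param grids activity grids of the new students (or `NULL`).
#' @param tab their tabular features (raw scale; the model standardizes).
#' @param zero_trajectory replace the trajectory-branch output with zeros at
#'   inference, reducing the model to a function of the tabular features
#'   (used by the fusion-ablation diagnostic).
#' @param ... unused.
#' @return Matrix of class probabilities, rows summing to 1.
#' @export
predict.deeppsy_model <- function(object, grids, tab, zero_trajectory = FALSE,
                                  ...) {
  tab <- as.matrix(tab)
  if (ncol(tab) != object$n_basic) {
    stop("dimension error: expected ", object$n_basic, " tabular features",
         call. = FALSE)
  }
  if (object$use_trajectory &&
      (is.null(grids) || !all(dim(grids)[3:4] == object$grid_dim))) {
    stop("dimension error: grids do not match the model's grid shape", call. = FALSE)
  }
  center <- object$tab_center %||% colMeans(tab)
  scale_ <- object$tab_scale %||% rep(1, ncol(tab))
  traj <- if (object$use_trajectory) {
    list(A1 = .grids_to_channels(grids), Wk = dim(grids)[2])
  } else NULL
  fw <- .dp_forward(object, traj, .dp_standardize(tab, center, scale_),
                    training = FALSE, zero_trajectory = zero_trajectory)
  fw$probs
}
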