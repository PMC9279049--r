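test_that("spec validation rejects inconsistent settings", {
  expect_error(deeppsy_spec(dropout = 1), "configuration")
  expect_error(deeppsy_spec(lstm_units = 0), "configuration")
  expect_s3_class(deeppsy_spec(), "deeppsy_spec")
})

test_that("parameter count equals the closed-form layer sum for the default spec", {
  spec <- deeppsy_spec()
  d <- 6L                                    # tabular features
  model <- build_deeppsy(spec, n_basic = d, n_weeks = 9, grid_dim = c(7, 24))
  # 7x24 same-conv keeps dims; pools give 4x12 then 2x6 -> flat 2*6*32
  flat <- 2 * 6 * 32
  expected <- (3 * 3 * 1 * 4 + 4) + (2 * 4) +          # conv1 + bn1
    (3 * 3 * 4 * 32 + 32) + (2 * 32) +                 # conv2 + bn2
    (flat * 16 + 16) +                                 # fc 16
    (16 * 64 + 64) +                                   # projection to lstm input
    4 * ((64 + 4) * 4 + 4) +                           # lstm gates
    (d * 8 + 8) + (8 * 4 + 4) +                        # basic branch
    ((4 + 4) * 4 + 4) +                                # fusion layer
    (4 * 2 + 2)                                        # softmax head
  expect_equal(n_params(model), expected)
})

test_that("same-padding trajectory stem preserves spatial dims through conv", {
  # conv output dims equal input dims at every kernel count
  for (F1 in c(2, 4, 8)) {
    sp <- deeppsy_spec(conv1_kernels = F1, seed = 1)
    m <- build_deeppsy(sp, n_basic = 2, n_weeks = 2)
    expect_equal(m$dims$pool1, c(4L, 12L))   # 7x24 -> conv same 7x24 -> pool
    expect_equal(m$dims$pool2, c(2L, 6L))
  }
})

test_that("softmax outputs are probabilities and duplicate inputs map identically", {
  set.seed(20)
  sp <- tiny_spec(seed = 2, epochs = 2)
  co <- small_cohort(seed = 2, per_level = 8, n_days = 14)
  mi <- model_inputs(co)
  m <- build_deeppsy(sp, n_basic = ncol(mi$tab), n_weeks = dim(mi$grids)[2])
  fit <- train_deeppsy(m, mi$grids, mi$tab, mi$y,
                       train_idx = seq_len(18), val_idx = 19:24)
  idx <- c(1, 5, 1)
  probs <- predict(fit$model, mi$grids[idx, , , , drop = FALSE],
                   mi$tab[idx, , drop = FALSE])
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_equal(probs[1, ], probs[3, ])       # duplicated student
  expect_error(predict(fit$model, mi$grids[idx, , , , drop = FALSE],
                       mi$tab[idx, 1:3, drop = FALSE]), "dimension")
})

test_that("model gradients pass a finite-difference check end to end", {
  set.seed(21)
  sp <- deeppsy_spec(conv1_kernels = 2, conv2_kernels = 3, fc_width = 4,
                     dropout = 0, lstm_input = 5, lstm_units = 2,
                     basic_widths = c(3, 2), fusion_width = 3, seed = 7)
  m <- build_deeppsy(sp, n_basic = 3, n_weeks = 2, grid_dim = c(5, 6))
  # keep pre-activations off the ReLU kink: random small biases
  for (nm in c("bf", "bp", "bb1", "bb2", "bz", "bo", "c1b", "c2b")) {
    m$params[[nm]][] <- stats::rnorm(length(m$params[[nm]]), 0, 0.05)
  }
  B <- 4
  grids <- array(stats::runif(B * 2 * 5 * 6), c(B, 2, 5, 6))
  traj <- list(A1 = deeppsy:::.grids_to_channels(grids), Wk = 2L)
  tab <- matrix(stats::rnorm(B * 3), B)
  y <- c(1L, 2L, 1L, 2L)
  cw <- c(1, 1.5)
  fw <- deeppsy:::.dp_forward(m, traj, tab, y = y, training = TRUE,
                              class_weights = cw)
  gr <- deeppsy:::.dp_backward(m, fw)
  loss_of <- function(params) {
    m2 <- m; m2$params <- params
    deeppsy:::.dp_forward(m2, traj, tab, y = y, training = TRUE,
                          class_weights = cw)$loss
  }
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
      num <- (loss_of(pp) - loss_of(pm)) / 2e-5
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("one training step moves parameters in both branches", {
  set.seed(22)
  sp <- tiny_spec(seed = 3, epochs = 1)
  co <- small_cohort(seed = 3, per_level = 8, n_days = 14)
  mi <- model_inputs(co)
  m0 <- build_deeppsy(sp, n_basic = ncol(mi$tab), n_weeks = dim(mi$grids)[2])
  fit <- train_deeppsy(m0, mi$grids, mi$tab, mi$y, train_idx = 1:8)
  moved <- vapply(names(m0$params), function(nm) {
    any(fit$model$params[[nm]] != m0$params[[nm]])
  }, logical(1))
  trajectory_par <- c("K1", "K2", "Wf", "Wp", "Wx", "Wh")
  basic_par <- c("Wb1", "Wb2", "Wz", "Wo")
  expect_true(all(moved[trajectory_par]))
  expect_true(all(moved[basic_par]))
})

test_that("zero learning rate freezes parameters and the loss", {
  # single full batch so batchnorm statistics are identical every epoch
  sp <- tiny_spec(seed = 4, epochs = 3, learning_rate = 0, dropout = 0,
                  batch_size = 24L)
  co <- small_cohort(seed = 4, per_level = 8, n_days = 14)
  mi <- model_inputs(co)
  m0 <- build_deeppsy(sp, n_basic = ncol(mi$tab), n_weeks = dim(mi$grids)[2])
  fit <- train_deeppsy(m0, mi$grids, mi$tab, mi$y, train_idx = seq_len(24))
  expect_identical(fit$model$params, m0$params)
  expect_equal(stats::sd(fit$log$train_loss), 0, tolerance = 1e-9)
})

test_that("training is bit-stable under a fixed seed and logs every epoch", {
  sp <- tiny_spec(seed = 5, epochs = 4)
  co <- small_cohort(seed = 5, per_level = 8, n_days = 14)
  mi <- model_inputs(co)
  run <- function() {
    m <- build_deeppsy(sp, n_basic = ncol(mi$tab), n_weeks = dim(mi$grids)[2])
    train_deeppsy(m, mi$grids, mi$tab, mi$y, train_idx = seq_len(18),
                  val_idx = 19:24)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$log, f2$log)
  expect_equal(nrow(f1$log), 4L)
  expect_false(anyNA(f1$log$val_loss))
})

test_that("the full model memorizes a strongly separable cohort", {
  co <- small_cohort(seed = 6, effects = 2, per_level = 10, n_days = 21)
  mi <- model_inputs(co)
  sp <- deeppsy_spec(seed = 6)               # full architecture, 60 epochs
  m <- build_deeppsy(sp, n_basic = ncol(mi$tab), n_weeks = dim(mi$grids)[2])
  fit <- train_deeppsy(m, mi$grids, mi$tab, mi$y, train_idx = seq_len(30))
  expect_gte(fit$log$train_acc[sp$epochs], 0.95)
  # training loss decreased from the first to the last decade of epochs
  expect_lt(stats::median(fit$log$train_loss[51:60]),
            stats::median(fit$log$train_loss[1:10]))
})

test_that("a trajectory-free variant runs on tabular features alone", {
  co <- small_cohort(seed = 7, per_level = 8, n_days = 14)
  mi <- model_inputs(co)
  sp <- tiny_spec(seed = 7, epochs = 3)
  m <- build_deeppsy(sp, n_basic = 1, use_trajectory = FALSE)
  fit <- train_deeppsy(m, NULL, mi$tab[, "gpa", drop = FALSE], mi$y,
                       train_idx = seq_len(24))
  probs <- predict(fit$model, NULL, mi$tab[, "gpa", drop = FALSE])
  expect_equal(rowSums(probs), rep(1, 24), tolerance = 1e-6)
})

test_that("zeroing the trajectory branch reduces the model to tabular features", {
  co <- small_cohort(seed = 88, effects = 2, per_level = 12, n_days = 14)
  mi <- model_inputs(co)
  sp <- tiny_spec(seed = 88, epochs = 10)
  splits <- split_data(mi$features, seed = 88)
  m <- build_deeppsy(sp, n_basic = ncol(mi$tab), n_weeks = dim(mi$grids)[2])
  fit <- train_deeppsy(m, mi$grids, mi$tab, mi$y, splits$train)
  # with the trajectory output zeroed, predictions ignore the grids entirely
  idx <- splits$test
  scrambled <- mi$grids[rev(idx), , , , drop = FALSE]
  p1 <- predict(fit$model, mi$grids[idx, , , , drop = FALSE],
                mi$tab[idx, , drop = FALSE], zero_trajectory = TRUE)
  p2 <- predict(fit$model, scrambled, mi$tab[idx, , drop = FALSE],
                zero_trajectory = TRUE)
  expect_equal(p1, p2, tolerance = 1e-12)
  # and recall sits at the level of a basic-branch-only model (paired seeds)
  diffs <- sapply(1:4, function(s) {
    spl <- split_data(mi$features, seed = s)
    sps <- tiny_spec(seed = s, epochs = 10)
    mf <- build_deeppsy(sps, n_basic = ncol(mi$tab), n_weeks = dim(mi$grids)[2])
    ff <- train_deeppsy(mf, mi$grids, mi$tab, mi$y, spl$train)
    pz <- predict(ff$model, mi$grids[spl$test, , , , drop = FALSE],
                  mi$tab[spl$test, , drop = FALSE], zero_trajectory = TRUE)
    mb <- build_deeppsy(sps, n_basic = ncol(mi$tab), use_trajectory = FALSE)
    fb <- train_deeppsy(mb, NULL, mi$tab, mi$y, spl$train)
    pb <- predict(fb$model, NULL, mi$tab[spl$test, , drop = FALSE])
    compute_metrics(mi$features$md[spl$test], as.integer(max.col(pz) == 2))$recall -
      compute_metrics(mi$features$md[spl$test], as.integer(max.col(pb) == 2))$recall
  })
  nz <- diffs[diffs != 0]
  p <- if (length(nz) == 0) 1 else stats::binom.test(sum(nz > 0), length(nz))$p.value
  expect_gt(p, 0.05)
})
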