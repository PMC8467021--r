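# The stacked multiview convolutional autoencoder: structural contracts,
# gradient correctness, training behaviour and translation equivariance.

tiny_cfg <- function(...) {
  model_config(kernel_len = 3L, conv_filters = 2L, deep_dim = 4L,
               encoded_dim = 3L, dropout = 0, kernel_reg = 1e-3, seed = 7, ...)
}

test_that("reconstruction preserves the tensor shape and the final layer has one map per source", {
  cfg <- model_config(seed = 1)
  model <- build_model(cfg, c(400L, 8L, 8L))
  expect_equal(dim(model$params$Wo)[2], 64L)   # m*n output maps
  v <- array(0, c(400, 8, 8)); v[100:120, 5, 3] <- 1
  tt <- anopeak:::new_crm_tensor(v, "chr1", 0, 10L, 40L, FALSE)
  rec <- reconstruct(model, tt)
  expect_equal(dim(rec$values), c(400L, 8L, 8L))
  # X too small for the kernels errors with an explanation
  expect_error(build_model(cfg, c(60L, 8L, 8L)), "kernel_len")
})

test_that("with all weights zeroed the reconstruction is constant in the input", {
  cfg <- tiny_cfg()
  model <- build_model(cfg, c(20L, 2L, 2L))
  model$params <- lapply(model$params, function(w) w * 0)
  t1 <- anopeak:::new_crm_tensor(array(0, c(20, 2, 2)), "c", 0, 10L, 6L, FALSE)
  v2 <- array(stats::runif(80), c(20, 2, 2))
  t2 <- anopeak:::new_crm_tensor(v2, "c", 0, 10L, 6L, FALSE)
  expect_equal(reconstruct(model, t1)$values, reconstruct(model, t2)$values)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_cfg()
  shape <- c(16L, 2L, 3L)
  model <- build_model(cfg, shape)
  # move biases off zero so no ReLU sits exactly on its kink
  p <- model$params
  set.seed(99)
  for (nm in names(p)) p[[nm]] <- p[[nm]] + stats::runif(length(p[[nm]]), 0.01, 0.08)
  xb <- matrix(stats::runif(prod(shape) * 3), ncol = 3)
  wcell <- anopeak:::nn_cell_weights(shape, cfg)
  lg <- anopeak:::nn_loss_grads(p, xb, shape, cfg, wcell)
  num_grad <- function(nm, idx, eps = 1e-6) {
    p1 <- p; p1[[nm]][idx] <- p1[[nm]][idx] + eps
    p2 <- p; p2[[nm]][idx] <- p2[[nm]][idx] - eps
    (anopeak:::nn_loss_grads(p1, xb, shape, cfg, wcell)$loss -
       anopeak:::nn_loss_grads(p2, xb, shape, cfg, wcell)$loss) / (2 * eps)
  }
  set.seed(4)
  for (nm in names(p)) {
    for (idx in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
      ng <- num_grad(nm, idx)
      ag <- lg$grads[[nm]][idx]
      expect_lt(abs(ng - ag) / max(1e-8, abs(ng) + abs(ag)), 1e-5)
    }
  }
})

test_that("the compiled convolutions match a naive R convolution", {
  set.seed(12)
  X <- 11L; G <- 3L; C <- 2L; Fl <- 2L; k <- 5L
  padl <- (k - 1L) %/% 2L
  w <- array(rnorm(C * Fl * k), c(C, Fl, k))
  a <- matrix(rnorm(C * X * G), C, X * G)
  idx <- anopeak:::nn_core_idx(X, G, k)
  out <- conv_fwd_cpp(anopeak:::nn_pad(a, X, G, k), w, X, G)[, idx]
  # naive: out[f, x, g] = sum_{d, c} w[c, f, d] * a[c, x + d - 1 - padl, g]
  for (g in seq_len(G)) {
    for (x in seq_len(X)) {
      for (f in seq_len(Fl)) {
        acc <- 0
        for (d in seq_len(k)) {
          xi <- x + d - 1L - padl
          if (xi >= 1 && xi <= X) {
            acc <- acc + sum(w[, f, d] * a[, (g - 1) * X + xi])
          }
        }
        expect_equal(out[f, (g - 1) * X + x], acc)
      }
    }
  }
})

test_that("training reduces the loss, keeps the best epoch and is seed-reproducible", {
  set.seed(31)
  shape <- c(20L, 2L, 2L)
  tens <- lapply(1:120, function(i) {
    v <- array(0, c(20, 2, 2))
    x <- sample(7:14, 1)
    v[x:(x + 2), 1, 1] <- 1
    v[x:(x + 2), 2, 2] <- 1
    anopeak:::new_crm_tensor(v, "c", 0, 10L, 6L, FALSE)
  })
  set <- tensor_set(tens)
  cfg <- model_config(kernel_len = 3L, conv_filters = 4L, deep_dim = 8L,
                      encoded_dim = 4L, learning_rate = 1e-3, batch_size = 24L,
                      batches_per_epoch = 5L, max_epochs = 15L, seed = 3)
  m1 <- train_model(build_model(cfg, shape), set)
  expect_true(m1$trained)
  expect_lt(m1$loss_history[m1$best_epoch], m1$loss_history[1])
  expect_equal(m1$loss_history[m1$best_epoch], min(m1$loss_history))
  # loss decreases over the first epochs
  expect_lt(m1$loss_history[5], m1$loss_history[1])
  # reproducibility
  m2 <- train_model(build_model(cfg, shape), set)
  expect_equal(m1$params, m2$params)
  expect_equal(m1$loss_history, m2$loss_history)
  # and reconstruction is deterministic after training (no dropout at inference)
  r1 <- reconstruct(m1, tens[[1]])
  r2 <- reconstruct(m1, tens[[1]])
  expect_identical(r1$values, r2$values)
})

test_that("reconstruction is translation-consistent away from the margins", {
  fx <- fixture_one_source()
  model <- fx$model
  X <- model$shape[1]
  v <- array(0, c(X, 2, 2))
  v[25:32, 1, 1] <- 1
  vs <- array(0, c(X, 2, 2))
  vs[26:33, 1, 1] <- 1
  mk <- function(v) anopeak:::new_crm_tensor(v, "c", 0, 10L, 10L, FALSE)
  r <- reconstruct(model, mk(v))$values
  rs <- reconstruct(model, mk(vs))$values
  peak_val <- max(abs(r[20:38, 1, 1]))
  # shifting the input by one bin shifts the reconstruction by one bin
  expect_lt(max(abs(rs[21:38, 1, 1] - r[20:37, 1, 1])), 0.1 * peak_val)
})

test_that("a ten-fold loss weight raises the rebuilt values of the weighted sources", {
  set.seed(44)
  cfg_gen <- generator_config(m = 4L, n = 4L)
  batch <- generate_batch(cfg_gen, 600, seed = 19, tensors = TRUE)
  set <- batch$tensors
  base <- model_config(kernel_len = 20L, conv_filters = 8L, deep_dim = 16L,
                       encoded_dim = 16L, learning_rate = 1e-3,
                       batches_per_epoch = 10L, max_epochs = 8L, seed = 6)
  m_plain <- train_model(build_model(base, set$shape), set)
  wcfg <- base
  # unreliable datasets (noise-only) get 10x loss weight
  wcfg$loss_weights <- list(datasets = c(10, 10, 1, 1))
  m_wt <- train_model(build_model(wcfg, set$shape), set)
  mean_rebuilt_unreliable <- function(model) {
    rec <- reconstruct_set(model, set)
    pres <- set$data > 0
    X <- set$shape[1]
    rows <- as.vector(outer(seq_len(2 * X), (seq_len(4) - 1) * 4 * X, "+"))
    mean(rec[rows, ][pres[rows, ]])
  }
  expect_gt(mean_rebuilt_unreliable(m_wt), mean_rebuilt_unreliable(m_plain))
})

test_that("non-finite losses abort with diagnostics", {
  set.seed(2)
  tens <- lapply(1:48, function(i) {
    anopeak:::new_crm_tensor(array(rbinom(80, 1, .3), c(20, 2, 2)), "c", 0,
                             10L, 6L, FALSE)
  })
  set <- tensor_set(tens)
  cfg <- model_config(kernel_len = 3L, conv_filters = 2L, deep_dim = 4L,
                      encoded_dim = 2L, learning_rate = 1e150, batch_size = 16L,
                      batches_per_epoch = 3L, max_epochs = 5L, seed = 1)
  model <- build_model(cfg, c(20L, 2L, 2L))
  expect_error(train_model(model, set), "loss")
})
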