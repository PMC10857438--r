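test_that("parameter counts reproduce the reference architecture exactly", {
  p84 <- init_model_params(encoder_config(input_shape = c(10, 84)))
  n84 <- count_trainable_parameters(p84)
  expect_equal(as.integer(n84), 109217L)
  expect_equal(attr(n84, "size_kb"), 426.63)

  p80 <- init_model_params(encoder_config(input_shape = c(10, 80)))
  n80 <- count_trainable_parameters(p80)
  expect_equal(as.integer(n80), 108833L)
  expect_equal(attr(n80, "size_kb"), 425.13)

  # only conv1 changes with the input width: 4 channels x 3 taps x 32 filters
  expect_equal(as.integer(n84) - as.integer(n80), 4L * 3L * 32L)
  expect_equal(length(p84$c1_W) - length(p80$c1_W), 384L)

  # layer-by-layer decomposition pins the architecture
  blocks <- c(conv1 = 84 * 3 * 32 + 32, conv2 = 32 * 3 * 64 + 64,
              lstm = 4 * ((64 + 64) * 64 + 64), attention = 64 * 64 + 1,
              head = (64 * 256 + 256) + (256 * 128 + 128) + (128 * 64 + 64))
  expect_equal(unname(blocks["conv2"]), 6208)
  expect_equal(unname(blocks["lstm"]), 33024)
  expect_equal(unname(blocks["attention"]), 4097)
  expect_equal(unname(blocks["head"]), 57792)
  expect_equal(sum(blocks), 109217)
  expect_equal(as.integer(count_trainable_parameters(list())), 0L)
})

test_that("encoder maps (B, 10, F) windows to 64-dimensional embeddings", {
  cfg <- encoder_config(input_shape = c(10, 84))
  p <- init_model_params(cfg, seed = 2)
  x <- array(rnorm(3 * 10 * 84), c(3, 10, 84))
  s <- encoder_forward(x, p, cfg)$s
  expect_equal(dim(s), c(3L, 64L))
  expect_error(encoder_forward(array(0, c(3, 10, 80)), p, cfg), "shape")
  # batch-order invariance: no cross-sample operations
  s2 <- encoder_forward(x[c(3, 1, 2), , , drop = FALSE], p, cfg)$s
  expect_equal(s2, s[c(3, 1, 2), ], tolerance = 1e-12)
  # deterministic with dropout off
  expect_identical(s, encoder_forward(x, p, cfg)$s)
})

test_that("attention rows are probability vectors mixing the hidden states", {
  set.seed(7)
  H <- matrix(rnorm(3 * 4), 3, 4)
  # zero scores: uniform weights, every context = column mean
  r0 <- multiplicative_attention(H, matrix(0, 4, 4), 0)
  expect_equal(r0$A, matrix(1 / 3, 3, 3))
  expect_equal(r0$C, matrix(colMeans(H), 3, 4, byrow = TRUE))
  # single timestep degenerates to the identity
  r1 <- multiplicative_attention(H[1, , drop = FALSE], diag(4), 0.3)
  expect_equal(r1$A, matrix(1, 1, 1))
  expect_equal(r1$C, H[1, , drop = FALSE])
  # arbitrary weights: rows still sum to one, entries in [0, 1]
  Wa <- matrix(rnorm(16), 4, 4)
  r <- multiplicative_attention(H, Wa, -0.2)
  expect_equal(rowSums(r$A), rep(1, 3))
  expect_true(all(r$A >= 0 & r$A <= 1))
})

test_that("attention matches the double-loop oracle on random instances", {
  set.seed(8)
  for (rep in 1:5) {
    T <- sample(2:6, 1); u <- sample(2:5, 1)
    H <- matrix(rnorm(T * u), T, u)
    Wa <- matrix(rnorm(u * u), u, u)
    ba <- rnorm(1)
    r <- multiplicative_attention(H, Wa, ba)
    # naive elementwise computation of scores, weights, contexts
    E <- matrix(0, T, T)
    for (t in 1:T) for (tp in 1:T) {
      E[t, tp] <- sum(H[t, ] * (Wa %*% H[tp, ])) + ba
    }
    A <- t(apply(E, 1, function(e) exp(e) / sum(exp(e))))
    C <- matrix(0, T, u)
    for (t in 1:T) for (tp in 1:T) C[t, ] <- C[t, ] + A[t, tp] * H[tp, ]
    expect_equal(r$A, A, tolerance = 1e-10)
    expect_equal(r$C, C, tolerance = 1e-10)
  }
})

test_that("projection head has 57,792 parameters and collapses under zero weights", {
  cfg <- encoder_config()
  p <- init_model_params(cfg, seed = 3)
  head_names <- grep("^p_", names(p), value = TRUE)
  expect_equal(sum(vapply(p[head_names], length, integer(1))), 57792L)
  s <- matrix(rnorm(5 * 64), 5, 64)
  z <- projection_forward(s, p)$z
  expect_equal(dim(z), c(5L, 64L))
  zero <- p
  for (nm in head_names) zero[[nm]] <- zero[[nm]] * 0
  expect_equal(projection_forward(s, zero)$z, matrix(0, 5, 64))
})

test_that("classifier heads emit softmax scores and the probe adds 650 parameters", {
  cfg <- encoder_config()
  probe <- init_head_params(cfg, 10, "linear_probe")
  expect_equal(sum(vapply(probe, length, integer(1))), 64L * 10L + 10L)
  s <- matrix(rnorm(6 * 64), 6, 64)
  out <- classifier_forward(s, probe)
  expect_equal(rowSums(out$probs), rep(1, 6), tolerance = 1e-12)
  mlp <- init_head_params(cfg, 4, "finetune_mlp", hidden = 32)
  out2 <- classifier_forward(s, mlp)
  expect_equal(dim(out2$probs), c(6L, 4L))
  expect_equal(rowSums(out2$probs), rep(1, 6), tolerance = 1e-12)
  # a one-hot logit row predicts its class
  onehot <- list(o_W = diag(64)[, 1:5] * 50, o_b = numeric(5))
  pr <- classifier_forward(diag(64)[3, , drop = FALSE], onehot)$probs
  expect_equal(which.max(pr), 3L)
})

test_that("analytic gradients match finite differences through the whole network", {
  set.seed(42)
  for (attention in c(TRUE, FALSE)) {
    cfg <- tiny_encoder(attention = attention)
    params <- init_model_params(cfg, seed = 7)
    B <- 3
    vi <- array(rnorm(B * 4 * 5), c(B, 4, 5))
    vj <- array(rnorm(B * 4 * 5), c(B, 4, 5))
    gf <- function(p) sensorclr:::.contrastive_grads(p, cfg, vi, vj, 0.5)
    g <- gf(params)
    for (nm in names(params)) {
      for (j in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        num <- num_grad(function(p) gf(p)$loss, params, nm, j)
        ana <- g$grads[[nm]][j]
        expect_equal(ana, num, tolerance = 1e-4,
                     info = sprintf("att=%s %s[%d]", attention, nm, j))
      }
    }
  }
})

test_that("gradients also match through the classification path", {
  set.seed(43)
  cfg <- tiny_encoder()
  params <- init_model_params(cfg, seed = 9)
  head <- init_head_params(cfg, 3, "finetune_mlp", hidden = 5, seed = 4)
  x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  y <- c(1L, 3L, 2L)
  enc_names <- grep("^p_", names(params), value = TRUE, invert = TRUE)
  w <- c(unclass(params)[enc_names], head)
  n_enc <- length(enc_names)
  gf <- function(w) {
    p <- structure(w[seq_len(n_enc)], class = "model_params")
    h <- w[-seq_len(n_enc)]
    fe <- encoder_forward(x, p, cfg, keep_cache = TRUE)
    cf <- classifier_forward(fe$s, h, keep_cache = TRUE)
    ce <- softmax_xent(cf$logits, y, grad = TRUE)
    cb <- classifier_backward(ce$dlogits, cf$cache, h)
    ge <- encoder_backward(cb$ds, fe$cache, p, cfg)
    reg <- sensorclr:::.add_kernel_l2(ce$loss, ge, p, cfg)
    list(loss = reg$loss, grads = c(reg$grads, cb$grads)[names(w)])
  }
  g <- gf(w)
  for (nm in names(w)) {
    for (j in sample(length(w[[nm]]), min(3, length(w[[nm]])))) {
      num <- num_grad(function(ww) gf(ww)$loss, w, nm, j)
      expect_equal(g$grads[[nm]][j], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, j))
    }
  }
})

test_that("checkpoints round-trip parameters and config", {
  cfg <- tiny_encoder()
  p <- init_model_params(cfg, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(p, path, extra = list(loss_history = c(1, 0.5)))
  ck <- load_checkpoint(path)
  expect_equal(unclass(ck$params), unclass(p), ignore_attr = TRUE)
  expect_equal(ck$config$lstm_units, cfg$lstm_units)
  expect_equal(ck$loss_history, c(1, 0.5))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
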