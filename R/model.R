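#' Encoder architecture configuration
#'
#' Describes the representation network: two 1-D convolutions (ReLU,
#' dropout after each, L2 on the kernels) over the feature channels, a
#' single LSTM layer returning all hidden states, multiplicative
#' self-attention over the hidden-state sequence, global max-pooling over
#' the time axis, and a three-layer projection head used only during
#' contrastive pre-training. Defaults reproduce the reference
#' configuration for 84-feature inputs; any input width and layer sizes
#' are supported (small configurations are used by the gradient-check
#' tests).
#'
#' @param input_shape `(timesteps, features)`, default `c(10, 84)`.
#' @param conv_filters Output channels of the two convolutions.
#' @param kernel_size Convolution kernel width (time axis).
#' @param conv_dropout Dropout rate after each convolution (training only).
#' @param l2_strength L2 penalty on convolution kernels.
#' @param lstm_units LSTM hidden size (also the attention dimension).
#' @param attention_regularizer L2 penalty on the attention weight matrix.
#' @param proj_dims Projection-head layer widths.
#' @param attention Include the self-attention layer; with `FALSE` the
#'   max-pool acts directly on the LSTM hidden states (the plain
#'   contrastive variant without attention).
#' @return An `encoder_config` object.
#' @export
encoder_config <- function(input_shape = c(10L, 84L),
                           conv_filters = c(32L, 64L),
                           kernel_size = 3L,
                           conv_dropout = 0.1,
                           l2_strength = 1e-4,
                           lstm_units = 64L,
                           attention_regularizer = 1e-4,
                           proj_dims = c(256L, 128L, 64L),
                           attention = TRUE) {
  cfg <- list(input_shape = as.integer(input_shape),
              conv_filters = as.integer(conv_filters),
              kernel_size = as.integer(kernel_size),
              conv_dropout = conv_dropout,
              l2_strength = l2_strength,
              lstm_units = as.integer(lstm_units),
              attention_regularizer = attention_regularizer,
              proj_dims = as.integer(proj_dims),
              attention = isTRUE(attention))
  stopifnot(length(cfg$input_shape) == 2L, all(cfg$input_shape > 0L),
            length(cfg$conv_filters) == 2L, all(cfg$conv_filters > 0L),
            cfg$kernel_size >= 1L, cfg$lstm_units > 0L,
            length(cfg$proj_dims) == 3L,
            cfg$conv_dropout >= 0, cfg$conv_dropout < 1)
  class(cfg) <- "encoder_config"
  cfg
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize encoder and projection-head parameters
#'
#' Weights use Glorot-uniform initialization; biases start at zero except
#' the LSTM forget gate, whose bias starts at one. Convolution kernels are
#' stored as `(kernel_size * in_channels) x out_channels` matrices with
#' the kernel taps stacked blockwise (earliest timestep first); LSTM gate
#' order is input, forget, candidate, output.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for the initialization draw.
#' @return Named list of parameter arrays (class `model_params`).
#' @export
init_model_params <- function(config, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  F <- config$input_shape[2L]
  K <- config$kernel_size
  n1 <- config$conv_filters[1L]; n2 <- config$conv_filters[2L]
  u <- config$lstm_units
  p <- config$proj_dims
  params <- list(
    c1_W = .glorot(K * F, n1), c1_b = numeric(n1),
    c2_W = .glorot(K * n1, n2), c2_b = numeric(n2),
    l_Wx = .glorot(n2, 4L * u), l_Wh = .glorot(u, 4L * u),
    l_b = c(numeric(u), rep(1, u), numeric(2L * u)),  # forget-gate bias 1
    a_W = if (config$attention) .glorot(u, u),
    a_b = if (config$attention) 0,
    p_W0 = .glorot(u, p[1L]), p_b0 = numeric(p[1L]),
    p_W1 = .glorot(p[1L], p[2L]), p_b1 = numeric(p[2L]),
    p_W2 = .glorot(p[2L], p[3L]), p_b2 = numeric(p[3L])
  )
  params <- params[!vapply(params, is.null, logical(1))]
  structure(params, class = "model_params", config = config)
}

#' Initialize a classifier head
#'
#' @param config The [encoder_config()] of the encoder feeding the head.
#' @param n_classes Number of activity classes.
#' @param head_kind `"linear_probe"` (single dense + softmax) or
#'   `"finetune_mlp"` (dense-ReLU hidden layer then dense + softmax).
#' @param hidden Hidden width of the fine-tuning head.
#' @param seed Integer seed.
#' @return Named list of head parameters.
#' @export
init_head_params <- function(config, n_classes, head_kind = c("linear_probe",
                                                              "finetune_mlp"),
                             hidden = 64L, seed = 1L) {
  head_kind <- match.arg(head_kind)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  u <- config$lstm_units
  if (head_kind == "linear_probe") {
    list(o_W = .glorot(u, n_classes), o_b = numeric(n_classes))
  } else {
    list(h_W = .glorot(u, hidden), h_b = numeric(hidden),
         o_W = .glorot(hidden, n_classes), o_b = numeric(n_classes))
  }
}

#' Count trainable parameters
#'
#' @param params A parameter list (or several concatenated).
#' @return Integer count of scalar trainable entries. The float32 size in
#'   KB is `count * 4 / 1024`, available via `attr(, "size_kb")`.
#' @export
#' @examples
#' p <- init_model_params(encoder_config())
#' count_trainable_parameters(p) # 109217
count_trainable_parameters <- function(params) {
  n <- sum(vapply(params, length, integer(1)))
  structure(n, size_kb = round(n * 4 / 1024, 2))
}

# ---- forward passes ---------------------------------------------------

# shifted row-block view used by the 1-D convolution: rows index (batch,
# time) with batch fastest; tap k reads timestep t + k with zero padding.
.conv_patches <- function(M, B, T, K) {
  half <- (K - 1L) %/% 2L
  BT <- B * T
  blocks <- vector("list", K)
  for (j in seq_len(K)) {
    k <- j - 1L - half
    Pk <- matrix(0, BT, ncol(M))
    r <- seq_len(BT)
    valid <- r + k * B >= 1L & r + k * B <= BT
    Pk[r[valid], ] <- M[r[valid] + k * B, , drop = FALSE]
    blocks[[j]] <- Pk
  }
  do.call(cbind, blocks)
}

.conv_scatter <- function(dP, B, T, K, nc) {
  half <- (K - 1L) %/% 2L
  BT <- B * T
  dM <- matrix(0, BT, nc)
  for (j in seq_len(K)) {
    k <- j - 1L - half
    dPk <- dP[, (j - 1L) * nc + seq_len(nc), drop = FALSE]
    r <- seq_len(BT)
    valid <- r + k * B >= 1L & r + k * B <= BT
    dM[r[valid] + k * B, ] <- dM[r[valid] + k * B, , drop = FALSE] +
      dPk[r[valid], , drop = FALSE]
  }
  dM
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Run the encoder forward
#'
#' Maps a batch of standardized windows to 64-dimensional embeddings:
#' conv1 (ReLU, dropout), conv2 (ReLU, dropout), LSTM over all timesteps,
#' multiplicative attention over the hidden-state sequence, global
#' max-pool over the time axis of the context sequence. Dropout is active
#' only when `training = TRUE`; with it off the pass is deterministic.
#'
#' @param x Array `(batch, timesteps, features)` matching the config.
#' @param params Parameters from [init_model_params()].
#' @param config The [encoder_config()].
#' @param training Enable dropout.
#' @param keep_cache Retain intermediates for [encoder_backward()].
#' @return List with `s` (matrix `batch x lstm_units`) and, if requested,
#'   `cache`.
#' @export
encoder_forward <- function(x, params, config, training = FALSE,
                            keep_cache = FALSE) {
  d <- dim(x)
  if (length(d) != 3L || d[2] != config$input_shape[1L] ||
      d[3] != config$input_shape[2L]) {
    stop(sprintf("input shape (%s) does not match config (B, %d, %d)",
                 paste(d, collapse = ", "),
                 config$input_shape[1L], config$input_shape[2L]))
  }
  B <- d[1]; T <- d[2]; F <- d[3]
  K <- config$kernel_size
  n1 <- config$conv_filters[1L]; n2 <- config$conv_filters[2L]
  u <- config$lstm_units
  drop <- if (training) config$conv_dropout else 0

  M0 <- matrix(x, B * T, F)
  P1 <- .conv_patches(M0, B, T, K)
  Z1 <- sweep(P1 %*% params$c1_W, 2L, params$c1_b, "+")
  R1 <- Z1 > 0
  A1 <- Z1 * R1
  D1 <- NULL
  if (drop > 0) {
    D1 <- matrix((stats::runif(length(A1)) >= drop) / (1 - drop),
                 nrow(A1), ncol(A1))
    A1 <- A1 * D1
  }

  P2 <- .conv_patches(A1, B, T, K)
  Z2 <- sweep(P2 %*% params$c2_W, 2L, params$c2_b, "+")
  R2 <- Z2 > 0
  A2 <- Z2 * R2
  D2 <- NULL
  if (drop > 0) {
    D2 <- matrix((stats::runif(length(A2)) >= drop) / (1 - drop),
                 nrow(A2), ncol(A2))
    A2 <- A2 * D2
  }

  # LSTM over T steps, batch-major
  h <- matrix(0, B, u); cc <- matrix(0, B, u)
  H <- array(0, dim = c(B, T, u))
  lstm_cache <- if (keep_cache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    Xt <- A2[(t - 1L) * B + seq_len(B), , drop = FALSE]
    Z <- Xt %*% params$l_Wx + h %*% params$l_Wh +
      matrix(params$l_b, B, 4L * u, byrow = TRUE)
    i <- .sigmoid(Z[, seq_len(u), drop = FALSE])
    f <- .sigmoid(Z[, u + seq_len(u), drop = FALSE])
    g <- tanh(Z[, 2L * u + seq_len(u), drop = FALSE])
    o <- .sigmoid(Z[, 3L * u + seq_len(u), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    H[, t, ] <- h
    if (keep_cache) {
      lstm_cache[[t]] <- list(Xt = Xt, i = i, f = f, g = g, o = o,
                              c_prev = c_prev, tc = tc)
    }
  }

  att <- if (config$attention) {
    .attention_forward(H, params$a_W, params$a_b)
  } else {
    list(A = NULL, C = H, HW = NULL)
  }

  # global max-pool over the time axis of the context sequence
  s <- att$C[, 1, , drop = TRUE]
  if (is.null(dim(s))) s <- matrix(s, B, u)
  amax <- matrix(1L, B, u)
  if (T > 1L) {
    for (t in 2:T) {
      Ct <- att$C[, t, , drop = TRUE]
      if (is.null(dim(Ct))) Ct <- matrix(Ct, B, u)
      upd <- Ct > s
      s[upd] <- Ct[upd]
      amax[upd] <- t
    }
  }

  out <- list(s = s)
  if (keep_cache) {
    out$cache <- list(B = B, T = T, F = F, M0 = M0, P1 = P1, R1 = R1, D1 = D1,
                      A1 = A1, P2 = P2, R2 = R2, D2 = D2, A2 = A2,
                      lstm = lstm_cache, H = H, HW = att$HW, A = att$A,
                      C = att$C, amax = amax, drop = drop)
  }
  out
}

# batched multiplicative attention; H is (B, T, u)
.attention_forward <- function(H, W_a, b_a) {
  d <- dim(H); B <- d[1]; T <- d[2]; u <- d[3]
  Hm <- matrix(H, B * T, u)
  HWm <- Hm %*% W_a
  A <- array(0, dim = c(B, T, T))
  C <- array(0, dim = c(B, T, u))
  for (b in seq_len(B)) {
    rows <- b + (seq_len(T) - 1L) * B
    Hb <- Hm[rows, , drop = FALSE]
    E <- HWm[rows, , drop = FALSE] %*% t(Hb) + as.numeric(b_a)
    E <- E - apply(E, 1L, max)
    W <- exp(E)
    Ab <- W / rowSums(W)
    A[b, , ] <- Ab
    C[b, , ] <- Ab %*% Hb
  }
  list(A = A, C = C, HW = HWm)
}

#' Multiplicative self-attention over a hidden-state sequence
#'
#' Scores every pair of hidden states as `e[t, t'] = t(h_t) W_a h_t' + b_a`
#' (a bilinear form plus scalar bias), softmax-normalizes each row into
#' attention weights, and mixes the states into context vectors
#' `c_t = sum_t' alpha[t, t'] h_t'`. Every row of the attention matrix is
#' a probability vector.
#'
#' @param H Matrix `(timesteps x units)` of hidden states.
#' @param W_a Attention weight matrix `(units x units)`.
#' @param b_a Scalar attention bias.
#' @return List with `A` (attention matrix, rows sum to 1) and `C`
#'   (context vectors, same shape as `H`).
#' @export
multiplicative_attention <- function(H, W_a, b_a = 0) {
  H3 <- array(H, dim = c(1L, nrow(H), ncol(H)))
  H3[1, , ] <- H
  r <- .attention_forward(H3, W_a, b_a)
  list(A = matrix(r$A[1, , ], nrow(H), nrow(H)),
       C = matrix(r$C[1, , ], nrow(H), ncol(H)))
}

#' Projection head forward pass
#'
#' Dense 64 -> 256 (ReLU) -> 128 (ReLU) -> 64 (linear); used only to
#' compute the contrastive loss and discarded afterwards.
#'
#' @param s Matrix `(batch x lstm_units)` of pooled embeddings.
#' @param params Parameters from [init_model_params()].
#' @param keep_cache Retain intermediates for the backward pass.
#' @return List with `z` (matrix `batch x proj_dims[3]`) and optionally
#'   `cache`.
#' @export
projection_forward <- function(s, params, keep_cache = FALSE) {
  Z0 <- sweep(s %*% params$p_W0, 2L, params$p_b0, "+")
  A0 <- Z0 * (Z0 > 0)
  Z1 <- sweep(A0 %*% params$p_W1, 2L, params$p_b1, "+")
  A1 <- Z1 * (Z1 > 0)
  z <- sweep(A1 %*% params$p_W2, 2L, params$p_b2, "+")
  out <- list(z = z)
  if (keep_cache) out$cache <- list(s = s, Z0 = Z0, A0 = A0, Z1 = Z1, A1 = A1)
  out
}

#' Classifier head forward pass
#'
#' @param s Embedding matrix `(batch x lstm_units)` from the encoder.
#' @param head Head parameters from [init_head_params()].
#' @param keep_cache Retain intermediates for the backward pass.
#' @return List with `probs` (softmax class scores, rows sum to 1),
#'   `logits`, and optionally `cache`.
#' @export
classifier_forward <- function(s, head, keep_cache = FALSE) {
  if (!is.null(head$h_W)) {
    Zh <- sweep(s %*% head$h_W, 2L, head$h_b, "+")
    Ah <- Zh * (Zh > 0)
    logits <- sweep(Ah %*% head$o_W, 2L, head$o_b, "+")
    cache <- list(s = s, Zh = Zh, Ah = Ah)
  } else {
    logits <- sweep(s %*% head$o_W, 2L, head$o_b, "+")
    cache <- list(s = s)
  }
  probs <- .softmax_rows(logits)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) out$cache <- cache
  out
}

.softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# ---- backward passes --------------------------------------------------

#' Backpropagate through the projection head
#'
#' @param dz Upstream gradient wrt the projected output.
#' @param cache Cache from `projection_forward(..., keep_cache = TRUE)`.
#' @param params Model parameters.
#' @return List with `ds` (gradient wrt the pooled embedding) and `grads`
#'   (named gradients for the head parameters).
#' @export
projection_backward <- function(dz, cache, params) {
  dW2 <- t(cache$A1) %*% dz
  db2 <- colSums(dz)
  dA1 <- dz %*% t(params$p_W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- t(cache$A0) %*% dZ1
  db1 <- colSums(dZ1)
  dA0 <- dZ1 %*% t(params$p_W1)
  dZ0 <- dA0 * (cache$Z0 > 0)
  dW0 <- t(cache$s) %*% dZ0
  db0 <- colSums(dZ0)
  ds <- dZ0 %*% t(params$p_W0)
  list(ds = ds,
       grads = list(p_W0 = dW0, p_b0 = db0, p_W1 = dW1, p_b1 = db1,
                    p_W2 = dW2, p_b2 = db2))
}

#' Backpropagate through the encoder
#'
#' @param ds Upstream gradient wrt the pooled embedding
#'   (`batch x lstm_units`).
#' @param cache Cache from `encoder_forward(..., keep_cache = TRUE)`.
#' @param params Model parameters.
#' @param config The [encoder_config()].
#' @return Named list of gradients for the convolution, LSTM and
#'   attention parameters.
#' @export
encoder_backward <- function(ds, cache, params, config) {
  B <- cache$B; T <- cache$T
  K <- config$kernel_size
  n1 <- config$conv_filters[1L]; n2 <- config$conv_filters[2L]
  u <- config$lstm_units

  # max-pool: route gradient to the argmax timestep
  dC <- array(0, dim = c(B, T, u))
  for (t in seq_len(T)) {
    mask <- cache$amax == t
    if (any(mask)) {
      slice <- matrix(0, B, u)
      slice[mask] <- ds[mask]
      dC[, t, ] <- slice
    }
  }

  if (!config$attention) {
    # no attention layer: the pool acted directly on the hidden states
    dH <- dC
    lg <- .lstm_conv_backward(dH, cache, params, config, B, T, K, n1, n2, u)
    return(lg)
  }

  # attention backward (per sample)
  Hm <- matrix(cache$H, B * T, u)
  dH <- array(0, dim = c(B, T, u))
  dWa <- matrix(0, u, u)
  dba <- 0
  for (b in seq_len(B)) {
    rows <- b + (seq_len(T) - 1L) * B
    Hb <- Hm[rows, , drop = FALSE]
    HWb <- cache$HW[rows, , drop = FALSE]
    Ab <- matrix(cache$A[b, , ], T, T)
    dCb <- matrix(dC[b, , ], T, u)
    dA <- dCb %*% t(Hb)
    dHb <- t(Ab) %*% dCb
    dE <- Ab * (dA - rowSums(dA * Ab))
    dHWb <- dE %*% Hb
    dHb <- dHb + t(dE) %*% HWb
    dHb <- dHb + dHWb %*% t(params$a_W)
    dWa <- dWa + t(Hb) %*% dHWb
    dba <- dba + sum(dE)
    dH[b, , ] <- dHb
  }

  lg <- .lstm_conv_backward(dH, cache, params, config, B, T, K, n1, n2, u)
  c(lg[c("c1_W", "c1_b", "c2_W", "c2_b", "l_Wx", "l_Wh", "l_b")],
    list(a_W = dWa, a_b = dba))
}

# LSTM-through-time and convolution backward shared by both encoder
# variants; dH is the gradient arriving at the hidden-state sequence.
.lstm_conv_backward <- function(dH, cache, params, config, B, T, K, n1, n2, u) {
  dWx <- matrix(0, n2, 4L * u); dWh <- matrix(0, u, 4L * u)
  db <- numeric(4L * u)
  dA2 <- matrix(0, B * T, n2)
  dh_next <- matrix(0, B, u); dc_next <- matrix(0, B, u)
  for (t in rev(seq_len(T))) {
    lc <- cache$lstm[[t]]
    dh <- matrix(dH[, t, ], B, u) + dh_next
    do_ <- dh * lc$tc
    dct <- dh * lc$o * (1 - lc$tc^2) + dc_next
    di <- dct * lc$g
    df <- dct * lc$c_prev
    dg <- dct * lc$i
    dZ <- cbind(di * lc$i * (1 - lc$i),
                df * lc$f * (1 - lc$f),
                dg * (1 - lc$g^2),
                do_ * lc$o * (1 - lc$o))
    h_prev <- if (t > 1L) matrix(cache$H[, t - 1L, ], B, u) else matrix(0, B, u)
    dWx <- dWx + t(lc$Xt) %*% dZ
    dWh <- dWh + t(h_prev) %*% dZ
    db <- db + colSums(dZ)
    dA2[(t - 1L) * B + seq_len(B), ] <- dZ %*% t(params$l_Wx)
    dh_next <- dZ %*% t(params$l_Wh)
    dc_next <- dct * lc$f
  }

  # conv2 backward
  if (!is.null(cache$D2)) dA2 <- dA2 * cache$D2
  dZ2 <- dA2 * cache$R2
  dW2 <- t(cache$P2) %*% dZ2
  db2 <- colSums(dZ2)
  dA1 <- .conv_scatter(dZ2 %*% t(params$c2_W), B, T, K, n1)

  # conv1 backward
  if (!is.null(cache$D1)) dA1 <- dA1 * cache$D1
  dZ1 <- dA1 * cache$R1
  dW1 <- t(cache$P1) %*% dZ1
  db1 <- colSums(dZ1)

  list(c1_W = dW1, c1_b = db1, c2_W = dW2, c2_b = db2,
       l_Wx = dWx, l_Wh = dWh, l_b = db)
}

#' Backpropagate through a classifier head
#'
#' @param dlogits Upstream gradient wrt the logits.
#' @param cache Cache from `classifier_forward(..., keep_cache = TRUE)`.
#' @param head Head parameters.
#' @return List with `ds` (gradient wrt the embedding) and `grads`.
#' @export
classifier_backward <- function(dlogits, cache, head) {
  if (!is.null(head$h_W)) {
    dWo <- t(cache$Ah) %*% dlogits
    dbo <- colSums(dlogits)
    dAh <- dlogits %*% t(head$o_W)
    dZh <- dAh * (cache$Zh > 0)
    dWh <- t(cache$s) %*% dZh
    dbh <- colSums(dZh)
    ds <- dZh %*% t(head$h_W)
    list(ds = ds, grads = list(h_W = dWh, h_b = dbh, o_W = dWo, o_b = dbo))
  } else {
    dWo <- t(cache$s) %*% dlogits
    dbo <- colSums(dlogits)
    ds <- dlogits %*% t(head$o_W)
    list(ds = ds, grads = list(o_W = dWo, o_b = dbo))
  }
}

# ---- checkpoints ------------------------------------------------------

#' Save or load a model checkpoint
#'
#' Checkpoints bundle the parameters, the encoder configuration and a
#' format version stamp in a single RDS container.
#'
#' @param params Model parameters (encoder config attached as attribute).
#' @param path Checkpoint file path.
#' @param extra Optional named list stored alongside (e.g. training log).
#' @export
save_checkpoint <- function(params, path, extra = list()) {
  obj <- c(list(version = 1L, package = "sensorclr",
                config = attr(params, "config"),
                params = unclass(params)), extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with `params` (class
#'   `model_params`, config attached) plus any extras stored at save time.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version) || is.null(obj$params)) {
    stop("not a sensorclr checkpoint: ", path)
  }
  params <- structure(obj$params, class = "model_params", config = obj$config)
  obj$params <- params
  obj
}
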