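#' Cosine similarity between two vectors
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 2), c(2, 1)) # 0.8
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

#' Normalized temperature-scaled cross-entropy (NT-Xent) loss
#'
#' Contrastive loss over `2N` projected embeddings arranged as interleaved
#' positive pairs (rows `2k - 1` and `2k` are the two views of sample
#' `k`). For each anchor `i` with positive partner `j`,
#' `l(i, j) = -log( exp(sim(i, j)/tau) / sum_{k != i} exp(sim(i, k)/tau) )`
#' with cosine similarity `sim`; the loss averages `l` over both orderings
#' of every pair. The internal softmax is stabilized by row-max
#' subtraction.
#'
#' @param Z Matrix `(2N x d)` of embeddings, interleaved positive pairs.
#' @param tau Temperature, `> 0`.
#' @param grad Also return the gradient wrt `Z`.
#' @return The scalar loss, or (with `grad = TRUE`) a list `loss`, `dZ`.
#' @export
nt_xent_loss <- function(Z, tau = 0.1, grad = FALSE) {
  if (tau <= 0) stop("temperature must be > 0")
  n2 <- nrow(Z)
  if (n2 < 2L || n2 %% 2L != 0L) stop("need an even number (>= 2) of embeddings")
  norms <- sqrt(rowSums(Z^2))
  if (any(norms == 0)) stop("zero embedding vector")
  U <- Z / norms
  S <- (U %*% t(U)) / tau
  partner <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
  diag(S) <- -Inf              # the k != i indicator: exclude self
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  denom <- rowSums(E)
  P <- E / denom
  pos <- S[cbind(seq_len(n2), partner)]
  loss <- mean(-(pos - m) + log(denom))
  if (!grad) return(loss)
  dS <- P
  dS[cbind(seq_len(n2), partner)] <- dS[cbind(seq_len(n2), partner)] - 1
  dS <- dS / n2
  diag(dS) <- 0
  dU <- ((dS + t(dS)) %*% U) / tau
  # through row normalization u = z / |z|
  dZ <- (dU - U * rowSums(dU * U)) / norms
  list(loss = loss, dZ = dZ)
}

#' Softmax cross-entropy loss
#'
#' @param logits Matrix `(batch x classes)`.
#' @param y Integer class indices (1-based).
#' @param grad Also return the gradient wrt the logits.
#' @return Scalar mean loss, or a list `loss`, `dlogits`.
#' @export
softmax_xent <- function(logits, y, grad = FALSE) {
  B <- nrow(logits)
  P <- .softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(B), y)] + eps))
  if (!grad) return(loss)
  dlogits <- P
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  list(loss = loss, dlogits = dlogits / B)
}

#' Cosine-decay learning-rate schedule
#'
#' Decays from `initial` to `initial * alpha` over `decay_steps` steps
#' along a half cosine, clamped afterwards.
#'
#' @param step Global step, `>= 0`.
#' @param initial Initial learning rate.
#' @param decay_steps Steps over which to decay.
#' @param alpha Floor as a fraction of `initial`.
#' @return The learning rate at `step`.
#' @export
#' @examples
#' cosine_decay_lr(0)    # 0.1
#' cosine_decay_lr(500)  # 0.05
#' cosine_decay_lr(1000) # 0
cosine_decay_lr <- function(step, initial = 0.1, decay_steps = 1000L,
                            alpha = 0) {
  frac <- min(step, decay_steps) / decay_steps
  decayed <- (1 - alpha) * 0.5 * (1 + cos(pi * frac)) + alpha
  initial * decayed
}

# ---- parameter-list arithmetic ---------------------------------------

.p_map2 <- function(f, a, b) {
  out <- a
  for (nm in names(a)) out[[nm]] <- f(a[[nm]], b[[nm]])
  out
}
.p_scale <- function(a, s) {
  out <- a
  for (nm in names(a)) out[[nm]] <- a[[nm]] * s
  out
}
.p_norm <- function(a) {
  sqrt(sum(vapply(a, function(v) sum(v^2), numeric(1))))
}
.p_zeros_like <- function(a) {
  out <- a
  for (nm in names(a)) out[[nm]] <- a[[nm]] * 0
  out
}

#' Construct a base optimizer
#'
#' Plain stochastic gradient descent (optional momentum) or Adam. The
#' returned object holds slot state keyed by parameter name and is updated
#' functionally by [optimizer_step()].
#'
#' @param kind `"sgd"` or `"adam"`.
#' @param lr Learning rate (may be overridden per step by a schedule).
#' @param momentum SGD momentum coefficient.
#' @param beta1,beta2,eps Adam moment coefficients and stabilizer.
#' @return An `optimizer` object.
#' @export
make_optimizer <- function(kind = c("sgd", "adam"), lr = 0.1, momentum = 0,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  kind <- match.arg(kind)
  structure(list(kind = kind, lr = lr, momentum = momentum, beta1 = beta1,
                 beta2 = beta2, eps = eps, state = list(), t = 0L),
            class = "optimizer")
}

#' Apply one optimizer step
#'
#' @param opt An optimizer from [make_optimizer()].
#' @param params Named parameter list.
#' @param grads Named gradient list (same names/shapes).
#' @param lr Learning rate for this step (defaults to the optimizer's).
#' @return List with updated `params` and `opt`.
#' @export
optimizer_step <- function(opt, params, grads, lr = opt$lr) {
  opt$t <- opt$t + 1L
  if (opt$kind == "sgd") {
    if (opt$momentum > 0) {
      if (length(opt$state) == 0L) opt$state <- .p_zeros_like(params)
      opt$state <- .p_map2(function(v, g) opt$momentum * v + g, opt$state, grads)
      params <- .p_map2(function(p, v) p - lr * v, params, opt$state)
    } else {
      params <- .p_map2(function(p, g) p - lr * g, params, grads)
    }
  } else {
    if (length(opt$state) == 0L) {
      opt$state <- list(m = .p_zeros_like(params), v = .p_zeros_like(params))
    }
    opt$state$m <- .p_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g,
                           opt$state$m, grads)
    opt$state$v <- .p_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2,
                           opt$state$v, grads)
    bc1 <- 1 - opt$beta1^opt$t
    bc2 <- 1 - opt$beta2^opt$t
    upd <- .p_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + opt$eps),
                   opt$state$m, opt$state$v)
    params <- .p_map2(function(p, u) p - lr * u, params, upd)
  }
  list(params = params, opt = opt)
}

#' Sharpness-aware minimization configuration
#'
#' @param rho Neighborhood radius of the inner maximization, `>= 0`
#'   (0 disables SAM).
#' @param weight_decay Coefficient of the `lambda * |w|^2` penalty added
#'   to the objective.
#' @return A `sam_config` object.
#' @export
sam_config <- function(rho = 0.05, weight_decay = 0) {
  stopifnot(rho >= 0, weight_decay >= 0)
  structure(list(rho = rho, weight_decay = weight_decay, p_norm = 2),
            class = "sam_config")
}

#' One SAM two-step update
#'
#' Sharpness-aware minimization first climbs to the worst-case loss within
#' an L2 ball of radius `rho` around the current weights — using the
#' first-order solution `epsilon = rho * g / |g|` with `g` the gradient at
#' `w` — then takes the base optimizer step with the gradient evaluated at
#' `w + epsilon`. The `epsilon` is computed from the global 2-norm over
#' all trainable parameters jointly. With `rho = 0` the trajectory is
#' bit-identical to the base optimizer. A zero gradient yields a plain
#' step.
#'
#' @param params Named parameter list.
#' @param grad_fn Function `params -> list(loss=, grads=)`, differentiable
#'   at the current parameters (it is called once, or twice when
#'   `rho > 0`).
#' @param config A [sam_config()].
#' @param opt Base optimizer from [make_optimizer()].
#' @param lr Learning rate for the descent step.
#' @return List with updated `params`, `opt` and the (first) `loss`.
#' @export
sam_update <- function(params, grad_fn, config = sam_config(), opt, lr = opt$lr) {
  g1 <- grad_fn(params)
  grads <- g1$grads
  if (config$rho > 0) {
    gn <- .p_norm(grads)
    if (gn > 0) {
      eps <- .p_scale(grads, config$rho / gn)
      g2 <- grad_fn(.p_map2(`+`, params, eps))
      grads <- g2$grads
    }
  }
  if (config$weight_decay > 0) {
    grads <- .p_map2(function(g, w) g + 2 * config$weight_decay * w,
                     grads, params)
  }
  step <- optimizer_step(opt, params, grads, lr = lr)
  list(params = step$params, opt = step$opt, loss = g1$loss)
}
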