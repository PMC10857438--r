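#' Training configuration for a protocol phase
#'
#' Bundles the hyperparameters of one phase with reference defaults:
#' pre-training runs 100 epochs at batch size 512 under SGD with cosine
#' decay (initial rate 0.1, 1000 decay steps); linear evaluation trains
#' the probe for 300 epochs at batch size 128 under Adam at 0.001;
#' fine-tuning runs 200 epochs at batch size 128 under Adam at 0.001.
#' The contrastive temperature is 0.1 and the default augmentation is
#' scaling with sigma 0.1. SAM can be switched on per phase
#' (`use_sam`), which together with the encoder's `attention` flag spans
#' the four model variants (plain contrastive, +SAM, +attention, both).
#'
#' @param phase `"pretrain"`, `"linear_eval"` or `"fine_tune"`.
#' @param epochs,batch_size Training length and batch size (phase default
#'   when `NULL`).
#' @param optimizer,lr Base optimizer and learning rate (phase default
#'   when `NULL`).
#' @param decay_steps Cosine-decay steps (pre-training only).
#' @param temperature NT-Xent temperature.
#' @param augmentation An [augmentation_spec()].
#' @param use_sam Wrap updates in sharpness-aware minimization.
#' @param sam_rho SAM neighborhood radius.
#' @param weight_decay Coefficient of the global L2 penalty applied in the
#'   update (0 = rely on the per-layer kernel regularizers only).
#' @param label_fraction Fraction of labeled training windows revealed to
#'   supervised phases, in `(0, 1]`.
#' @param head_hidden Hidden width of the fine-tuning MLP head.
#' @param seed Integer seed governing every random draw of the phase.
#' @param verbose Print a line per epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(phase = c("pretrain", "linear_eval", "fine_tune"),
                         epochs = NULL, batch_size = NULL,
                         optimizer = NULL, lr = NULL, decay_steps = 1000L,
                         temperature = 0.1,
                         augmentation = augmentation_spec(),
                         use_sam = TRUE, sam_rho = 0.05, weight_decay = 0,
                         label_fraction = 1, head_hidden = 64L,
                         seed = 1L, verbose = FALSE) {
  phase <- match.arg(phase)
  defaults <- switch(phase,
    pretrain   = list(epochs = 100L, batch_size = 512L, optimizer = "sgd",
                      lr = 0.1),
    linear_eval = list(epochs = 300L, batch_size = 128L, optimizer = "adam",
                       lr = 0.001),
    fine_tune  = list(epochs = 200L, batch_size = 128L, optimizer = "adam",
                      lr = 0.001))
  cfg <- list(phase = phase,
              epochs = as.integer(epochs %||% defaults$epochs),
              batch_size = as.integer(batch_size %||% defaults$batch_size),
              optimizer = optimizer %||% defaults$optimizer,
              lr = lr %||% defaults$lr,
              decay_steps = as.integer(decay_steps),
              temperature = temperature,
              augmentation = augmentation,
              use_sam = isTRUE(use_sam), sam_rho = sam_rho,
              weight_decay = weight_decay,
              label_fraction = label_fraction,
              head_hidden = as.integer(head_hidden),
              seed = as.integer(seed), verbose = isTRUE(verbose))
  stopifnot(cfg$epochs >= 1L, cfg$batch_size >= 2L,
            cfg$label_fraction > 0, cfg$label_fraction <= 1)
  class(cfg) <- "train_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# loss + gradients of one contrastive batch through encoder + projection,
# including the per-layer kernel regularizers
.contrastive_grads <- function(params, enc_cfg, view_i, view_j, tau) {
  B <- dim(view_i)[1]
  fi <- encoder_forward(view_i, params, enc_cfg, training = TRUE,
                        keep_cache = TRUE)
  fj <- encoder_forward(view_j, params, enc_cfg, training = TRUE,
                        keep_cache = TRUE)
  pi <- projection_forward(fi$s, params, keep_cache = TRUE)
  pj <- projection_forward(fj$s, params, keep_cache = TRUE)
  d <- ncol(pi$z)
  Z <- matrix(0, 2L * B, d)
  odd <- seq(1L, 2L * B, 2L)
  Z[odd, ] <- pi$z
  Z[odd + 1L, ] <- pj$z
  nt <- nt_xent_loss(Z, tau, grad = TRUE)
  bi <- projection_backward(nt$dZ[odd, , drop = FALSE], pi$cache, params)
  bj <- projection_backward(nt$dZ[odd + 1L, , drop = FALSE], pj$cache, params)
  gi <- encoder_backward(bi$ds, fi$cache, params, enc_cfg)
  gj <- encoder_backward(bj$ds, fj$cache, params, enc_cfg)
  grads <- .p_map2(`+`, c(gi, bi$grads), c(gj, bj$grads))
  .add_kernel_l2(nt$loss, grads, params, enc_cfg)
}

.add_kernel_l2 <- function(loss, grads, params, enc_cfg) {
  l2 <- enc_cfg$l2_strength
  ar <- enc_cfg$attention_regularizer
  if (l2 > 0) {
    loss <- loss + l2 * (sum(params$c1_W^2) + sum(params$c2_W^2))
    grads$c1_W <- grads$c1_W + 2 * l2 * params$c1_W
    grads$c2_W <- grads$c2_W + 2 * l2 * params$c2_W
  }
  if (!is.null(params$a_W) && ar > 0) {
    loss <- loss + ar * sum(params$a_W^2)
    grads$a_W <- grads$a_W + 2 * ar * params$a_W
  }
  list(loss = loss, grads = grads[names(params)])
}

#' Contrastive pre-training of the encoder
#'
#' Minimizes the NT-Xent loss over augmented view pairs of unlabeled
#' windows, by SGD with cosine decay, optionally wrapped in
#' sharpness-aware minimization. No labels are used.
#'
#' @param dataset A standardized `windowed_dataset` (labels ignored).
#' @param enc_cfg An [encoder_config()] matching the window shape.
#' @param config A [train_config()] with `phase = "pretrain"`.
#' @return A `pretrain_result`: list with `params` (encoder + projection),
#'   `loss_history` (mean loss per epoch), `enc_cfg`, `config`.
#' @export
pretrain <- function(dataset,
                     enc_cfg = encoder_config(input_shape = dim(dataset$data)[2:3]),
                     config = train_config("pretrain")) {
  stopifnot(config$phase == "pretrain")
  n <- dim(dataset$data)[1]
  if (n < 2L) stop("need at least 2 windows to form a contrastive batch")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  params <- init_model_params(enc_cfg, seed = config$seed)
  opt <- make_optimizer(config$optimizer, lr = config$lr)
  samc <- sam_config(rho = if (config$use_sam) config$sam_rho else 0,
                     weight_decay = config$weight_decay)
  gstep <- 0L
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next
      batch <- dataset$data[idx, , , drop = FALSE]
      views <- make_views(batch, config$augmentation)
      lr <- if (config$optimizer == "sgd") {
        cosine_decay_lr(gstep, initial = config$lr,
                        decay_steps = config$decay_steps)
      } else config$lr
      grad_fn <- function(p) .contrastive_grads(p, enc_cfg, views$view_i,
                                                views$view_j,
                                                config$temperature)
      upd <- sam_update(params, grad_fn, samc, opt, lr = lr)
      params <- upd$params; opt <- upd$opt
      losses <- c(losses, upd$loss)
      gstep <- gstep + 1L
    }
    loss_history[epoch] <- mean(losses)
    if (config$verbose) {
      message(sprintf("pretrain epoch %d/%d: loss %.4f", epoch,
                      config$epochs, loss_history[epoch]))
    }
  }
  structure(list(params = params, loss_history = loss_history,
                 enc_cfg = enc_cfg, config = config),
            class = "pretrain_result")
}

#' @export
print.pretrain_result <- function(x, ...) {
  cat(sprintf("<pretrain_result> %s trainable parameters, %d epochs, final loss %.4f\n",
              format(as.integer(count_trainable_parameters(x$params)),
                     big.mark = ","),
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Encode windows with a frozen encoder
#'
#' @param params Encoder parameters.
#' @param enc_cfg The [encoder_config()].
#' @param data Array `(n, timesteps, features)`.
#' @param batch_size Windows encoded per forward pass.
#' @return Matrix `(n x lstm_units)` of embeddings (dropout off).
#' @export
encode_windows <- function(params, enc_cfg, data, batch_size = 512L) {
  n <- dim(data)[1]
  out <- matrix(0, n, enc_cfg$lstm_units)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- encoder_forward(data[idx, , , drop = FALSE], params,
                                  enc_cfg, training = FALSE)$s
  }
  out
}

.as_class_index <- function(labels, classes) {
  y <- match(labels, classes)
  if (anyNA(y)) stop("labels outside the declared class set")
  y
}

#' Linear evaluation of a pre-trained encoder
#'
#' Freezes the encoder, drops the projection head, and trains a single
#' dense softmax classifier (the probe) on embeddings of labeled training
#' windows; representation quality is then read off the held-out test
#' metrics. The encoder is never updated.
#'
#' @param pretrained A `pretrain_result` (or list with `params`,
#'   `enc_cfg`).
#' @param train_ds,test_ds Labeled `windowed_dataset`s (standardized with
#'   the training statistics).
#' @param config A [train_config()] with `phase = "linear_eval"`. Its
#'   `label_fraction` subsamples the labeled training windows.
#' @return List with `report` (an `eval_report`), `head`, `classes` and
#'   `loss_history`.
#' @export
linear_evaluate <- function(pretrained, train_ds, test_ds,
                            config = train_config("linear_eval")) {
  stopifnot(config$phase == "linear_eval")
  .supervised_protocol(pretrained, train_ds, test_ds, config,
                       head_kind = "linear_probe", update_encoder = FALSE)
}

#' Semi-supervised fine-tuning of a pre-trained encoder
#'
#' Unfreezes the encoder, attaches a two-layer MLP head (ReLU hidden
#' layer, softmax output) and trains the whole network with cross-entropy
#' on the revealed label fraction; SAM optional.
#'
#' @inheritParams linear_evaluate
#' @param config A [train_config()] with `phase = "fine_tune"`.
#' @return List with `report`, `params` (updated encoder), `head`,
#'   `classes` and `loss_history`.
#' @export
fine_tune <- function(pretrained, train_ds, test_ds,
                      config = train_config("fine_tune")) {
  stopifnot(config$phase == "fine_tune")
  .supervised_protocol(pretrained, train_ds, test_ds, config,
                       head_kind = "finetune_mlp", update_encoder = TRUE)
}

.supervised_protocol <- function(pretrained, train_ds, test_ds, config,
                                 head_kind, update_encoder) {
  enc_cfg <- pretrained$enc_cfg
  params <- pretrained$params
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  train_ds <- drop_unlabeled_windows(train_ds)
  test_ds <- drop_unlabeled_windows(test_ds)
  if (config$label_fraction < 1) {
    train_ds <- sample_label_fraction(train_ds, config$label_fraction,
                                      seed = config$seed)
  }
  n <- dim(train_ds$data)[1]
  if (n == 0L) stop("no labeled training windows")
  classes <- sort(unique(c(train_ds$labels, test_ds$labels)))
  unseen <- setdiff(unique(test_ds$labels), unique(train_ds$labels))
  if (length(unseen) > 0L) {
    warning(sprintf("class(es) absent from training labels: %s",
                    paste(unseen, collapse = ", ")), call. = FALSE)
  }
  y_train <- .as_class_index(train_ds$labels, classes)

  head <- init_head_params(enc_cfg, length(classes), head_kind,
                           hidden = config$head_hidden, seed = config$seed)
  opt <- make_optimizer(config$optimizer, lr = config$lr)
  samc <- sam_config(rho = if (config$use_sam) config$sam_rho else 0,
                     weight_decay = config$weight_decay)

  emb_train <- NULL
  if (!update_encoder) {
    emb_train <- encode_windows(params, enc_cfg, train_ds$data)
  }
  # the projection head is discarded downstream: fine-tuning updates the
  # encoder proper plus the classifier head only
  enc_names <- grep("^p_", names(params), value = TRUE, invert = TRUE)
  n_enc <- length(enc_names)
  loss_history <- numeric(config$epochs)
  work <- if (update_encoder) c(unclass(params)[enc_names], head) else head
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      yb <- y_train[idx]
      if (update_encoder) {
        xb <- train_ds$data[idx, , , drop = FALSE]
        grad_fn <- function(w) {
          p <- structure(w[seq_len(n_enc)], class = "model_params")
          h <- w[-seq_len(n_enc)]
          fe <- encoder_forward(xb, p, enc_cfg, training = TRUE,
                                keep_cache = TRUE)
          cf <- classifier_forward(fe$s, h, keep_cache = TRUE)
          ce <- softmax_xent(cf$logits, yb, grad = TRUE)
          cb <- classifier_backward(ce$dlogits, cf$cache, h)
          ge <- encoder_backward(cb$ds, fe$cache, p, enc_cfg)
          reg <- .add_kernel_l2(ce$loss, ge, p, enc_cfg)
          list(loss = reg$loss, grads = c(reg$grads, cb$grads)[names(w)])
        }
      } else {
        sb <- emb_train[idx, , drop = FALSE]
        grad_fn <- function(h) {
          cf <- classifier_forward(sb, h, keep_cache = TRUE)
          ce <- softmax_xent(cf$logits, yb, grad = TRUE)
          cb <- classifier_backward(ce$dlogits, cf$cache, h)
          list(loss = ce$loss, grads = cb$grads[names(h)])
        }
      }
      upd <- sam_update(work, grad_fn, samc, opt, lr = config$lr)
      work <- upd$params; opt <- upd$opt
      losses <- c(losses, upd$loss)
    }
    loss_history[epoch] <- mean(losses)
    if (config$verbose) {
      message(sprintf("%s epoch %d/%d: loss %.4f", config$phase, epoch,
                      config$epochs, loss_history[epoch]))
    }
  }

  if (update_encoder) {
    params <- unclass(params)
    params[enc_names] <- work[seq_len(n_enc)]
    params <- structure(params, class = "model_params", config = enc_cfg)
    head <- work[-seq_len(n_enc)]
  } else {
    head <- work
  }
  emb_test <- encode_windows(params, enc_cfg, test_ds$data)
  pred <- classes[max.col(classifier_forward(emb_test, head)$probs,
                          ties.method = "first")]
  report <- compute_metrics(test_ds$labels, pred, classes)
  report$phase <- config$phase
  report$label_fraction <- config$label_fraction
  out <- list(report = report, head = head, classes = classes,
              loss_history = loss_history)
  if (update_encoder) out$params <- params
  out
}

#' Cross-home transfer protocol
#'
#' Pre-trains the encoder on one home's unlabeled windows, then evaluates
#' the downstream tasks — linear probing and fine-tuning — on a different
#' home's labeled windows. Source and target must share the feature
#' dimensionality (the encoder input width). Both downstream runs reuse
#' the single pre-trained checkpoint.
#'
#' @param source_ds Unlabeled `windowed_dataset` of the source home.
#' @param target_train,target_test Labeled `windowed_dataset`s of the
#'   target home.
#' @param pretrain_config,linear_config,finetune_config Phase
#'   [train_config()]s.
#' @param enc_cfg Optional [encoder_config()].
#' @return List with `pretrained`, `linear` and `finetune` results; the
#'   reports carry `transfer = TRUE`.
#' @export
transfer_protocol <- function(source_ds, target_train, target_test,
                              pretrain_config = train_config("pretrain"),
                              linear_config = train_config("linear_eval"),
                              finetune_config = train_config("fine_tune"),
                              enc_cfg = NULL) {
  ds_f <- dim(source_ds$data)[3]
  tg_f <- dim(target_train$data)[3]
  if (ds_f != tg_f) {
    stop(sprintf("feature dimension mismatch: source has %d, target has %d",
                 ds_f, tg_f))
  }
  if (is.null(enc_cfg)) {
    enc_cfg <- encoder_config(input_shape = dim(source_ds$data)[2:3])
  }
  pre <- pretrain(source_ds, enc_cfg, pretrain_config)
  lin <- linear_evaluate(pre, target_train, target_test, linear_config)
  fit <- fine_tune(pre, target_train, target_test, finetune_config)
  lin$report$transfer <- TRUE
  fit$report$transfer <- TRUE
  list(pretrained = pre, linear = lin, finetune = fit)
}

#' Classification metrics for a protocol run
#'
#' Accuracy plus precision, recall and F1 per class and as
#' support-weighted averages, all on the percent scale, with the full
#' confusion matrix.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class universe (defaults to the labels present).
#' @return An `eval_report`: list with `accuracy`, `precision`, `recall`,
#'   `f1` (weighted averages, %), `per_class` data frame, `confusion`
#'   matrix, `n`.
#' @export
#' @examples
#' compute_metrics(c("a", "b", "a"), c("a", "b", "b"))$accuracy
compute_metrics <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must be non-empty and of equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  tf <- factor(y_true, levels = classes)
  pf <- factor(y_pred, levels = classes)
  cm <- table(true = tf, predicted = pf)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / sum(support)
  report <- list(
    accuracy = 100 * sum(tp) / sum(cm),
    precision = 100 * sum(w * prec),
    recall = 100 * sum(w * rec),
    f1 = 100 * sum(w * f1),
    per_class = data.frame(class = classes, support = as.integer(support),
                           precision = 100 * as.numeric(prec),
                           recall = 100 * as.numeric(rec),
                           f1 = 100 * as.numeric(f1),
                           stringsAsFactors = FALSE),
    confusion = cm,
    n = length(y_true)
  )
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  tag <- if (!is.null(x$phase)) paste0(" [", x$phase,
    if (isTRUE(x$transfer)) ", transfer" else "",
    if (!is.null(x$label_fraction) && x$label_fraction < 1)
      sprintf(", %g%% labels", 100 * x$label_fraction) else "", "]") else ""
  cat(sprintf("<eval_report>%s n=%d\n", tag, x$n))
  cat(sprintf("  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%% (weighted)\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Majority-class baseline report
#'
#' Predicts the most frequent training label for every test window; the
#' floor any trained model must beat.
#'
#' @param train_labels Labels whose mode defines the prediction.
#' @param test_labels Held-out labels to score against.
#' @return An `eval_report`.
#' @export
majority_baseline <- function(train_labels, test_labels) {
  train_labels <- train_labels[!is.na(train_labels)]
  test_labels <- test_labels[!is.na(test_labels)]
  maj <- names(which.max(table(train_labels)))
  compute_metrics(test_labels, rep(maj, length(test_labels)),
                  sort(unique(c(train_labels, test_labels))))
}
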