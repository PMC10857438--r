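# Reduced-scale protocol experiment shared by the acceptance tests.
# Study conditions: the day-3 simulated home (disjoint room affinities),
# 20 pre-training epochs at batch 128 with the cosine decay horizon set to
# the actual step count, 100-epoch probes, 30-epoch fine-tuning. The probe
# quality comparison runs at a 10% label fraction (the low-annotation
# regime the protocols target); fine-tune vs probe is paired at 50%.

protocol_seeds <- 1:5
protocol_fractions <- c(0.01, 0.05, 0.1, 0.2, 0.3)

.protocol_cache <- new.env(parent = emptyenv())

protocol_splits <- function() {
  synth_dataset(days = 3, seed = 11L)$splits
}

protocol_pretrained <- function(seed) {
  key <- paste0("pre_", seed)
  if (is.null(.protocol_cache[[key]])) {
    sp <- protocol_splits()
    enc <- encoder_config(input_shape = dim(sp$train$data)[2:3])
    .protocol_cache[[key]] <- pretrain(
      sp$train, enc,
      train_config("pretrain", epochs = 20, batch_size = 128,
                   decay_steps = 80, seed = seed))
  }
  .protocol_cache[[key]]
}

protocol_probe <- function(pre, seed, fraction = 1) {
  sp <- protocol_splits()
  suppressWarnings(linear_evaluate(
    pre, sp$train, sp$test,
    train_config("linear_eval", epochs = 100, seed = seed,
                 label_fraction = fraction)))$report$f1
}

protocol_finetune <- function(pre, seed, fraction) {
  sp <- protocol_splits()
  suppressWarnings(fine_tune(
    pre, sp$train, sp$test,
    train_config("fine_tune", epochs = 30, seed = seed,
                 label_fraction = fraction)))$report$f1
}

# second synthetic home for the transfer protocol: same floor plan (same
# feature dimensionality) but a shifted daily schedule and firing rates
transfer_home_config <- function() {
  base <- synthetic_home_config()
  acts <- base$activities
  acts$tod_peak <- (acts$tod_peak + 6) %% 24
  acts$rate <- acts$rate * c(0.8, 1.3, 1.1, 0.7, 1.2)
  synthetic_home_config(activities = acts)
}
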