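# Shared fixtures, built in code; cached per test process.

# the seven-row annotated meal-preparation snippet used across I/O tests
table1_lines <- c(
  "2010-11-04 08:33:52.929406 M018 ON Meal_Preparation begin",
  "2010-11-04 08:33:53.911115 M019 OFF",
  "2010-11-04 08:33:54.892943 M017 ON",
  "2010-11-04 08:33:57.253739 M018 OFF",
  "2010-11-04 08:35:43.498813 M019 OFF",
  "2010-11-04 08:35:44.246428 M019 ON",
  "2010-11-04 08:35:45.822482 M018 OFF Meal_Preparation end"
)

# small sensor map for hand-built feature tests
tiny_map <- function(n_motion = 3L, rooms = c("Kitchen", "Bedroom")) {
  data.frame(
    sensor_id = sprintf("M%03d", seq_len(n_motion)),
    location = rep(rooms, length.out = n_motion),
    modality = "motion",
    stringsAsFactors = FALSE
  )
}

# hand-built event table: one event per row at the given epoch seconds
events_at <- function(t, sensor, state = "ON", label = NULL) {
  day <- floor(t / 86400)
  secday <- t - day * 86400
  h <- floor(secday / 3600); mi <- floor((secday - h * 3600) / 60)
  s <- secday - h * 3600 - mi * 60
  ev <- data.frame(
    date = format(as.Date(day, origin = "1970-01-01"), "%Y-%m-%d"),
    time = sprintf("%02d:%02d:%09.6f", h, mi, s),
    sensor_id = sensor, state = state,
    activity = NA_character_, marker = NA_character_, t = t,
    stringsAsFactors = FALSE
  )
  if (!is.null(label)) ev$label <- label
  ev
}

# simulated-home dataset shared by the protocol tests; cached by key
.synth_cache <- new.env(parent = emptyenv())
synth_dataset <- function(days = 2, seed = 11L, config = synthetic_home_config()) {
  key <- paste(days, seed, digest_cfg(config), sep = "_")
  if (is.null(.synth_cache[[key]])) {
    map <- generate_home(config)
    ev <- suppressWarnings(
      propagate_activity_labels(clean_events(
        simulate_events(map, config, days = days, seed = seed))))
    fv <- suppressMessages(featurize(ev, map))
    ds <- make_sliding_windows(fv$features, fv$labels)
    sp <- split_dataset(ds, c(0.7, 0.15, 0.15), seed = 1L)
    stats <- suppressWarnings(feature_stats(sp$train))
    sp <- lapply(sp, standardize, stats = stats)
    .synth_cache[[key]] <- list(map = map, events = ev, vectors = fv,
                                windows = ds, splits = sp)
  }
  .synth_cache[[key]]
}
digest_cfg <- function(config) {
  paste0(nrow(config$activities), "-", config$noise_prob, "-",
         config$label_noise)
}

# small encoder configuration for gradient and oracle tests
tiny_encoder <- function(T = 4L, F = 5L, attention = TRUE) {
  encoder_config(input_shape = c(T, F), conv_filters = c(3L, 4L),
                 lstm_units = 6L, proj_dims = c(7L, 6L, 5L),
                 conv_dropout = 0, l2_strength = 1e-3,
                 attention_regularizer = 1e-3, attention = attention)
}

# central finite difference of fn at params[[nm]][j]
num_grad <- function(fn, params, nm, j, eps = 1e-6) {
  up <- params; up[[nm]][j] <- up[[nm]][j] + eps
  dn <- params; dn[[nm]][j] <- dn[[nm]][j] - eps
  (fn(up) - fn(dn)) / (2 * eps)
}
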