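#' Length of the summary feature vector for a sensor map
#'
#' The windowed feature layout holds 14 window-level features plus, for
#' each non-temperature sensor, an event count and a recency value, giving
#' `2 * S + 14` features for `S` sensors.
#'
#' @param sensor_map A sensor map data frame, or an integer sensor count.
#' @return Integer feature-vector length.
#' @export
#' @examples
#' feature_dim(35) # 84
#' feature_dim(33) # 80
feature_dim <- function(sensor_map) {
  s <- if (is.data.frame(sensor_map)) nrow(sensor_map) else as.integer(sensor_map)
  2L * s + 14L
}

#' Summarize an event stream into fixed-length feature vectors
#'
#' Partitions a cleaned, time-sorted event stream into consecutive
#' non-overlapping blocks of `event_window_len` events and computes one
#' summary vector per block:
#'
#' 1. hour of the last event; 2. seconds-of-day of the last event; 3. day
#' of week of the last event (0 = Sunday); 4. block duration in seconds;
#' 5. gap between the last two events; 6. dominant (most frequent) sensor
#' index of the previous block; 7. dominant sensor two blocks back; 8. last
#' sensor index; 9. last sensor's location index; 10. last motion sensor's
#' location index; 11. entropy (natural log) of the block's sensor-count
#' distribution; 12. change in event rate (events/s) between the second
#' and first half of the block; 13. number of location transitions between
#' consecutive events; 14. number of distinct sensors; then per-sensor
#' event counts and per-sensor time (s) since last firing, in sensor-map
#' order. Sensors never yet fired get a recency sentinel capped at the
#' dataset time span. Sensor and location indices are 1-based positions in
#' the sensor map (0 = undefined, e.g. no previous block).
#'
#' A trailing partial block is dropped. Blocks may span activity episodes;
#' each block's label is the majority propagated label ([window_label()]).
#'
#' @param events Cleaned event table, optionally with a `label` column from
#'   [propagate_activity_labels()].
#' @param sensor_map Sensor map covering every sensor id in `events`.
#' @param event_window_len Events per block (default 30).
#' @return List with `features` (numeric matrix, one row per block, columns
#'   named) and `labels` (character, `NA` where a block has no labeled
#'   event).
#' @export
featurize <- function(events, sensor_map, event_window_len = 30L) {
  stopifnot(event_window_len >= 2L)
  s_ids <- sensor_map$sensor_id
  S <- length(s_ids)
  sensor_idx <- match(events$sensor_id, s_ids)
  if (anyNA(sensor_idx)) {
    stop(sprintf("sensor(s) not in sensor map: %s",
                 paste(unique(events$sensor_id[is.na(sensor_idx)]), collapse = ", ")))
  }
  locs <- unique(sensor_map$location)
  loc_of_sensor <- match(sensor_map$location, locs)
  is_motion <- sensor_map$modality == "motion"

  n <- nrow(events)
  n_blocks <- n %/% event_window_len
  if (n_blocks * event_window_len < n) {
    message(sprintf("featurize: dropping trailing partial block of %d events",
                    n - n_blocks * event_window_len))
  }
  F <- feature_dim(S)
  feat <- matrix(0, n_blocks, F)
  labels <- rep(NA_character_, n_blocks)
  if (n_blocks == 0L) {
    colnames(feat) <- .feature_names(s_ids)
    return(list(features = feat, labels = labels))
  }

  t <- events$t
  span <- max(t) - min(t)
  last_fired <- rep(NA_real_, S)   # running last-firing time per sensor
  dominant_prev <- 0
  dominant_prev2 <- 0
  half <- event_window_len %/% 2L

  has_label <- !is.null(events$label)
  for (b in seq_len(n_blocks)) {
    i0 <- (b - 1L) * event_window_len + 1L
    i1 <- b * event_window_len
    idx <- i0:i1
    si <- sensor_idx[idx]
    tb <- t[idx]

    counts <- tabulate(si, nbins = S)
    p <- counts[counts > 0] / event_window_len
    entropy <- -sum(p * log(p))
    dominant <- which.max(counts)

    ev_loc <- loc_of_sensor[si]
    transitions <- sum(ev_loc[-1] != ev_loc[-length(ev_loc)])

    dur1 <- max(tb[half] - tb[1L], 1e-3)
    dur2 <- max(tb[event_window_len] - tb[half + 1L], 1e-3)
    rate_change <- half / dur2 - half / dur1

    motion_pos <- which(is_motion[si])
    last_motion_loc <- if (length(motion_pos) > 0L) {
      loc_of_sensor[si[motion_pos[length(motion_pos)]]]
    } else 0

    # recency relative to block end; never-fired sensors get the capped sentinel
    before <- last_fired
    for (j in idx) before[sensor_idx[j]] <- t[j]
    recency <- tb[event_window_len] - before
    recency[is.na(before)] <- span
    recency <- pmin(recency, span)
    last_fired <- before

    lt <- as.POSIXlt(tb[event_window_len], origin = "1970-01-01", tz = "UTC")
    secday <- tb[event_window_len] - floor(tb[event_window_len] / 86400) * 86400

    feat[b, ] <- c(
      lt$hour,
      secday,
      lt$wday,
      tb[event_window_len] - tb[1L],
      tb[event_window_len] - tb[event_window_len - 1L],
      dominant_prev,
      dominant_prev2,
      si[event_window_len],
      ev_loc[event_window_len],
      last_motion_loc,
      entropy,
      rate_change,
      transitions,
      sum(counts > 0L),
      counts,
      recency
    )
    dominant_prev2 <- dominant_prev
    dominant_prev <- dominant
    if (has_label) labels[b] <- window_label(events$label[idx])
  }
  colnames(feat) <- .feature_names(s_ids)
  list(features = feat, labels = labels)
}

.feature_names <- function(s_ids) {
  c("hour", "seconds_of_day", "day_of_week", "duration", "gap_last",
    "dominant_prev", "dominant_prev2", "last_sensor", "last_location",
    "last_motion_location", "entropy", "rate_change", "transitions",
    "distinct_sensors",
    paste0("count_", s_ids), paste0("since_", s_ids))
}

#' Majority label of a block of events
#'
#' The block label is the most frequent non-missing propagated label; ties
#' are broken in favor of the label occurring latest in the block. A block
#' with no labeled event gets `NA`.
#'
#' @param labels Character vector of per-event labels (`NA` = unlabeled).
#' @return A single label or `NA`.
#' @export
window_label <- function(labels) {
  lab <- labels[!is.na(labels)]
  if (length(lab) == 0L) return(NA_character_)
  counts <- table(lab)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  # tie: latest-occurring tied label wins (the label of the last event
  # among the tied candidates)
  for (l in rev(lab)) if (l %in% top) return(l)
  top[1L]
}

#' Number of sliding windows over a sequence
#'
#' @param n Number of feature vectors.
#' @param size Window length in vectors.
#' @param step Stride between window starts.
#' @return `floor((n - size)/step) + 1` for `n >= size`, else 0.
#' @export
#' @examples
#' count_sliding_windows(731106, 10, 5) # 146220
count_sliding_windows <- function(n, size, step) {
  if (n < size) return(0L)
  as.integer((n - size) %/% step + 1L)
}

#' Slice feature vectors into overlapping windows
#'
#' Produces the 3-D model input: consecutive slices of `size` feature
#' vectors at stride `round(size * (1 - overlap))`. Each window inherits
#' the label of its last feature vector.
#'
#' @param features Numeric matrix of feature vectors (rows in time order).
#' @param labels Optional per-vector labels.
#' @param size Window length in vectors (default 10).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5, i.e. stride 5).
#' @return A `windowed_dataset`: list with `data` (array `n_windows x size
#'   x n_features`), `labels`, `size`, `step`.
#' @export
make_sliding_windows <- function(features, labels = NULL, size = 10L,
                                 overlap = 0.5) {
  stopifnot(overlap >= 0, overlap < 1)
  step <- max(1L, as.integer(round(size * (1 - overlap))))
  n <- nrow(features)
  nw <- count_sliding_windows(n, size, step)
  if (nw == 0L) {
    warning(sprintf("fewer vectors (%d) than window size (%d): empty dataset",
                    n, size), call. = FALSE)
  }
  data <- array(0, dim = c(nw, size, ncol(features)))
  wlab <- rep(NA_character_, nw)
  starts <- if (nw > 0L) seq.int(1L, by = step, length.out = nw) else integer(0)
  for (i in seq_len(nw)) {
    rows <- starts[i]:(starts[i] + size - 1L)
    data[i, , ] <- features[rows, , drop = FALSE]
    if (!is.null(labels)) wlab[i] <- labels[rows[size]]
  }
  structure(list(data = data, labels = wlab, size = size, step = step),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<windowed_dataset> %d windows x %d timesteps x %d features\n",
              d[1], d[2], d[3]))
  nl <- sum(!is.na(x$labels))
  cat(sprintf("  labeled windows: %d/%d (%d classes)\n", nl, d[1],
              length(unique(stats::na.omit(x$labels)))))
  invisible(x)
}

#' Per-feature standardization statistics
#'
#' Computes population mean and standard deviation per feature channel,
#' pooling windows and timesteps. Fit these on the training split only and
#' reuse them for validation/test to avoid information leakage.
#'
#' @param dataset A `windowed_dataset`.
#' @param sd_floor Lower bound for the standard deviation (constant
#'   channels would otherwise divide by zero).
#' @return List with `mean` and `sd` vectors (length = n features).
#' @export
feature_stats <- function(dataset, sd_floor = 1e-8) {
  d <- dim(dataset$data)
  m <- matrix(dataset$data, d[1] * d[2], d[3])
  mu <- colMeans(m)
  sd <- sqrt(colMeans(m^2) - mu^2)
  if (any(sd < sd_floor)) {
    warning(sprintf("%d constant feature channel(s); sd floored",
                    sum(sd < sd_floor)), call. = FALSE)
  }
  list(mean = mu, sd = pmax(sd, sd_floor))
}

#' Standardize a windowed dataset to zero mean and unit variance
#'
#' @param dataset A `windowed_dataset`.
#' @param stats Reference statistics from [feature_stats()] (computed on
#'   the training split). Defaults to the dataset's own statistics.
#' @return The dataset with each feature channel transformed by
#'   `(x - mean)/sd`.
#' @export
standardize <- function(dataset, stats = feature_stats(dataset)) {
  d <- dim(dataset$data)
  m <- matrix(dataset$data, d[1] * d[2], d[3])
  m <- sweep(m, 2L, stats$mean, "-")
  m <- sweep(m, 2L, stats$sd, "/")
  dataset$data <- array(m, dim = d)
  dataset$standardized <- TRUE
  dataset
}

#' Split a windowed dataset into train / validation / test
#'
#' Windows are assigned uniformly at random, reproducibly under `seed`;
#' the three parts are disjoint and exhaustive.
#'
#' @param dataset A `windowed_dataset`.
#' @param proportions Numeric length-3 vector summing to 1.
#' @param seed Integer seed.
#' @return List of `windowed_dataset`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(dataset, proportions = c(0.7, 0.15, 0.15),
                          seed = 1L) {
  stopifnot(length(proportions) == 3L,
            abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0))
  n <- dim(dataset$data)[1]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(proportions[1] * n)
  n_val <- floor(proportions[2] * n)
  idx <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[setdiff(seq_len(n), seq_len(n_train + n_val))])
  lapply(idx, function(i) subset_windows(dataset, sort(i)))
}

#' Subset a windowed dataset by window index
#'
#' @param dataset A `windowed_dataset`.
#' @param idx Integer window indices.
#' @return The subsetted `windowed_dataset`.
#' @export
subset_windows <- function(dataset, idx) {
  out <- dataset
  out$data <- dataset$data[idx, , , drop = FALSE]
  out$labels <- dataset$labels[idx]
  out
}

#' Draw a labeled fraction of a training set
#'
#' For semi-supervised runs: keeps `floor(fraction * n)` (at least one)
#' labeled windows, sampled uniformly without replacement among windows
#' that carry a label.
#'
#' @param dataset A `windowed_dataset`.
#' @param fraction Label fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `windowed_dataset` of the sampled labeled windows.
#' @export
sample_label_fraction <- function(dataset, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  labeled <- which(!is.na(dataset$labels))
  k <- max(1L, floor(fraction * length(labeled)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  keep <- sort(sample(labeled, k))
  sub <- subset_windows(dataset, keep)
  present <- unique(sub$labels)
  missing <- setdiff(unique(stats::na.omit(dataset$labels)), present)
  if (length(missing) > 0L) {
    warning(sprintf("label fraction %.3f yields no samples for class(es): %s",
                    fraction, paste(missing, collapse = ", ")), call. = FALSE)
  }
  sub
}

#' Drop windows that carry no activity label
#'
#' Aruba-style semantics: unlabeled stretches are excluded from supervised
#' stages (for Milan-style semantics map them to `"Other"` instead, via
#' [remap_milan_activities()] before featurization).
#'
#' @param dataset A `windowed_dataset`.
#' @return The dataset restricted to labeled windows.
#' @export
drop_unlabeled_windows <- function(dataset) {
  subset_windows(dataset, which(!is.na(dataset$labels)))
}

# Preserve the caller's RNG state around internally seeded draws.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
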