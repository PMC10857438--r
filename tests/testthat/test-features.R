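test_that("feature-vector length is 2*S + 14 for any sensor count", {
  expect_equal(feature_dim(35), 84L)
  expect_equal(feature_dim(33), 80L)
  for (S in c(1L, 2L, 7L, 19L, 50L)) {
    expect_equal(feature_dim(S), 2L * S + 14L)
    map <- data.frame(sensor_id = sprintf("M%03d", seq_len(S)),
                      location = "Room", modality = "motion",
                      stringsAsFactors = FALSE)
    ev <- do.call(rbind, lapply(seq_len(30L), function(i)
      events_at(1e6 + i, map$sensor_id[1 + (i - 1) %% S])))
    fv <- featurize(ev, map)
    expect_equal(ncol(fv$features), 2L * S + 14L)
  }
})

test_that("a single-sensor block is degenerate: zero entropy, one distinct sensor", {
  map <- tiny_map(3)
  ev <- do.call(rbind, lapply(1:30, function(i) events_at(2000 + i * 2, "M002")))
  fv <- featurize(ev, map)
  f <- fv$features[1, ]
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["distinct_sensors"]), 1)
  expect_equal(unname(f["count_M002"]), 30)
  expect_equal(unname(f["count_M001"]), 0)
  expect_equal(unname(f["last_sensor"]), 2)
  expect_equal(unname(f["transitions"]), 0)
})

test_that("block entropy matches the brute-force -sum(p log p) for uniform spreads", {
  for (k in c(2L, 3L, 5L, 6L)) {
    map <- tiny_map(k)
    sensors <- rep(map$sensor_id, length.out = 30L)
    ev <- do.call(rbind, lapply(1:30, function(i) events_at(3000 + i, sensors[i])))
    fv <- featurize(ev, map)
    counts <- table(sensors)
    p <- counts / 30
    expect_equal(unname(fv$features[1, "entropy"]), -sum(p * log(p)),
                 tolerance = 1e-12)
    if (30L %% k == 0L) {
      expect_equal(unname(fv$features[1, "entropy"]), log(k), tolerance = 1e-12)
    }
  }
})

test_that("per-sensor counts always sum to the event-window length", {
  fx <- synth_dataset()
  counts <- fx$vectors$features[, grep("^count_", colnames(fx$vectors$features))]
  expect_true(all(rowSums(counts) == 30))
  expect_true(all(counts == floor(counts) & counts >= 0))
})

test_that("calendar and timing features describe the block's last event", {
  map <- tiny_map(2)
  # 30 events, one per minute, ending 2010-11-04 (a Thursday) 08:30:00
  t_end <- as.numeric(as.Date("2010-11-04")) * 86400 + 8.5 * 3600
  ev <- do.call(rbind, lapply(1:30, function(i)
    events_at(t_end - (30 - i) * 60, c("M001", "M002")[1 + i %% 2])))
  f <- featurize(ev, map)$features[1, ]
  expect_equal(unname(f["hour"]), 8)
  expect_equal(unname(f["seconds_of_day"]), 8.5 * 3600)
  expect_equal(unname(f["day_of_week"]), 4)       # POSIX wday, Sunday = 0
  expect_equal(unname(f["duration"]), 29 * 60)
  expect_equal(unname(f["gap_last"]), 60)
  expect_equal(unname(f["transitions"]), 29)      # strict alternation
  expect_equal(unname(f["distinct_sensors"]), 2)
})

test_that("dominant-sensor features lag by one and two blocks", {
  map <- tiny_map(3)
  blocks <- c(rep("M001", 30), rep("M003", 30), rep("M002", 30))
  ev <- do.call(rbind, lapply(seq_along(blocks), function(i)
    events_at(5000 + i, blocks[i])))
  fv <- featurize(ev, map)
  expect_equal(unname(fv$features[, "dominant_prev"]), c(0, 1, 3))
  expect_equal(unname(fv$features[, "dominant_prev2"]), c(0, 0, 1))
})

test_that("per-sensor recency tracks firings across blocks with a capped sentinel", {
  map <- tiny_map(2)
  ev <- rbind(
    do.call(rbind, lapply(1:30, function(i) events_at(1000 + i, "M001"))),
    do.call(rbind, lapply(1:30, function(i) events_at(2000 + i, "M002")))
  )
  fv <- featurize(ev, map)
  span <- 2030 - 1001
  # block 1: M002 never fired -> sentinel = span
  expect_equal(unname(fv$features[1, "since_M001"]), 0)
  expect_equal(unname(fv$features[1, "since_M002"]), span)
  # block 2: M001 last fired at 1030, block ends at 2030
  expect_equal(unname(fv$features[2, "since_M001"]), 1000)
  expect_equal(unname(fv$features[2, "since_M002"]), 0)
})

test_that("unknown sensors are reported by name and partial blocks dropped", {
  map <- tiny_map(2)
  ev <- do.call(rbind, lapply(1:30, function(i) events_at(1000 + i, "M009")))
  expect_error(featurize(ev, map), "M009")
  short <- do.call(rbind, lapply(1:35, function(i) events_at(1000 + i, "M001")))
  expect_message(fv <- featurize(short, map), "partial block")
  expect_equal(nrow(fv$features), 1L)
})

test_that("block labels take the majority, break ties by the latest event", {
  expect_equal(window_label(rep("Relax", 30)), "Relax")
  expect_equal(window_label(c(rep("Relax", 16), rep("Eating", 14))), "Relax")
  expect_equal(window_label(c(rep("Relax", 15), rep("Eating", 15))), "Eating")
  expect_equal(window_label(c(rep("Eating", 15), rep("Relax", 15))), "Relax")
  expect_true(is.na(window_label(rep(NA_character_, 30))))
  expect_equal(window_label(c(NA, "Work", NA)), "Work")
})

test_that("sliding-window counts match brute-force enumeration of start offsets", {
  expect_equal(count_sliding_windows(731106, 10, 5), 146220L)
  expect_equal(count_sliding_windows(10, 10, 5), 1L)
  expect_equal(count_sliding_windows(15, 10, 5), 2L)
  expect_equal(count_sliding_windows(14, 10, 5), 1L)
  expect_equal(count_sliding_windows(9, 10, 5), 0L)
  for (n in c(1, 5, 10, 23, 57)) {
    for (size in c(2, 5, 10)) {
      for (step in c(1, 3, 5)) {
        brute <- sum(vapply(seq_len(max(n, 1)), function(s)
          s + size - 1 <= n, logical(1)) &
            ((seq_len(max(n, 1)) - 1) %% step == 0))
        expect_equal(count_sliding_windows(n, size, step), brute,
                     info = sprintf("n=%d size=%d step=%d", n, size, step))
      }
    }
  }
})

test_that("windows slice consecutive vectors and inherit the last vector's label", {
  feats <- matrix(seq_len(15 * 2), 15, 2)
  labs <- letters[1:15]
  ds <- make_sliding_windows(feats, labs, size = 10, overlap = 0.5)
  expect_equal(dim(ds$data), c(2, 10, 2))
  expect_equal(ds$data[1, , 1], 1:10)
  expect_equal(ds$data[2, , 1], 6:15)
  expect_equal(ds$labels, c("j", "o"))
  expect_equal(ds$step, 5L)
  expect_warning(empty <- make_sliding_windows(feats[1:4, ], size = 10),
                 "empty")
  expect_equal(dim(empty$data)[1], 0L)
})

test_that("standardization hits closed-form z-scores and is idempotent", {
  feats <- matrix(c(1, 2, 3), 3, 1)
  ds <- make_sliding_windows(feats, size = 1, overlap = 0)
  st <- feature_stats(ds)
  z <- standardize(ds, st)
  expect_equal(as.numeric(z$data), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)                    # population sd
  st2 <- feature_stats(z)
  expect_equal(st2$mean, 0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(st2$sd, 1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(standardize(z, st2)$data, z$data, tolerance = 1e-12)
  # constant channel: floored sd maps to all zeros
  cst <- make_sliding_windows(matrix(5, 4, 1), size = 2, overlap = 0)
  expect_warning(stc <- feature_stats(cst), "constant")
  expect_true(all(standardize(cst, stc)$data == 0))
})

test_that("val and test reuse training statistics", {
  fx <- synth_dataset()
  st <- feature_stats(fx$splits$train)
  expect_equal(unname(st$mean), rep(0, length(st$mean)), tolerance = 1e-8)
  expect_equal(unname(st$sd[st$sd > 1e-6]),
               rep(1, sum(st$sd > 1e-6)), tolerance = 1e-6)
  # test split standardized with train stats need not be centered
  mt <- feature_stats(fx$splits$test)
  expect_false(isTRUE(all.equal(unname(mt$mean), rep(0, length(mt$mean)),
                                tolerance = 1e-8)))
})

test_that("splits are disjoint, exhaustive and reproducible", {
  feats <- matrix(rnorm(200), 100, 2)
  ds <- make_sliding_windows(feats, size = 2, overlap = 0)
  a <- split_dataset(ds, c(0.6, 0.2, 0.2), seed = 7)
  b <- split_dataset(ds, c(0.6, 0.2, 0.2), seed = 7)
  expect_equal(a$train$data, b$train$data)
  n <- vapply(a, function(s) dim(s$data)[1], numeric(1))
  expect_equal(sum(n), 50)
  all_rows <- c(a$train$data[, 1, 1], a$val$data[, 1, 1], a$test$data[, 1, 1])
  expect_equal(sort(all_rows), sort(ds$data[, 1, 1]))
  onto_train <- split_dataset(ds, c(1, 0, 0), seed = 1)
  expect_equal(dim(onto_train$train$data)[1], 50)
})

test_that("label-fraction subsampling draws the floored count, at least one", {
  labs <- rep(c("a", "b"), 50)
  ds <- make_sliding_windows(matrix(rnorm(400), 100, 4), labs,
                             size = 1, overlap = 0)
  sub <- sample_label_fraction(ds, 0.1, seed = 3)
  expect_equal(dim(sub$data)[1], 10L)
  expect_equal(floor(0.01 * 146220), 1462L)  # the large-scale arithmetic
  one <- suppressWarnings(sample_label_fraction(ds, 0.001, seed = 3))
  expect_equal(dim(one$data)[1], 1L)
  expect_warning(sample_label_fraction(ds, 0.01, seed = 3), "class")
  s1 <- sample_label_fraction(ds, 0.2, seed = 9)
  s2 <- sample_label_fraction(ds, 0.2, seed = 9)
  expect_equal(s1$data, s2$data)
})
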