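#' Configuration for a synthetic smart home
#'
#' Describes the simulated home and resident: rooms with motion-sensor
#' counts (plus door sensors at entrances), and an activity repertoire in
#' which each activity has a log-normal episode duration, an exponential
#' inter-event gap rate, a set of affine rooms whose motion sensors fire
#' during the activity, and a Gaussian time-of-day preference. Episodes
#' are generated by a semi-Markov process: an activity is drawn from the
#' time-of-day prior combined with a transition weight from the previous
#' activity, a duration is drawn, sensor firings (ON followed by OFF) are
#' emitted at the activity's rate, and begin/end annotations are written
#' on the first and last event of the episode. Idle periods between
#' episodes emit sparse unlabeled firings from random sensors.
#'
#' The defaults describe five activities with disjoint room affinities and
#' clearly different firing rates — deliberately well-separated activity
#' signatures that a supervised model should classify near-perfectly.
#'
#' @param rooms Named integer vector: motion sensors per room.
#' @param door_rooms Rooms that get one door sensor each.
#' @param activities Data frame with columns `name`, `room` (affine room),
#'   `rate` (events/s), `median_minutes`, `sdlog` (duration spread),
#'   `tod_peak` (hour), `tod_sd` (hours).
#' @param transition Activity transition weight matrix (rows = from,
#'   columns = to); default uniform.
#' @param idle_rate Firing rate (events/s) of unlabeled idle periods.
#' @param idle_median_minutes Median idle gap between episodes.
#' @param noise_prob Probability that a firing comes from a random sensor
#'   instead of the activity's affine room set.
#' @param label_noise Fraction of episodes whose begin/end annotation is
#'   omitted.
#' @return A `synthetic_home_config` object.
#' @export
synthetic_home_config <- function(
    rooms = c(Kitchen = 4L, `Living room` = 4L, Bedroom = 4L,
              Bathroom = 2L, Office = 3L),
    door_rooms = c("Front door", "Back door"),
    activities = data.frame(
      name = c("Meal_Preparation", "Relax", "Sleeping", "Bathing", "Work"),
      room = c("Kitchen", "Living room", "Bedroom", "Bathroom", "Office"),
      rate = c(0.5, 0.15, 0.08, 0.4, 0.25),
      median_minutes = c(8, 15, 30, 6, 20),
      sdlog = c(0.3, 0.3, 0.3, 0.3, 0.3),
      tod_peak = c(12, 20, 1, 7, 14),
      tod_sd = c(5, 4, 4, 3, 3),
      stringsAsFactors = FALSE),
    transition = NULL,
    idle_rate = 0.02,
    idle_median_minutes = 3,
    noise_prob = 0.02,
    label_noise = 0) {
  stopifnot(length(rooms) >= 1L, sum(rooms) >= 1L, nrow(activities) >= 1L,
            all(activities$rate > 0), all(activities$median_minutes > 0),
            all(activities$room %in% names(rooms)),
            label_noise >= 0, label_noise <= 1, noise_prob >= 0,
            noise_prob <= 1)
  k <- nrow(activities)
  if (is.null(transition)) {
    transition <- matrix(1 / k, k, k,
                         dimnames = list(activities$name, activities$name))
  }
  structure(list(rooms = rooms, door_rooms = door_rooms,
                 activities = activities, transition = transition,
                 idle_rate = idle_rate,
                 idle_median_minutes = idle_median_minutes,
                 noise_prob = noise_prob, label_noise = label_noise),
            class = "synthetic_home_config")
}

#' Generate the sensor map of a synthetic home
#'
#' Motion sensors are numbered `M001, M002, ...` room by room; door rooms
#' get `D001, ...`. The layout is a pure function of the configuration.
#'
#' @param config A [synthetic_home_config()].
#' @return A sensor map data frame (`sensor_id`, `location`, `modality`).
#' @export
generate_home <- function(config) {
  stopifnot(inherits(config, "synthetic_home_config"))
  rows <- list()
  m <- 0L
  for (r in names(config$rooms)) {
    n <- config$rooms[[r]]
    if (n > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        sensor_id = sprintf("M%03d", m + seq_len(n)), location = r,
        modality = "motion", stringsAsFactors = FALSE)
      m <- m + n
    }
  }
  d <- 0L
  for (r in config$door_rooms) {
    d <- d + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      sensor_id = sprintf("D%03d", d), location = r, modality = "door",
      stringsAsFactors = FALSE)
  }
  validate_sensor_map(do.call(rbind, rows))
}

#' Simulate a labeled CASAS-format event log
#'
#' Runs the semi-Markov activity process of the configuration over the
#' horizon and returns an event table in the same layout as
#' [parse_casas_log()] plus a `truth` column carrying the ground-truth
#' activity of every event (`NA` for idle events). The `activity` and
#' `marker` columns hold the begin/end annotations exactly as a CASAS log
#' would, so `write_casas_log()` then [parse_casas_log()] then
#' [propagate_activity_labels()] recovers `truth` exactly when
#' `label_noise` is zero.
#'
#' @param sensor_map Map from [generate_home()] (must cover the config's
#'   rooms).
#' @param config A [synthetic_home_config()].
#' @param days Horizon in days, `>= 1`.
#' @param seed Integer seed.
#' @param start Origin of the simulated clock (UTC date string).
#' @return Event data frame with columns `date`, `time`, `sensor_id`,
#'   `state`, `activity`, `marker`, `t`, `truth`.
#' @export
simulate_events <- function(sensor_map, config, days = 1, seed = 1L,
                            start = "2021-03-01") {
  stopifnot(inherits(config, "synthetic_home_config"), days >= 1)
  acts <- config$activities
  if (nrow(acts) == 0L) stop("empty activity set")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  motion_ids <- sensor_map$sensor_id[sensor_map$modality == "motion"]
  room_sensors <- split(motion_ids,
                        sensor_map$location[sensor_map$modality == "motion"])
  all_ids <- sensor_map$sensor_id

  t0 <- as.numeric(as.Date(start)) * 86400
  t_end <- t0 + days * 86400
  t <- t0
  prev <- sample.int(nrow(acts), 1L)
  ev_t <- numeric(0); ev_s <- character(0); ev_state <- character(0)
  ev_act <- character(0); ev_marker <- character(0); ev_truth <- character(0)

  emit <- function(times, ids, states, truth, annotate) {
    o <- order(times)
    times <- times[o]; ids <- ids[o]; states <- states[o]
    n <- length(times)
    act <- rep(NA_character_, n); mark <- rep(NA_character_, n)
    if (annotate && n >= 1L) {
      act[1L] <- truth; mark[1L] <- "begin"
      act[n] <- truth; mark[n] <- "end"
    }
    ev_t <<- c(ev_t, times); ev_s <<- c(ev_s, ids)
    ev_state <<- c(ev_state, states)
    ev_act <<- c(ev_act, act); ev_marker <<- c(ev_marker, mark)
    ev_truth <<- c(ev_truth, rep(if (is.na(truth)) NA_character_ else truth, n))
  }

  while (t < t_end) {
    # idle gap with sparse unlabeled firings
    idle <- stats::rlnorm(1L, log(config$idle_median_minutes * 60), 0.5)
    n_idle <- stats::rpois(1L, config$idle_rate * idle)
    if (n_idle > 0L) {
      times <- t + sort(stats::runif(n_idle, 0, idle))
      ids <- sample(all_ids, n_idle, replace = TRUE)
      states <- ifelse(grepl("^M", ids),
                       sample(c("ON", "OFF"), n_idle, replace = TRUE),
                       sample(c("OPEN", "CLOSE"), n_idle, replace = TRUE))
      emit(times, ids, states, NA_character_, FALSE)
    }
    t <- t + idle
    if (t >= t_end) break

    # choose next activity: time-of-day prior x transition weight
    hour <- (t / 3600) %% 24
    dh <- pmin(abs(hour - acts$tod_peak), 24 - abs(hour - acts$tod_peak))
    prior <- exp(-0.5 * (dh / acts$tod_sd)^2)
    w <- prior * config$transition[prev, ]
    a <- sample.int(nrow(acts), 1L, prob = w / sum(w))

    dur <- stats::rlnorm(1L, log(acts$median_minutes[a] * 60), acts$sdlog[a])
    dur <- min(dur, t_end - t)
    # ON firings at the activity's rate; each followed by its OFF
    gaps <- stats::rexp(max(2L, ceiling(dur * acts$rate[a] * 1.5)),
                        acts$rate[a])
    on_times <- t + cumsum(gaps)
    on_times <- on_times[on_times < t + dur]
    while (length(on_times) < 1L) {            # guarantee a visible episode
      on_times <- t + stats::runif(1L, 0, dur)
    }
    pool <- room_sensors[[acts$room[a]]]
    ids <- sample(pool, length(on_times), replace = TRUE)
    if (config$noise_prob > 0) {
      swap <- stats::runif(length(ids)) < config$noise_prob
      if (any(swap)) ids[swap] <- sample(all_ids, sum(swap), replace = TRUE)
    }
    off_times <- on_times + pmin(stats::rexp(length(on_times),
                                             acts$rate[a] * 2), 2)
    states <- ifelse(grepl("^M", c(ids, ids)),
                     rep(c("ON", "OFF"), each = length(ids)),
                     rep(c("OPEN", "CLOSE"), each = length(ids)))
    annotate <- stats::runif(1L) >= config$label_noise
    emit(c(on_times, off_times), c(ids, ids), states, acts$name[a], annotate)
    # the episode owns the clock until its last OFF has fired, so
    # episodes never interleave and no two events collide exactly
    t <- max(t + dur, max(off_times) + 1e-3)
    prev <- a
  }

  o <- order(ev_t)
  t_sec <- ev_t[o]
  day <- floor(t_sec / 86400)
  secday <- t_sec - day * 86400
  h <- floor(secday / 3600); mi <- floor((secday - h * 3600) / 60)
  sec <- secday - h * 3600 - mi * 60
  ev <- data.frame(
    date = format(as.Date(day, origin = "1970-01-01"), "%Y-%m-%d"),
    time = sprintf("%02d:%02d:%09.6f", h, mi, sec),
    sensor_id = ev_s[o], state = ev_state[o], activity = ev_act[o],
    marker = ev_marker[o], t = t_sec, truth = ev_truth[o],
    stringsAsFactors = FALSE
  )
  # re-derive t from the formatted (microsecond-truncated) timestamp so
  # that a written log parses back to identical times
  ev$t <- vapply(seq_len(nrow(ev)), function(i) {
    .parse_casas_timestamp(ev$date[i], ev$time[i])$t
  }, numeric(1))
  ev
}

#' Write the ground-truth sidecar of a simulated log
#'
#' @param events Result of [simulate_events()].
#' @param path Output TSV path (`event`, `truth` columns; one row per
#'   event in file order).
#' @export
write_ground_truth <- function(events, path) {
  utils::write.table(
    data.frame(event = seq_len(nrow(events)), truth = events$truth),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
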