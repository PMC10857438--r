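#' Parse a CASAS-style smart-home event log
#'
#' Reads whitespace-delimited sensor event lines of the form
#' `date time sensor_id state [activity] [begin|end]` into an event table.
#' Timestamps may carry a microsecond fraction separated by either `.` or
#' `:` (both dialects occur in CASAS exports); they are normalized to a
#' six-digit `.`-separated fraction.
#'
#' A line with exactly five fields (an activity but no begin/end marker) is
#' rejected by default, since markers are what delimit activity episodes;
#' set `allow_unmarked_activity = TRUE` to accept such lines.
#'
#' @param x A file path or a character vector of log lines.
#' @param strict If `TRUE`, malformed lines raise an error; otherwise they
#'   are collected in the `rejects` attribute of the result.
#' @param allow_unmarked_activity Accept five-field lines (activity without
#'   a begin/end marker).
#' @return A data frame with columns `date`, `time`, `sensor_id`, `state`,
#'   `activity`, `marker` (the latter two `NA` where absent) and `t`, the
#'   timestamp in seconds since 1970-01-01 UTC. Malformed lines are stored
#'   in `attr(, "rejects")` as a data frame of line numbers, text and
#'   reasons; retrieve it with [casas_rejects()].
#' @seealso [write_casas_log()], [clean_events()], [propagate_activity_labels()]
#' @export
#' @examples
#' ev <- parse_casas_log(c(
#'   "2010-11-04 08:33:52.929406 M018 ON Meal_Preparation begin",
#'   "2010-11-04 08:33:53.911115 M019 OFF"))
#' ev$sensor_id
parse_casas_log <- function(x, strict = FALSE, allow_unmarked_activity = FALSE) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    as.character(x)
  }
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  lines <- lines[keep]
  n <- length(lines)

  date <- time <- sensor <- state <- activity <- marker <- character(n)
  tsec <- numeric(n)
  ok <- logical(n)
  reason <- character(n)

  if (n > 0L) {
    parts <- strsplit(trimws(lines), "[ \t]+")
    for (i in seq_len(n)) {
      f <- parts[[i]]
      nf <- length(f)
      if (nf < 4L || nf > 6L) {
        reason[i] <- sprintf("expected 4-6 fields, got %d", nf)
        next
      }
      if (nf == 5L && !allow_unmarked_activity) {
        reason[i] <- "activity without begin/end marker"
        next
      }
      ts <- .parse_casas_timestamp(f[1L], f[2L])
      if (is.null(ts)) {
        reason[i] <- sprintf("unparseable timestamp '%s %s'", f[1L], f[2L])
        next
      }
      if (!grepl("^[A-Za-z]+[0-9]+$", f[3L])) {
        reason[i] <- sprintf("bad sensor id '%s'", f[3L])
        next
      }
      if (nf == 6L && !(f[6L] %in% c("begin", "end"))) {
        reason[i] <- sprintf("bad marker '%s'", f[6L])
        next
      }
      date[i] <- ts$date
      time[i] <- ts$time
      tsec[i] <- ts$t
      sensor[i] <- f[3L]
      state[i] <- f[4L]
      activity[i] <- if (nf >= 5L) f[5L] else NA_character_
      marker[i] <- if (nf == 6L) f[6L] else NA_character_
      ok[i] <- TRUE
    }
  }

  if (strict && any(!ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("malformed log line %d: %s", idx[bad], reason[bad]))
  }

  ev <- data.frame(
    date = date[ok], time = time[ok], sensor_id = sensor[ok],
    state = state[ok], activity = activity[ok], marker = marker[ok],
    t = tsec[ok], stringsAsFactors = FALSE
  )
  ev$activity[!is.na(ev$activity) & ev$activity == ""] <- NA_character_
  rejects <- data.frame(
    line = idx[!ok], text = lines[!ok], reason = reason[!ok],
    stringsAsFactors = FALSE
  )
  attr(ev, "rejects") <- rejects
  ev
}

# Accepts "HH:MM:SS", "HH:MM:SS.ffffff" and the ":"-fraction dialect
# "HH:MM:SS:ffffff"; returns normalized strings plus numeric seconds.
.parse_casas_timestamp <- function(date, time) {
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", date)) return(NULL)
  d <- as.Date(date, format = "%Y-%m-%d")
  if (is.na(d)) return(NULL)
  p <- strsplit(time, ":", fixed = TRUE)[[1L]]
  frac <- 0
  if (length(p) == 4L) {               # HH:MM:SS:ffffff
    if (!grepl("^[0-9]+$", p[4L])) return(NULL)
    frac <- as.numeric(paste0("0.", p[4L]))
    p <- p[1:3]
  }
  if (length(p) != 3L) return(NULL)
  if (grepl(".", p[3L], fixed = TRUE)) {
    sp <- strsplit(p[3L], ".", fixed = TRUE)[[1L]]
    if (length(sp) != 2L || !grepl("^[0-9]+$", sp[2L])) return(NULL)
    frac <- as.numeric(paste0("0.", sp[2L]))
    p[3L] <- sp[1L]
  }
  if (!all(grepl("^[0-9]+$", p))) return(NULL)
  hms <- as.integer(p)
  if (hms[1L] > 23L || hms[2L] > 59L || hms[3L] > 60L) return(NULL)
  secday <- hms[1L] * 3600 + hms[2L] * 60 + hms[3L] + frac
  list(
    date = format(d, "%Y-%m-%d"),
    time = sprintf("%02d:%02d:%09.6f", hms[1L], hms[2L], hms[3L] + frac),
    t = as.numeric(d) * 86400 + secday
  )
}

#' Rejected lines from a parsed log
#'
#' @param events Result of [parse_casas_log()].
#' @return Data frame of rejected lines (line number, text, reason).
#' @export
casas_rejects <- function(events) {
  r <- attr(events, "rejects")
  if (is.null(r)) {
    r <- data.frame(line = integer(), text = character(), reason = character(),
                    stringsAsFactors = FALSE)
  }
  r
}

#' Write events back to the CASAS log format
#'
#' Output is byte-stable for a fixed input table: single-space separated
#' fields, timestamps with a six-digit microsecond fraction, activity and
#' marker appended only where present. `write(parse(write(x)))` is a
#' fixpoint.
#'
#' @param events Event table as returned by [parse_casas_log()].
#' @param path Output file path; omit to return the lines invisibly.
#' @return The formatted lines, invisibly.
#' @export
write_casas_log <- function(events, path = NULL) {
  lines <- character(nrow(events))
  if (nrow(events) > 0L) {
    lines <- paste(events$date, events$time, events$sensor_id, events$state)
    has_act <- !is.na(events$activity)
    lines[has_act] <- paste(lines[has_act], events$activity[has_act])
    has_mark <- !is.na(events$marker)
    lines[has_mark] <- paste(lines[has_mark], events$marker[has_mark])
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Clean a parsed event stream
#'
#' Applies the standard cleaning pass: drops records with a missing sensor
#' id or state, removes temperature-sensor (`T*`) events (only motion and
#' door sensors feed feature extraction), removes duplicate records — two
#' records are duplicates when their (timestamp, sensor, state) triple is
#' identical — and stably sorts by timestamp so that ties keep file order.
#' The operation is idempotent.
#'
#' @param events Event table.
#' @param verbose Print a summary of removal counts.
#' @return The cleaned event table, with removal counts in
#'   `attr(, "cleaning_counts")`.
#' @export
clean_events <- function(events, verbose = FALSE) {
  n0 <- nrow(events)
  missing <- is.na(events$sensor_id) | events$sensor_id == "" |
    is.na(events$state) | events$state == ""
  ev <- events[!missing, , drop = FALSE]
  n_missing <- n0 - nrow(ev)

  temp <- grepl("^[Tt]", ev$sensor_id)
  ev <- ev[!temp, , drop = FALSE]
  n_temp <- sum(temp)

  key <- paste(sprintf("%.6f", ev$t), ev$sensor_id, ev$state)
  dup <- duplicated(key)
  ev <- ev[!dup, , drop = FALSE]
  n_dup <- sum(dup)

  ev <- ev[order(ev$t, method = "radix"), , drop = FALSE]
  rownames(ev) <- NULL
  counts <- c(missing_fields = n_missing, temperature = n_temp,
              duplicates = n_dup)
  attr(ev, "cleaning_counts") <- counts
  attr(ev, "rejects") <- attr(events, "rejects")
  if (verbose) {
    message(sprintf("clean_events: removed %d missing-field, %d temperature, %d duplicate records",
                    n_missing, n_temp, n_dup))
  }
  ev
}

#' Propagate begin/end activity annotations to every bracketed event
#'
#' CASAS logs annotate only the first (`begin`) and last (`end`) event of an
#' activity episode. This fills in the label for every event between a
#' `X begin` and its matching `X end`, inclusive. Nested or interleaved
#' brackets are resolved innermost-wins (the most recently opened episode
#' labels the event), with a warning. An unmatched `begin` is closed at the
#' last event; an `end` without a matching `begin` leaves that event
#' unlabeled. Event count and order are never changed.
#'
#' @param events Time-sorted event table.
#' @return The event table with an additional `label` column
#'   (`NA` outside any episode).
#' @export
propagate_activity_labels <- function(events) {
  n <- nrow(events)
  label <- rep(NA_character_, n)
  stack <- character(0)
  warned_nested <- FALSE
  for (i in seq_len(n)) {
    m <- events$marker[i]
    if (!is.na(m) && m == "begin") {
      if (length(stack) > 0L && !warned_nested) {
        warning("overlapping activity brackets; resolving innermost-wins",
                call. = FALSE)
        warned_nested <- TRUE
      }
      stack <- c(stack, events$activity[i])
      label[i] <- events$activity[i]
    } else if (!is.na(m) && m == "end") {
      act <- events$activity[i]
      pos <- which(stack == act)
      if (length(pos) == 0L) {
        warning(sprintf("'%s end' without matching begin at row %d", act, i),
                call. = FALSE)
        label[i] <- if (length(stack) > 0L) stack[length(stack)] else NA_character_
      } else {
        label[i] <- act
        stack <- stack[-pos[length(pos)]]
      }
    } else {
      if (length(stack) > 0L) label[i] <- stack[length(stack)]
    }
  }
  if (length(stack) > 0L) {
    warning(sprintf("%d unmatched begin marker(s); episode(s) closed at last event",
                    length(stack)), call. = FALSE)
  }
  events$label <- label
  events
}

# Raw Milan annotation -> consolidated ADL category. Keys are matched with
# "_" and " " treated as equivalent.
.milan_activity_map <- c(
  "Read"               = "Relax",
  "Watch TV"           = "Relax",
  "Morning Meds"       = "Medication",
  "Eve Meds"           = "Medication",
  "Master Bathrm"      = "Bathing",
  "Guest Bathrm"       = "Bathing",
  "Desk Activity"      = "Work",
  "Chores"             = "Work",
  "Meditate"           = "Other",
  "Master Bedroom"     = "Other",
  "Master Bedroom Activity" = "Other",
  "Dining Rm Activity" = "Eating",
  "Kitchen Activity"   = "Meal_Preparation",
  "Sleep"              = "Sleeping",
  "Meal_Preparation"   = "Meal_Preparation",
  "Relax"              = "Relax",
  "Eating"             = "Eating",
  "Work"               = "Work",
  "Sleeping"           = "Sleeping",
  "Bed_to_Toilet"      = "Bed_to_Toilet",
  "Bed to Toilet"      = "Bed_to_Toilet",
  "Leave_Home"         = "Leave_Home",
  "Leave Home"         = "Leave_Home",
  "Medication"         = "Medication",
  "Bathing"            = "Bathing",
  "Other"              = "Other"
)

#' Remap raw Milan activity annotations to consolidated ADL categories
#'
#' The Milan test bed uses fine-grained activity names (e.g. `Kitchen
#' Activity`, `Morning Meds`) that are consolidated into ten activities of
#' daily living for modeling: Meal_Preparation, Relax, Eating, Work,
#' Sleeping, Bed_to_Toilet, Leave_Home, Medication, Bathing and Other.
#' Unlabeled events map to `"Other"` (the resident not engaged in any
#' specific tracked activity).
#'
#' @param label Character vector of raw labels (`NA` allowed).
#' @param unknown What to do with an unrecognized raw label: map to
#'   `"Other"` (default) or raise an error.
#' @return Character vector of consolidated labels.
#' @export
#' @examples
#' remap_milan_activities(c("Kitchen Activity", "Morning Meds", NA))
remap_milan_activities <- function(label, unknown = c("other", "error")) {
  unknown <- match.arg(unknown)
  key <- gsub("_", " ", label, fixed = TRUE)
  map <- .milan_activity_map
  names(map) <- gsub("_", " ", names(map), fixed = TRUE)
  out <- unname(map[key])
  out[is.na(label)] <- "Other"
  miss <- is.na(out) & !is.na(label)
  if (any(miss)) {
    if (unknown == "error") {
      stop(sprintf("unknown Milan activity label(s): %s",
                   paste(unique(label[miss]), collapse = ", ")))
    }
    out[miss] <- "Other"
  }
  out
}

#' Load or read a sensor location map
#'
#' A sensor map associates each sensor id with a room and a modality
#' (motion / door / temperature, inferred from the leading letter M / D /
#' T). Maps for the Aruba and Milan test beds ship with the package.
#'
#' @param name `"aruba"` or `"milan"` for the packaged maps.
#' @return Data frame with columns `sensor_id`, `location`, `modality`.
#' @export
sensor_map <- function(name = c("aruba", "milan")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("sensor_map_", name, ".tsv"),
                      package = "sensorclr", mustWork = TRUE)
  read_sensor_map(path)
}

#' @rdname sensor_map
#' @param path Path to a tab-separated file with columns `sensor_id`,
#'   `location`, `modality`.
#' @export
read_sensor_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  validate_sensor_map(m)
}

#' @rdname sensor_map
#' @param map A sensor map data frame to validate.
#' @export
validate_sensor_map <- function(map) {
  stopifnot(all(c("sensor_id", "location", "modality") %in% names(map)))
  if (anyDuplicated(map$sensor_id)) {
    stop("duplicate sensor ids in sensor map")
  }
  inferred <- c(M = "motion", D = "door", T = "temperature")[
    substr(map$sensor_id, 1L, 1L)]
  bad <- !is.na(inferred) & inferred != map$modality
  if (any(bad)) {
    stop(sprintf("modality mismatch for sensor(s): %s",
                 paste(map$sensor_id[bad], collapse = ", ")))
  }
  map
}
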