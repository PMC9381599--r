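#' Read one participant's sensor streams from disk
#'
#' Reads the three stream files of the monitoring system into a validated
#' [home_recording()]:
#'
#' * PIR CSV, either per-epoch (`participant_id,room,timestamp,state`) or
#'   run-length encoded (`participant_id,room,timestamp_start,timestamp_end,state`);
#' * door CSV (`participant_id,door,timestamp,event` with event open/close);
#' * bed-sensor JSON-Lines, one record per night with channel arrays on the
#'   4-s grid and `null` for missing samples.
#'
#' Malformed rows are rejected with an error naming the file and offending
#' field, never silently dropped. Door streams are de-duplicated and
#' state-normalized: when two consecutive events of one door carry the same
#' state (dropped events are common with reed switches), a synthetic
#' complementary event is inserted at the interval midpoint and a warning is
#' emitted.
#'
#' @param pir_path,door_path,bed_path File paths; any may be `NULL` to skip
#'   that stream.
#' @param participant_id Expected participant id; rows for other ids are an
#'   error.
#' @param timezone IANA timezone of the apartment (timestamps are stored
#'   timezone-aware; DST days of 23/25 h are legal).
#' @return A validated `home_recording`.
#' @export
read_recording <- function(pir_path = NULL, door_path = NULL, bed_path = NULL,
                           participant_id, timezone = "UTC") {
  pir <- if (is.null(pir_path)) empty_pir() else read_pir_csv(pir_path, participant_id, timezone)
  doors <- if (is.null(door_path)) empty_doors() else read_door_csv(door_path, participant_id, timezone)
  nights <- if (is.null(bed_path)) empty_nights() else read_bed_jsonl(bed_path, participant_id, timezone)
  doors <- normalize_door_events(doors)
  home_recording(participant_id, pir = pir, doors = doors, nights = nights, timezone = timezone)
}

parse_iso_time <- function(x, tz, file, field) {
  out <- as.POSIXct(sub("Z$", "", x), tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: row %d, field '%s': unparseable timestamp '%s' (expected ISO-8601 UTC)",
      file, bad[1], field, x[bad[1]]
    ))
  }
  lubridate::with_tz(out, tz)
}

read_pir_csv <- function(path, participant_id, tz) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  rle_form <- all(c("timestamp_start", "timestamp_end") %in% names(df))
  need <- if (rle_form) {
    c("participant_id", "room", "timestamp_start", "timestamp_end", "state")
  } else {
    c("participant_id", "room", "timestamp", "state")
  }
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  check_participant(df, participant_id, path)
  bad_room <- which(!df$room %in% room_labels(essential_only = FALSE))
  if (length(bad_room) > 0) {
    abort(sprintf("%s: row %d, field 'room': unknown room '%s'", path, bad_room[1], df$room[bad_room[1]]))
  }
  st <- suppressWarnings(as.integer(df$state))
  bad_state <- which(is.na(st) | !st %in% c(0L, 1L))
  if (length(bad_state) > 0) {
    abort(sprintf("%s: row %d, field 'state': '%s' is not 0/1", path, bad_state[1], df$state[bad_state[1]]))
  }
  if (rle_form) {
    pir <- tibble(
      room = df$room,
      start = parse_iso_time(df$timestamp_start, tz, path, "timestamp_start"),
      end = parse_iso_time(df$timestamp_end, tz, path, "timestamp_end"),
      state = st
    )
    check_monotone_per_group(pir$start, pir$room, path, "timestamp_start")
    pir
  } else {
    ep <- tibble(
      room = df$room,
      timestamp = parse_iso_time(df$timestamp, tz, path, "timestamp"),
      state = st
    )
    check_monotone_per_group(ep$timestamp, ep$room, path, "timestamp", strict = TRUE)
    epochs_to_runs(ep)
  }
}

check_participant <- function(df, participant_id, path) {
  bad <- which(df$participant_id != participant_id)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: row %d, field 'participant_id': found '%s', expected '%s'",
      path, bad[1], df$participant_id[bad[1]], participant_id
    ))
  }
}

check_monotone_per_group <- function(times, group, path, field, strict = FALSE) {
  for (g in unique(group)) {
    tt <- as.numeric(times[group == g])
    if (is.unsorted(tt, strictly = strict)) {
      abort(sprintf("%s: non-monotone '%s' within stream '%s'", path, field, g))
    }
  }
}

read_door_csv <- function(path, participant_id, tz) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("participant_id", "door", "timestamp", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  check_participant(df, participant_id, path)
  bad <- which(!df$door %in% DOOR_LABELS)
  if (length(bad) > 0) {
    abort(sprintf("%s: row %d, field 'door': unknown door '%s'", path, bad[1], df$door[bad[1]]))
  }
  bad <- which(!df$event %in% c("open", "close"))
  if (length(bad) > 0) {
    abort(sprintf("%s: row %d, field 'event': '%s' is not open/close", path, bad[1], df$event[bad[1]]))
  }
  out <- tibble(
    door = df$door,
    time = parse_iso_time(df$timestamp, tz, path, "timestamp"),
    state = df$event
  )
  check_monotone_per_group(out$time, out$door, path, "timestamp")
  arrange(out, .data$time, .data$door)
}

read_bed_jsonl <- function(path, participant_id, tz) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_nights())
  recs <- lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) abort(sprintf("%s: line %d: invalid JSON (%s)", path, i, conditionMessage(e)))
    )
    for (f in c("participant_id", "start", "end")) {
      if (is.null(x[[f]])) abort(sprintf("%s: line %d: missing field '%s'", path, i, f))
    }
    if (x$participant_id != participant_id) {
      abort(sprintf(
        "%s: line %d, field 'participant_id': found '%s', expected '%s'",
        path, i, x$participant_id, participant_id
      ))
    }
    be <- x$bed_exits
    if (is.null(be) || length(be) == 0L) {
      be_tbl <- tibble(start = as.POSIXct(character()), end = as.POSIXct(character()))
    } else {
      if (is.list(be)) be <- do.call(rbind, be)
      be_tbl <- tibble(
        start = parse_iso_time(be[, 1], tz, path, "bed_exits"),
        end = parse_iso_time(be[, 2], tz, path, "bed_exits")
      )
    }
    tt <- x$toss_turns
    tt_times <- if (is.null(tt) || length(tt) == 0L) {
      as.POSIXct(character(), tz = tz)
    } else {
      parse_iso_time(unlist(tt), tz, path, "toss_turns")
    }
    tibble(
      start = parse_iso_time(x$start, tz, path, "start"),
      end = parse_iso_time(x$end, tz, path, "end"),
      hr = list(as.numeric(x$hr)),
      rr = list(as.numeric(x$rr)),
      activity = list(as.numeric(x$activity)),
      stage = list(as.character(x$stage)),
      toss_turns = list(tt_times),
      bed_exits = list(be_tbl)
    )
  })
  arrange(bind_rows(recs), .data$start)
}

#' Normalize a door-event stream to strict open/close alternation
#'
#' Reed-switch streams drop events; downstream outing detection requires
#' alternation. Exact duplicate events are removed; where two consecutive
#' events of the same door share a state, a synthetic complementary event is
#' inserted at the interval midpoint (with a warning counting insertions).
#'
#' @param doors Door event tibble (`door`, `time`, `state`).
#' @return Normalized tibble, time-ordered, alternating per door.
#' @export
normalize_door_events <- function(doors) {
  if (nrow(doors) == 0L) return(doors)
  doors <- distinct(arrange(doors, .data$time, .data$door))
  inserted <- 0L
  out <- lapply(split(doors, doors$door), function(d) {
    d <- d[order(d$time), ]
    reps <- which(d$state[-1] == d$state[-nrow(d)])
    while (length(reps) > 0) {
      i <- reps[1]
      mid <- d$time[i] + as.numeric(difftime(d$time[i + 1], d$time[i], units = "secs")) / 2
      comp <- if (d$state[i] == "open") "close" else "open"
      d <- bind_rows(
        d[seq_len(i), ],
        tibble(door = d$door[1], time = mid, state = comp),
        d[(i + 1):nrow(d), ]
      )
      inserted <<- inserted + 1L
      reps <- which(d$state[-1] == d$state[-nrow(d)])
    }
    d
  })
  if (inserted > 0) {
    warn(sprintf("door stream normalization inserted %d synthetic complementary event(s)", inserted))
  }
  arrange(bind_rows(out), .data$time, .data$door)
}

#' Write a home recording in its canonical on-disk form
#'
#' Writes `<id>_pir.csv` (run-length encoded), `<id>_doors.csv` and
#' `<id>_bed.jsonl` under `dir`. Timestamps are serialized as ISO-8601 UTC;
#' the canonical form round-trips byte-identically through
#' [read_recording()].
#'
#' @param rec A `home_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "home_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- rec$participant_id
  paths <- c(
    pir = file.path(dir, paste0(id, "_pir.csv")),
    doors = file.path(dir, paste0(id, "_doors.csv")),
    bed = file.path(dir, paste0(id, "_bed.jsonl"))
  )
  iso <- function(x) format(lubridate::with_tz(x, "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  pir <- arrange(rec$pir, .data$room, .data$start)
  readr::write_csv(tibble(
    participant_id = rep(id, nrow(pir)), room = pir$room,
    timestamp_start = iso(pir$start), timestamp_end = iso(pir$end), state = pir$state
  ), paths[["pir"]])
  readr::write_csv(tibble(
    participant_id = rep(id, nrow(rec$doors)), door = rec$doors$door,
    timestamp = iso(rec$doors$time), event = rec$doors$state
  ), paths[["doors"]])
  con <- file(paths[["bed"]], open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(rec$nights))) {
    n <- rec$nights[i, ]
    be <- n$bed_exits[[1]]
    rec_json <- jsonlite::toJSON(
      list(
        participant_id = id,
        start = iso(n$start[[1]]), end = iso(n$end[[1]]),
        hr = round(n$hr[[1]], 3), rr = round(n$rr[[1]], 3),
        activity = round(n$activity[[1]], 3), stage = n$stage[[1]],
        toss_turns = iso(n$toss_turns[[1]]),
        bed_exits = lapply(seq_len(nrow(be)), function(j) c(iso(be$start[j]), iso(be$end[j])))
      ),
      auto_unbox = TRUE, na = "null", digits = NA
    )
    writeLines(rec_json, con)
  }
  invisible(paths)
}

#' Validate a directory of stream files
#'
#' Scans `dir` for `*_pir.csv`, `*_doors.csv`, `*_bed.jsonl` triplets (one
#' per participant id prefix) and attempts a full validated read of each.
#'
#' @param dir Directory containing stream files.
#' @param timezone Timezone passed to [read_recording()].
#' @return Tibble with one row per (participant, stream) and columns
#'   `participant_id`, `file`, `ok`, `message`.
#' @export
validate_stream_dir <- function(dir, timezone = "UTC") {
  files <- list.files(dir, pattern = "_(pir\\.csv|doors\\.csv|bed\\.jsonl)$")
  ids <- unique(sub("_(pir\\.csv|doors\\.csv|bed\\.jsonl)$", "", files))
  rows <- list()
  for (id in ids) {
    specs <- list(
      c(file = paste0(id, "_pir.csv"), arg = "pir_path"),
      c(file = paste0(id, "_doors.csv"), arg = "door_path"),
      c(file = paste0(id, "_bed.jsonl"), arg = "bed_path")
    )
    for (s in specs) {
      path <- file.path(dir, s[["file"]])
      if (!file.exists(path)) next
      res <- tryCatch(
        {
          args <- list(participant_id = id, timezone = timezone)
          args[[s[["arg"]]]] <- path
          suppressWarnings(do.call(read_recording, args))
          c(ok = TRUE, message = "")
        },
        error = function(e) c(ok = FALSE, message = conditionMessage(e))
      )
      rows[[length(rows) + 1L]] <- tibble(
        participant_id = id, file = s[["file"]],
        ok = as.logical(res[["ok"]]), message = res[["message"]]
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(participant_id = character(), file = character(), ok = logical(), message = character()))
  }
  bind_rows(rows)
}
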