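# Readers, writers and validators for the three observation tables.
#
# All inputs are comma-delimited UTF-8 text with a header row:
#   roster.csv        id, sex, age_years, matriline, reproductive_status,
#                     sterilized
#   scans.csv         date, id_a, id_b, pair_type, mount_observed,
#                     vd_contact_observed
#   focal_sessions.csv session_id, id_a, id_b, date, clock_start,
#                     planned_seconds, observed_seconds, pauses,
#                     focal_schedule
#   focal_events.csv  session_id, t_start, t_end, behavior, actor, receiver,
#                     modifiers, out_of_sight
# `pauses` is "start-end;start-end" in seconds since clock_start;
# `focal_schedule` is "id:seconds;id:seconds"; `modifiers` is ";"-separated.
# Dates are ISO-8601 calendar days; day arithmetic is in whole days.

.repro_statuses <- c("nulliparous", "parous", "lactating", "menopausal_like",
                     "not_applicable")

#' Age class of a female
#'
#' Females are adolescent from sexual maturity (3.5 years) to their fifth
#' year and adult from age 5 on; younger females are immature and males have
#' no age class in this analysis.
#'
#' @param sex Character vector, `"F"` or `"M"`.
#' @param age_years Numeric ages in years.
#' @return Character vector: `"adolescent"`, `"adult"` or `NA`.
#' @export
age_class <- function(sex, age_years) {
  ifelse(sex == "F" & age_years >= 5, "adult",
         ifelse(sex == "F" & age_years >= 3.5, "adolescent", NA_character_))
}

#' Is an individual sexually mature?
#'
#' Maturity thresholds: females at 3.5 years, males at 4.5 years.
#'
#' @inheritParams age_class
#' @return Logical vector.
#' @export
is_mature <- function(sex, age_years) {
  (sex == "F" & age_years >= 3.5) | (sex == "M" & age_years >= 4.5)
}

#' Read and validate a population roster
#'
#' @param path Path to `roster.csv`.
#' @return A data frame with columns `id`, `sex`, `age_years`, `matriline`,
#'   `reproductive_status`, `sterilized`, plus derived `mature` and
#'   `age_class`. Logs the counts of mature females and males.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("id", "sex", "age_years", "matriline",
                "reproductive_status", "sterilized")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("roster is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("roster file has a header but no rows", call. = FALSE)
    out <- data.frame(id = character(0), sex = character(0),
                      age_years = numeric(0), matriline = character(0),
                      reproductive_status = character(0),
                      sterilized = logical(0), mature = logical(0),
                      age_class = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0L) stop("duplicate individual id(s): ",
                             paste(dup, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    if (!df$sex[i] %in% c("F", "M")) {
      row_error(path, lines[i], paste0("unknown sex '", df$sex[i], "'"))
    }
    age <- suppressWarnings(as.numeric(df$age_years[i]))
    if (is.na(age)) {
      row_error(path, lines[i], paste0("non-numeric age '", df$age_years[i], "'"))
    }
    if (age < 0) row_error(path, lines[i], "negative age")
    if (!df$reproductive_status[i] %in% .repro_statuses) {
      row_error(path, lines[i], paste0("unknown reproductive status '",
                                       df$reproductive_status[i], "'"))
    }
    if (df$reproductive_status[i] == "menopausal_like" && age < 26) {
      row_error(path, lines[i],
                "menopausal_like requires age_years >= 26")
    }
    if (df$sex[i] == "M" && df$reproductive_status[i] != "not_applicable") {
      row_error(path, lines[i],
                "male reproductive_status must be 'not_applicable'")
    }
  }
  out <- data.frame(
    id = df$id,
    sex = df$sex,
    age_years = as.numeric(df$age_years),
    matriline = df$matriline,
    reproductive_status = df$reproductive_status,
    sterilized = as.logical(df$sterilized),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$sterilized)) {
    stop("sterilized must be TRUE/FALSE")
  }
  out$mature <- is_mature(out$sex, out$age_years)
  out$age_class <- age_class(out$sex, out$age_years)
  message(sprintf("roster: %d mature females, %d mature males",
                  sum(out$mature & out$sex == "F"),
                  sum(out$mature & out$sex == "M")))
  out
}

#' Write a roster table
#' @param roster Data frame as returned by [read_roster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  cols <- c("id", "sex", "age_years", "matriline", "reproductive_status",
            "sterilized")
  utils::write.csv(roster[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a scan-sampling sighting log
#'
#' Each row is one pair sighted on one day with mount / ventro-dorsal-contact
#' flags. Pair keys are canonicalized (lexicographic id order) and duplicate
#' (pair, date) rows are collapsed with a logical OR of the flags — a pair is
#' only counted once per day, independent of the number of sightings.
#'
#' @param path Path to `scans.csv`.
#' @param roster Roster data frame; all ids must resolve against it.
#' @return A data frame with columns `date` (Date), `id_a`, `id_b`
#'   (canonical order), `pair_id`, `pair_type` (`"FF"` or `"MF"`),
#'   `mount_observed`, `vd_contact_observed`.
#' @export
read_scan_log <- function(path, roster) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("date", "id_a", "id_b", "pair_type", "mount_observed",
                "vd_contact_observed")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("scan log is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(data.frame(date = as.Date(character(0)), id_a = character(0),
                      id_b = character(0), pair_id = character(0),
                      pair_type = character(0), mount_observed = logical(0),
                      vd_contact_observed = logical(0),
                      stringsAsFactors = FALSE))
  }
  lines <- seq_len(nrow(df)) + 1L
  unknown <- setdiff(unique(c(df$id_a, df$id_b)), roster$id)
  if (length(unknown) > 0L) {
    stop("scan log references id(s) not in roster: ",
         paste(unknown, collapse = ", "))
  }
  same <- which(df$id_a == df$id_b)
  if (length(same) > 0L) {
    row_error(path, lines[same[1L]], "id_a equals id_b")
  }
  date <- as.Date(df$date)
  if (anyNA(date)) {
    row_error(path, lines[which(is.na(date))[1L]], "unparseable date")
  }
  sex <- stats::setNames(roster$sex, roster$id)
  expected_type <- ifelse(sex[df$id_a] == "F" & sex[df$id_b] == "F", "FF",
                          ifelse(sex[df$id_a] != sex[df$id_b], "MF", "MM"))
  if (any(expected_type == "MM")) {
    row_error(path, lines[which(expected_type == "MM")[1L]],
              "male-male pairs are not part of the consort analysis")
  }
  mismatch <- which(df$pair_type != expected_type)
  if (length(mismatch) > 0L) {
    row_error(path, lines[mismatch[1L]],
              sprintf("pair_type '%s' inconsistent with roster sexes ('%s')",
                      df$pair_type[mismatch[1L]],
                      expected_type[mismatch[1L]]))
  }
  mount <- as.logical(df$mount_observed)
  vd <- as.logical(df$vd_contact_observed)
  if (anyNA(mount) || anyNA(vd)) {
    stop("mount_observed / vd_contact_observed must be TRUE/FALSE")
  }
  neither <- which(!mount & !vd)
  if (length(neither) > 0L) {
    row_error(path, lines[neither[1L]],
              "a scan record requires mount_observed or vd_contact_observed")
  }
  out <- data.frame(
    date = date,
    id_a = pmin(df$id_a, df$id_b),
    id_b = pmax(df$id_a, df$id_b),
    pair_type = expected_type,
    mount_observed = mount,
    vd_contact_observed = vd,
    stringsAsFactors = FALSE
  )
  out$pair_id <- pair_key(out$id_a, out$id_b)
  key <- paste(out$pair_id, out$date)
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning(sprintf(
      "collapsed %d duplicate (pair, date) scan row(s) with OR of flags",
      n_dup), call. = FALSE)
    out <- do.call(rbind, lapply(split(out, key), function(g) {
      g$mount_observed[1L] <- any(g$mount_observed)
      g$vd_contact_observed[1L] <- any(g$vd_contact_observed)
      g[1L, ]
    }))
  }
  out <- out[order(out$pair_id, out$date),
             c("date", "id_a", "id_b", "pair_id", "pair_type",
               "mount_observed", "vd_contact_observed")]
  rownames(out) <- NULL
  out
}

#' Write a scan log
#' @param scans Data frame as returned by [read_scan_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_log <- function(scans, path) {
  cols <- c("date", "id_a", "id_b", "pair_type", "mount_observed",
            "vd_contact_observed")
  utils::write.csv(scans[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Parse "a-b;c-d" pause strings to a 2-column numeric matrix (seconds since
# clock_start); "" -> zero rows.
parse_pauses <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(numeric(0), ncol = 2L))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed pauses field: ", s)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (anyNA(m) || any(m[, 2L] < m[, 1L])) stop("malformed pauses field: ", s)
  m
}

format_pauses <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return("")
  paste(sprintf("%g-%g", m[, 1L], m[, 2L]), collapse = ";")
}

parse_schedule <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed focal_schedule field: ", s)
  stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                  vapply(parts, `[`, "", 1L))
}

format_schedule <- function(x) {
  if (length(x) == 0L) return("")
  paste(sprintf("%s:%g", names(x), unname(x)), collapse = ";")
}

#' Read and validate a focal-sampling log
#'
#' Reads the session header table and the timed event table of the
#' 20-minute dyadic focal protocol. Event times are seconds from session
#' start; instantaneous events have `t_end == t_start`, states have
#' `t_end > t_start`. The recording mode and the allowed modifiers of every
#' event are cross-checked against the behaviour catalog, and directional
#' behaviours must name an actor and a receiver belonging to the session's
#' pair.
#'
#' @param sessions_path Path to `focal_sessions.csv`.
#' @param events_path Path to `focal_events.csv`.
#' @param catalog An `ethogram` object.
#' @param roster Roster data frame.
#' @return A list with `sessions` (one row per session; `pauses` and
#'   `focal_schedule` are list-columns) and `events` (sorted by
#'   `session_id`, `t_start`).
#' @export
read_focal_log <- function(sessions_path, events_path, catalog, roster) {
  sdf <- utils::read.csv(sessions_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  s_required <- c("session_id", "id_a", "id_b", "date", "clock_start",
                  "planned_seconds", "observed_seconds", "pauses",
                  "focal_schedule")
  miss <- setdiff(s_required, names(sdf))
  if (length(miss) > 0L) {
    stop("focal session table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sdf$session_id)) {
    stop("duplicate session_id(s): ",
         paste(unique(sdf$session_id[duplicated(sdf$session_id)]),
               collapse = ", "))
  }
  unknown <- setdiff(unique(c(sdf$id_a, sdf$id_b)), roster$id)
  if (length(unknown) > 0L) {
    stop("focal sessions reference id(s) not in roster: ",
         paste(unknown, collapse = ", "))
  }
  sessions <- data.frame(
    session_id = sdf$session_id,
    pair_id = pair_key(sdf$id_a, sdf$id_b),
    id_a = pmin(sdf$id_a, sdf$id_b),
    id_b = pmax(sdf$id_a, sdf$id_b),
    date = as.Date(sdf$date),
    clock_start = clock_to_seconds(sdf$clock_start),
    planned_seconds = as.numeric(sdf$planned_seconds),
    observed_seconds = as.numeric(sdf$observed_seconds),
    stringsAsFactors = FALSE
  )
  if (anyNA(sessions$date)) stop("unparseable session date")
  if (any(sessions$observed_seconds > sessions$planned_seconds + 1e-9)) {
    stop("observed_seconds exceeds planned_seconds for session(s): ",
         paste(sessions$session_id[sessions$observed_seconds >
           sessions$planned_seconds + 1e-9], collapse = ", "))
  }
  sessions$pauses <- lapply(sdf$pauses, parse_pauses)
  sessions$focal_schedule <- lapply(sdf$focal_schedule, parse_schedule)
  for (i in seq_len(nrow(sessions))) {
    sched <- sessions$focal_schedule[[i]]
    if (length(sched) > 0L) {
      if (abs(sum(sched) - sessions$observed_seconds[i]) > 1e-6) {
        stop("focal_schedule of session ", sessions$session_id[i],
             " does not total observed_seconds")
      }
      bad <- setdiff(names(sched),
                     c(sessions$id_a[i], sessions$id_b[i]))
      if (length(bad) > 0L) {
        stop("focal_schedule of session ", sessions$session_id[i],
             " names non-member id(s): ", paste(bad, collapse = ", "))
      }
    }
  }

  edf <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  e_required <- c("session_id", "t_start", "t_end", "behavior", "actor",
                  "receiver", "modifiers", "out_of_sight")
  miss <- setdiff(e_required, names(edf))
  if (length(miss) > 0L) {
    stop("focal event table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  events <- data.frame(
    session_id = edf$session_id,
    t_start = as.numeric(edf$t_start),
    t_end = as.numeric(edf$t_end),
    behavior = edf$behavior,
    actor = ifelse(nzchar(edf$actor), edf$actor, NA_character_),
    receiver = ifelse(nzchar(edf$receiver), edf$receiver, NA_character_),
    modifiers = edf$modifiers,
    out_of_sight = as.logical(edf$out_of_sight),
    stringsAsFactors = FALSE
  )
  if (nrow(events) > 0L) {
    validate_focal_events(events, sessions, catalog, events_path)
    events <- events[order(events$session_id, events$t_start, events$t_end), ]
    rownames(events) <- NULL
  }
  list(sessions = sessions, events = events)
}

validate_focal_events <- function(events, sessions, catalog, path = "events") {
  lines <- seq_len(nrow(events)) + 1L
  orphan <- which(!events$session_id %in% sessions$session_id)
  if (length(orphan) > 0L) {
    row_error(path, lines[orphan[1L]],
              paste0("event references unknown session '",
                     events$session_id[orphan[1L]], "'"))
  }
  idx <- match(events$session_id, sessions$session_id)
  planned <- sessions$planned_seconds[idx]
  unknown_b <- which(!events$behavior %in% catalog$behaviors$code &
                       !events$out_of_sight)
  if (length(unknown_b) > 0L) {
    row_error(path, lines[unknown_b[1L]],
              paste0("behavior '", events$behavior[unknown_b[1L]],
                     "' not in catalog"))
  }
  bad_t <- which(events$t_start < 0 | events$t_end < events$t_start)
  if (length(bad_t) > 0L) {
    row_error(path, lines[bad_t[1L]],
              "event interval must satisfy 0 <= t_start <= t_end")
  }
  over <- which(events$t_end > planned + 1e-9)
  if (length(over) > 0L) {
    row_error(path, lines[over[1L]],
              "t_end exceeds the session's planned length")
  }
  beh <- ifelse(events$out_of_sight, NA_character_, events$behavior)
  mode <- behavior_mode(catalog, beh)
  bad_event <- which(!events$out_of_sight & mode == "event" &
                       events$t_end != events$t_start)
  if (length(bad_event) > 0L) {
    row_error(path, lines[bad_event[1L]],
              "instantaneous (event-mode) behaviors must have t_end == t_start")
  }
  bad_state <- which(!events$out_of_sight & mode == "state" &
                       events$t_end <= events$t_start)
  if (length(bad_state) > 0L) {
    row_error(path, lines[bad_state[1L]],
              "state behaviors must have t_end > t_start")
  }
  for (i in seq_len(nrow(events))) {
    if (events$out_of_sight[i]) next
    mods <- strsplit(events$modifiers[i], ";", fixed = TRUE)[[1L]]
    mods <- mods[nzchar(mods)]
    bad <- setdiff(mods, allowed_modifiers(catalog, events$behavior[i]))
    if (length(bad) > 0L) {
      row_error(path, lines[i],
                paste0("modifier '", bad[1L], "' not allowed on behavior '",
                       events$behavior[i], "'"))
    }
    if (behavior_directional(catalog, events$behavior[i])) {
      if (is.na(events$actor[i]) || is.na(events$receiver[i])) {
        row_error(path, lines[i],
                  paste0("directional behavior '", events$behavior[i],
                         "' requires actor and receiver"))
      }
      members <- c(sessions$id_a[idx[i]], sessions$id_b[idx[i]])
      if (!all(c(events$actor[i], events$receiver[i]) %in% members)) {
        row_error(path, lines[i],
                  "actor/receiver must belong to the session's pair")
      }
    }
  }
  invisible(TRUE)
}

#' Write a focal log (session headers and events)
#'
#' @param focal List with `sessions` and `events` as returned by
#'   [read_focal_log()].
#' @param sessions_path,events_path Output paths.
#' @return Invisibly, `c(sessions_path, events_path)`.
#' @export
write_focal_log <- function(focal, sessions_path, events_path) {
  s <- focal$sessions
  out_s <- data.frame(
    session_id = s$session_id, id_a = s$id_a, id_b = s$id_b,
    date = s$date, clock_start = seconds_to_clock(s$clock_start),
    planned_seconds = s$planned_seconds,
    observed_seconds = s$observed_seconds,
    pauses = vapply(s$pauses, format_pauses, ""),
    focal_schedule = vapply(s$focal_schedule, format_schedule, ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out_s, sessions_path, row.names = FALSE, quote = FALSE)
  e <- focal$events
  out_e <- data.frame(
    session_id = e$session_id, t_start = e$t_start, t_end = e$t_end,
    behavior = e$behavior,
    actor = ifelse(is.na(e$actor), "", e$actor),
    receiver = ifelse(is.na(e$receiver), "", e$receiver),
    modifiers = e$modifiers, out_of_sight = e$out_of_sight,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out_e, events_path, row.names = FALSE, quote = FALSE)
  invisible(c(sessions_path, events_path))
}

# "HH:MM:SS" (or bare seconds) -> seconds since midnight, and back.
clock_to_seconds <- function(x) {
  vapply(x, function(s) {
    if (grepl(":", s, fixed = TRUE)) {
      p <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1L]])
      if (length(p) == 2L) p <- c(p, 0)
      if (length(p) != 3L || anyNA(p)) stop("unparseable clock time: ", s)
      p[1L] * 3600 + p[2L] * 60 + p[3L]
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("unparseable clock time: ", s)
      v
    }
  }, numeric(1L), USE.NAMES = FALSE)
}

seconds_to_clock <- function(x) {
  sprintf("%02d:%02d:%02d", as.integer(x %/% 3600),
          as.integer((x %% 3600) %/% 60), as.integer(round(x %% 60)))
}
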