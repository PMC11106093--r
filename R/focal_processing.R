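# Focal-session validation and per-pair duration/frequency accounting.
#
# Sessions are 20-minute (1200 s) dyadic focals, 10 min per partner. A
# session is discarded when it is shorter than 15 min (< 900 s, i.e. < 75%),
# when an out-of-sight pause resumed more than three hours after the
# session's original start, or when it duplicates an earlier session of the
# same pair on the same day (pairs are sampled once per day).

#' Classify focal sessions against the observation protocol
#'
#' @param sessions Session header table from [read_focal_log()].
#' @param min_seconds Minimum observed duration to keep a session (default
#'   900 s = 75% of 1200; the boundary itself is kept, "less than 15 min" is
#'   discarded).
#' @param resume_hours Maximum delay, from the session's original clock
#'   start, at which a paused session may resume (default 3 h, inclusive).
#' @return A data frame `session_id`, `pair_id`, `valid`, `reason`
#'   (`ok`, `too_short`, `resume_window_exceeded`, `duplicate_pair_day`),
#'   `observed_seconds`. Counts of discarded sessions are logged by reason.
#' @export
validate_sessions <- function(sessions, min_seconds = 900, resume_hours = 3) {
  n <- nrow(sessions)
  reason <- rep("ok", n)
  too_short <- sessions$observed_seconds < min_seconds
  reason[too_short] <- "too_short"
  resume_limit <- resume_hours * 3600
  late <- vapply(sessions$pauses, function(p) {
    nrow(p) > 0L && any(p[, 2L] > resume_limit)
  }, logical(1L))
  reason[reason == "ok" & late] <- "resume_window_exceeded"
  # first session of a pair-day (by clock start, then session_id) is kept
  key <- paste(sessions$pair_id, sessions$date)
  o <- order(key, sessions$clock_start, sessions$session_id)
  dup <- logical(n)
  dup[o] <- duplicated(key[o])
  reason[reason == "ok" & dup] <- "duplicate_pair_day"
  out <- data.frame(session_id = sessions$session_id,
                    pair_id = sessions$pair_id,
                    valid = reason == "ok", reason = reason,
                    observed_seconds = sessions$observed_seconds,
                    stringsAsFactors = FALSE)
  n_bad <- table(reason[reason != "ok"])
  if (length(n_bad) > 0L) {
    message("discarded sessions: ",
            paste(sprintf("%s=%d", names(n_bad), as.integer(n_bad)),
                  collapse = ", "))
  }
  out
}

#' Pair consort duration of one focal session
#'
#' PCD is the measure of the union of all time intervals during which at
#' least one consort-behaviour state (proximity, body-contact affiliations,
#' grooming, cofeeding, travel) holds. Concurrent states never double-count,
#' so PCD can never exceed the session length. Instantaneous consort events
#' (mounts) carry zero measure — the states surrounding them carry the
#' duration. Out-of-sight intervals are excluded from the union, and an
#' explicit separation event truncates any state that spans it.
#'
#' @param events Event rows of a single session, validated.
#' @param catalog An `ethogram` object.
#' @return Seconds of consort behaviour (a single non-negative number).
#' @export
compute_pcd <- function(events, catalog) {
  union_of_states(events, catalog, catalog$consort_behavior_codes)
}

# Union length of the state behaviours in `codes`, minus out-of-sight time,
# with separation events truncating spanning states.
union_of_states <- function(events, catalog, codes) {
  if (nrow(events) == 0L) return(0)
  unknown <- setdiff(unique(events$behavior[!events$out_of_sight]),
                     catalog$behaviors$code)
  if (length(unknown) > 0L) {
    stop("event references behavior not in catalog: ",
         paste(unknown, collapse = ", "))
  }
  is_state <- !events$out_of_sight &
    behavior_mode(catalog, events$behavior) == "state" &
    events$behavior %in% codes
  st <- events[which(is_state), , drop = FALSE]
  if (nrow(st) == 0L) return(0)
  starts <- st$t_start; ends <- st$t_end
  sep_cat <- catalog$behaviors$code[catalog$behaviors$category == "separation"]
  seps <- events$t_start[!events$out_of_sight &
                           events$behavior %in% sep_cat]
  for (s in seps) {
    spanning <- starts < s & ends > s
    ends[spanning] <- s
  }
  oos <- events[which(events$out_of_sight), , drop = FALSE]
  interval_union_minus(starts, ends, oos$t_start, oos$t_end)
}

#' Aggregate focal sessions and bouts into per-pair summaries
#'
#' For every pair with at least one valid session: total observation
#' duration `TOD` (sum of valid sessions' observed seconds), `PCD` (summed
#' per-session consort-state unions), mount counts per actor, total and
#' pelvic-movement mount counts, `IBC_seconds` (union of huddle/embrace
#' states) and `GR_seconds` (grooming in both directions), joined with the
#' pair's recurrence rate and days observed from the scan data. Pairs with
#' focal data but zero valid sessions are excluded with a warning.
#'
#' @param sessions,events Focal tables from [read_focal_log()].
#' @param validity Output of [validate_sessions()].
#' @param bout_summary `pair_summary` component of [segment_bouts()] (may
#'   omit pairs; their RR/days are then `NA`).
#' @param catalog An `ethogram` object.
#' @return A data frame with one row per pair: `pair_id`, `id_a`, `id_b`,
#'   `n_valid_sessions`, `TOD`, `PCD`, `mounts_a`, `mounts_b`,
#'   `total_mounts`, `pelvic_mounts`, `IBC_seconds`, `GR_seconds`,
#'   `recurrence_rate`, `days_observed`.
#' @export
aggregate_pairs <- function(sessions, events, validity, bout_summary,
                            catalog) {
  valid_ids <- validity$session_id[validity$valid]
  dropped_pairs <- setdiff(sessions$pair_id,
                           sessions$pair_id[sessions$session_id %in% valid_ids])
  if (length(dropped_pairs) > 0L) {
    warning(sprintf("excluded %d pair(s) with no valid focal session: %s",
                    length(dropped_pairs),
                    paste(dropped_pairs, collapse = ", ")), call. = FALSE)
  }
  keep <- sessions$session_id %in% valid_ids
  sess <- sessions[keep, , drop = FALSE]
  if (nrow(sess) == 0L) {
    return(data.frame(pair_id = character(0), id_a = character(0),
                      id_b = character(0), n_valid_sessions = integer(0),
                      TOD = numeric(0), PCD = numeric(0),
                      mounts_a = integer(0), mounts_b = integer(0),
                      total_mounts = integer(0), pelvic_mounts = integer(0),
                      IBC_seconds = numeric(0), GR_seconds = numeric(0),
                      recurrence_rate = integer(0), days_observed = integer(0),
                      stringsAsFactors = FALSE))
  }
  ev <- events[events$session_id %in% sess$session_id, , drop = FALSE]
  mount_codes <- catalog$behaviors$code[catalog$behaviors$category == "mount"]
  groom_codes <- catalog$behaviors$code[catalog$behaviors$category == "grooming"]
  rows <- lapply(split(sess, sess$pair_id), function(ps) {
    pid <- ps$pair_id[1L]
    pe <- ev[ev$session_id %in% ps$session_id, , drop = FALSE]
    per_session <- split(pe, factor(pe$session_id, levels = ps$session_id))
    pcd <- sum(vapply(per_session, compute_pcd, 0, catalog = catalog))
    ibc <- sum(vapply(per_session, union_of_states, 0, catalog = catalog,
                      codes = catalog$ibc_codes))
    gr <- sum(vapply(per_session, union_of_states, 0, catalog = catalog,
                     codes = groom_codes))
    mounts <- pe[!pe$out_of_sight & pe$behavior %in% mount_codes, ,
                 drop = FALSE]
    pelvic <- sum(grepl("(^|;)pelvic_movement(;|$)", mounts$modifiers))
    data.frame(
      pair_id = pid, id_a = ps$id_a[1L], id_b = ps$id_b[1L],
      n_valid_sessions = nrow(ps),
      TOD = sum(ps$observed_seconds), PCD = pcd,
      mounts_a = sum(mounts$actor == ps$id_a[1L], na.rm = TRUE),
      mounts_b = sum(mounts$actor == ps$id_b[1L], na.rm = TRUE),
      total_mounts = nrow(mounts), pelvic_mounts = pelvic,
      IBC_seconds = ibc, GR_seconds = gr,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  i <- match(out$pair_id, bout_summary$pair_id)
  out$recurrence_rate <- bout_summary$recurrence_rate[i]
  out$days_observed <- bout_summary$days_observed[i]
  stopifnot(all(out$PCD <= out$TOD + 1e-9),
            all(out$IBC_seconds <= out$PCD + 1e-9),
            all(out$GR_seconds <= out$PCD + 1e-9),
            all(out$pelvic_mounts <= out$total_mounts))
  out
}
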