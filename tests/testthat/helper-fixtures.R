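# Fixture builders and independent oracles shared across the suite.

ORIGIN <- as.Date("2020-01-01")

mk_roster <- function(n_f = 6, n_m = 4, f_age = 8, m_age = 10) {
  ids_f <- sprintf("F%02d", seq_len(n_f))
  ids_m <- sprintf("M%02d", seq_len(n_m))
  df <- data.frame(
    id = c(ids_f, ids_m),
    sex = c(rep("F", n_f), rep("M", n_m)),
    age_years = c(rep(f_age, n_f), rep(m_age, n_m)),
    matriline = "mat01",
    reproductive_status = c(rep("parous", n_f), rep("not_applicable", n_m)),
    sterilized = FALSE,
    stringsAsFactors = FALSE)
  df$mature <- is_mature(df$sex, df$age_years)
  df$age_class <- age_class(df$sex, df$age_years)
  df
}

# Scan records for one pair, in the shape read_scan_log() returns.
mk_scans <- function(days, a = "F01", b = "F02", mount = TRUE, vd = FALSE,
                     type = "FF") {
  n <- length(days)
  data.frame(
    date = ORIGIN + days - 1,
    id_a = rep(pmin(a, b), n), id_b = rep(pmax(a, b), n),
    pair_id = rep(pair_key(a, b), n), pair_type = rep(type, n),
    mount_observed = rep_len(mount, n),
    vd_contact_observed = rep_len(vd, n),
    stringsAsFactors = FALSE)
}

mk_session <- function(sid = "S1", a = "F01", b = "F02",
                       date = ORIGIN, observed = 1200, planned = 1200,
                       clock = 9 * 3600,
                       pauses = matrix(numeric(0), ncol = 2)) {
  s <- data.frame(session_id = sid, pair_id = pair_key(a, b),
                  id_a = pmin(a, b), id_b = pmax(a, b), date = date,
                  clock_start = clock, planned_seconds = planned,
                  observed_seconds = observed, stringsAsFactors = FALSE)
  s$pauses <- list(pauses)
  s$focal_schedule <- list(stats::setNames(c(observed / 2, observed / 2),
                                           c(pmin(a, b), pmax(a, b))))
  s
}

mk_event <- function(sid, behavior, t0, t1 = t0, actor = NA_character_,
                     receiver = NA_character_, modifiers = "",
                     oos = FALSE) {
  data.frame(session_id = sid, t_start = t0, t_end = t1,
             behavior = behavior, actor = actor, receiver = receiver,
             modifiers = modifiers, out_of_sight = oos,
             stringsAsFactors = FALSE)
}

mk_events <- function(...) do.call(rbind, list(...))

# Brute-force segmentation oracle: enumerate every assignment of cuts
# between adjacent sighting dates, keep those where every within-bout gap
# has <= `gap` intervening days and every cut has >= gap + 1; asserts the
# valid assignment is unique.
brute_segment <- function(days, gap = 3) {
  days <- sort(unique(days))
  k <- length(days)
  if (k == 1L) return(list(days))
  d <- diff(days)
  valid <- NULL
  for (mask in 0:(2^(k - 1L) - 1L)) {
    cut <- bitwAnd(mask, bitwShiftL(1L, 0:(k - 2L))) > 0L
    if (all(d[cut] >= gap + 2) && all(d[!cut] <= gap + 1)) {
      if (!is.null(valid)) stop("segmentation not unique for ",
                                paste(days, collapse = ","))
      valid <- cut
    }
  }
  if (is.null(valid)) stop("no valid segmentation for ",
                           paste(days, collapse = ","))
  unname(split(days, cumsum(c(0, valid))))
}

# 1-second discretization oracle for the consort-duration interval union
# (exact on integer-second fixtures). Bin i covers [i-1, i).
pcd_bins_oracle <- function(events, catalog, L = 1200) {
  state_codes <- catalog$behaviors$code[catalog$behaviors$mode == "state"]
  bins <- rep(FALSE, L)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$out_of_sight) next
    if (!(e$behavior %in% catalog$consort_behavior_codes)) next
    if (!(e$behavior %in% state_codes)) next
    if (e$t_end > e$t_start) bins[(e$t_start + 1):e$t_end] <- TRUE
  }
  for (i in which(events$out_of_sight)) {
    e <- events[i, ]
    if (e$t_end > e$t_start) bins[(e$t_start + 1):e$t_end] <- FALSE
  }
  sum(bins)
}

# Random integer-second event fixture for one session.
random_event_fixture <- function(sid = "S1", catalog, L = 1200) {
  states <- c("proximity_3m", "groom", "huddle", "embrace", "contact_sit",
              "cofeed")
  rows <- list()
  for (j in seq_len(sample(0:8, 1L))) {
    beh <- sample(states, 1L)
    t0 <- sample(0:(L - 2L), 1L)
    t1 <- min(L, t0 + sample(1:400, 1L))
    dir <- beh == "groom"
    rows[[length(rows) + 1L]] <- mk_event(
      sid, beh, t0, t1,
      actor = if (dir) "F01" else NA_character_,
      receiver = if (dir) "F02" else NA_character_)
  }
  for (j in seq_len(sample(0:3, 1L))) {
    tm <- sample(0:L, 1L)
    rows[[length(rows) + 1L]] <- mk_event(
      sid, "mount", tm, tm, actor = "F01", receiver = "F02",
      modifiers = if (stats::runif(1) < 0.5) "pelvic_movement" else "")
  }
  if (stats::runif(1) < 0.4) {
    t0 <- sample(0:(L - 2L), 1L)
    t1 <- min(L, t0 + sample(1:300, 1L))
    rows[[length(rows) + 1L]] <- mk_event(sid, "", t0, t1, oos = TRUE)
  }
  if (length(rows) == 0L) {
    return(mk_event(sid, "mount", 1, 1, actor = "F01", receiver = "F02")[0, ])
  }
  do.call(rbind, rows)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
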