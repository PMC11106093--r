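# Seeded synthetic mating-season generator.
#
# Emulates the observational design the analysis assumes: a roster of ~76
# mature females and ~49 mature males, a 126-day season with a 12-day
# mid-season observation break, female-female consort pairs whose latent
# pair-bond strength couples intensive body contact to bout duration and
# recurrence, daily scan sightings with imperfect detection, and one
# 20-minute focal session per detected pair-day. Ground truth (bonds and
# bout schedules) is returned separately and is never read by the analysis.

#' Configuration for the synthetic season generator
#'
#' Defaults are the "effect" preset: the latent bond drives intensive body
#' contact, bout length and re-consort hazard, while mounting, pelvic
#' movement, reciprocity and grooming are bond-independent, so the
#' qualitative correlation pattern of the study (IBC correlated with
#' stability, M/PM/MR/GR not) is recoverable by the pipeline.
#' `preset = "null"` zeroes the three couplings for type-I-error
#' calibration.
#'
#' @param seed Integer RNG seed; the same config gives a bit-identical
#'   corpus.
#' @param preset `"effect"` (default) or `"null"`.
#' @param n_females,n_males Mature roster sizes.
#' @param season_days Length of the season in calendar days.
#' @param blackout_days Days (1-based) with no observation (default a
#'   12-day mid-season block, the holiday closure).
#' @param n_ff_pairs Number of female-female consort pairs.
#' @param n_ff_pool Number of homosexually active females the pairs are
#'   drawn from.
#' @param coupling_ibc Slope of the per-session IBC rate in the bond.
#' @param ibc_base_rate,ibc_session_sd Baseline IBC fraction of a session
#'   and its per-session noise SD.
#' @param coupling_duration Extra expected bout days at bond = 1.
#' @param base_bout_len Expected bout length (days) at bond = 0.
#' @param coupling_recurrence,base_recurrence Daily re-consort hazard slope
#'   and intercept after a bout ends.
#' @param min_rejoin_gap Minimum clear days before a pair can re-consort
#'   (keeps true bouts separable under the gap rule even when trailing and
#'   leading contact-sitting days are observed).
#' @param first_start_frac Fraction of the season within which a pair's
#'   first bout starts (early starts leave room for recurrence).
#' @param mount_rate Expected mounts per full 1200 s session.
#' @param pelvic_prob Probability a mount carries pelvic movement.
#' @param reciprocity_conc Concentration of the symmetric Beta actor-share
#'   distribution (small = one-sided pairs common).
#' @param detection_prob Probability a pair-day in consort is sighted.
#' @param invalid_frac Fraction of focal sessions made invalid (half too
#'   short, half resumed too late) to exercise protocol validation.
#' @param vd_ext_prob Probability a ventro-dorsal-contact-only sighting is
#'   recorded on the day before/after a bout.
#' @param vd_flag_prob Probability a mount day also records vd contact.
#' @param gr_mean_rate,gr_sd_rate Grooming fraction of a session (mean, SD),
#'   bond-independent.
#' @param prox_cover Range of the 3 m proximity state's session coverage.
#' @param hetero_background Generate male-female scan records as background
#'   for the activity/demographic analyses.
#' @param hetero_partner_rate Mean number of male partners per female (scaled
#'   by reproductive-status multipliers).
#' @param status_mult_hetero,status_mult_homo Named activity multipliers by
#'   reproductive status.
#' @param start_date Calendar date of season day 1.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             preset = c("effect", "null"),
                             n_females = 76L, n_males = 49L,
                             season_days = 126L,
                             blackout_days = 86:97,
                             n_ff_pairs = 26L, n_ff_pool = 35L,
                             coupling_ibc = 0.30,
                             ibc_base_rate = 0.03,
                             ibc_session_sd = 0.02,
                             coupling_duration = 2,
                             base_bout_len = 1.5,
                             coupling_recurrence = 0.30,
                             base_recurrence = 0.005,
                             min_rejoin_gap = 7L,
                             first_start_frac = 0.1,
                             mount_rate = 10,
                             pelvic_prob = 0.5,
                             reciprocity_conc = 2,
                             detection_prob = 0.98,
                             invalid_frac = 0.05,
                             vd_ext_prob = 0.25,
                             vd_flag_prob = 0.3,
                             gr_mean_rate = 0.12,
                             gr_sd_rate = 0.06,
                             prox_cover = c(0.55, 0.95),
                             hetero_background = TRUE,
                             hetero_partner_rate = 5,
                             status_mult_hetero = c(nulliparous = 1,
                                                    parous = 1,
                                                    lactating = 0.25,
                                                    menopausal_like = 0.15),
                             status_mult_homo = c(nulliparous = 1,
                                                  parous = 1,
                                                  lactating = 0.5,
                                                  menopausal_like = 0.4),
                             start_date = as.Date("2019-09-26")) {
  preset <- match.arg(preset)
  if (preset == "null") {
    coupling_ibc <- 0; coupling_duration <- 0; coupling_recurrence <- 0
  }
  cfg <- list(seed = as.integer(seed), preset = preset,
              n_females = as.integer(n_females),
              n_males = as.integer(n_males),
              season_days = as.integer(season_days),
              blackout_days = as.integer(blackout_days),
              n_ff_pairs = as.integer(n_ff_pairs),
              n_ff_pool = as.integer(n_ff_pool),
              coupling_ibc = coupling_ibc, ibc_base_rate = ibc_base_rate,
              ibc_session_sd = ibc_session_sd,
              coupling_duration = coupling_duration,
              base_bout_len = base_bout_len,
              coupling_recurrence = coupling_recurrence,
              base_recurrence = base_recurrence,
              min_rejoin_gap = as.integer(min_rejoin_gap),
              first_start_frac = first_start_frac,
              mount_rate = mount_rate, pelvic_prob = pelvic_prob,
              reciprocity_conc = reciprocity_conc,
              detection_prob = detection_prob,
              invalid_frac = invalid_frac,
              vd_ext_prob = vd_ext_prob, vd_flag_prob = vd_flag_prob,
              gr_mean_rate = gr_mean_rate, gr_sd_rate = gr_sd_rate,
              prox_cover = prox_cover,
              hetero_background = isTRUE(hetero_background),
              hetero_partner_rate = hetero_partner_rate,
              status_mult_hetero = status_mult_hetero,
              status_mult_homo = status_mult_homo,
              start_date = start_date)
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  probs <- c(cfg$pelvic_prob, cfg$detection_prob, cfg$invalid_frac,
             cfg$vd_ext_prob, cfg$vd_flag_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_females <= 0L) stop("n_females must be positive")
  if (cfg$n_males <= 0L) stop("n_males must be positive")
  if (cfg$season_days < 2L) stop("season_days must be at least 2")
  if (cfg$n_ff_pairs <= 0L) stop("n_ff_pairs must be positive")
  if (cfg$n_ff_pool > cfg$n_females) {
    stop("n_ff_pool cannot exceed n_females")
  }
  if (choose(cfg$n_ff_pool, 2L) < cfg$n_ff_pairs) {
    stop("n_ff_pool too small for the requested number of pairs")
  }
  neg <- c(cfg$coupling_ibc, cfg$coupling_duration, cfg$coupling_recurrence,
           cfg$base_recurrence, cfg$mount_rate)
  if (any(neg < 0)) stop("rates and couplings must be non-negative")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic population roster
#'
#' Females are composed to match the study demography at the default sizes:
#' ~10 adolescents (3.5-5 y, nulliparous) and ~66 adults, with a
#' reproductive-status mix of ~12 nulliparous, ~52 parous, ~7 lactating and
#' ~5 menopausal-like females (aged at least 26); parous females are
#' sterilized (the facility's population-control practice), all others are
#' intact. Other roster sizes scale the mix proportionally.
#'
#' @param config A [synthetic_config()].
#' @return A roster data frame in the shape of [read_roster()]'s output.
#' @export
generate_roster <- function(config) {
  config <- validate_synthetic_config(unclass(config))
  set.seed(config$seed)
  nf <- config$n_females
  # scale the default 10/2/52/7/5 composition of 76 females
  n_menop <- max(1L, round(nf * 5 / 76))
  n_lact <- max(1L, round(nf * 7 / 76))
  n_adol <- max(1L, round(nf * 10 / 76))
  n_nulli_ad <- max(0L, round(nf * 2 / 76))
  n_parous <- nf - n_menop - n_lact - n_adol - n_nulli_ad
  if (n_parous < 0L) stop("n_females too small for the status composition")
  status <- c(rep("nulliparous", n_adol + n_nulli_ad),
              rep("parous", n_parous), rep("lactating", n_lact),
              rep("menopausal_like", n_menop))
  ages <- c(round(stats::runif(n_adol, 3.5, 5), 1),
            round(stats::runif(n_nulli_ad, 5, 7), 1),
            round(stats::runif(n_parous, 5, 25), 1),
            round(stats::runif(n_lact, 6, 20), 1),
            round(stats::runif(n_menop, 26, 28), 1))
  n_matrilines <- 17L
  mat_weights <- c(rep(5, 11L), rep(1, n_matrilines - 11L))
  females <- data.frame(
    id = sprintf("F%02d", seq_len(nf)),
    sex = "F",
    age_years = ages,
    matriline = sprintf("mat%02d", sample(n_matrilines, nf, replace = TRUE,
                                          prob = mat_weights)),
    reproductive_status = status,
    sterilized = status == "parous",
    stringsAsFactors = FALSE)
  males <- data.frame(
    id = sprintf("M%02d", seq_len(config$n_males)),
    sex = "M",
    age_years = round(stats::runif(config$n_males, 4.5, 25), 1),
    matriline = sprintf("mat%02d", sample(n_matrilines, config$n_males,
                                          replace = TRUE,
                                          prob = mat_weights)),
    reproductive_status = "not_applicable",
    sterilized = FALSE,
    stringsAsFactors = FALSE)
  roster <- rbind(females, males)
  roster$mature <- is_mature(roster$sex, roster$age_years)
  roster$age_class <- age_class(roster$sex, roster$age_years)
  roster
}

# Simulate one pair's true bout schedule on the observation calendar.
# Returns a data frame (start, end) of whole-day bouts; bouts never touch
# blackout days and consecutive bouts are separated by >= min_rejoin_gap
# clear days, so the gap rule recovers the partition exactly.
simulate_bout_schedule <- function(b, config) {
  season <- config$season_days
  blackout <- config$blackout_days
  mean_len <- config$base_bout_len + config$coupling_duration * b
  hazard <- config$base_recurrence + config$coupling_recurrence * b
  first_window <- setdiff(seq_len(max(2L, floor(season *
    (config$first_start_frac %||% 0.3)))), blackout)
  start <- sample(first_window, 1L)
  starts <- integer(0); ends <- integer(0)
  repeat {
    len <- 1L + stats::rgeom(1L, prob = min(1, 1 / mean_len))
    days <- seq(start, min(start + len - 1L, season))
    cut <- which(days %in% blackout)
    if (length(cut) > 0L) days <- days[seq_len(min(cut) - 1L)]
    starts <- c(starts, days[1L]); ends <- c(ends, days[length(days)])
    day <- ends[length(ends)] + config$min_rejoin_gap
    start <- NA_integer_
    while (day <= season) {
      if (!(day %in% blackout) && stats::runif(1L) < hazard) {
        start <- day; break
      }
      day <- day + 1L
    }
    if (is.na(start)) break
  }
  data.frame(start = starts, end = ends)
}

#' Generate a full synthetic season
#'
#' Produces the three observation tables the pipeline consumes — scan
#' records, focal session headers and focal events — plus the generator's
#' ground truth. Per female-female pair a latent bond strength is drawn;
#' bout lengths are geometric with mean increasing in the bond, re-consort
#' hazard increases in the bond, per-session intensive-body-contact seconds
#' increase in the bond, and mounting, pelvic movement, actor shares and
#' grooming are bond-independent. Each detected pair-day yields one scan
#' record and one focal session; a configurable fraction of sessions is
#' made invalid. Ventro-dorsal-contact-only sightings are added on days
#' adjacent to bouts. Optionally, male-female scan records are generated as
#' background, with reproductive-status-dependent activity.
#'
#' @param config A [synthetic_config()].
#' @param roster Roster from [generate_roster()] (or compatible).
#' @return A list with `scans`, `sessions`, `events` (pipeline inputs),
#'   `ground_truth` (never read by the analysis) and `config`.
#' @export
generate_season <- function(config, roster) {
  config <- validate_synthetic_config(unclass(config))
  set.seed(config$seed + 1L)
  females <- roster[roster$sex == "F" & roster$mature, , drop = FALSE]
  males <- roster[roster$sex == "M" & roster$mature, , drop = FALSE]
  if (nrow(females) < 2L) {
    stop("roster must contain at least two mature females")
  }

  day_to_date <- function(day) config$start_date + day - 1L

  # --- female-female pairs -------------------------------------------------
  w_homo <- config$status_mult_homo[females$reproductive_status]
  w_homo[is.na(w_homo)] <- 1
  pool <- sample(females$id, min(config$n_ff_pool, nrow(females)),
                 prob = w_homo)
  combos <- utils::combn(sort(pool), 2L)
  sel <- sample(ncol(combos), config$n_ff_pairs)
  ff_pairs <- data.frame(id_a = combos[1L, sel], id_b = combos[2L, sel],
                         stringsAsFactors = FALSE)
  ff_pairs$pair_id <- pair_key(ff_pairs$id_a, ff_pairs$id_b)
  ff_pairs$bond <- stats::runif(nrow(ff_pairs))
  ff_pairs$actor_share_a <- stats::rbeta(nrow(ff_pairs),
                                         config$reciprocity_conc,
                                         config$reciprocity_conc)

  # chunked accumulation as parallel vectors; data frames are built once
  scan_chunks <- list(); sess_chunks <- list(); ev_chunks <- list()
  gt_bout_chunks <- list()
  pauses_list <- list(); sched_list <- list()
  session_counter <- 0L

  for (i in seq_len(nrow(ff_pairs))) {
    p <- ff_pairs[i, ]
    sched <- simulate_bout_schedule(p$bond, config)
    for (k in seq_len(nrow(sched))) {
      bout_days <- seq(sched$start[k], sched$end[k])
      # ventro-dorsal-contact-only sightings flanking the bout
      vd_days <- integer(0)
      for (cand in c(sched$start[k] - 1L, sched$end[k] + 1L)) {
        if (cand >= 1L && cand <= config$season_days &&
            !(cand %in% config$blackout_days) &&
            stats::runif(1L) < config$vd_ext_prob) {
          vd_days <- c(vd_days, cand)
        }
      }
      gt_bout_chunks[[length(gt_bout_chunks) + 1L]] <- list(
        pair_id = p$pair_id, bout_index = k,
        start_day = min(c(bout_days, vd_days)),
        end_day = max(c(bout_days, vd_days)),
        n_days = length(bout_days) + length(vd_days))
      detected <- bout_days[stats::runif(length(bout_days)) <=
                              config$detection_prob]
      vd_detected <- vd_days[stats::runif(length(vd_days)) <=
                               config$detection_prob]
      nd <- length(detected); nv <- length(vd_detected)
      if (nd + nv > 0L) {
        scan_chunks[[length(scan_chunks) + 1L]] <- list(
          day = c(detected, vd_detected),
          id_a = rep(p$id_a, nd + nv), id_b = rep(p$id_b, nd + nv),
          pair_type = rep("FF", nd + nv),
          mount = c(rep(TRUE, nd), rep(FALSE, nv)),
          vd = c(stats::runif(nd) < config$vd_flag_prob, rep(TRUE, nv)))
      }
      # one focal session per detected mount day
      for (d in detected) {
        session_counter <- session_counter + 1L
        sid <- sprintf("S%05d", session_counter)
        invalid_type <- "none"
        if (stats::runif(1L) < config$invalid_frac) {
          invalid_type <- sample(c("short", "late_resume"), 1L)
        }
        observed <- if (invalid_type == "short")
          round(stats::runif(1L, 300, 880)) else 1200
        pauses <- matrix(numeric(0), ncol = 2L)
        if (invalid_type == "late_resume") {
          pauses <- matrix(c(600, 10800 + round(stats::runif(1L, 60, 1800))),
                           ncol = 2L)
        } else if (stats::runif(1L) < 0.1) {
          pauses <- matrix(c(600, 600 + round(stats::runif(1L, 120, 3600))),
                           ncol = 2L)
        }
        ibc_rate <- max(0, config$ibc_base_rate +
                          config$coupling_ibc * p$bond +
                          stats::rnorm(1L, 0, config$ibc_session_sd))
        sess_chunks[[session_counter]] <- list(
          session_id = sid, pair_id = p$pair_id, id_a = p$id_a,
          id_b = p$id_b, day = d,
          clock_start = 9 * 3600 + round(stats::runif(1L, 0, 6 * 3600)),
          observed = observed, bond = p$bond, ibc_rate_true = ibc_rate,
          invalid_type = invalid_type)
        pauses_list[[session_counter]] <- pauses
        sched_list[[session_counter]] <-
          stats::setNames(c(observed / 2, observed / 2), c(p$id_a, p$id_b))
        ev_chunks[[session_counter]] <- make_session_events(
          sid, p$id_a, p$id_b, observed, ibc_rate, p$actor_share_a, config)
      }
    }
  }

  # --- male-female background sightings ------------------------------------
  if (config$hetero_background && nrow(males) > 0L) {
    obs_days <- setdiff(seq_len(config$season_days), config$blackout_days)
    for (i in seq_len(nrow(females))) {
      mult <- config$status_mult_hetero[females$reproductive_status[i]]
      if (is.na(mult)) mult <- 1
      n_part <- stats::rpois(1L, config$hetero_partner_rate * mult)
      if (n_part == 0L) next
      partners <- sample(males$id, min(n_part, nrow(males)))
      for (m in partners) {
        n_bouts <- 1L + stats::rpois(1L, 0.2)
        for (k in seq_len(n_bouts)) {
          start <- sample(obs_days, 1L)
          len <- 1L + stats::rpois(1L, 0.8)
          days <- intersect(seq(start, min(start + len - 1L,
                                           config$season_days)), obs_days)
          days <- days[stats::runif(length(days)) <= config$detection_prob]
          if (length(days) == 0L) next
          nd <- length(days)
          scan_chunks[[length(scan_chunks) + 1L]] <- list(
            day = days,
            id_a = rep(pmin(females$id[i], m), nd),
            id_b = rep(pmax(females$id[i], m), nd),
            pair_type = rep("MF", nd),
            mount = rep(TRUE, nd),
            vd = stats::runif(nd) < 0.15)
        }
      }
    }
  }

  if (length(scan_chunks) == 0L) {
    stop("no scan records generated; check detection_prob and pair settings")
  }
  pull <- function(chunks, field) unlist(lapply(chunks, `[[`, field),
                                         use.names = FALSE)
  scans <- data.frame(
    date = day_to_date(pull(scan_chunks, "day")),
    id_a = pull(scan_chunks, "id_a"), id_b = pull(scan_chunks, "id_b"),
    pair_type = pull(scan_chunks, "pair_type"),
    mount_observed = pull(scan_chunks, "mount"),
    vd_contact_observed = pull(scan_chunks, "vd"),
    stringsAsFactors = FALSE)
  scans$pair_id <- pair_key(scans$id_a, scans$id_b)
  # one record per (pair, date): collapse duplicates with OR of flags
  key <- paste(scans$pair_id, scans$date)
  scans$mount_observed <- as.logical(
    stats::ave(scans$mount_observed, key, FUN = any))
  scans$vd_contact_observed <- as.logical(
    stats::ave(scans$vd_contact_observed, key, FUN = any))
  scans <- scans[!duplicated(key), , drop = FALSE]
  scans <- scans[order(scans$pair_id, scans$date),
                 c("date", "id_a", "id_b", "pair_id", "pair_type",
                   "mount_observed", "vd_contact_observed")]
  rownames(scans) <- NULL

  if (session_counter > 0L) {
    sessions <- data.frame(
      session_id = pull(sess_chunks, "session_id"),
      pair_id = pull(sess_chunks, "pair_id"),
      id_a = pull(sess_chunks, "id_a"), id_b = pull(sess_chunks, "id_b"),
      date = day_to_date(pull(sess_chunks, "day")),
      clock_start = pull(sess_chunks, "clock_start"),
      planned_seconds = 1200,
      observed_seconds = pull(sess_chunks, "observed"),
      stringsAsFactors = FALSE)
    sessions$pauses <- pauses_list
    sessions$focal_schedule <- sched_list
    events <- data.frame(
      session_id = pull(ev_chunks, "session_id"),
      t_start = pull(ev_chunks, "t_start"),
      t_end = pull(ev_chunks, "t_end"),
      behavior = pull(ev_chunks, "behavior"),
      actor = pull(ev_chunks, "actor"),
      receiver = pull(ev_chunks, "receiver"),
      modifiers = pull(ev_chunks, "modifiers"),
      out_of_sight = pull(ev_chunks, "out_of_sight"),
      stringsAsFactors = FALSE)
    gt_sessions <- data.frame(
      session_id = pull(sess_chunks, "session_id"),
      pair_id = pull(sess_chunks, "pair_id"),
      day = pull(sess_chunks, "day"),
      bond = pull(sess_chunks, "bond"),
      ibc_rate_true = pull(sess_chunks, "ibc_rate_true"),
      invalid_type = pull(sess_chunks, "invalid_type"),
      stringsAsFactors = FALSE)
  } else {
    sessions <- data.frame(session_id = character(0), pair_id = character(0),
                           id_a = character(0), id_b = character(0),
                           date = as.Date(character(0)),
                           clock_start = numeric(0),
                           planned_seconds = numeric(0),
                           observed_seconds = numeric(0),
                           stringsAsFactors = FALSE)
    sessions$pauses <- list(); sessions$focal_schedule <- list()
    events <- empty_events()
    gt_sessions <- data.frame(session_id = character(0),
                              pair_id = character(0), day = integer(0),
                              bond = numeric(0), ibc_rate_true = numeric(0),
                              invalid_type = character(0),
                              stringsAsFactors = FALSE)
  }

  ground_truth <- list(
    pairs = ff_pairs[, c("pair_id", "id_a", "id_b", "bond",
                         "actor_share_a")],
    bouts = data.frame(
      pair_id = pull(gt_bout_chunks, "pair_id"),
      bout_index = pull(gt_bout_chunks, "bout_index"),
      start_day = pull(gt_bout_chunks, "start_day"),
      end_day = pull(gt_bout_chunks, "end_day"),
      n_days = pull(gt_bout_chunks, "n_days"),
      stringsAsFactors = FALSE),
    sessions = gt_sessions
  )
  list(scans = scans, sessions = sessions, events = events,
       ground_truth = ground_truth, config = config)
}

empty_events <- function() {
  data.frame(session_id = character(0), t_start = numeric(0),
             t_end = numeric(0), behavior = character(0),
             actor = character(0), receiver = character(0),
             modifiers = character(0), out_of_sight = logical(0),
             stringsAsFactors = FALSE)
}

# Event stream of one focal session: a proximity state covering most of the
# session, mounts inside it (bond-independent rate, pair-specific actor
# share), one intensive-body-contact state whose length carries the bond
# signal, and one bond-independent grooming state. Returns parallel vectors
# (a list) so the caller can assemble one data frame for the whole corpus.
make_session_events <- function(sid, id_a, id_b, observed, ibc_rate,
                                share_a, config) {
  L <- observed
  frac <- stats::runif(1L, config$prox_cover[1L], config$prox_cover[2L])
  plen <- round(frac * L, 1)
  pstart <- round(stats::runif(1L, 0, L - plen), 1)
  t_start <- pstart; t_end <- pstart + plen
  behavior <- "proximity_3m"
  actor <- NA_character_; receiver <- NA_character_; modifiers <- ""
  n_mounts <- stats::rpois(1L, config$mount_rate * L / 1200)
  if (n_mounts > 0L) {
    tm <- round(sort(stats::runif(n_mounts, pstart, pstart + plen)), 1)
    actor_is_a <- stats::runif(n_mounts) < share_a
    t_start <- c(t_start, tm); t_end <- c(t_end, tm)
    behavior <- c(behavior, rep("mount", n_mounts))
    actor <- c(actor, ifelse(actor_is_a, id_a, id_b))
    receiver <- c(receiver, ifelse(actor_is_a, id_b, id_a))
    modifiers <- c(modifiers,
                   ifelse(stats::runif(n_mounts) < config$pelvic_prob,
                          "pelvic_movement", ""))
  }
  ibc_sec <- round(min(ibc_rate * L, 0.9 * L), 1)
  if (ibc_sec >= 1) {
    st <- round(stats::runif(1L, 0, L - ibc_sec), 1)
    t_start <- c(t_start, st); t_end <- c(t_end, st + ibc_sec)
    behavior <- c(behavior,
                  sample(c("huddle", "embrace"), 1L, prob = c(0.7, 0.3)))
    actor <- c(actor, NA_character_); receiver <- c(receiver, NA_character_)
    modifiers <- c(modifiers, "")
  }
  gr_sec <- round(min(max(0, stats::rnorm(1L, config$gr_mean_rate,
                                          config$gr_sd_rate)) * L,
                      0.9 * L), 1)
  if (gr_sec >= 1) {
    st <- round(stats::runif(1L, 0, L - gr_sec), 1)
    a_grooms <- stats::runif(1L) < 0.5
    t_start <- c(t_start, st); t_end <- c(t_end, st + gr_sec)
    behavior <- c(behavior, "groom")
    actor <- c(actor, if (a_grooms) id_a else id_b)
    receiver <- c(receiver, if (a_grooms) id_b else id_a)
    modifiers <- c(modifiers, "")
  }
  list(session_id = rep(sid, length(t_start)), t_start = t_start,
       t_end = t_end, behavior = behavior, actor = actor,
       receiver = receiver, modifiers = modifiers,
       out_of_sight = rep(FALSE, length(t_start)))
}

#' Write a synthetic corpus to a directory as delimited text
#'
#' Writes `roster.csv`, `scans.csv`, `focal_sessions.csv`,
#' `focal_events.csv` and `ground_truth.json` (the latter kept separate so
#' the analysis cannot accidentally consume it).
#'
#' @param season Output of [generate_season()].
#' @param roster The roster the season was generated from.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(season, roster, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roster(roster, file.path(dir, "roster.csv"))
  write_scan_log(season$scans, file.path(dir, "scans.csv"))
  write_focal_log(season, file.path(dir, "focal_sessions.csv"),
                  file.path(dir, "focal_events.csv"))
  gt <- season$ground_truth
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
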