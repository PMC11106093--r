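# Consort bout segmentation under the three-day gap rule.
#
# A consort is an association of two individuals in which at least one mount
# was observed. Sightings of the same pair stay in one ongoing bout as long
# as no more than three consecutive unobserved days separate them
# (same bout iff next_date - prev_date <= gap_days + 1); resumption after
# four or more clear days starts a new bout. Days on which the pair was only
# seen in ventro-dorsal contact sitting extend a consort when they precede or
# follow a mount day.

#' Filter ventro-dorsal-contact-only days to those that extend a consort
#'
#' A vd-contact-only sighting counts toward a consort only when it is
#' adjacent to the pair's mounting activity: the day must fall within one
#' calendar day of a provisional mount-day bout (segmented under the gap
#' rule from mount days alone), which covers both a day immediately
#' preceding/following a mount day and a day bridged between two mount days
#' of the same bout. All other vd-contact-only records are dropped (logged).
#' A retained vd-contact day participates in gap bridging downstream, so it
#' can fuse two mount-day bouts that would otherwise be separate.
#'
#' @param records Scan records as returned by [read_scan_log()]
#'   (canonicalized, one row per pair-day).
#' @param gap_days Maximum number of intervening unobserved days within one
#'   bout (default 3).
#' @return The filtered records, same columns.
#' @export
attach_vd_contact_days <- function(records, gap_days = 3) {
  if (nrow(records) == 0L) return(records)
  keep <- logical(nrow(records))
  for (pid in unique(records$pair_id)) {
    idx <- which(records$pair_id == pid)
    mount_days <- as.integer(records$date[idx][records$mount_observed[idx]])
    vd_only <- !records$mount_observed[idx]
    keep[idx[!vd_only]] <- TRUE
    if (length(mount_days) == 0L || !any(vd_only)) next
    bouts <- split_gap(sort(mount_days), gap_days)
    vd_days <- as.integer(records$date[idx][vd_only])
    ok <- vapply(vd_days, function(d) {
      any(vapply(bouts, function(b) {
        d >= min(b) - 1L && d <= max(b) + 1L
      }, logical(1L)))
    }, logical(1L))
    keep[idx[vd_only]] <- ok
  }
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf(
      "dropped %d vd-contact-only day(s) not adjacent to mounting activity",
      dropped))
  }
  records[keep, , drop = FALSE]
}

# Split a sorted integer day vector into runs with consecutive differences
# <= gap_days + 1 (i.e. at most gap_days intervening unobserved days).
split_gap <- function(days, gap_days = 3) {
  if (length(days) == 0L) return(list())
  brk <- c(FALSE, diff(days) > gap_days + 1L)
  unname(split(days, cumsum(brk)))
}

#' Segment a pair's sighting days into consort bouts
#'
#' For each pair the (filtered) sighting dates are sorted and cut wherever
#' four or more unobserved days intervene. Pairs without any mount day are
#' excluded with a warning: a consort requires at least one observed mount.
#'
#' @param records Scan records, ideally passed through
#'   [attach_vd_contact_days()] first.
#' @param gap_days Maximum intervening unobserved days within a bout.
#' @return An object of class `consort_bouts`: a list with
#'   * `bouts`: one row per bout (`pair_id`, `pair_type`, `bout_index`,
#'     `start_date`, `end_date`, `n_days`);
#'   * `bout_dates`: one row per (bout, date);
#'   * `pair_summary`: one row per pair (`pair_id`, `pair_type`,
#'     `recurrence_rate`, `days_observed`).
#' @export
segment_bouts <- function(records, gap_days = 3) {
  empty <- list(
    bouts = data.frame(pair_id = character(0), pair_type = character(0),
                       bout_index = integer(0),
                       start_date = as.Date(character(0)),
                       end_date = as.Date(character(0)), n_days = integer(0),
                       stringsAsFactors = FALSE),
    bout_dates = data.frame(pair_id = character(0), bout_index = integer(0),
                            date = as.Date(character(0)),
                            stringsAsFactors = FALSE),
    pair_summary = data.frame(pair_id = character(0), pair_type = character(0),
                              recurrence_rate = integer(0),
                              days_observed = integer(0),
                              stringsAsFactors = FALSE))
  class(empty) <- "consort_bouts"
  if (nrow(records) == 0L) return(empty)

  no_mount <- tapply(records$mount_observed, records$pair_id, function(x) !any(x))
  bad_pairs <- names(no_mount)[no_mount]
  if (length(bad_pairs) > 0L) {
    warning(sprintf(
      "excluded %d pair(s) with no mount day (vd-contact alone is not a consort): %s",
      length(bad_pairs), paste(bad_pairs, collapse = ", ")), call. = FALSE)
    records <- records[!records$pair_id %in% bad_pairs, , drop = FALSE]
    if (nrow(records) == 0L) return(empty)
  }

  bouts <- list(); bout_dates <- list(); summaries <- list()
  for (pid in unique(records$pair_id)) {
    idx <- which(records$pair_id == pid)
    ptype <- records$pair_type[idx[1L]]
    days <- sort(unique(as.integer(records$date[idx])))
    runs <- split_gap(days, gap_days)
    bouts[[pid]] <- data.frame(
      pair_id = pid, pair_type = ptype,
      bout_index = seq_along(runs),
      start_date = as.Date(vapply(runs, min, 0L), origin = "1970-01-01"),
      end_date = as.Date(vapply(runs, max, 0L), origin = "1970-01-01"),
      n_days = vapply(runs, length, 0L),
      stringsAsFactors = FALSE)
    bout_dates[[pid]] <- data.frame(
      pair_id = pid,
      bout_index = rep(seq_along(runs), lengths(runs)),
      date = as.Date(unlist(runs), origin = "1970-01-01"),
      stringsAsFactors = FALSE)
    summaries[[pid]] <- data.frame(
      pair_id = pid, pair_type = ptype,
      recurrence_rate = length(runs),
      days_observed = length(days),
      stringsAsFactors = FALSE)
  }
  out <- list(bouts = do.call(rbind, c(bouts, list(make.row.names = FALSE))),
              bout_dates = do.call(rbind, c(bout_dates,
                                            list(make.row.names = FALSE))),
              pair_summary = do.call(rbind, c(summaries,
                                              list(make.row.names = FALSE))))
  class(out) <- "consort_bouts"
  out
}

#' Per-female consort activity counts
#'
#' Counts, for every sexually mature female on the roster, the number of
#' homosexual (female-female) and heterosexual (male-female) consort bouts
#' she participates in and her numbers of distinct partners in each mode.
#' Females never sighted get zero counts — the analysis population is the
#' roster, not the sighting log. Consorts are bouts: a female in two
#' independent bouts with the same partner has two consorts but one partner.
#'
#' @param records Scan records (both FF and MF rows), as from
#'   [read_scan_log()].
#' @param roster Roster data frame.
#' @param gap_days Gap-rule parameter, see [segment_bouts()].
#' @return A data frame with one row per mature female: `id`,
#'   `homo_consorts`, `homo_partners`, `hetero_consorts`, `hetero_partners`,
#'   `total_consorts`, `total_partners`.
#' @export
consort_activity <- function(records, roster, gap_days = 3) {
  females <- roster$id[roster$sex == "F" & roster$mature]
  in_rec <- unique(c(records$id_a, records$id_b))
  f_rec <- in_rec[in_rec %in% roster$id[roster$sex == "F"]]
  missing <- setdiff(f_rec, roster$id)
  if (length(missing) > 0L) {
    stop("female id(s) in records but not roster: ",
         paste(missing, collapse = ", "))
  }
  seg <- segment_bouts(attach_vd_contact_days(records, gap_days), gap_days)
  b <- seg$bouts
  if (nrow(b) > 0L) {
    mem <- pair_members(b$pair_id)
    b$id_a <- mem[, 1L]; b$id_b <- mem[, 2L]
  }
  out <- data.frame(id = females, homo_consorts = 0L, homo_partners = 0L,
                    hetero_consorts = 0L, hetero_partners = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    f <- out$id[i]
    mine <- b[b$id_a == f | b$id_b == f, , drop = FALSE]
    if (nrow(mine) == 0L) next
    partner <- ifelse(mine$id_a == f, mine$id_b, mine$id_a)
    homo <- mine$pair_type == "FF"
    out$homo_consorts[i] <- sum(homo)
    out$homo_partners[i] <- length(unique(partner[homo]))
    out$hetero_consorts[i] <- sum(!homo)
    out$hetero_partners[i] <- length(unique(partner[!homo]))
  }
  out$total_consorts <- out$homo_consorts + out$hetero_consorts
  out$total_partners <- out$homo_partners + out$hetero_partners
  out
}
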