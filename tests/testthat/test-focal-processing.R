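test_that("session validity applies the 75% and three-hour rules exactly", {
  sessions <- rbind(
    mk_session("S1", observed = 899),                       # < 15 min
    mk_session("S2", a = "F03", b = "F04", observed = 900), # boundary kept
    mk_session("S3", a = "F05", b = "F06",
               pauses = matrix(c(600, 3 * 3600), ncol = 2)),   # resumed at 3 h
    mk_session("S4", a = "F01", b = "F03",
               pauses = matrix(c(600, 3 * 3600 + 60), ncol = 2)))
  v <- quiet(validate_sessions(sessions))
  expect_equal(v$reason, c("too_short", "ok", "ok",
                           "resume_window_exceeded"))
  expect_equal(v$valid, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("a second session for the same pair-day is discarded", {
  sessions <- rbind(
    mk_session("S1", clock = 10 * 3600),
    mk_session("S2", clock = 14 * 3600))  # same pair, same date, later
  v <- quiet(validate_sessions(sessions))
  expect_equal(v$reason[v$session_id == "S1"], "ok")
  expect_equal(v$reason[v$session_id == "S2"], "duplicate_pair_day")
})

test_that("consort duration is an interval union, not a sum of states", {
  cat <- default_ethogram()
  # overlapping proximity and grooming cover 400 s, not 600
  ev <- mk_events(
    mk_event("S1", "proximity_3m", 0, 300),
    mk_event("S1", "groom", 100, 400, "F01", "F02"))
  expect_equal(compute_pcd(ev, cat), 400)
  # disjoint states add up
  ev2 <- mk_events(mk_event("S1", "huddle", 0, 100),
                   mk_event("S1", "huddle", 200, 300))
  expect_equal(compute_pcd(ev2, cat), 200)
  # no consort behavior, no duration; mounts alone carry zero measure
  expect_equal(compute_pcd(mk_event("S1", "mount", 50, 50, "F01", "F02"),
                           cat), 0)
  expect_equal(compute_pcd(ev[0, ], cat), 0)
  # out-of-sight time is excluded from the union
  ev3 <- mk_events(mk_event("S1", "proximity_3m", 0, 600),
                   mk_event("S1", "", 100, 200, oos = TRUE))
  expect_equal(compute_pcd(ev3, cat), 500)
  # an explicit separation event truncates a spanning state
  ev4 <- mk_events(mk_event("S1", "proximity_3m", 0, 600),
                   mk_event("S1", "separation", 250, 250))
  expect_equal(compute_pcd(ev4, cat), 250)
  # unknown behavior code is an error
  expect_error(compute_pcd(mk_event("S1", "tickle", 0, 10), cat),
               "not in catalog")
})

test_that("interval union matches the 1-second discretization oracle", {
  cat <- default_ethogram()
  set.seed(403)
  for (rep in 1:120) {
    ev <- random_event_fixture("S1", cat)
    expect_equal(compute_pcd(ev, cat), pcd_bins_oracle(ev, cat))
  }
})

test_that("pair aggregation sums sessions and counts mounts by actor", {
  cat <- default_ethogram()
  sessions <- rbind(mk_session("S1"), mk_session("S2", date = ORIGIN + 1))
  events <- mk_events(
    mk_event("S1", "mount", 10, 10, "F01", "F02"),
    mk_event("S1", "mount", 20, 20, "F01", "F02", "pelvic_movement"),
    mk_event("S1", "mount", 30, 30, "F01", "F02"),
    mk_event("S1", "embrace", 0, 50),
    mk_event("S1", "huddle", 40, 90),
    mk_event("S2", "mount", 10, 10, "F02", "F01", "pelvic_movement"),
    mk_event("S2", "groom", 100, 400, "F02", "F01"))
  v <- validate_sessions(sessions)
  bouts <- segment_bouts(mk_scans(c(1, 2)))$pair_summary
  agg <- aggregate_pairs(sessions, events, v, bouts, cat)
  expect_equal(agg$TOD, 2400)
  expect_equal(agg$mounts_a, 3)   # F01 is the canonical first member
  expect_equal(agg$mounts_b, 1)
  expect_equal(agg$total_mounts, 4)
  expect_equal(agg$pelvic_mounts, 2)
  expect_equal(agg$IBC_seconds, 90)  # embrace [0,50] union huddle [40,90]
  expect_equal(agg$GR_seconds, 300)
  expect_equal(agg$recurrence_rate, 1)
  expect_equal(agg$days_observed, 2)
  expect_true(agg$PCD <= agg$TOD && agg$IBC_seconds <= agg$PCD)
})

test_that("events in invalid sessions never reach the pair summary", {
  cat <- default_ethogram()
  sessions <- rbind(mk_session("S1"),
                    mk_session("S2", date = ORIGIN + 1, observed = 400))
  events <- mk_events(
    mk_event("S1", "huddle", 0, 100),
    mk_event("S2", "huddle", 0, 400),
    mk_event("S2", "mount", 10, 10, "F01", "F02"))
  v <- quiet(validate_sessions(sessions))
  bouts <- segment_bouts(mk_scans(c(1, 2)))$pair_summary
  agg <- aggregate_pairs(sessions, events, v, bouts, cat)
  expect_equal(agg$n_valid_sessions, 1)
  expect_equal(agg$TOD, 1200)
  expect_equal(agg$IBC_seconds, 100)
  expect_equal(agg$total_mounts, 0)
  # a pair whose only session is invalid is excluded with a warning
  solo <- mk_session("S9", a = "F05", b = "F06", observed = 100)
  expect_warning(
    agg2 <- aggregate_pairs(rbind(sessions, solo), events,
                            quiet(validate_sessions(rbind(sessions, solo))),
                            bouts, cat),
    "no valid focal session")
  expect_false(pair_key("F05", "F06") %in% agg2$pair_id)
})

test_that("dropping IBC states zeroes IBC seconds but not mount counts", {
  cat <- default_ethogram()
  sessions <- mk_session("S1")
  events <- mk_events(
    mk_event("S1", "mount", 10, 10, "F01", "F02"),
    mk_event("S1", "huddle", 0, 200),
    mk_event("S1", "proximity_3m", 0, 800))
  v <- validate_sessions(sessions)
  bouts <- segment_bouts(mk_scans(1))$pair_summary
  full <- aggregate_pairs(sessions, events, v, bouts, cat)
  no_ibc <- aggregate_pairs(sessions,
                            events[events$behavior != "huddle", ],
                            v, bouts, cat)
  expect_equal(no_ibc$IBC_seconds, 0)
  expect_equal(no_ibc$total_mounts, full$total_mounts)
  expect_equal(no_ibc$PCD, 800)
})
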