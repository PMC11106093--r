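write_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("roster rows are typed, counted and age-classed", {
  path <- write_lines(c(
    "id,sex,age_years,matriline,reproductive_status,sterilized",
    "F01,F,27,mat01,parous,TRUE",
    "F02,F,4.0,mat02,nulliparous,FALSE",
    "F03,F,2.5,mat01,nulliparous,FALSE",
    "M01,M,10,mat03,not_applicable,FALSE"))
  expect_message(r <- read_roster(path), "1 mature males")
  expect_equal(nrow(r), 4)
  expect_equal(r$age_class[r$id == "F01"], "adult")      # 27 y parous
  expect_equal(r$age_class[r$id == "F02"], "adolescent")
  expect_true(is.na(r$age_class[r$id == "F03"]))         # immature
  expect_false(r$mature[r$id == "F03"])
  expect_equal(sum(r$mature & r$sex == "F"), 2)
})

test_that("roster validation locates malformed rows", {
  bad_status <- write_lines(c(
    "id,sex,age_years,matriline,reproductive_status,sterilized",
    "F01,F,8,mat01,pregnant,FALSE"))
  expect_error(read_roster(bad_status), "line 2.*pregnant")
  neg_age <- write_lines(c(
    "id,sex,age_years,matriline,reproductive_status,sterilized",
    "F01,F,8,mat01,parous,FALSE",
    "F02,F,-1,mat01,parous,FALSE"))
  expect_error(read_roster(neg_age), "line 3.*negative age")
  young_menop <- write_lines(c(
    "id,sex,age_years,matriline,reproductive_status,sterilized",
    "F01,F,20,mat01,menopausal_like,FALSE"))
  expect_error(read_roster(young_menop), "26")
  empty <- write_lines(
    "id,sex,age_years,matriline,reproductive_status,sterilized")
  expect_warning(r <- read_roster(empty), "no rows")
  expect_equal(nrow(r), 0)
})

test_that("roster round-trips through write_roster", {
  path <- write_lines(c(
    "id,sex,age_years,matriline,reproductive_status,sterilized",
    "F01,F,27,mat01,parous,TRUE",
    "M01,M,10,mat03,not_applicable,FALSE"))
  r <- quiet(read_roster(path))
  out <- withr::local_tempfile(fileext = ".csv")
  write_roster(r, out)
  r2 <- quiet(read_roster(out))
  expect_equal(r2, r)
})

test_that("scan rows canonicalize, deduplicate with OR, and validate", {
  roster <- mk_roster()
  path <- write_lines(c(
    "date,id_a,id_b,pair_type,mount_observed,vd_contact_observed",
    "2020-01-05,F02,F01,FF,TRUE,FALSE",   # reversed ids
    "2020-01-05,F01,F02,FF,FALSE,TRUE",   # duplicate pair-day
    "2020-01-06,F01,M01,MF,TRUE,FALSE"))
  expect_warning(s <- read_scan_log(path, roster), "duplicate")
  expect_equal(nrow(s), 2)
  ff <- s[s$pair_type == "FF", ]
  expect_equal(ff$id_a, "F01")
  expect_equal(ff$id_b, "F02")
  expect_true(ff$mount_observed && ff$vd_contact_observed)  # OR of flags

  mismatch <- write_lines(c(
    "date,id_a,id_b,pair_type,mount_observed,vd_contact_observed",
    "2020-01-05,F01,M01,FF,TRUE,FALSE"))
  expect_error(read_scan_log(mismatch, roster), "inconsistent")
  unknown <- write_lines(c(
    "date,id_a,id_b,pair_type,mount_observed,vd_contact_observed",
    "2020-01-05,F01,F99,FF,TRUE,FALSE"))
  expect_error(read_scan_log(unknown, roster), "F99")
  self <- write_lines(c(
    "date,id_a,id_b,pair_type,mount_observed,vd_contact_observed",
    "2020-01-05,F01,F01,FF,TRUE,FALSE"))
  expect_error(read_scan_log(self, roster), "id_a equals id_b")
  no_flag <- write_lines(c(
    "date,id_a,id_b,pair_type,mount_observed,vd_contact_observed",
    "2020-01-05,F01,F02,FF,FALSE,FALSE"))
  expect_error(read_scan_log(no_flag, roster), "requires mount_observed")
})

test_that("focal logs are validated against catalog and session pair", {
  roster <- mk_roster()
  catalog <- default_ethogram()
  sess <- write_lines(c(
    paste0("session_id,id_a,id_b,date,clock_start,planned_seconds,",
           "observed_seconds,pauses,focal_schedule"),
    "S1,F01,F02,2020-01-05,09:30:00,1200,1200,,F01:600;F02:600"))
  ev_ok <- write_lines(c(
    "session_id,t_start,t_end,behavior,actor,receiver,modifiers,out_of_sight",
    "S1,30,30,mount,F01,F02,pelvic_movement,FALSE",
    "S1,100,160,groom,F02,F01,,FALSE"))
  fl <- read_focal_log(sess, ev_ok, catalog, roster)
  expect_equal(nrow(fl$events), 2)
  expect_equal(fl$events$t_end[fl$events$behavior == "mount"], 30)
  expect_equal(fl$sessions$clock_start, 9.5 * 3600)
  expect_equal(with(fl$events[fl$events$behavior == "groom", ],
                    t_end - t_start), 60)

  bad_interval <- write_lines(c(
    "session_id,t_start,t_end,behavior,actor,receiver,modifiers,out_of_sight",
    "S1,200,150,huddle,,,,FALSE"))
  expect_error(read_focal_log(sess, bad_interval, catalog, roster),
               "line 2")
  too_long <- write_lines(c(
    "session_id,t_start,t_end,behavior,actor,receiver,modifiers,out_of_sight",
    "S1,1100,1300,huddle,,,,FALSE"))
  expect_error(read_focal_log(sess, too_long, catalog, roster),
               "planned length")
  bad_modifier <- write_lines(c(
    "session_id,t_start,t_end,behavior,actor,receiver,modifiers,out_of_sight",
    "S1,100,160,groom,F02,F01,pelvic_movement,FALSE"))
  expect_error(read_focal_log(sess, bad_modifier, catalog, roster),
               "pelvic_movement")
  outsider <- write_lines(c(
    "session_id,t_start,t_end,behavior,actor,receiver,modifiers,out_of_sight",
    "S1,30,30,mount,F03,F02,,FALSE"))
  expect_error(read_focal_log(sess, outsider, catalog, roster),
               "session's pair")
})

test_that("a focal log round-trips through write_focal_log", {
  roster <- mk_roster()
  catalog <- default_ethogram()
  sessions <- rbind(
    mk_session("S1", observed = 1200,
               pauses = matrix(c(600, 900), ncol = 2)),
    mk_session("S2", a = "F03", b = "F04", date = ORIGIN + 1,
               observed = 1000))
  events <- mk_events(
    mk_event("S1", "mount", 30, 30, "F01", "F02", "pelvic_movement"),
    mk_event("S1", "huddle", 100, 400),
    mk_event("S2", "groom", 5, 105, "F03", "F04"))
  sp <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  write_focal_log(list(sessions = sessions, events = events), sp, ep)
  back <- read_focal_log(sp, ep, catalog, roster)
  expect_equal(back$sessions$session_id, sessions$session_id)
  expect_equal(back$sessions$observed_seconds, sessions$observed_seconds)
  expect_equal(back$sessions$pauses, sessions$pauses)
  expect_equal(back$sessions$focal_schedule, sessions$focal_schedule)
  expect_equal(back$events$behavior, events$behavior)
  expect_equal(back$events$t_start, events$t_start)
  expect_equal(back$events$modifiers, events$modifiers)
})
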