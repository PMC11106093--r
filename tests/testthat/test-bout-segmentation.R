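test_that("gap-rule boundaries split exactly at four intervening days", {
  # 3 intervening unobserved days: still the same bout
  one <- segment_bouts(mk_scans(c(10, 14)))
  expect_equal(one$pair_summary$recurrence_rate, 1)
  expect_equal(one$pair_summary$days_observed, 2)
  # 4 intervening unobserved days: a new consort
  two <- segment_bouts(mk_scans(c(10, 15)))
  expect_equal(two$pair_summary$recurrence_rate, 2)
  expect_equal(two$pair_summary$days_observed, 2)
  # a single sighting is one bout of one day
  single <- segment_bouts(mk_scans(10))
  expect_equal(single$pair_summary$recurrence_rate, 1)
  expect_equal(single$pair_summary$days_observed, 1)
  expect_equal(single$bouts$start_date, single$bouts$end_date)
})

test_that("vd-contact-only days extend consorts only next to mounting", {
  # day following a mount day is retained
  recs <- rbind(mk_scans(10), mk_scans(11, mount = FALSE, vd = TRUE))
  kept <- attach_vd_contact_days(recs)
  expect_equal(nrow(kept), 2)
  # an isolated vd day ten days from any mount is dropped
  far <- rbind(mk_scans(10), mk_scans(20, mount = FALSE, vd = TRUE))
  expect_message(kept2 <- attach_vd_contact_days(far), "dropped 1")
  expect_equal(as.integer(kept2$date - ORIGIN) + 1, 10)
  # a vd day bridged inside a mount bout is retained
  mid <- rbind(mk_scans(c(10, 14)), mk_scans(12, mount = FALSE, vd = TRUE))
  expect_equal(nrow(attach_vd_contact_days(mid)), 3)
  # empty in, empty out
  expect_equal(nrow(attach_vd_contact_days(mk_scans(integer(0)))), 0)
})

test_that("a retained vd day can fuse two mount bouts via gap bridging", {
  # mounts on days 10 and 15 alone form two bouts; a vd day on 11 puts the
  # gap 11 -> 15 at three intervening days, fusing them into one consort
  recs <- rbind(mk_scans(c(10, 15)),
                mk_scans(11, mount = FALSE, vd = TRUE))
  seg <- segment_bouts(attach_vd_contact_days(recs))
  expect_equal(seg$pair_summary$recurrence_rate, 1)
  expect_equal(seg$pair_summary$days_observed, 3)
})

test_that("pairs without any mount day are excluded as non-consorts", {
  recs <- rbind(mk_scans(c(10, 11)),
                mk_scans(c(10, 11), a = "F03", b = "F04",
                         mount = FALSE, vd = TRUE))
  expect_warning(seg <- segment_bouts(recs), "no mount day")
  expect_equal(seg$pair_summary$pair_id, pair_key("F01", "F02"))
})

test_that("segmentation matches the brute-force cut enumeration oracle", {
  set.seed(401)
  for (rep in 1:80) {
    days <- sort(sample(1:40, sample(1:8, 1)))
    seg <- segment_bouts(mk_scans(days))
    oracle <- brute_segment(days)
    expect_equal(seg$pair_summary$recurrence_rate, length(oracle))
    expect_equal(seg$bouts$n_days, lengths(oracle))
    expect_equal(seg$bouts$start_date,
                 ORIGIN + vapply(oracle, min, 0) - 1)
  }
})

test_that("segmentation is order-invariant, monotone and additive", {
  set.seed(402)
  for (rep in 1:25) {
    days <- sort(sample(1:60, sample(2:12, 1)))
    recs <- mk_scans(days)
    seg <- segment_bouts(recs)
    # permutation invariance
    shuf <- recs[sample(nrow(recs)), ]
    expect_equal(segment_bouts(shuf)$pair_summary, seg$pair_summary)
    # sum rule: bout day counts total the days observed
    expect_equal(sum(seg$bouts$n_days), seg$pair_summary$days_observed)
    # monotonicity: one extra sighting never decreases days observed
    extra <- setdiff(1:60, days)[1]
    seg2 <- segment_bouts(rbind(recs, mk_scans(extra)))
    expect_gte(seg2$pair_summary$days_observed,
               seg$pair_summary$days_observed)
  }
})

test_that("per-female activity counts consorts as bouts, partners once", {
  roster <- mk_roster(n_f = 6, n_m = 4)
  recs <- rbind(
    mk_scans(c(10, 20)),                      # F01-F02: two bouts
    mk_scans(30, a = "F01", b = "F03"),       # F01-F03: one bout
    mk_scans(5, a = "F01", b = "M01", type = "MF"))
  act <- quiet(consort_activity(recs, roster))
  f1 <- act[act$id == "F01", ]
  expect_equal(f1$homo_consorts, 3)   # 2 bouts with F02 + 1 with F03
  expect_equal(f1$homo_partners, 2)
  expect_equal(f1$hetero_consorts, 1)
  expect_equal(f1$hetero_partners, 1)
  expect_equal(f1$total_consorts, 4)
  # a never-sighted female has all-zero counts but stays in the table
  f5 <- act[act$id == "F05", ]
  expect_equal(unlist(f5[, -1]), c(homo_consorts = 0, homo_partners = 0,
                                   hetero_consorts = 0, hetero_partners = 0,
                                   total_consorts = 0, total_partners = 0))
  # four distinct female partners count as four
  recs4 <- rbind(mk_scans(10), mk_scans(20, b = "F03"),
                 mk_scans(30, b = "F04"), mk_scans(40, b = "F05"))
  act4 <- quiet(consort_activity(recs4, roster))
  expect_equal(act4$homo_partners[act4$id == "F01"], 4)
})
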