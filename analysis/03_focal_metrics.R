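#!/usr/bin/env Rscript
# Stage 3 — validate focal sessions and derive the pair metric table.
#
# Applies the focal protocol rules (discard sessions under 15 min, sessions
# resumed more than 3 h after their original start, and duplicate pair-day
# sessions), aggregates per-pair durations and mount counts, and computes
# the pair-level indices: mounts per focal second (M), pelvic-movement rate
# (PM), mounting reciprocity (MR), intensive-body-contact and grooming
# rates, alongside pair consort duration (PCD), recurrence rate (RR) and
# days observed.

suppressPackageStartupMessages(library(consortr))

catalog <- default_ethogram()
roster <- read_roster("results/corpus/roster.csv")
scans <- read_scan_log("results/corpus/scans.csv", roster)
focal <- read_focal_log("results/corpus/focal_sessions.csv",
                        "results/corpus/focal_events.csv", catalog, roster)

seg <- segment_bouts(attach_vd_contact_days(scans))
validity <- validate_sessions(focal$sessions)
summary <- aggregate_pairs(focal$sessions, focal$events, validity,
                           seg$pair_summary, catalog)
metrics <- compute_metrics(summary)

write.csv(validity, "results/session_validity.csv", row.names = FALSE)
write.csv(summary, "results/pair_summary.csv", row.names = FALSE)
write.csv(metrics, "results/pair_metrics.csv", row.names = FALSE)

cat(sprintf("sessions: %d recorded, %d valid (%s)\n", nrow(validity),
            sum(validity$valid),
            paste(sprintf("%s %d", names(table(validity$reason)),
                          as.integer(table(validity$reason))),
                  collapse = ", ")))
cat(sprintf("pairs in metric table: %d\n", nrow(metrics)))
cat(sprintf("focal time per pair: mean %.1f min (range %.0f-%.0f)\n",
            mean(summary$TOD) / 60, min(summary$TOD) / 60,
            max(summary$TOD) / 60))
cat(sprintf("IBC rate: median %.3f; grooming rate: median %.3f\n",
            median(metrics$IBC_rate), median(metrics$GR_rate)))
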