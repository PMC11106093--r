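#!/usr/bin/env Rscript
# Stage 2 — segment consort bouts and count per-female activity.
#
# Reads the corpus from stage 1, keeps ventro-dorsal-contact-only days only
# where they extend mounting activity, segments each pair's sighting days
# into bouts under the three-day gap rule, and tabulates per-female
# homosexual/heterosexual consort and partner counts.

suppressPackageStartupMessages(library(consortr))

roster <- read_roster("results/corpus/roster.csv")
scans <- read_scan_log("results/corpus/scans.csv", roster)

filtered <- attach_vd_contact_days(scans)
seg <- segment_bouts(filtered)
activity <- consort_activity(scans, roster)

dir.create("results", showWarnings = FALSE)
write.csv(seg$bouts, "results/bouts.csv", row.names = FALSE)
write.csv(seg$pair_summary, "results/pair_bout_summary.csv",
          row.names = FALSE)
write.csv(activity, "results/activity.csv", row.names = FALSE)

ff <- seg$pair_summary[seg$pair_summary$pair_type == "FF", ]
recur <- ff[ff$recurrence_rate > 1, ]
cat(sprintf("pairs with consort bouts: %d FF, %d MF\n", nrow(ff),
            sum(seg$pair_summary$pair_type == "MF")))
cat(sprintf("FF pairs recurring (>1 bout): %d; recurrence rate mean %.2f (range %d-%d)\n",
            nrow(recur), mean(ff$recurrence_rate),
            min(ff$recurrence_rate), max(ff$recurrence_rate)))
cat(sprintf("females homosexually active: %d of %d (%.0f%%)\n",
            sum(activity$homo_consorts > 0), nrow(activity),
            100 * mean(activity$homo_consorts > 0)))
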