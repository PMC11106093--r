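#!/usr/bin/env Rscript
# Stage 1 — simulate one mating season.
#
# Generates the default synthetic corpus: a roster of 76 mature females and
# 49 mature males, a 126-day season with a 12-day mid-season observation
# break, 26 female-female consort pairs whose latent bond strength drives
# intensive body contact and bout stability, plus male-female background
# sightings. Writes the observation tables (and the generator's ground
# truth, which later stages never read) under results/corpus/.

suppressPackageStartupMessages(library(consortr))

cfg <- synthetic_config(seed = 20190926)
roster <- generate_roster(cfg)
season <- generate_season(cfg, roster)
write_corpus(season, roster, "results/corpus")

cat(sprintf("roster: %d mature females, %d mature males\n",
            sum(roster$sex == "F" & roster$mature),
            sum(roster$sex == "M" & roster$mature)))
cat(sprintf("scan records: %d (%d FF, %d MF pair-days)\n",
            nrow(season$scans), sum(season$scans$pair_type == "FF"),
            sum(season$scans$pair_type == "MF")))
cat(sprintf("focal sessions: %d on %d female-female pairs\n",
            nrow(season$sessions), length(unique(season$sessions$pair_id))))
cat("corpus written to results/corpus/\n")
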