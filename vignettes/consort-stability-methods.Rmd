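---
title: "Consortship stability from scan and focal sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consortship stability from scan and focal sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consortr)
```

## The scientific problem

During the mating season, Japanese macaques (*Macaca fuscata*) form
exclusive short-term sexual associations — consortships — including
female–female pairs. The question this package operationalises is whether
the *stability* of a female–female consort (how long a pair stays
together, and how often the same pair re-forms) is driven by sexual
behaviour (mounting frequency, pelvic movement, mounting reciprocity) or
by affiliative behaviour with intense body contact (huddling and
embracing), with grooming treated as a separate, lower-intensity contact
behaviour.

Two complementary observation streams feed the analysis:

* **Scan (behavioural) sampling** surveys the whole group daily and
  records, once per pair per day, which potential consort pairs were seen
  (with flags for observed mounting and for ventro-dorsal contact
  sitting). This stream yields bout structure: days observed and
  recurrence.
* **Focal sampling** follows one consorting pair for a planned 20-minute
  session (10 min per partner), recording every behaviour with start and
  end times. This stream yields true frequencies and durations.

## Consort bouts and the gap rule

A consort requires at least one observed mount. A pair's sighting days are
segmented into bouts with a three-day gap rule: two sightings belong to
the same bout when at most three unobserved days lie between them
(`next - prev <= 4` days); resumption after four or more clear days starts
a new, independent consort. The two phrasings of the rule ("no more than a
three consecutive day gap" and "after four or more days ... a new
consort") are consistent only under this reading, which
`segment_bouts()` implements and the test suite checks against a
brute-force enumeration of every possible cut assignment.

Days on which a pair was seen only in ventro-dorsal contact sitting count
toward a consort when they are adjacent to its mounting activity.
`attach_vd_contact_days()` keeps a vd-contact-only day when it falls
within one calendar day of a provisional mount-day bout (this covers both
the day immediately before/after a mount day and a day bridged between two
mount days of the same bout); retained days then take part in gap
bridging, so a kept vd-contact day can fuse two mount-day runs into one
bout. All other vd-contact-only days are dropped, and a pair with no mount
day at all is excluded: contact sitting alone is not a consort.

Per pair this produces the two stability variables of the analysis:
**days observed** (distinct sighting days across bouts) and the
**recurrence rate RR** (number of independent bouts).

## Focal protocol rules

`validate_sessions()` classifies sessions against the protocol:

* sessions observed for less than 900 s (75 % of the planned 1200 s) are
  discarded; exactly 15 minutes is kept,
* a paused session may resume up to three hours (inclusive) after its
  original clock start; later resumption invalidates the session,
* a pair is sampled once per day; a second same-day session is discarded.

One interpretation was open: whether the pause itself counts toward
observed time. Here `observed_seconds` counts observed time only, which is
the conservative reading of an out-of-sight pause.

## Duration accounting: interval unions

**Pair consort duration (PCD)** is the time a pair spends in consort, i.e.
the measure of the union of all intervals during which at least one
consort-behaviour state holds (3 m proximity, huddling, embracing, contact
sitting, grooming, cofeeding, travelling together, mutual following).
A union — not a sum of state durations — because states overlap freely
(grooming inside the proximity radius must not count twice) and because
`PCD <= TOD` must hold structurally. Instantaneous mount events carry zero
measure; the states around them carry the duration. Out-of-sight intervals
are subtracted from the union, and an explicit separation event truncates
any state spanning it, supporting both recording styles (observers who
close states on separation, and observers who log a separation marker).
`IBC_seconds` and `GR_seconds` are the same union restricted to
huddle/embrace and to grooming (both directions) respectively. The
implementation is exact interval arithmetic; tests compare it against a
one-second discretisation oracle on random fixtures, where it is exact on
integer-second inputs.

## Pair-level indices

With `TOD` the summed observed seconds of a pair's valid sessions:

* `M = total_mounts / TOD` (mounts per focal second),
* `PM = pelvic_mounts / total_mounts` (each mount scored 0/1 for pelvic
  movement), undefined without mounts,
* `MR = 100 - |pA - pB|` where `pA`, `pB` are the partners' percentage
  shares of active mounts: 100 is fully reciprocal mounting, 0 fully
  one-sided. The printed formula omits the absolute value, but the worked
  examples (50 %/50 % giving 100; 100 %/0 % giving 0) and the 0–100 range
  force the symmetric reading, which is also invariant under partner
  relabelling. Undefined without mounts,
* `IBC_rate = IBC_seconds / TOD`, `GR_rate = GR_seconds / TOD`.

Undefined `PM`/`MR` values propagate as missing and are excluded pairwise
from correlations; zero would assert complete one-sidedness, which is a
different behavioural claim than "no mounts observed". Rates stay in
native units (per second, fractions); no per-minute rescaling.

## Statistical surface

`spearman_matrix()` correlates the eight pair variables (days, RR, PCD,
MR, PM, M, IBC rate, GR rate) with average-rank Spearman coefficients and
two-sided p values, Holm-adjusted in a single family of all 28 unique
pairs. The p value uses the t approximation for `n >= 10` and a seeded
permutation test below that, where the approximation is poor. Group
comparisons use the tie-corrected Kruskal–Wallis test for three or more
groups and a Mann–Whitney test for two, reported as a standardised Z from
the tie-corrected normal approximation (the form used in the field's
reports); post-hoc pairwise Mann–Whitney tests are Holm-adjusted within
the family of group pairs of one variable, not globally. Prevalence uses
all analysed mature females as the denominator, and the access-to-males
correlations keep inactive females as zeros, so `n` equals the analysed
roster size. No regression modelling is attempted: the per-pair sample is
deliberately summarised descriptively and nonparametrically.

## The synthetic season generator

No raw observation data are distributed with the study, so the package
ships a generator (`synthetic_config()`, `generate_roster()`,
`generate_season()`) that emulates the observation design end to end and
makes every stage testable, with a serialized ground truth the analysis
never reads.

The roster reproduces the study demography at its default size: 76 mature
females (10 adolescents; 12 nulliparous, 52 parous, 7 lactating, 5
menopausal-like aged 26+) and 49 mature males, sex ratio 0.64. Parous
females are sterilized, leaving 24 reproductively intact females.

For each of 26 female–female pairs a latent bond strength `b ~ U(0, 1)` is
drawn. The bond couples three things: per-session intensive-body-contact
seconds (linear in `b` with Gaussian session noise), expected bout length
(geometric), and the daily Bernoulli hazard of re-consorting after a bout.
Mounting rate (Poisson per session), pelvic movement (Bernoulli per
mount), the pair's actor share (symmetric Beta), and grooming and
proximity coverage are bond-independent. Each pair-day is sighted with a
detection probability, yields one scan record and one focal session, and a
small fraction of sessions is made invalid (too short or resumed too late)
to exercise the protocol rules. A 12-day mid-season observation break
(the holiday closure) carries no observations, and bouts are scheduled
around it. Consecutive true bouts are separated by at least seven clear
days so that the gap rule — even after ventro-dorsal contact-sitting days
extend a bout by one day on each side — always recovers the true bout
partition; with perfect detection the recovery is exact, which the
acceptance tests assert.

Two presets define the study conditions for calibration:

* **null** (`preset = "null"`): all three couplings zero. Used for type-I
  control: across replicate seasons the Holm-adjusted IBC–days correlation
  must stay non-significant.
* **effect** (the defaults): couplings strong enough that the published
  qualitative pattern — IBC rate positively and significantly correlated
  with days, RR and PCD after Holm correction, while M, PM, MR and GR stay
  non-significant — is the modal outcome across replicate seasons of 26
  pairs.

The effect preset deliberately amplifies recurrence beyond the field
scale reported for this group (mean RR near 7 here versus 1.75 among
recurring pairs in the field, where only 8 of 31 pairs recurred at all).
This is a power consideration, chosen once at design time: with 26 pairs
and a recurrence variable confined to 1–4 with two thirds of pairs tied at
1, the tie structure caps the achievable rank correlation below the
Holm-corrected significance threshold, so no generator faithful to that
marginal distribution can make the RR leg of the pattern reliably
recoverable. What passing the calibration shows is therefore that the
pipeline detects a bond-driven contact–stability coupling when one is
present at detectable strength and reports none when absent — not that
the field data's effect sizes are reproduced. Other simplifications to
keep in mind: behaviour magnitudes (IBC seconds per session, mount rates)
are assumptions, not published values; sessions contain a single
proximity block and one IBC and grooming state each, whereas real focal
streams are more fragmented; and detection is independent across days,
with no observer fatigue or visibility structure.

## Numerical and degenerate-input choices

* Dates are ISO-8601 calendar days; all day arithmetic is in whole days.
* Event times are real-valued seconds from session start; the protocol
  clock (`clock_start`, pause intervals) is kept separately for the
  three-hour rule.
* Duplicate scan rows collapse by OR of flags (a pair counts once per
  day); duplicate focal sessions for a pair-day are invalidated, keeping
  the earliest by clock start with session id as the tie-break.
* The interval-union routines treat intervals as closed; zero-length
  states are impossible by validation, and empty unions have measure 0.
* `TOD = 0` pairs are excluded upstream with a warning; reaching the
  metric computation with one is an error, not a silent `NaN`.
* Thresholds (gap days, 900 s, 3 h) are arguments with protocol defaults,
  so sensitivity analyses need no code edits. The gap rule itself was
  data-derived in the original protocol, which is another reason to keep
  it configurable.
* Replicate counts used by the calibration tests (200 null seasons, 100
  effect seasons, 1000-case oracle sweeps) were chosen to keep binomial
  uncertainty on the pass rates a few percent while the whole suite stays
  inside a few minutes on one CPU.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 20190926)
roster <- generate_roster(cfg)
season <- generate_season(cfg, roster)
res <- analyze_consorts(roster, season$scans, season$sessions,
                        season$events)
round(res$correlations$rho["IBC_rate", c("days_observed", "RR", "PCD")], 3)
res$demographics$sex_ratio
```

The `analysis/` directory runs the same computation as a four-stage
narrative workflow (simulate, segment, metrics, statistics) writing its
tables under `results/`.

## Known limitations

* The ethogram is a faithful reconstruction from the behaviours named in
  the study's main text, not the study's full (unpublished) catalogue;
  `load_ethogram()` accepts a user catalogue, and widening the IBC set is
  allowed but warned about.
* The per-pair analysis treats pairs as independent although some females
  appear in several pairs — as in the source analysis, which kept to
  descriptive statistics for the same reason.
* Observation effort per day is not modelled (the field protocol had no
  effort column); detection is a single per-day probability in the
  generator.
* p values from the original software's defaults may differ slightly in
  tie handling; the implementation documents its choices (average ranks,
  tie-corrected variances) and tests them against independent routes.
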