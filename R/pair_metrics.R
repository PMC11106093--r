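# Derived per-pair behavioural indices.
#
# All frequency/duration variables are normalized by the pair's total focal
# observation time (TOD) because pairs observed on more days would otherwise
# mechanically accumulate more behaviour. Units are kept native: mounts per
# second and dimensionless fractions.

#' Mounting reciprocity of a pair
#'
#' MR = 100 - |pA - pB|, where pA and pB are the two partners' percentage
#' shares of active mounts (pA + pB = 100). 100 means both partners mounted
#' equally often; 0 means mounting was completely one-sided. Undefined
#' (returned as `NA`) when the pair has no mounts: an absent behaviour is
#' not the same as a one-sided one.
#'
#' @param mounts_by_actor Numeric vector of length 2: each partner's active
#'   mount count (zeros allowed; order irrelevant).
#' @return MR in `[0, 100]`, or `NA` when there are no mounts.
#' @examples
#' mounting_reciprocity(c(5, 5))  # 100
#' mounting_reciprocity(c(8, 0))  # 0
#' @export
mounting_reciprocity <- function(mounts_by_actor) {
  if (length(mounts_by_actor) != 2L) {
    stop("mounts_by_actor must give exactly the two partners' counts")
  }
  if (any(is.na(mounts_by_actor)) || any(mounts_by_actor < 0)) {
    stop("mount counts must be non-negative")
  }
  total <- sum(mounts_by_actor)
  if (total == 0) return(NA_real_)
  shares <- 100 * mounts_by_actor / total
  100 - abs(shares[1L] - shares[2L])
}

#' Pelvic-movement rate of a pair
#'
#' PM = (mounts with pelvic movement) / (all mounts); each mount is scored
#' 0/1 for the concurrence of pelvic movement (rubbing, grinding or
#' thrusting). Undefined (`NA`) for mount-free pairs.
#'
#' @param pelvic_mounts,total_mounts Non-negative counts,
#'   `pelvic_mounts <= total_mounts`.
#' @return PM in `[0, 1]`, or `NA` when `total_mounts` is 0.
#' @export
pelvic_movement_rate <- function(pelvic_mounts, total_mounts) {
  if (any(pelvic_mounts < 0) || any(total_mounts < 0)) {
    stop("counts must be non-negative")
  }
  if (any(pelvic_mounts > total_mounts)) {
    stop("pelvic_mounts cannot exceed total_mounts")
  }
  ifelse(total_mounts > 0, pelvic_mounts / total_mounts, NA_real_)
}

#' Compute the pair-level metric table from pair summaries
#'
#' Derives, per pair: `M` (mounts per second of focal duration),
#' `PM` (pelvic movements per mount), `MR` (mounting reciprocity),
#' `IBC_rate` and `GR_rate` (fractions of focal time in intensive body
#' contact and grooming), and copies through `PCD`, `RR` and
#' `days_observed`. `PM` and `MR` are `NA` for mount-free pairs and are
#' excluded pairwise downstream, never imputed as zero.
#'
#' @param summary Pair summary table from [aggregate_pairs()].
#' @return A data frame with columns `pair_id`, `days_observed`, `RR`,
#'   `PCD`, `MR`, `PM`, `M`, `IBC_rate`, `GR_rate`.
#' @export
compute_metrics <- function(summary) {
  if (nrow(summary) > 0L && any(summary$TOD <= 0)) {
    stop("pair(s) with TOD = 0 must be excluded before computing metrics: ",
         paste(summary$pair_id[summary$TOD <= 0], collapse = ", "))
  }
  mr <- vapply(seq_len(nrow(summary)), function(i) {
    mounting_reciprocity(c(summary$mounts_a[i], summary$mounts_b[i]))
  }, numeric(1L))
  data.frame(
    pair_id = summary$pair_id,
    days_observed = summary$days_observed,
    RR = summary$recurrence_rate,
    PCD = summary$PCD,
    MR = mr,
    PM = pelvic_movement_rate(summary$pelvic_mounts, summary$total_mounts),
    M = summary$total_mounts / summary$TOD,
    IBC_rate = summary$IBC_seconds / summary$TOD,
    GR_rate = summary$GR_seconds / summary$TOD,
    stringsAsFactors = FALSE
  )
}
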