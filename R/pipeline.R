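# End-to-end orchestration: read -> segment -> validate -> aggregate ->
# metrics -> statistics -> report.

.table2_variables <- c("days_observed", "RR", "PCD", "MR", "PM", "M",
                       "IBC_rate", "GR_rate")

#' Run the consort analysis on in-memory observation tables
#'
#' The computational core of the pipeline, shared by [run_pipeline()], the
#' test-suite and simulation studies: segments consort bouts under the gap
#' rule, computes per-female activity, validates focal sessions, aggregates
#' pair summaries, derives the pair metric table, and computes the
#' statistical surface (Spearman matrix with Holm correction, group
#' comparisons by age class and reproductive status, demographic summary,
#' access-to-males correlations).
#'
#' @param roster Roster data frame ([read_roster()] shape).
#' @param scans Scan records ([read_scan_log()] shape).
#' @param sessions,events Focal tables ([read_focal_log()] shape).
#' @param catalog An `ethogram` object.
#' @param gap_days Gap-rule parameter (default 3, the study protocol).
#' @param min_session_seconds,resume_hours Session-validity thresholds
#'   (defaults 900 s and 3 h, the study protocol).
#' @param variables Metric columns for the correlation matrix (default the
#'   eight study variables).
#' @param seed Seed for permutation p values.
#' @return A list with components `bouts`, `activity`, `validity`,
#'   `pair_summary`, `metrics`, `correlations`, `comparisons_age`,
#'   `comparisons_status`, `demographics`, `access`, and `counts` (stage
#'   bookkeeping).
#' @export
analyze_consorts <- function(roster, scans, sessions, events,
                             catalog = default_ethogram(), gap_days = 3,
                             min_session_seconds = 900, resume_hours = 3,
                             variables = .table2_variables, seed = 1L) {
  filtered <- attach_vd_contact_days(scans, gap_days)
  seg <- segment_bouts(filtered, gap_days)
  activity <- consort_activity(scans, roster, gap_days)
  validity <- validate_sessions(sessions, min_seconds = min_session_seconds,
                                resume_hours = resume_hours)
  out <- list(bouts = seg, activity = activity, validity = validity)

  out$pair_summary <- aggregate_pairs(sessions, events, validity,
                                      seg$pair_summary, catalog)
  out$metrics <- compute_metrics(out$pair_summary)
  if (nrow(out$metrics) >= 4L) {
    out$correlations <- spearman_matrix(out$metrics, variables, seed = seed)
  } else {
    out$correlations <- NULL
    if (nrow(out$metrics) > 0L) {
      message("too few pairs with metrics (", nrow(out$metrics),
              ") for the correlation matrix; skipped")
    }
  }
  if (nrow(activity) > 0L) {
    grp <- function(g) tryCatch(
      compare_groups(activity, roster, g),
      error = function(e) {
        message("group comparison by ", g, " skipped: ",
                conditionMessage(e)); NULL
      })
    out$comparisons_age <- grp("age_class")
    out$comparisons_status <- grp("reproductive_status")
    out$demographics <- demographic_summary(roster, activity)
    out$access <- access_to_males(activity, seed = seed)
  } else {
    message("no analyzable females; statistics stage skipped")
    out$comparisons_age <- out$comparisons_status <- NULL
    out$demographics <- out$access <- NULL
  }
  out$counts <- list(
    n_scan_records = nrow(scans),
    n_scan_records_retained = nrow(filtered),
    n_pairs_sighted = length(unique(scans$pair_id)),
    n_pairs_with_bouts = nrow(seg$pair_summary),
    n_bouts = nrow(seg$bouts),
    n_sessions = nrow(sessions),
    n_valid_sessions = sum(validity$valid),
    sessions_discarded = as.list(table(validity$reason[!validity$valid])),
    n_pairs_with_metrics = nrow(out$metrics)
  )
  out
}

#' Run the full pipeline from files on disk
#'
#' Reads the roster, scan log and focal log named in `config`, runs
#' [analyze_consorts()], writes every stage output as CSV/JSON under
#' `config$output_dir`, and returns (and writes) a machine-readable
#' `report.json` carrying input hashes, the configuration actually used,
#' stage counts and all statistics. The defaults reproduce the study
#' protocol exactly (3-day gap, 900 s minimum session, 3 h resume window).
#'
#' @param config A list: `roster`, `scans`, `focal_sessions`,
#'   `focal_events` (input paths), optional `ethogram` (path or
#'   `"default"`), `gap_days`, `min_session_seconds`, `resume_hours`,
#'   `variables`, `seed`, and `output_dir`.
#' @return The run report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  required <- c("roster", "scans", "focal_sessions", "focal_events",
                "output_dir")
  miss <- setdiff(required, names(config))
  if (length(miss) > 0L) {
    stop("run config is missing field(s): ", paste(miss, collapse = ", "))
  }
  catalog <- if (is.null(config$ethogram) ||
                 identical(config$ethogram, "default")) {
    default_ethogram()
  } else load_ethogram(config$ethogram)
  gap_days <- config$gap_days %||% 3
  min_s <- config$min_session_seconds %||% 900
  resume_h <- config$resume_hours %||% 3
  variables <- config$variables %||% .table2_variables
  seed <- config$seed %||% 1L

  roster <- read_roster(config$roster)
  scans <- read_scan_log(config$scans, roster)
  focal <- read_focal_log(config$focal_sessions, config$focal_events,
                          catalog, roster)
  res <- analyze_consorts(roster, scans, focal$sessions, focal$events,
                          catalog = catalog, gap_days = gap_days,
                          min_session_seconds = min_s,
                          resume_hours = resume_h,
                          variables = variables, seed = seed)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$output_dir, f)
  utils::write.csv(res$bouts$bouts, outfile("bouts.csv"), row.names = FALSE)
  utils::write.csv(res$bouts$pair_summary, outfile("pair_bout_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$activity, outfile("activity.csv"), row.names = FALSE)
  utils::write.csv(res$validity, outfile("session_validity.csv"),
                   row.names = FALSE)
  utils::write.csv(res$pair_summary, outfile("pair_summary.csv"),
                   row.names = FALSE)
  metrics_out <- res$metrics
  names(metrics_out)[names(metrics_out) == "days_observed"] <- "days_observed"
  utils::write.csv(metrics_out, outfile("pair_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(res$correlations)) {
    utils::write.csv(res$correlations$rho, outfile("correlation_matrix.csv"))
    utils::write.csv(res$correlations$p_adjusted,
                     outfile("correlation_p_adjusted.csv"))
  }
  comp_df <- function(comps) {
    if (is.null(comps)) return(NULL)
    do.call(rbind, lapply(comps, function(r) data.frame(
      grouping = r$grouping, variable = r$variable, test = r$test,
      statistic = r$statistic, df = r$df, p_raw = r$p_raw,
      stringsAsFactors = FALSE)))
  }
  comps <- rbind(comp_df(res$comparisons_age), comp_df(res$comparisons_status))
  if (!is.null(comps)) {
    utils::write.csv(comps, outfile("group_comparisons.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$demographics)) {
    jsonlite::write_json(res$demographics, outfile("demographics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  report <- list(
    inputs = lapply(config[c("roster", "scans", "focal_sessions",
                             "focal_events")], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    config = list(gap_days = gap_days, min_session_seconds = min_s,
                  resume_hours = resume_h, variables = variables,
                  seed = seed),
    counts = res$counts,
    statistics = list(
      correlations = if (is.null(res$correlations)) NULL else list(
        variables = res$correlations$variables,
        rho = res$correlations$rho,
        p_raw = res$correlations$p_raw,
        p_adjusted = res$correlations$p_adjusted,
        n_used = res$correlations$n_used),
      comparisons_age = res$comparisons_age,
      comparisons_status = res$comparisons_status,
      demographics = res$demographics,
      access_to_males = res$access)
  )
  jsonlite::write_json(report, outfile("report.json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor", force = TRUE)
  invisible(report)
}
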