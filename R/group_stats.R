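# Study-level statistics: Spearman correlation matrix with Holm-Bonferroni
# correction, nonparametric group comparisons, demographic summaries.

#' Holm-Bonferroni step-down adjustment
#'
#' Thin, validating wrapper over `stats::p.adjust(method = "holm")`: sort the
#' raw p values ascending, multiply the i-th smallest by (m - i + 1), enforce
#' the running maximum, cap at 1 and return in input order.
#'
#' @param p_values Numeric vector of raw p values in `[0, 1]` (`NA` allowed,
#'   passed through; the family size counts non-missing tests only).
#' @return Adjusted p values in input order.
#' @export
holm_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "holm")
  out
}

#' Spearman rank correlation with a two-sided p value
#'
#' Rho is the Pearson correlation of average ranks (ties share their mean
#' rank). The two-sided p uses the t-distribution approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` for `n >= 10` and a seeded
#' permutation test below that, where the t approximation is poor.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped pairwise.
#' @param n_perm Number of permutations for the small-n p value.
#' @param seed Seed for the permutation p value (local RNG scope).
#' @return A list with `rho`, `p`, `n` (complete pairs used).
#' @export
spearman_test <- function(x, y, n_perm = 10000, seed = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2L)
  } else {
    p <- local({
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
      perm <- replicate(n_perm, abs(stats::cor(rx, sample(ry))))
      (1 + sum(perm >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Spearman correlation matrix with Holm-Bonferroni correction
#'
#' Computes all pairwise Spearman correlations between the given metric
#' columns with pairwise-complete deletion (undefined PM/MR values drop out
#' of their own tests only), then Holm-adjusts the raw two-sided p values
#' over the single family of all unique variable pairs (28 tests for the
#' 8-variable set). Constant variables yield `NA` correlations with a
#' warning.
#'
#' @param metrics Data frame of per-pair metrics.
#' @param variables Character vector of column names to correlate.
#' @param seed Seed for small-n permutation p values.
#' @return A list of class `correlation_matrix`: `variables`, `rho`,
#'   `p_raw`, `p_adjusted` (symmetric matrices, unit diagonal, `NA`
#'   diagonal for p), and `n_used`.
#' @export
spearman_matrix <- function(metrics, variables, seed = 1L) {
  miss <- setdiff(variables, names(metrics))
  if (length(miss) > 0L) {
    stop("metrics table lacks column(s): ", paste(miss, collapse = ", "))
  }
  k <- length(variables)
  rho <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p_raw <- rho
  n_used <- matrix(NA_integer_, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1
  pairs <- utils::combn(k, 2L)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    res <- spearman_test(metrics[[variables[a]]], metrics[[variables[b]]],
                         seed = seed + j)
    rho[a, b] <- rho[b, a] <- res$rho
    p_raw[a, b] <- p_raw[b, a] <- res$p
    n_used[a, b] <- n_used[b, a] <- res$n
  }
  if (anyNA(rho[upper.tri(rho)])) {
    warning("some correlations are undefined (constant variable or too few ",
            "complete pairs)", call. = FALSE)
  }
  upper <- p_raw[upper.tri(p_raw)]
  adj <- holm_adjust(upper)
  p_adjusted <- p_raw
  p_adjusted[upper.tri(p_adjusted)] <- adj
  p_adjusted[lower.tri(p_adjusted)] <- t(p_adjusted)[lower.tri(p_adjusted)]
  diag(n_used) <- vapply(variables, function(v)
    sum(!is.na(metrics[[v]])), integer(1L))
  structure(list(variables = variables, rho = rho, p_raw = p_raw,
                 p_adjusted = p_adjusted, n_used = n_used),
            class = "correlation_matrix")
}

#' Mann-Whitney U test with normal approximation and tie correction
#'
#' Reports the standardized statistic Z (the form reported in the study
#' literature) alongside U and the two-sided p value. The normal
#' approximation with the tie-corrected variance is used; for small
#' tie-free samples `stats::wilcox.test` provides the exact alternative.
#'
#' @param x,y Numeric samples for the two groups.
#' @return A list with `U` (for the first sample), `Z`, `p`, `n` (c(n1, n2)).
#' @export
mann_whitney_z <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term)
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) return(list(U = U, Z = 0, p = 1, n = c(n1, n2)))
  Z <- (U - mu) / sqrt(sigma2)
  list(U = U, Z = Z, p = min(1, 2 * stats::pnorm(-abs(Z))), n = c(n1, n2))
}

#' Compare consort activity between female groups
#'
#' For each activity variable, runs a Kruskal-Wallis test (tie-corrected)
#' when the grouping has three or more non-empty groups, or a Mann-Whitney
#' test (reporting Z) for two groups; with three or more groups, all
#' pairwise Mann-Whitney post-hocs are Holm-adjusted within the family of
#' group pairs of that variable. Empty groups are dropped with a warning.
#'
#' @param activity Per-female activity table from [consort_activity()].
#' @param roster Roster data frame.
#' @param grouping `"age_class"` or `"reproductive_status"`.
#' @param variables Activity columns to test (default homosexual and
#'   heterosexual consort counts).
#' @return A list, one element per variable, each with `grouping`,
#'   `variable`, `groups` (sizes), `test` (`"kruskal-wallis"` or
#'   `"mann-whitney"`), `statistic` (H or Z), `df` (KW only), `p_raw`, and
#'   `pairwise` (data frame of post-hoc comparisons, or `NULL`).
#' @export
compare_groups <- function(activity, roster,
                           grouping = c("age_class", "reproductive_status"),
                           variables = c("homo_consorts", "hetero_consorts")) {
  grouping <- match.arg(grouping)
  g <- roster[[grouping]][match(activity$id, roster$id)]
  if (anyNA(g)) {
    stop("grouping '", grouping, "' is undefined for some analyzed females")
  }
  lv <- unique(g)
  sizes <- table(g)
  empty <- setdiff(lv, names(sizes)[sizes > 0])
  if (length(empty) > 0L) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  lv <- names(sizes)[sizes > 0]
  if (length(lv) < 2L) stop("need at least two non-empty groups")
  lapply(variables, function(v) {
    x <- activity[[v]]
    res <- list(grouping = grouping, variable = v,
                groups = stats::setNames(as.integer(sizes[lv]), lv))
    if (length(lv) == 2L) {
      mw <- mann_whitney_z(x[g == lv[1L]], x[g == lv[2L]])
      res$test <- "mann-whitney"
      res$statistic <- mw$Z
      res$df <- NA_integer_
      res$p_raw <- mw$p
      res$pairwise <- NULL
    } else {
      kw <- stats::kruskal.test(x, factor(g, levels = lv))
      res$test <- "kruskal-wallis"
      res$statistic <- unname(kw$statistic)
      res$df <- unname(kw$parameter)
      res$p_raw <- kw$p.value
      cmb <- utils::combn(lv, 2L)
      pw <- data.frame(group_a = cmb[1L, ], group_b = cmb[2L, ],
                       Z = NA_real_, p_raw = NA_real_,
                       stringsAsFactors = FALSE)
      for (j in seq_len(ncol(cmb))) {
        mw <- mann_whitney_z(x[g == cmb[1L, j]], x[g == cmb[2L, j]])
        pw$Z[j] <- mw$Z; pw$p_raw[j] <- mw$p
      }
      pw$p_adjusted <- holm_adjust(pw$p_raw)
      res$pairwise <- pw
    }
    res
  })
}

#' Group-level demographic and consort-activity summary
#'
#' Mirrors the study's group-level reporting: counts of mature males and
#' analyzed females, the male:female sex ratio (two decimals), mean, SD and
#' range of consorts and partners per mode (overall / homosexual /
#' heterosexual) over the females active in that mode, the prevalence of
#' female homosexual activity among all analyzed females, and the number of
#' matrilines represented among homosexually active females.
#'
#' @param roster Roster data frame.
#' @param activity Per-female activity table from [consort_activity()].
#' @return A nested list; modes with no active female report `NULL` rather
#'   than zeros.
#' @export
demographic_summary <- function(roster, activity) {
  stopifnot(all(activity$id %in% roster$id))
  n_m <- sum(roster$sex == "M" & roster$mature)
  n_f <- nrow(activity)
  mode_stats <- function(consorts, partners, active) {
    if (!any(active)) return(NULL)
    list(n_active = sum(active),
         consorts = list(mean = mean(consorts[active]),
                         sd = stats::sd(consorts[active]),
                         range = range(consorts[active])),
         partners = list(mean = mean(partners[active]),
                         sd = stats::sd(partners[active]),
                         range = range(partners[active])))
  }
  mat <- roster$matriline[match(activity$id, roster$id)]
  list(
    n_mature_males = n_m,
    n_analyzed_females = n_f,
    sex_ratio = round(n_m / n_f, 2),
    overall = mode_stats(activity$total_consorts, activity$total_partners,
                         activity$total_consorts > 0),
    homosexual = mode_stats(activity$homo_consorts, activity$homo_partners,
                            activity$homo_consorts > 0),
    heterosexual = mode_stats(activity$hetero_consorts,
                              activity$hetero_partners,
                              activity$hetero_consorts > 0),
    homosexual_prevalence = mean(activity$homo_consorts > 0),
    n_matrilines_homosexual =
      length(unique(mat[activity$homo_consorts > 0]))
  )
}

#' Relate female homosexual activity to access to male partners
#'
#' Spearman correlations, over all analyzed females (inactive females enter
#' as zeros), of homosexual vs heterosexual partner numbers and homosexual
#' vs heterosexual consort counts.
#'
#' @param activity Per-female activity table from [consort_activity()].
#' @param seed Seed for small-n permutation p values.
#' @return A list with elements `partners` and `consorts`, each `rho`, `p`,
#'   `n`.
#' @export
access_to_males <- function(activity, seed = 1L) {
  list(
    partners = spearman_test(activity$homo_partners,
                             activity$hetero_partners, seed = seed),
    consorts = spearman_test(activity$homo_consorts,
                             activity$hetero_consorts, seed = seed + 1L)
  )
}
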