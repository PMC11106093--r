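test_that("Holm step-down matches hand-computed values and caps at 1", {
  expect_equal(holm_adjust(0.05), 0.05)
  # sorted (0.01, 0.03, 0.04) -> x3, x2, x1 with running max
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(1, 1)), c(1, 1))
  expect_equal(holm_adjust(c(NA, 0.01, 0.04)), c(NA, 0.02, 0.04))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm adjustment is monotone in the raw p values", {
  set.seed(405)
  for (rep in 1:30) {
    p <- runif(8)
    p2 <- p
    i <- sample(8, 1)
    p2[i] <- min(1, p2[i] + runif(1, 0, 1 - p2[i]))
    expect_true(all(holm_adjust(p2) >= holm_adjust(p) - 1e-12))
  }
})

test_that("Spearman rho and p agree with the stats-package route", {
  set.seed(406)
  # ties included: rho must match cor(method = "spearman") to 1e-12 and the
  # large-n p must match cor.test's t approximation
  for (rep in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)
    y <- x + sample(-2:2, 15, replace = TRUE)
    res <- spearman_test(x, y)
    expect_equal(res$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  }
  # perfect monotone and antitone association
  expect_equal(spearman_test(1:12, (1:12)^2)$rho, 1)
  expect_equal(spearman_test(1:5, 5:1)$rho, -1)
  # below n = 10 a seeded permutation p is used and is reproducible
  small1 <- spearman_test(1:8, c(2, 1, 4, 3, 6, 5, 8, 7), seed = 9)
  small2 <- spearman_test(1:8, c(2, 1, 4, 3, 6, 5, 8, 7), seed = 9)
  expect_identical(small1$p, small2$p)
  exact <- cor.test(1:8, c(2, 1, 4, 3, 6, 5, 8, 7),
                    method = "spearman")$p.value
  expect_lt(abs(small1$p - exact), 0.01)
})

test_that("the correlation matrix is symmetric with one Holm family", {
  set.seed(407)
  df <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  df$d <- df$a + rnorm(20, 0, 0.1)
  cm <- spearman_matrix(df, c("a", "b", "c", "d"))
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(diag(cm$rho), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(cm$p_adjusted >= cm$p_raw - 1e-12, na.rm = TRUE))
  expect_true(all(cm$p_adjusted <= 1, na.rm = TRUE))
  # adjusted values equal Holm over the 6 unique tests, replaced in place
  up <- upper.tri(cm$p_raw)
  expect_equal(cm$p_adjusted[up], holm_adjust(cm$p_raw[up]))
  expect_equal(cm$n_used[up], rep(20L, 6), ignore_attr = TRUE)
  # undefined PM/MR-style columns drop out pairwise, not listwise
  df$e <- c(rep(NA, 12), rnorm(8))
  cm2 <- suppressWarnings(spearman_matrix(df, c("a", "b", "e")))
  expect_equal(cm2$n_used["a", "b"], 20L)
  expect_equal(cm2$n_used["a", "e"], 8L)
  # a constant variable yields missing correlations with a warning
  df$f <- 1
  expect_warning(cm3 <- spearman_matrix(df, c("a", "f")), "undefined")
  expect_true(is.na(cm3$rho["a", "f"]))
})

test_that("Mann-Whitney Z matches wilcox.test and nulls out on ties", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 7.3)
  y <- c(2.1, 6.6, 8.2, 9.9, 5.5, 10.3, 11.1)
  mw <- mann_whitney_z(x, y)
  wt <- wilcox.test(x, y, correct = FALSE, exact = FALSE)
  expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
  expect_equal(mw$U, unname(wt$statistic))
  # two identical samples: Z ~ 0, p ~ 1
  same <- mann_whitney_z(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)
  # Kruskal-Wallis with two groups is the squared Mann-Whitney Z
  kw <- kruskal.test(list(x, y))
  expect_equal(unname(kw$statistic), mw$Z^2, tolerance = 1e-10)
  expect_equal(kw$p.value, mw$p, tolerance = 1e-10)
})

test_that("group comparisons pick the right test and post-hoc family", {
  roster <- mk_roster(n_f = 40, n_m = 2)
  roster$reproductive_status[roster$sex == "F"] <-
    rep(c("nulliparous", "parous", "lactating", "menopausal_like"), 10)
  roster$age_years[roster$reproductive_status == "menopausal_like"] <- 27
  roster$age_class[1:8] <- "adolescent"
  set.seed(408)
  activity <- data.frame(
    id = roster$id[roster$sex == "F"],
    homo_consorts = rpois(40, 2), homo_partners = rpois(40, 1),
    hetero_consorts = rpois(40, 5), hetero_partners = rpois(40, 3),
    stringsAsFactors = FALSE)
  activity$total_consorts <- activity$homo_consorts +
    activity$hetero_consorts
  activity$total_partners <- activity$homo_partners +
    activity$hetero_partners
  # a large shift in one status group is detected by Kruskal-Wallis
  shift <- roster$reproductive_status[match(activity$id, roster$id)] ==
    "lactating"
  activity$hetero_consorts[shift] <- activity$hetero_consorts[shift] + 15
  res <- compare_groups(activity, roster, "reproductive_status")
  hetero <- res[[which(vapply(res, `[[`, "", "variable") ==
                         "hetero_consorts")]]
  expect_equal(hetero$test, "kruskal-wallis")
  expect_equal(hetero$df, 3)           # four status categories
  expect_lt(hetero$p_raw, 0.05)
  expect_equal(nrow(hetero$pairwise), 6)
  expect_equal(hetero$pairwise$p_adjusted,
               holm_adjust(hetero$pairwise$p_raw))
  # two age classes use Mann-Whitney and report Z
  res_age <- compare_groups(activity, roster, "age_class")
  expect_equal(res_age[[1]]$test, "mann-whitney")
  expect_true(is.numeric(res_age[[1]]$statistic))
  expect_null(res_age[[1]]$pairwise)
})

test_that("demographic summary reports the study-style aggregates", {
  roster <- mk_roster(n_f = 76, n_m = 49)
  activity <- data.frame(
    id = roster$id[roster$sex == "F"],
    homo_consorts = c(rep(2, 35), rep(0, 41)),
    homo_partners = c(rep(1, 35), rep(0, 41)),
    hetero_consorts = c(rep(0, 7), rep(8, 69)),
    hetero_partners = c(rep(0, 7), rep(5, 69)),
    stringsAsFactors = FALSE)
  activity$total_consorts <- activity$homo_consorts +
    activity$hetero_consorts
  activity$total_partners <- activity$homo_partners +
    activity$hetero_partners
  d <- demographic_summary(roster, activity)
  expect_equal(d$sex_ratio, 0.64)        # 49 males to 76 females
  expect_equal(d$n_analyzed_females, 76)
  expect_equal(d$homosexual_prevalence, 35 / 76, tolerance = 1e-12)
  expect_equal(d$homosexual$n_active, 35)
  expect_equal(d$heterosexual$consorts$mean, 8)
  # a mode with no active females reports NULL, not zeros
  activity$homo_consorts <- 0
  d2 <- demographic_summary(roster, activity)
  expect_null(d2$homosexual)
})

test_that("access-to-males correlations include inactive females as zeros", {
  act <- data.frame(
    id = sprintf("F%02d", 1:12),
    homo_consorts = c(0, 0, 1:10), homo_partners = c(0, 0, 1:10),
    hetero_consorts = c(0, 0, 1:10), hetero_partners = c(0, 0, 1:10),
    stringsAsFactors = FALSE)
  res <- access_to_males(act)
  expect_equal(res$consorts$rho, 1)
  expect_equal(res$consorts$n, 12)   # zeros kept in the denominator
  # independent counts give a near-zero correlation at study size
  set.seed(409)
  act2 <- data.frame(id = sprintf("F%02d", 1:76),
                     homo_consorts = rpois(76, 2),
                     homo_partners = rpois(76, 1),
                     hetero_consorts = rpois(76, 7),
                     hetero_partners = rpois(76, 5))
  res2 <- access_to_males(act2)
  expect_lt(abs(res2$consorts$rho), 0.25)
  expect_gt(res2$consorts$p, 0.05)
})
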