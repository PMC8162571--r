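test_that("ROI summaries are masked-aware, local and complete", {
  labels <- array(0L, c(6, 6, 1))
  labels[1:3, , 1] <- 1L
  labels[4:6, , 1] <- 2L
  map <- array(NA_real_, dim(labels))
  map[labels == 1] <- 71.09
  map[labels == 2] <- 50
  s <- roi_summarize(map, labels, roi_names = c("1" = "TA", "2" = "PL"))
  expect_equal(s$value[s$roi == "TA"], 71.09)
  expect_equal(s$voxel_count, c(18, 18))

  # a masked voxel is excluded and decrements the count
  map[1, 1, 1] <- NA
  s2 <- roi_summarize(map, labels)
  expect_equal(s2$voxel_count[s2$label == 1], 17)
  expect_equal(s2$value[s2$label == 1], 71.09)

  # locality: changing ROI 2 leaves ROI 1 untouched
  map[labels == 2] <- 999
  s3 <- roi_summarize(map, labels)
  expect_equal(s3$value[s3$label == 1], s2$value[s2$label == 1])

  expect_error(roi_summarize(map, labels, require = c(1, 2, 3)),
               "missing label")
})

test_that("normality screening behaves under null, degenerate and
           bimodal samples", {
  # type-I behaviour is exercised in depth in the acceptance suite;
  # here: calibration on a modest replicate count
  set.seed(21)
  rej <- replicate(300, {
    nc <- normality_check(rnorm(25), B = 1500)
    !nc$pass
  })
  # each test rejects ~5%; both-pass fails at most ~10%
  expect_lt(mean(rej), 0.15)
  expect_gt(mean(rej), 0.02)

  deg <- normality_check(rep(3.3, 10))
  expect_false(deg$pass)
  expect_match(deg$reason, "zero variance")

  set.seed(22)
  bim <- normality_check(c(rnorm(50), rnorm(50, 10)), B = 2000)
  expect_lt(bim$p_lilliefors, 0.05)
  expect_lt(bim$p_anderson_darling, 0.05)

  expect_error(normality_check(rnorm(3)), "n >= 4")
})

test_that("Monte-Carlo normality p-values track the reference
           implementations", {
  set.seed(30)
  x <- rnorm(50, mean = 5, sd = 2)
  nc <- normality_check(x, B = 10000)
  expect_equal(nc$p_lilliefors, nortest::lillie.test(x)$p.value,
               tolerance = 0.05)
  expect_equal(nc$p_anderson_darling, nortest::ad.test(x)$p.value,
               tolerance = 0.05)
})

test_that("group comparison: identical groups, Welch defaults, paired
           guard, permutation cross-check", {
  g <- c(3.1, 4.2, 5.0, 2.7)
  same <- group_compare(g, g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(group_compare(rnorm(12), rnorm(11), mode = "paired"),
               "12 and 11")

  # small-n Welch p against the exhaustive two-sample permutation oracle
  a <- c(4.9, 6.1, 5.4, 7.0)
  b <- c(5.8, 7.2, 6.6, 8.1)
  cmp <- group_compare(a, b)
  pool <- c(a, b)
  idx <- utils::combn(8, 4)
  tstat <- function(x, y) {
    (mean(x) - mean(y)) /
      sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  }
  obs <- abs(tstat(a, b))
  perm <- apply(idx, 2, function(i) abs(tstat(pool[i], pool[-i])))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(cmp$p_value - p_perm), 0.06)
})

test_that("percent differences preserve sign, invert consistently and
           round away from zero", {
  expect_equal(percent_difference(0.11, 0.08), 37.5)
  expect_equal(report_percent(percent_difference(0.11, 0.08)), 38)
  pd <- percent_difference(3.8, 8.9)
  expect_equal(pd, -57.3033707865169, tolerance = 1e-12)
  expect_equal(report_percent(abs(pd)), 57)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "non-zero")
  expect_equal(report_percent(c(0.5, -0.5, 2.49)), c(1, -1, 2))

  # consistency: forward and reversed percent differences invert exactly
  a <- 3.8; b <- 8.9
  p <- percent_difference(a, b, reference = "b")
  q <- percent_difference(b, a, reference = "b")   # reference value = a
  expect_equal(1 + p / 100, a / b, tolerance = 1e-12)
  expect_equal(1 + q / 100, b / a, tolerance = 1e-12)
})

test_that("cohort table reproduces grand averages and flags degenerate
           cells", {
  par <- trate_cohort_params()
  # two identical subjects per cohort pin the per-muscle means
  d <- do.call(rbind, lapply(seq_len(nrow(par)), function(i) {
    data.frame(subject = rep(c("a1", "a2", "c1", "c2"), 1),
               cohort = c("als", "als", "control", "control"),
               muscle = par$muscle[i],
               value = c(par$mean_case[i], par$mean_case[i],
                         par$mean_ref[i], par$mean_ref[i]))
  }))
  tab <- cohort_table(d, reference = "control", normality_B = 0)
  grand <- tab[tab$muscle == "(all)", ]
  expect_equal(grand$mean_ref, 82.152, tolerance = 1e-9)
  expect_equal(grand$mean_case, 46.694, tolerance = 1e-9)

  # single-subject cell: CI and comparison flagged NA, row still present
  d1 <- d[d$subject != "a2" | d$muscle != "TA", ]
  tab1 <- cohort_table(d1, reference = "control", normality_B = 0)
  row <- tab1[tab1$muscle == "TA", ]
  expect_true(is.na(row$ci_lo_case) && is.na(row$p_value))
  expect_false(is.na(row$mean_case))

  expect_error(cohort_table(d[d$cohort == "als", ]), "2 cohorts")
})

test_that("cohort summaries converge to the generating distribution", {
  set.seed(31)
  n <- 1e4
  v <- rnorm(n, 82.15, 14.65)
  d <- data.frame(subject = seq_len(2 * n),
                  cohort = rep(c("control", "als"), each = n),
                  muscle = "TA",
                  value = c(v, rnorm(n, 46.7, 9.5)))
  tab <- cohort_table(d, reference = "control", normality_B = 0)
  r <- tab[tab$muscle == "TA", ]
  expect_equal(r$mean_ref, 82.15, tolerance = 0.01)   # ~4 se
  expect_equal(r$sd_ref, 14.65, tolerance = 0.03)
  expect_lt(r$p_value, 1e-10)
})

test_that("longitudinal change and monthly rates are exact arithmetic", {
  lc <- longitudinal_change(100, 95.30, 6)
  expect_equal(lc$pct, -4.7, tolerance = 1e-12)
  expect_equal(lc$rate_per_month, -4.7 / 6, tolerance = 1e-12)
  expect_equal(longitudinal_change(55, 55, 6)$pct, 0)
  lc2 <- longitudinal_change(100, 78.38, 6)
  expect_equal(lc2$pct, -21.62, tolerance = 1e-12)
  expect_equal(lc2$rate_per_month, -3.60333333333, tolerance = 1e-9)
  # linear in pct, inverse in interval
  expect_equal(longitudinal_change(10, 12, 3)$rate_per_month,
               2 * longitudinal_change(10, 12, 6)$rate_per_month)
  expect_error(longitudinal_change(0, 5, 6), "non-zero")
  expect_error(longitudinal_change(10, 5, 0), "interval")

  # cohort averaging across subjects
  lcm <- longitudinal_change(c(100, 80), c(90, 76), 6, cohort_mean = TRUE)
  expect_equal(lcm$mean_pct, mean(c(-10, -5)))
})

test_that("clinical score records enforce instrument ranges", {
  cs <- clinical_scores("p1", 1, 42, 7, 129.8, 135.9)
  expect_s3_class(cs, "clinical_scores")
  expect_error(clinical_scores("p1", 1, 52, 7, 100, 100), "0-48")
  expect_error(clinical_scores("p1", 1, 42, 13, 100, 100), "0-12")
  expect_error(clinical_scores("p1", 2, 42, 7, 100, 100,
                               visit_interval = -1), "interval")
})
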