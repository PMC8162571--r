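# Cohort and longitudinal statistics over per-muscle ROI summaries:
# normality screening (Monte-Carlo Lilliefors and Anderson-Darling),
# Welch/paired group comparisons, percent differences, per-cohort
# summary tables with t-based confidence intervals, and
# percent-per-month longitudinal rates.

#' Summarize a voxelwise map over labelled ROIs
#'
#' Per-label mean of the metric over ROI voxels, excluding masked (NA)
#' voxels, with the surviving voxel count. Label 0 is background and is
#' never summarized.
#'
#' @param map Numeric array (NA = masked voxel).
#' @param labels Integer label array of the same shape.
#' @param roi_names Optional named vector/list mapping label id (as
#'   character) to ROI name.
#' @param require Optional label ids that must be present (error if not).
#' @return Data frame with columns `label`, `roi`, `value`,
#'   `voxel_count`.
#' @export
roi_summarize <- function(map, labels, roi_names = NULL, require = NULL) {
  if (length(map) != length(labels))
    stop("map and labels must have identical shape")
  lab <- as.vector(labels)
  ids <- sort(setdiff(unique(lab), 0))
  if (!is.null(require)) {
    missing <- setdiff(require, ids)
    if (length(missing) > 0)
      stop("missing label(s): ", paste(missing, collapse = ", "))
  }
  vals <- as.vector(map)
  out <- do.call(rbind, lapply(ids, function(i) {
    v <- vals[lab == i]
    v <- v[is.finite(v)]
    data.frame(label = i,
               value = if (length(v)) mean(v) else NA_real_,
               voxel_count = length(v))
  }))
  out$roi <- if (!is.null(roi_names))
    vapply(as.character(out$label),
           function(k) if (!is.null(roi_names[[k]])) roi_names[[k]] else k,
           character(1))
  else as.character(out$label)
  out[, c("label", "roi", "value", "voxel_count")]
}

# --- normality tests ------------------------------------------------------

.lilliefors_stat <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean = mean(x), sd = stats::sd(x))
  i <- seq_len(n)
  max(pmax(i / n - z, z - (i - 1) / n))
}

.ad_stat <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean = mean(x), sd = stats::sd(x))
  z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
}

# Null distributions of both statistics under sampling from a normal
# with estimated mean/sd, by Monte Carlo at the sample's own n.
# Cached per (n, B, seed) for the session; the draw uses a private RNG
# stream so callers' seeds are untouched.
.norm_null_cache <- new.env(parent = emptyenv())

.normality_null <- function(n, B, seed) {
  key <- paste(n, B, seed, sep = "_")
  hit <- .norm_null_cache[[key]]
  if (!is.null(hit)) return(hit)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  lil <- numeric(B); ad <- numeric(B)
  for (b in seq_len(B)) {
    x <- stats::rnorm(n)
    lil[b] <- .lilliefors_stat(x)
    ad[b] <- .ad_stat(x)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out <- list(lilliefors = lil, ad = ad)
  .norm_null_cache[[key]] <- out
  out
}

#' Normality screening with Lilliefors and Anderson-Darling tests
#'
#' Both tests compare the sample against a normal distribution with
#' estimated mean and standard deviation. P-values come from a seeded
#' Monte-Carlo null distribution simulated at the sample's own size
#' (`B` draws, cached per size), which is exact-in-expectation at any
#' `n >= 4` rather than relying on large-sample approximation tables.
#' The sample is declared normal ("pass") when both p-values are at
#' least `alpha`.
#'
#' A zero-variance (degenerate) sample is reported as a failure with an
#' explanatory reason rather than an error.
#'
#' @param values Numeric sample, `n >= 4`.
#' @param B Monte-Carlo null size (default 10000).
#' @param alpha Significance level for the pass flag (default 0.05).
#' @param null_seed Seed of the null-distribution stream.
#' @return List with `p_lilliefors`, `p_anderson_darling`, `pass`,
#'   `reason` (non-empty only on degenerate input), and the observed
#'   statistics `D` and `A2`.
#' @export
normality_check <- function(values, B = 10000, alpha = 0.05,
                            null_seed = 20260101) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) stop("normality_check requires n >= 4")
  if (stats::sd(values) == 0)
    return(list(p_lilliefors = 0, p_anderson_darling = 0, pass = FALSE,
                reason = "degenerate sample: zero variance",
                D = NA_real_, A2 = NA_real_))
  null <- .normality_null(n, B, null_seed)
  D <- .lilliefors_stat(values)
  A2 <- .ad_stat(values)
  p_lil <- (1 + sum(null$lilliefors >= D)) / (B + 1)
  p_ad <- (1 + sum(null$ad >= A2)) / (B + 1)
  list(p_lilliefors = p_lil, p_anderson_darling = p_ad,
       pass = p_lil >= alpha && p_ad >= alpha, reason = character(0),
       D = D, A2 = A2)
}

# --- group comparison -----------------------------------------------------

#' Compare a metric between two groups
#'
#' Two-sample mode (default) uses Welch's unequal-variance t-test, the
#' appropriate choice for two independent cohorts of unequal size;
#' paired mode pairs observations by index (e.g. the two visits of the
#' same subjects) and requires equal lengths. Both are two-tailed.
#'
#' @param group_a,group_b Numeric vectors. `group_b` is the reference
#'   group for the percent difference.
#' @param mode `"two_sample"` (Welch) or `"paired"`.
#' @return List with `statistic` (t), `df`, `p_value` (two-tailed),
#'   `percent_difference` (of means, reference = `group_b`), `mode`,
#'   `mean_a`, `mean_b`.
#' @examples
#' group_compare(rnorm(12, 27.7, 5.5), rnorm(11, 71.1, 13.5))
#' @export
group_compare <- function(group_a, group_b,
                          mode = c("two_sample", "paired")) {
  mode <- match.arg(mode)
  if (mode == "paired" && length(group_a) != length(group_b))
    stop(sprintf(paste("paired comparison requires equal sample sizes,",
                       "got %d and %d; use mode = 'two_sample' for",
                       "independent cohorts"),
                 length(group_a), length(group_b)))
  if (mode == "two_sample" && (length(group_a) < 2 || length(group_b) < 2))
    stop("each group needs n >= 2")
  ht <- if (isTRUE(all.equal(group_a, group_b)))
    # identical groups (zero-variance difference): define t = 0, p = 1
    list(statistic = c(t = 0), parameter = c(df = length(group_a) - 1),
         p.value = 1)
  else tryCatch(
    stats::t.test(group_a, group_b, paired = (mode == "paired"),
                  var.equal = FALSE, alternative = "two.sided"),
    error = function(e) {
      if (!grepl("constant", conditionMessage(e))) stop(e)
      # both groups (or the paired differences) are constant: the test
      # degenerates; distinct means separate perfectly
      d <- mean(group_a) - mean(group_b)
      list(statistic = c(t = sign(d) * if (d == 0) 0 else Inf),
           parameter = c(df = NA_real_),
           p.value = if (d == 0) 1 else 0)
    })
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       percent_difference = percent_difference(mean(group_a), mean(group_b),
                                               reference = "b"),
       mode = mode, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Percent difference between two values
#'
#' `(a - b) / reference * 100`, sign preserved; rounding happens only at
#' the report layer (see [report_percent()]).
#'
#' @param a,b Values in the same units.
#' @param reference `"b"` (default) or `"a"`: which value to divide by.
#' @return Signed percent difference.
#' @examples
#' percent_difference(0.11, 0.08)   # 37.5
#' percent_difference(3.8, 8.9)     # -57.30337
#' @export
percent_difference <- function(a, b, reference = c("b", "a")) {
  reference <- match.arg(reference)
  ref <- if (reference == "b") b else a
  if (any(ref == 0)) stop("reference value must be non-zero")
  (a - b) / ref * 100
}

#' Display rounding for percent values
#'
#' Nearest integer, halves away from zero (reports quote percent
#' differences as whole percents).
#'
#' @param x Percent value(s).
#' @return Rounded value(s).
#' @examples
#' report_percent(37.5)   # 38
#' report_percent(-57.3)  # -57
#' @export
report_percent <- function(x) sign(x) * floor(abs(x) + 0.5)

# --- cohort table ---------------------------------------------------------

#' Cohort summary and comparison table per muscle
#'
#' For a long-format data frame of subject-level per-muscle metric
#' values in two cohorts, computes per muscle and cohort the mean, SD
#' (n-1 denominator) and t-based 95% confidence interval of the mean;
#' the Welch two-tailed comparison between cohorts with its percent
#' difference (reference = the reference cohort); both normality
#' p-values per cohort; and a Bonferroni-adjusted p-value column
#' (reported for transparency; the per-muscle raw p-values are the
#' primary result). A grand-average row summarizes the per-muscle
#' cohort means.
#'
#' Muscles represented by a single subject in a cohort get `NA`
#' confidence limits (flagged, not emitted as a degenerate interval).
#'
#' @param data Data frame with columns `subject`, `cohort`, `muscle`,
#'   `value`.
#' @param reference Cohort level used as reference for percent
#'   differences (default `"control"`).
#' @param conf_level Confidence level (default 0.95).
#' @param normality_B Monte-Carlo size for [normality_check()] (set 0 to
#'   skip the normality columns).
#' @return Data frame, one row per muscle plus a `"(all)"`
#'   grand-average row.
#' @export
cohort_table <- function(data, reference = "control", conf_level = 0.95,
                         normality_B = 2000) {
  stopifnot(all(c("subject", "cohort", "muscle", "value") %in% names(data)))
  cohorts <- unique(as.character(data$cohort))
  if (length(cohorts) != 2) stop("need exactly 2 cohorts")
  if (!reference %in% cohorts)
    stop("reference cohort '", reference, "' not present")
  other <- setdiff(cohorts, reference)
  muscles <- unique(as.character(data$muscle))

  ci <- function(v) {
    n <- length(v)
    if (n < 2) return(c(NA_real_, NA_real_))
    se <- stats::sd(v) / sqrt(n)
    q <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    mean(v) + c(-1, 1) * q * se
  }

  rows <- lapply(muscles, function(m) {
    va <- data$value[data$muscle == m & data$cohort == other]
    vb <- data$value[data$muscle == m & data$cohort == reference]
    if (length(va) == 0 || length(vb) == 0)
      stop("empty cohort for muscle ", m)
    # single-subject cells are flagged (NA comparison/CI), not emitted
    # as degenerate intervals
    cmp <- if (length(va) < 2 || length(vb) < 2)
      list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
           percent_difference = percent_difference(mean(va), mean(vb)))
    else group_compare(va, vb, mode = "two_sample")
    cia <- ci(va); cib <- ci(vb)
    row <- data.frame(
      muscle = m,
      mean_case = mean(va), sd_case = stats::sd(va),
      ci_lo_case = cia[1], ci_hi_case = cia[2], n_case = length(va),
      mean_ref = mean(vb), sd_ref = stats::sd(vb),
      ci_lo_ref = cib[1], ci_hi_ref = cib[2], n_ref = length(vb),
      t = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
      percent_difference = cmp$percent_difference)
    if (normality_B > 0) {
      row$p_lillie_case <- if (length(va) >= 4)
        normality_check(va, B = normality_B)$p_lilliefors else NA_real_
      row$p_ad_case <- if (length(va) >= 4)
        normality_check(va, B = normality_B)$p_anderson_darling else NA_real_
      row$p_lillie_ref <- if (length(vb) >= 4)
        normality_check(vb, B = normality_B)$p_lilliefors else NA_real_
      row$p_ad_ref <- if (length(vb) >= 4)
        normality_check(vb, B = normality_B)$p_anderson_darling else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))

  grand <- out[1, , drop = FALSE]
  grand[1, ] <- NA
  grand$muscle <- "(all)"
  grand$mean_case <- mean(out$mean_case)
  grand$sd_case <- stats::sd(out$mean_case)
  grand$mean_ref <- mean(out$mean_ref)
  grand$sd_ref <- stats::sd(out$mean_ref)
  grand$percent_difference <- percent_difference(grand$mean_case,
                                                 grand$mean_ref)
  rbind(out, grand)
}

# --- longitudinal ---------------------------------------------------------

#' Longitudinal percent change and monthly rate
#'
#' `pct = (v2 - v1)/v1 * 100` and `rate = pct / interval` in percent per
#' month. Vectorized over subjects; `cohort_mean = TRUE` additionally
#' returns the across-subject averages.
#'
#' @param v1,v2 Metric at visit 1 / visit 2 (same subjects, same order).
#' @param interval_months Between-visit interval(s) in months (> 0).
#' @param cohort_mean Also return across-subject means.
#' @return List with `pct`, `rate_per_month`, and (if requested)
#'   `mean_pct`, `mean_rate_per_month`.
#' @examples
#' longitudinal_change(100, 95.3, 6)   # -4.7% -> -0.783 %/month
#' @export
longitudinal_change <- function(v1, v2, interval_months,
                                cohort_mean = FALSE) {
  if (any(interval_months <= 0)) stop("interval must be > 0")
  if (any(v1 == 0)) stop("visit-1 value must be non-zero")
  if (length(v1) != length(v2)) stop("v1 and v2 must have equal length")
  pct <- (v2 - v1) / v1 * 100
  rate <- pct / interval_months
  out <- list(pct = pct, rate_per_month = rate)
  if (cohort_mean) {
    out$mean_pct <- mean(pct)
    out$mean_rate_per_month <- mean(rate)
  }
  out
}

#' Clinical score record
#'
#' Validates a row of clinical measures accompanying an imaging visit:
#' total and lower-limb ALSFRS-R (functional rating, 0-48 instrument
#' range) and left/right lower-limb hand-held dynamometry sums (lbs).
#'
#' @param subject_id Subject identifier.
#' @param visit Visit number.
#' @param ALSFRS_R_total Total functional score in \[0, 48\].
#' @param ALSFRS_R_LL Lower-limb subscore in \[0, 12\].
#' @param HHD_total_left,HHD_total_right Dynamometry sums, lbs (>= 0).
#' @param visit_interval Months since the previous visit (> 0, or NA
#'   for a first visit).
#' @return A one-row data frame of class `clinical_scores`.
#' @export
clinical_scores <- function(subject_id, visit, ALSFRS_R_total,
                            ALSFRS_R_LL, HHD_total_left, HHD_total_right,
                            visit_interval = NA_real_) {
  if (ALSFRS_R_total < 0 || ALSFRS_R_total > 48)
    stop("ALSFRS_R_total outside the 0-48 instrument range")
  if (ALSFRS_R_LL < 0 || ALSFRS_R_LL > 12)
    stop("ALSFRS_R_LL outside the 0-12 instrument range")
  if (HHD_total_left < 0 || HHD_total_right < 0)
    stop("HHD sums must be >= 0")
  if (!is.na(visit_interval) && visit_interval <= 0)
    stop("visit interval must be > 0")
  structure(data.frame(subject_id = subject_id, visit = visit,
                       ALSFRS_R_total = ALSFRS_R_total,
                       ALSFRS_R_LL = ALSFRS_R_LL,
                       HHD_total_left = HHD_total_left,
                       HHD_total_right = HHD_total_right,
                       visit_interval = visit_interval),
            class = c("clinical_scores", "data.frame"))
}
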