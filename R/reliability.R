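#' Two-sample Kolmogorov-Smirnov covariate-shift test
#'
#' Compares the empirical distribution of one feature between initial-test
#' sessions and retest sessions. No multiplicity correction is applied,
#' matching the uncorrected per-feature reporting convention of the
#' pipeline.
#'
#' @param initial_values,retest_values Numeric samples (>= 2 values each).
#' @return List `D` (KS statistic) and `p` (asymptotic p-value).
#' @export
ks_shift_test <- function(initial_values, retest_values) {
  if (length(initial_values) < 2 || length(retest_values) < 2)
    stop("need at least 2 values per sample")
  kt <- suppressWarnings(stats::ks.test(initial_values, retest_values))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Fisher exact label-shift test
#'
#' Two-tailed exact test of the 2x2 visit-by-class table, used instead of
#' a chi-squared test because per-visit class counts are small.
#'
#' @param initial_labels,retest_labels Binary label vectors
#'   (`"positive"`/`"negative"` or any two-level coding).
#' @return Two-tailed p-value.
#' @export
fisher_label_shift <- function(initial_labels, retest_labels) {
  if (length(initial_labels) == 0 || length(retest_labels) == 0)
    stop("each visit needs at least one session")
  lev <- sort(unique(c(as.character(initial_labels),
                       as.character(retest_labels))))
  tab <- rbind(table(factor(initial_labels, levels = lev)),
               table(factor(retest_labels, levels = lev)))
  stats::fisher.test(tab)$p.value
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Reliability of single measurements from a one-way ANOVA with subject as
#' the random grouping factor:
#' `ICC = (MS_R - MS_W) / (MS_R + (k - 1) MS_W)`, where `MS_R` is the
#' between-subject and `MS_W` the within-subject (residual) mean square
#' and `k` the measurements per subject. The p-value comes from
#' `F = MS_R / MS_W`; the confidence interval is the exact F-based
#' interval.
#'
#' @param table Subjects x k matrix of repeated measurements (rows with
#'   missing values are dropped).
#' @param conf Confidence level for the interval.
#' @return An `icc_result`: `icc`, `ms_r`, `ms_w`, `k`, `n`, `f_stat`,
#'   `p`, `ci`.
#' @export
icc_1_1 <- function(table, conf = 0.95) {
  table <- as.matrix(table)
  table <- table[stats::complete.cases(table), , drop = FALSE]
  n <- nrow(table)
  k <- ncol(table)
  if (n < 2 || k < 2)
    stop("ICC(1,1) needs >= 2 subjects with >= 2 measurements each")
  subj_means <- rowMeans(table)
  grand <- mean(table)
  ms_r <- k * sum((subj_means - grand)^2) / (n - 1)
  ms_w <- sum((table - subj_means)^2) / (n * (k - 1))
  if (ms_r == 0 && ms_w == 0)
    stop("all values identical; ICC undefined (0/0)")
  f <- ms_r / ms_w
  df1 <- n - 1
  df2 <- n * (k - 1)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  icc <- (ms_r - ms_w) / (ms_r + (k - 1) * ms_w)
  alpha <- 1 - conf
  fl <- f / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f * stats::qf(1 - alpha / 2, df2, df1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  structure(list(icc = icc, ms_r = ms_r, ms_w = ms_w, k = k, n = n,
                 f_stat = f, p = p, ci = ci), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.3f [%.3f, %.3f], F(%d,%d) = %.2f, p = %.4g\n",
              x$icc, x$ci[1], x$ci[2], x$n - 1, x$n * (x$k - 1), x$f_stat,
              x$p))
  invisible(x)
}

#' Cohen's kappa between two visits' labels
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_e = sum_k n_k1 n_k2 / N^2` over categories. The p-value is a
#' two-sided large-sample z-test of `kappa = 0` (null-variance formula).
#'
#' @param labels_a,labels_b Equal-length label vectors (visit 1, visit 2).
#' @return A `kappa_result`: `kappa`, `p_o`, `p_e`, `z`, `p`, `n`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  n <- length(labels_a)
  if (n == 0) stop("no paired labels")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  p_o <- mean(a == b)
  pa <- table(a) / n
  pb <- table(b) / n
  p_e <- sum(pa * pb)
  if (p_e >= 1)
    stop("both visits constant with the same class; kappa undefined")
  kappa <- (p_o - p_e) / (1 - p_e)
  # large-sample variance under H0: kappa = 0 (Fleiss)
  var0 <- (p_e + p_e^2 - sum(pa * pb * (pa + pb))) / (n * (1 - p_e)^2)
  z <- kappa / sqrt(var0)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(kappa = kappa, p_o = p_o, p_e = unname(p_e), z = z, p = p,
                 n = n), class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa = %.3f (p_o = %.3f, p_e = %.3f), z = %.2f, p = %.4g\n",
              x$kappa, x$p_o, x$p_e, x$z, x$p))
  invisible(x)
}

#' Percentage of individuals with a consistent outcome across visits
#'
#' @param labels_a,labels_b Paired label vectors.
#' @return Percentage in `[0, 100]`.
#' @export
consistency_percentage <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  100 * mean(as.character(labels_a) == as.character(labels_b))
}

#' Concept-drift report across paired visits
#'
#' Combines covariate-shift tests (per-feature KS), label-shift tests
#' (per-method Fisher), feature reliability (ICC on paired visits) and
#' outcome reliability (ICC of diagnostics, kappa and consistency of
#' labels) into one report. The advisory verdict mirrors the inference
#' logic for concept drift: drift is indicated when feature distributions
#' and label proportions are stable (significant fractions near the test
#' level, feature ICCs high) while the outcome labels themselves are
#' unreliable across visits (kappa/ICC near zero).
#'
#' @param features Wide feature data frame with columns `subject_id`,
#'   `visit` (`"initial"`/`"retest"`) and one column per feature.
#' @param label_sets Named list of label data frames, each with
#'   `subject_id`, `visit`, `label` and optionally `diagnostic`.
#' @param alpha Test level.
#' @param icc_low Threshold below which outcome reliability counts as low.
#' @param stable_frac Maximum significant fraction counted as "stable"
#'   (default `2 * alpha`).
#' @return A `drift_report` list; see fields in the implementation.
#' @export
drift_report <- function(features, label_sets, alpha = 0.05,
                         icc_low = 0.3, stable_frac = 2 * alpha) {
  meta_cols <- c("subject_id", "visit", "session_id", "cohort")
  feat_cols <- setdiff(colnames(features), meta_cols)
  ini <- features[features$visit == "initial", , drop = FALSE]
  ret <- features[features$visit == "retest", , drop = FALSE]
  paired <- intersect(ini$subject_id, ret$subject_id)
  if (length(paired) == 0) stop("no subjects with both visits")

  ks <- do.call(rbind, lapply(feat_cols, function(f) {
    r <- ks_shift_test(ini[[f]], ret[[f]])
    data.frame(feature = f, D = r$D, p = r$p)
  }))
  feat_icc <- vapply(feat_cols, function(f) {
    tab <- cbind(ini[[f]][match(paired, ini$subject_id)],
                 ret[[f]][match(paired, ret$subject_id)])
    tryCatch(icc_1_1(tab)$icc, error = function(e) NA_real_)
  }, numeric(1))

  lab_rows <- lapply(names(label_sets), function(nm) {
    ls <- label_sets[[nm]]
    li <- ls[ls$visit == "initial", ]
    lr <- ls[ls$visit == "retest", ]
    pr <- intersect(li$subject_id, lr$subject_id)
    a <- li$label[match(pr, li$subject_id)]
    b <- lr$label[match(pr, lr$subject_id)]
    kap <- tryCatch(cohens_kappa(a, b)$kappa, error = function(e) NA_real_)
    oicc <- if (!is.null(ls$diagnostic))
      tryCatch(icc_1_1(cbind(li$diagnostic[match(pr, li$subject_id)],
                             lr$diagnostic[match(pr, lr$subject_id)]))$icc,
               error = function(e) NA_real_) else NA_real_
    data.frame(method = nm,
               fisher_p = fisher_label_shift(li$label, lr$label),
               kappa = kap, outcome_icc = oicc,
               consistency_pct = consistency_percentage(a, b))
  })
  lab <- do.call(rbind, lab_rows)

  frac_ks_sig <- mean(ks$p <= alpha)
  frac_fisher_sig <- mean(lab$fisher_p <= alpha)
  mean_feat_icc <- mean(feat_icc, na.rm = TRUE)
  mean_kappa <- mean(lab$kappa, na.rm = TRUE)
  stable_features <- frac_ks_sig <= stable_frac
  stable_labels <- frac_fisher_sig <= stable_frac
  low_outcome_rel <- mean_kappa < icc_low &&
    (all(is.na(lab$outcome_icc)) ||
       mean(lab$outcome_icc, na.rm = TRUE) < icc_low)
  drift <- stable_features && stable_labels && low_outcome_rel
  verdict <- if (drift) "concept drift indicated"
             else "no concept drift indicated"
  structure(list(ks = ks, feature_icc = feat_icc, labels = lab,
                 frac_ks_significant = frac_ks_sig,
                 frac_fisher_significant = frac_fisher_sig,
                 mean_feature_icc = mean_feat_icc,
                 mean_kappa = mean_kappa, n_paired_subjects = length(paired),
                 alpha = alpha, verdict = verdict),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat("Concept-drift report (", x$n_paired_subjects,
      " paired subjects)\n", sep = "")
  cat(sprintf("  features: %.1f%% KS-significant, mean ICC %.2f\n",
              100 * x$frac_ks_significant, x$mean_feature_icc))
  cat(sprintf("  labels:   %.1f%% Fisher-significant, mean kappa %.2f\n",
              100 * x$frac_fisher_significant, x$mean_kappa))
  cat("  verdict:  ", x$verdict, "\n", sep = "")
  invisible(x)
}
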