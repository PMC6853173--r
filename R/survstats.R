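# Survival estimation and inferential statistics: Kaplan-Meier product-limit
# curves, log-rank tests, Fisher r-to-z comparison of two correlations,
# Pearson correlation with p, Benjamini-Hochberg adjustment, metastasis
# incidence summaries with chi-square, and qPCR delta-CT expression.

new_test_result <- function(statistic, p.value, method, ...) {
  stopifnot(p.value >= 0, p.value <= 1)
  structure(c(list(statistic = statistic, p.value = p.value,
                   method = method), list(...)),
            class = "xsub_test")
}

#' @export
print.xsub_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %s\n", x$method,
              format(x$statistic, digits = 4),
              format.pval(x$p.value, digits = 3)))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate for one group
#'
#' Standard product-limit conventions: censored times reduce the risk set
#' without a step, and at tied times deaths are processed before
#' censorings.
#'
#' @param time Non-negative follow-up times.
#' @param event Logical/0-1 event indicators (TRUE = event observed).
#' @return Object of class `km_curve`: data.frame with columns time,
#'   n_risk, n_event, n_censor, surv.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time < 0)) stop2("km_estimate: negative time")
  fit <- survival::survfit(survival::Surv(time, as.logical(event)) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Log-rank test comparing survival across groups
#'
#' Unweighted log-rank chi-square with k - 1 degrees of freedom for k
#' groups.
#'
#' @param time Non-negative follow-up times.
#' @param event Logical/0-1 event indicators.
#' @param group Group labels (>= 2 groups, each >= 1 record).
#' @return An `xsub_test` with fields statistic, p.value, df.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop2("logrank_test: negative time")
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop2("logrank_test: >= 2 groups required")
  if (!any(as.logical(event))) stop2("logrank_test: no events observed")
  fit <- survival::survdiff(
    survival::Surv(time, as.logical(event)) ~ group)
  df <- nlevels(group) - 1L
  new_test_result(unname(fit$chisq),
                  stats::pchisq(fit$chisq, df, lower.tail = FALSE),
                  "log-rank test", df = df)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value.
#'
#' @param r1,r2 Correlation coefficients with `|r| < 1`.
#' @param n1,n2 Sample sizes (>= 4) underlying each correlation.
#' @return An `xsub_test` with fields statistic (z), p.value, n1, n2.
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2) {
  for (r in c(r1, r2))
    if (!is.finite(r) || abs(r) >= 1)
      stop2("fisher_rz_compare: |r| must be < 1 (got %s)", format(r))
  n1 <- assert_count(n1, "n1", lower = 4L)
  n2 <- assert_count(n2, "n2", lower = 4L)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  new_test_result(z, 2 * stats::pnorm(-abs(z)),
                  "Fisher r-to-z comparison", n1 = n1, n2 = n2)
}

#' Pearson correlation with two-sided p-value
#'
#' r with the t-transform p-value on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return An `xsub_test` with fields statistic (r), p.value, n, df.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop2("pearson_with_p: equal-length vectors of >= 3 values required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop2("pearson_with_p: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_test_result(unname(ct$estimate), ct$p.value, "Pearson correlation",
                  n = length(x), df = unname(ct$parameter))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop2("bh_adjust: p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Metastasis incidence per genotype
#'
#' Percentage of animals per genotype carrying a given metastatic site
#' (or any site for `site = "any"`), with raw counts.
#'
#' @param cohort GEMM cohort table (see [kpn_incidence_fixture()]):
#'   data.frame with columns animal, genotype, time_days, event, sites
#'   (";"-separated site labels, empty string for none).
#' @param site One of [MET_SITES] or `"any"`.
#' @return data.frame with columns genotype, n, affected, incidence_pct.
#' @export
incidence_summary <- function(cohort, site = "any") {
  stopifnot(is.data.frame(cohort),
            all(c("genotype", "sites") %in% colnames(cohort)))
  if (nrow(cohort) == 0L) stop2("incidence_summary: empty cohort")
  if (!site %in% c(MET_SITES, "any"))
    stop2("incidence_summary: unknown site '%s'", site)
  site_sets <- strsplit(cohort$sites, ";", fixed = TRUE)
  affected <- if (site == "any") {
    vapply(site_sets, function(s) length(s[nzchar(s)]) > 0L, logical(1L))
  } else {
    vapply(site_sets, function(s) site %in% s, logical(1L))
  }
  out <- do.call(rbind, lapply(split(affected, cohort$genotype), function(a) {
    data.frame(n = length(a), affected = sum(a),
               incidence_pct = 100 * sum(a) / length(a))
  }))
  data.frame(genotype = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Two-sided Pearson chi-square with 1 degree of freedom, without Yates
#' continuity correction by default (a flag enables it).
#'
#' @param a,b,c,d Non-negative cell counts, row-wise:
#'   `matrix(c(a, c, b, d), 2)` i.e. rows (a, b) and (c, d).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return An `xsub_test` with fields statistic, p.value, df.
#' @export
chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts) | counts < 0))
    stop2("chisq_2x2: counts must be non-negative")
  if (sum(counts) == 0) stop2("chisq_2x2: all counts are zero")
  tab <- matrix(c(a, c, b, d), nrow = 2L)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_test_result(unname(ht$statistic), ht$p.value,
                  "chi-square test (2x2)", df = unname(ht$parameter))
}

#' Relative qPCR expression by the delta-CT method
#'
#' `2^-(ct_target - ct_reference)`, the expression of a target gene
#' relative to a reference gene (e.g. Actb).
#'
#' @param ct_target,ct_reference Finite CT values (vectors recycle as
#'   usual).
#' @return Relative expression values.
#' @export
delta_ct_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop2("delta_ct_expression: CT values must be finite")
  2^(-(ct_target - ct_reference))
}
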