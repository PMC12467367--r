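#' Statistical significance of an individual pre-post change
#'
#' The sum-of-standard-errors rule used with manual conversion tables: a
#' change is called statistically significant when the absolute difference
#' of the two measures strictly exceeds the sum of their standard errors.
#' The direction is polarity-aware: on a `higher_is_better` scale a measure
#' increase is an improvement, on a `higher_is_worse` (impairment-impact)
#' scale a decrease is. A z statistic \eqn{d/\sqrt{se_1^2+se_2^2}} is also
#' reported for transparency; the verdict uses only the sum-of-SEs rule.
#'
#' @param measure_1,se_1 first (pre) measure and standard error, logits.
#' @param measure_2,se_2 second (post) measure and standard error.
#' @param polarity `"higher_is_better"` or `"higher_is_worse"`.
#' @return A list of class `change_result`: the inputs plus `difference`
#'   (`measure_2 - measure_1`), `se_sum`, `significant`, `z`, `direction`
#'   (`improved` / `worsened` / `unchanged`).
#' @examples
#' significant_change(0, 0.3, 1.0, 0.3, "higher_is_better")
#' @export
significant_change <- function(measure_1, se_1, measure_2, se_2,
                               polarity = c("higher_is_better",
                                            "higher_is_worse")) {
  polarity <- match.arg(polarity)
  assert_scalar_num(measure_1, "measure_1")
  assert_scalar_num(measure_2, "measure_2")
  assert_scalar_num(se_1, "se_1"); assert_scalar_num(se_2, "se_2")
  if (se_1 <= 0 || se_2 <= 0)
    stop_rk("standard errors must be > 0", "raschkey_validation_error")
  d <- measure_2 - measure_1
  se_sum <- se_1 + se_2
  sig <- abs(d) > se_sum          # strict: |d| == se_sum is not significant
  direction <- if (d == 0) "unchanged"
  else if ((d > 0) == (polarity == "higher_is_better")) "improved"
  else "worsened"
  structure(list(measure_1 = measure_1, se_1 = se_1,
                 measure_2 = measure_2, se_2 = se_2,
                 difference = d, se_sum = se_sum, significant = sig,
                 z = d / sqrt(se_1^2 + se_2^2),
                 direction = direction, polarity = polarity),
            class = "change_result")
}

#' @export
print.change_result <- function(x, ...) {
  cat(sprintf(
    "%.2f (SE %.2f) -> %.2f (SE %.2f): difference %.2f vs SE sum %.2f -> %s (%s)\n",
    x$measure_1, x$se_1, x$measure_2, x$se_2, x$difference, x$se_sum,
    if (x$significant) "significant" else "not significant", x$direction))
  invisible(x)
}

#' Two-tailed paired t-test
#'
#' Thin wrapper around the standard paired t-test with explicit handling of
#' the degenerate zero-variance-of-differences case (t undefined, noted).
#'
#' @param x,y paired numeric vectors of equal length (at least 2).
#' @return List with `t`, `df`, `p_two_sided`, `mean_difference`, `note`
#'   (`NA` unless degenerate).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_rk("x and y must be paired vectors of equal length >= 2",
            "raschkey_validation_error")
  d <- x - y
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = length(d) - 1L, p_two_sided = NA_real_,
                mean_difference = mean(d),
                note = "zero variance of differences; t undefined"))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, mean_difference = mean(d), note = NA_character_)
}

#' Agreement analysis between two sets of person measures
#'
#' External-validity comparison of the same persons measured by two scoring
#' engines: per-person absolute measure difference and absolute SE
#' difference, a flag where the measure difference meets the disagreement
#' criterion (default 0.5 logits), summary minimum / maximum / mean, and a
#' two-tailed paired t-test on the measures.
#'
#' @param pairs data frame with columns `measure_a`, `se_a`, `measure_b`,
#'   `se_b` and optionally `person_id`.
#' @param criterion disagreement threshold in logits (flag when
#'   `|a - b| >= criterion`).
#' @return A list of class `agreement_report`: `table` (per-pair), `n`,
#'   `min`, `max`, `mean`, `n_flagged`, `criterion`, `t_test`.
#' @export
compare_measure_sets <- function(pairs, criterion = 0.5) {
  pairs <- as.data.frame(pairs)
  need <- c("measure_a", "se_a", "measure_b", "se_b")
  if (!all(need %in% names(pairs)))
    stop_rk(sprintf("pairs needs columns %s", paste(need, collapse = ", ")),
            "raschkey_validation_error")
  if (nrow(pairs) < 2L)
    stop_rk("need at least 2 pairs", "raschkey_validation_error")
  tab <- data.frame(
    person_id = pairs$person_id %||% sprintf("P%03d", seq_len(nrow(pairs))),
    abs_difference = abs(pairs$measure_a - pairs$measure_b),
    se_difference = abs(pairs$se_a - pairs$se_b))
  tab$exceeds_criterion <- tab$abs_difference >= criterion
  structure(list(table = tab, n = nrow(tab),
                 min = min(tab$abs_difference),
                 max = max(tab$abs_difference),
                 mean = mean(tab$abs_difference),
                 n_flagged = sum(tab$exceeds_criterion),
                 criterion = criterion,
                 t_test = paired_t_test(pairs$measure_a, pairs$measure_b)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Agreement over %d pairs: |difference| min %.2f, mean %.2f, max %.2f logits; %d pair(s) >= %.2f\n",
    x$n, x$min, x$mean, x$max, x$n_flagged, x$criterion))
  tt <- x$t_test
  if (is.na(tt$t)) cat("Paired t: undefined (", tt$note, ")\n", sep = "")
  else cat(sprintf("Paired t(%d) = %.3f, two-sided p = %.3f\n",
                   tt$df, tt$t, tt$p_two_sided))
  invisible(x)
}

#' Summarize a set of pre-post comparisons
#'
#' Tallies how many individual changes were statistically significant by the
#' sum-of-SEs rule and reports the share as a percentage (one decimal),
#' together with a paired t-test on the pre/post measures.
#'
#' @param changes a list of [significant_change()] results.
#' @return A list of class `outcome_summary`: `n`, `n_significant`,
#'   `proportion_significant_pct` (one decimal), `n_improved`, `t_test`.
#' @export
outcome_summary <- function(changes) {
  if (!length(changes))
    stop_rk("empty comparison list", "raschkey_validation_error")
  stopifnot(all(vapply(changes, inherits, logical(1), "change_result")))
  sig <- vapply(changes, `[[`, logical(1), "significant")
  m1 <- vapply(changes, `[[`, numeric(1), "measure_1")
  m2 <- vapply(changes, `[[`, numeric(1), "measure_2")
  structure(list(
    n = length(changes), n_significant = sum(sig),
    proportion_significant_pct = round_half_up(100 * mean(sig), 1),
    n_improved = sum(vapply(changes, `[[`, character(1),
                            "direction") == "improved"),
    t_test = if (length(changes) >= 2L) paired_t_test(m2, m1) else NULL),
    class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("%d of %d comparisons significant (%.1f%%); %d improved\n",
              x$n_significant, x$n, x$proportion_significant_pct,
              x$n_improved))
  invisible(x)
}
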