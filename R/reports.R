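#' Summarize intervention activity-group recordings
#'
#' Therapists record, per session week, the minutes spent in each of the six
#' intervention activity groups: I Preparation, II Rote practice/exercise,
#' III Simulated occupation, IV Restorative occupation, V Acquisitional
#' occupation, VI Adaptive occupation. Groups IV-VI are the occupation-based
#' methods. Percentages are computed on the grand total of minutes across
#' therapists and groups, rounded half-up to one decimal.
#'
#' @param records data frame with columns `therapist`, `sessions` and the
#'   six minute columns `I`..`VI` (one row per therapist).
#' @return A list of class `activity_summary`: `total_sessions`,
#'   `total_minutes`, `minutes` (named vector I..VI), `percent` (named,
#'   1 decimal), `occupation_based_percent` (groups IV+V+VI share, 1
#'   decimal).
#' @examples
#' recs <- data.frame(therapist = 1:2, sessions = c(3, 4),
#'                    I = c(0, 10), II = c(30, 0), III = c(0, 0),
#'                    IV = c(60, 90), V = c(30, 0), VI = c(0, 10))
#' activity_group_summary(recs)
#' @export
activity_group_summary <- function(records) {
  records <- as.data.frame(records)
  gnames <- c("I", "II", "III", "IV", "V", "VI")
  if (!all(c("therapist", "sessions", gnames) %in% names(records)))
    stop_rk("records needs columns therapist, sessions, I..VI",
            "raschkey_validation_error")
  if (!nrow(records))
    stop_rk("no activity records", "raschkey_validation_error")
  mins <- as.matrix(records[, gnames])
  if (any(mins < 0) || any(records$sessions < 0))
    stop_rk("minutes and session counts must be >= 0",
            "raschkey_validation_error")
  total <- sum(mins)
  if (total <= 0)
    stop_rk("zero total intervention minutes", "raschkey_validation_error")
  by_group <- colSums(mins)
  pct <- round_half_up(100 * by_group / total, 1)
  occ <- round_half_up(100 * sum(by_group[c("IV", "V", "VI")]) / total, 1)
  structure(list(total_sessions = sum(records$sessions),
                 total_minutes = total, minutes = by_group, percent = pct,
                 occupation_based_percent = occ,
                 n_therapists = nrow(records)),
            class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("%d sessions by %d therapist(s), %g min total\n",
              x$total_sessions, x$n_therapists, x$total_minutes))
  for (g in names(x$minutes))
    cat(sprintf("  %-4s %6g min  %5.1f%%\n", g, x$minutes[[g]],
                x$percent[[g]]))
  cat(sprintf("Occupation-based (IV+V+VI): %.1f%%\n",
              x$occupation_based_percent))
  invisible(x)
}

#' Read activity records from CSV
#' @param path CSV with columns `therapist`, `sessions`, `I`..`VI`.
#' @return Data frame of activity records.
#' @export
read_activity_records <- function(path) {
  if (!file.exists(path))
    stop_rk(sprintf("file not found: %s", path), "raschkey_io_error")
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a conversion table as CSV
#' @param tab a [conversion_table()].
#' @param path file path.
#' @export
write_conversion_table <- function(tab, path) {
  stopifnot(inherits(tab, "conversion_table"))
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Assemble a digital evaluation report
#'
#' Combines two (or more) scored evaluations of one person on one calibrated
#' scale into the summary-sheet structure of the software's digital report:
#' per evaluation the raw score, measure, SE and missing/imputed items, and
#' for each consecutive pair a polarity-aware significance-of-change block.
#' Measures print rounded to two decimals; the JSON serialization carries
#' full precision.
#'
#' @param person_id person identifier.
#' @param evaluations list of evaluations; each is a list with `date` (tag)
#'   and `result` (an [impute_and_measure()] result or a one-row
#'   [score_persons()] table).
#' @param calib the [calibration()] used for scoring.
#' @param comments optional named character vector of free-text comments per
#'   item.
#' @return A list of class `digital_report`.
#' @export
digital_report <- function(person_id, evaluations, calib, comments = NULL) {
  stopifnot(inherits(calib, "calibration"), length(evaluations) >= 1L)
  evs <- lapply(evaluations, function(ev) {
    res <- ev$result
    if (inherits(res, "imputation_result")) {
      list(date = ev$date, theta = res$measure$theta, se = res$measure$se,
           raw_score = res$measure$raw_score,
           n_missing = res$measure$n_missing,
           imputed_items = res$imputed$item_id, method = res$method)
    } else {
      list(date = ev$date, theta = res$theta[1], se = res$se[1],
           raw_score = res$raw_score[1], n_missing = res$n_missing[1],
           imputed_items = character(0), method = "complete")
    }
  })
  comparisons <- list()
  if (length(evs) >= 2L)
    for (i in seq_len(length(evs) - 1L))
      comparisons[[i]] <- significant_change(
        evs[[i]]$theta, evs[[i]]$se, evs[[i + 1]]$theta, evs[[i + 1]]$se,
        polarity = calib$spec$polarity)
  structure(list(person_id = person_id, scale_id = calib$spec$scale_id,
                 polarity = calib$spec$polarity, model = calib$provenance$model,
                 evaluations = evs, comparisons = comparisons,
                 comments = comments),
            class = "digital_report")
}

#' @export
print.digital_report <- function(x, ...) {
  cat(format_digital_report(x), sep = "\n")
  invisible(x)
}

#' Render a digital report as markdown
#' @param report a [digital_report()].
#' @return Character vector of markdown lines.
#' @export
format_digital_report <- function(report) {
  lines <- c(sprintf("# Evaluation report: person %s, scale %s",
                     report$person_id, report$scale_id),
             sprintf("Polarity: %s (improvement = measure %s)",
                     report$polarity,
                     if (report$polarity == "higher_is_better") "increase"
                     else "decrease"),
             "", "| Evaluation | Raw score | Measure | SE | Missing |",
             "|---|---|---|---|---|")
  for (ev in report$evaluations)
    lines <- c(lines, sprintf("| %s | %d | %.2f | %.2f | %d |", ev$date,
                              ev$raw_score, ev$theta, ev$se, ev$n_missing))
  if (length(report$comparisons)) {
    lines <- c(lines, "", "## Change")
    for (ch in report$comparisons)
      lines <- c(lines, sprintf(
        "- %.2f -> %.2f: difference %.2f vs SE sum %.2f: **%s** (%s)",
        ch$measure_1, ch$measure_2, ch$difference, ch$se_sum,
        if (ch$significant) "significant" else "not significant",
        ch$direction))
  }
  if (length(report$comments)) {
    lines <- c(lines, "", "## Comments",
               sprintf("- %s: %s", names(report$comments), report$comments))
  }
  lines
}

#' Write a digital report as JSON
#' @param report a [digital_report()].
#' @param path file path.
#' @export
write_digital_report <- function(report, path) {
  stopifnot(inherits(report, "digital_report"))
  x <- unclass(report)
  x$comparisons <- lapply(x$comparisons, unclass)
  write_json_canonical(c(list(schema = "raschkey/digital_report/1"), x), path)
}
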