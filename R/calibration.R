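#' Construct a calibration (item difficulties and category thresholds)
#'
#' A calibration holds the fixed parameters needed to score persons on a
#' scale: one difficulty per item (logits, with standard error) and one
#' ordered set of Rasch-Andrich thresholds per category-count group. The
#' identification conventions are part of the object: item difficulties are
#' mean-centered within the scale, and thresholds sum to zero within each
#' group. A dichotomous group has an empty threshold vector (its single
#' implicit threshold is 0 by the centering convention).
#'
#' @param spec a [scale_spec()].
#' @param difficulty numeric vector of item difficulties, named by item id
#'   (or in `spec` item order).
#' @param thresholds named list, one numeric vector per group id;
#'   `numeric(0)` for dichotomous groups. A group with m categories has
#'   m - 1 thresholds.
#' @param se item difficulty standard errors (optional; `NA` if unknown).
#' @param threshold_se list of threshold standard errors matching
#'   `thresholds` (optional).
#' @param model which Rasch variant produced the parameters:
#'   `"dichotomous"`, `"rating_scale"`, `"partial_credit"` or `"group"`.
#' @param note free-text provenance note.
#' @return An object of class `calibration`.
#' @export
calibration <- function(spec, difficulty, thresholds = NULL, se = NULL,
                        threshold_se = NULL,
                        model = c("group", "dichotomous", "rating_scale",
                                  "partial_credit"),
                        note = "") {
  stopifnot(inherits(spec, "scale_spec"))
  model <- match.arg(model)
  ids <- spec$items$item_id
  if (is.null(names(difficulty))) {
    if (length(difficulty) != length(ids))
      stop_rk("unnamed difficulty vector must cover every item",
              "raschkey_validation_error")
    names(difficulty) <- ids
  }
  if (!setequal(names(difficulty), ids))
    stop_rk("difficulty names must match the spec's item ids",
            "raschkey_validation_error")
  difficulty <- difficulty[ids]
  if (abs(mean(difficulty)) > 1e-9)
    stop_rk(sprintf("item difficulties must be mean-centered (mean = %.3g)",
                    mean(difficulty)),
            "raschkey_validation_error")

  if (is.null(thresholds)) thresholds <- list()
  for (g in spec$groups$group_id) {
    m <- spec$groups$n_categories[spec$groups$group_id == g]
    tau <- thresholds[[g]] %||% numeric(0)
    if (m == 2L) {
      if (length(tau) && any(tau != 0))
        stop_rk(sprintf("dichotomous group '%s' must have an empty threshold list", g),
                "raschkey_validation_error")
      thresholds[[g]] <- numeric(0)
    } else {
      if (length(tau) != m - 1L)
        stop_rk(sprintf("group '%s' needs %d thresholds, got %d",
                        g, m - 1L, length(tau)),
                "raschkey_validation_error")
      if (abs(sum(tau)) > 1e-9)
        stop_rk(sprintf("thresholds of group '%s' must sum to 0 (sum = %.3g)",
                        g, sum(tau)),
                "raschkey_validation_error")
      thresholds[[g]] <- as.numeric(tau)
    }
  }
  thresholds <- thresholds[spec$groups$group_id]

  if (is.null(se)) se <- rep(NA_real_, length(ids))
  if (is.null(names(se))) names(se) <- ids
  se <- se[ids]
  if (is.null(threshold_se))
    threshold_se <- lapply(thresholds, function(t) rep(NA_real_, length(t)))

  structure(list(spec = spec, difficulty = difficulty, se = se,
                 thresholds = thresholds, threshold_se = threshold_se,
                 provenance = list(
                   model = model,
                   centering = "items mean-zero per scale; thresholds mean-zero per group",
                   note = note)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration of '%s'> (%s model)\n", x$spec$scale_id,
              x$provenance$model))
  cat(sprintf("  %d item difficulties in [%.2f, %.2f] logits\n",
              length(x$difficulty), min(x$difficulty), max(x$difficulty)))
  for (g in names(x$thresholds)) {
    tau <- x$thresholds[[g]]
    cat(sprintf("  group '%s' thresholds: %s\n", g,
                if (length(tau)) paste(sprintf("%.3f", tau), collapse = ", ")
                else "(dichotomous)"))
  }
  invisible(x)
}

#' Read / write calibrations as JSON
#'
#' The serialization embeds the scale specification, so a calibration file is
#' self-contained for anchored scoring.
#'
#' @param calib a [calibration()].
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a [calibration()].
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration"))
  spec <- calib$spec
  x <- list(
    schema = "raschkey/calibration/1",
    scale = list(
      scale_id = spec$scale_id,
      polarity = spec$polarity,
      domain_vocabulary = spec$domain_vocabulary,
      groups = spec$groups,
      items = spec$items),
    model = calib$provenance$model,
    centering = calib$provenance$centering,
    note = calib$provenance$note,
    items = data.frame(item_id = names(calib$difficulty),
                       difficulty = unname(calib$difficulty),
                       se = unname(calib$se)),
    thresholds = calib$thresholds,
    threshold_se = calib$threshold_se)
  write_json_canonical(x, path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- read_json_file(path)
  if (!identical(x$schema, "raschkey/calibration/1"))
    stop_rk(sprintf("unrecognized calibration schema in %s", path),
            "raschkey_io_error")
  spec <- scale_spec(x$scale$scale_id, x$scale$items, x$scale$groups,
                     polarity = x$scale$polarity,
                     domain_vocabulary = x$scale$domain_vocabulary)
  thr <- lapply(x$thresholds, as.numeric)
  thr_se <- lapply(x$threshold_se, as.numeric)
  calibration(spec,
              difficulty = stats::setNames(x$items$difficulty, x$items$item_id),
              thresholds = thr,
              se = stats::setNames(x$items$se, x$items$item_id),
              threshold_se = thr_se,
              model = x$model, note = x$note %||% "")
}
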