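#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf("Rasch %s-model fit of '%s'\n", x$model,
              x$calibration$spec$scale_id))
  cat(sprintf("  %d persons (%d extreme), %d items",
              nrow(x$persons), sum(x$persons$extreme_flag),
              length(x$calibration$difficulty)))
  if (length(x$dropped_items))
    cat(sprintf(" (%d dropped)", length(x$dropped_items)))
  cat("\n")
  cat(sprintf("  converged: %s after %d iteration(s); log-likelihood %.2f\n",
              x$converged, x$iterations, x$logLik))
  cat(sprintf("  item difficulty range: [%.2f, %.2f] logits\n",
              min(x$calibration$difficulty), max(x$calibration$difficulty)))
  invisible(x)
}

#' Extract item parameters from a Rasch fit
#'
#' @param object a [rasch()] fit.
#' @param what `"difficulty"` for the item difficulties, `"thresholds"` for
#'   the per-group threshold list, `"all"` for both.
#' @param ... unused.
#' @return Named numeric vector, list, or list of both.
#' @export
coef.rasch_fit <- function(object, what = c("difficulty", "thresholds", "all"),
                           ...) {
  what <- match.arg(what)
  switch(what,
         difficulty = object$calibration$difficulty,
         thresholds = object$calibration$thresholds,
         all = list(difficulty = object$calibration$difficulty,
                    thresholds = object$calibration$thresholds))
}

#' @export
logLik.rasch_fit <- function(object, ...) {
  npar <- length(object$calibration$difficulty) - 1L +
    length(unlist(object$calibration$thresholds)) +
    sum(!object$persons$extreme_flag)
  structure(object$logLik, df = npar, class = "logLik")
}

#' Residuals of a Rasch fit
#'
#' Score residuals \eqn{x - E} or standardized residuals
#' \eqn{(x - E)/\sqrt{W}} for every observed cell; missing cells stay `NA`.
#'
#' @param object a [rasch()] fit.
#' @param type `"standardized"` (default) or `"response"`.
#' @param ... unused.
#' @return Person-by-item numeric matrix.
#' @export
residuals.rasch_fit <- function(object, type = c("standardized", "response"),
                                ...) {
  type <- match.arg(type)
  standardized_residuals(object$responses, object$calibration,
                         object$persons, standardize = type == "standardized")
}

standardized_residuals <- function(responses, calib, persons = NULL,
                                   standardize = TRUE) {
  x <- unclass(responses)
  if (is.null(persons)) persons <- score_persons(responses, calib)
  mom <- item_moments(persons$theta, calib, colnames(x))
  r <- x - mom$E
  if (standardize) r <- r / sqrt(mom$W)
  r[is.na(x)] <- NA
  dimnames(r) <- dimnames(x)
  r
}

#' Predict person measures for new response data
#'
#' Anchored scoring of `newdata` against the fitted calibration; with
#' `newdata = NULL` the fitted person table is returned.
#'
#' @param object a [rasch()] fit.
#' @param newdata a [response_matrix()] (or coercible) on the same scale.
#' @param ... passed to [score_persons()].
#' @return Person-measure data frame (see [score_persons()]).
#' @export
predict.rasch_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$persons)
  score_persons(newdata, object$calibration, ...)
}

#' Simulate response matrices from a Rasch fit
#'
#' Draws ratings from the fitted category probabilities at the fitted (or
#' supplied) person measures.
#'
#' @param object a [rasch()] fit.
#' @param nsim number of simulated matrices.
#' @param seed integer seed (required for reproducibility).
#' @param theta person measures to simulate at; defaults to the fitted ones.
#' @param ... unused.
#' @return A list of `nsim` [response_matrix()] objects.
#' @export
simulate.rasch_fit <- function(object, nsim = 1, seed = NULL, theta = NULL,
                               ...) {
  if (is.null(theta)) theta <- object$persons$theta
  lapply(seq_len(nsim), function(i) {
    simulate_responses(simulation_config(
      object$calibration$spec, object$calibration,
      n_persons = length(theta), theta = theta,
      seed = if (is.null(seed)) i else seed + i - 1L))$responses
  })
}

#' Summarize a Rasch fit
#'
#' Collects the standard validation evidence: item difficulties with fit
#' statistics (infit/outfit mean squares and standardized fit, point-measure
#' correlation), person/item reliability and separation, and the
#' rating-category diagnostics.
#'
#' @param object a [rasch()] fit.
#' @param ... unused.
#' @return An object of class `summary.rasch_fit`.
#' @export
summary.rasch_fit <- function(object, ...) {
  fit <- item_fit(object$responses, object$calibration,
                  persons = object$persons)
  pm <- point_measure_correlation(object$responses, object$persons)
  fit$point_measure_r <- pm$r[match(fit$item_id, pm$item_id)]
  rel_p <- reliability_separation(object$persons)
  rel_i <- reliability_separation(
    data.frame(theta = object$calibration$difficulty,
               se = object$calibration$se), extremes = TRUE)
  cats <- category_diagnostics(object$responses, object$calibration,
                               persons = object$persons)
  structure(list(fit = object, items = fit, person_reliability = rel_p,
                 item_reliability = rel_i, categories = cats),
            class = "summary.rasch_fit")
}

#' @export
print.summary.rasch_fit <- function(x, ...) {
  print(x$fit)
  cat("\nItem statistics:\n")
  it <- x$items
  it$difficulty <- round(x$fit$calibration$difficulty[it$item_id], 2)
  print(format(data.frame(item = it$item_id, difficulty = it$difficulty,
                          infit = round(it$infit_mnsq, 2),
                          outfit = round(it$outfit_mnsq, 2),
                          infit_z = round(it$infit_z, 2),
                          outfit_z = round(it$outfit_z, 2),
                          pt_meas_r = round(it$point_measure_r, 2)),
               justify = "left"),
        row.names = FALSE)
  cat(sprintf("\nPerson separation %.2f, reliability %.2f; item separation %.2f, reliability %.2f\n",
              x$person_reliability$separation,
              x$person_reliability$reliability,
              x$item_reliability$separation,
              x$item_reliability$reliability))
  invisible(x)
}

#' Plot a Rasch fit as a key form
#'
#' Shorthand for plotting the fitted calibration's key form; see
#' [keyform()].
#'
#' @param x a [rasch()] fit.
#' @param person optional row of the person table (or a person id) to
#'   overlay as a vertical measure line with SE whiskers.
#' @param ... passed to [plot.keyform()].
#' @export
plot.rasch_fit <- function(x, person = NULL, ...) {
  kf <- keyform(x$calibration)
  if (is.character(person))
    person <- x$persons[x$persons$person_id == person, ]
  plot(kf, person = person, ...)
}
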