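#' Raw-score to measure conversion table
#'
#' For a complete answered-item set, maps every attainable raw score to a
#' logit measure and model standard error. Interior scores solve the test
#' characteristic curve equation \eqn{\sum_i E_i(\theta) = s} to a residual
#' below 1e-8 score units; the extreme scores (0 and the maximum) are first
#' adjusted into the interior by the extreme-score adjustment and flagged.
#'
#' @param calib a [calibration()].
#' @param items item ids forming the answered set (default: whole scale).
#' @param control a [rasch_control()] (extreme-score adjustment).
#' @return A data frame of class `conversion_table` with columns
#'   `raw_score`, `measure`, `se`, `extreme_flag`; measures are strictly
#'   increasing in the raw score.
#' @export
conversion_table <- function(calib, items = names(calib$difficulty),
                             control = rasch_control()) {
  stopifnot(inherits(calib, "calibration"))
  if (!length(items))
    stop_rk("empty item subset", "raschkey_validation_error")
  if (anyNA(match(items, names(calib$difficulty))))
    stop_rk("items not covered by the calibration", "raschkey_config_error")
  m <- item_categories(calib$spec, items)
  smax <- sum(m - 1L)
  scores <- 0:smax
  adj <- control$extreme_score_adjustment
  target <- pmin(pmax(scores, adj), smax - adj)
  obs <- matrix(TRUE, length(scores), length(items),
                dimnames = list(NULL, items))
  theta <- solve_theta(target, obs, calib)
  se <- person_se(theta, obs, calib)
  structure(data.frame(raw_score = scores, measure = theta, se = se,
                       extreme_flag = scores == 0L | scores == smax),
            class = c("conversion_table", "data.frame"),
            items = items, scale_id = calib$spec$scale_id)
}

#' Key-form layout of a calibrated scale
#'
#' The key form places every item's category boundaries (Rasch-Andrich
#' thresholds, the 50/50 points between adjacent categories) on the logit
#' axis: \eqn{\delta_i} for a dichotomous item, \eqn{\delta_i + \tau_{g,k}}
#' for polytomous ones. Items are ordered by difficulty with the most
#' frequently impacted (easiest-to-endorse, lowest \eqn{\delta}) items
#' first, i.e. at the bottom of the plotted hierarchy. Boundary positions
#' within an item are listed in threshold order even if their values are
#' disordered.
#'
#' @param calib a [calibration()].
#' @return An object of class `keyform`: data frame `items` (one row per
#'   item in hierarchy order: `item_id`, `label`, `group_id`,
#'   `n_categories`, `difficulty`) and list `boundaries` of per-item
#'   boundary positions.
#' @export
keyform <- function(calib) {
  stopifnot(inherits(calib, "calibration"))
  spec <- calib$spec
  ord <- order(calib$difficulty)   # most frequently impacted first
  items <- spec$items[ord, , drop = FALSE]
  m <- item_categories(spec)[items$item_id]
  df <- data.frame(item_id = items$item_id, label = items$label,
                   group_id = items$group_id, n_categories = unname(m),
                   difficulty = unname(calib$difficulty[items$item_id]),
                   stringsAsFactors = FALSE, row.names = NULL)
  boundaries <- lapply(seq_len(nrow(df)), function(i) {
    tau <- calib$thresholds[[df$group_id[i]]]
    if (!length(tau)) df$difficulty[i] else df$difficulty[i] + tau
  })
  names(boundaries) <- df$item_id
  structure(list(items = df, boundaries = boundaries,
                 scale_id = spec$scale_id, polarity = spec$polarity),
            class = "keyform")
}

#' @export
print.keyform <- function(x, ...) {
  cat(sprintf("<keyform of '%s'> %d items, difficulty hierarchy %.2f .. %.2f logits\n",
              x$scale_id, nrow(x$items), min(x$items$difficulty),
              max(x$items$difficulty)))
  invisible(x)
}

#' Write a key form as JSON
#' @param kf a [keyform()].
#' @param path file path.
#' @export
write_keyform <- function(kf, path) {
  stopifnot(inherits(kf, "keyform"))
  write_json_canonical(list(schema = "raschkey/keyform/1",
                            scale_id = kf$scale_id, polarity = kf$polarity,
                            items = kf$items, boundaries = kf$boundaries),
                       path)
}

#' Plot a key form
#'
#' Draws each item as a horizontal row with its category boundaries marked
#' at their logit positions (`:` semantics of the printed key forms: a
#' boundary is the 50/50 point between adjacent categories), shaded by
#' category-count group. A person measure can be overlaid as a vertical
#' line with SE whiskers.
#'
#' @param x a [keyform()].
#' @param person optional one-row data frame with `theta` and `se` (a row of
#'   a [score_persons()] table).
#' @param ... passed to [graphics::plot()].
#' @export
plot.keyform <- function(x, person = NULL, ...) {
  df <- x$items
  n <- nrow(df)
  rng <- range(unlist(x$boundaries))
  groups <- unique(df$group_id)
  shade <- stats::setNames(grDevices::hcl.colors(max(3, length(groups)),
                                                 "Pastel 1")[seq_along(groups)],
                           groups)
  graphics::plot(NA, xlim = rng + c(-1, 1), ylim = c(0.5, n + 0.5),
                 xlab = "measure (logits)", ylab = "", yaxt = "n",
                 main = sprintf("Key form: %s", x$scale_id), ...)
  graphics::axis(2, at = seq_len(n), labels = df$item_id, las = 2,
                 cex.axis = 0.5)
  for (i in seq_len(n)) {
    b <- x$boundaries[[i]]
    graphics::rect(rng[1] - 1, i - 0.4, rng[2] + 1, i + 0.4,
                   col = shade[[df$group_id[i]]], border = NA)
    graphics::points(b, rep(i, length(b)), pch = "|", cex = 0.8)
  }
  if (!is.null(person) && nrow(person)) {
    graphics::abline(v = person$theta[1], col = "red", lwd = 2)
    graphics::abline(v = person$theta[1] + c(-1, 1) * person$se[1],
                     col = "blue", lty = 2)
  }
  invisible(x)
}

#' Measure a person with missing ratings imputed from the key form
#'
#' Handles up to four missing ratings. With method `"anchored_ml"` the
#' provisional measure is the anchored maximum-likelihood estimate from the
#' answered items; with `"keyform_L1"` it is the key-form reading: the
#' vertical line through the score profile minimizing the total L1 distance
#' \eqn{\sum_i |x_i - E_i(\theta)|} over answered items (a flat minimizing
#' interval resolves to its midpoint). Each missing item is then assigned
#' its most probable category at the provisional measure (ties resolve to
#' the lower category), and the final measure and SE are re-estimated from
#' the completed response vector with the imputed cells flagged.
#'
#' @param person_responses a single person's ratings: named vector (names =
#'   item ids, `NA` = missing) or a one-row [response_matrix()].
#' @param calib a [calibration()].
#' @param method `"anchored_ml"` (default) or `"keyform_L1"`.
#' @param control a [rasch_control()].
#' @return A list of class `imputation_result`: `measure` (one-row person
#'   table for the completed vector), `provisional_theta`, `imputed`
#'   (data frame `item_id`, `category`, `probability`), `method`,
#'   `completed` (the completed rating vector).
#' @export
impute_and_measure <- function(person_responses, calib,
                               method = c("anchored_ml", "keyform_L1"),
                               control = rasch_control()) {
  method <- match.arg(method)
  stopifnot(inherits(calib, "calibration"))
  spec <- calib$spec
  ids <- spec$items$item_id
  if (inherits(person_responses, "response_matrix") ||
      is.matrix(person_responses)) {
    if (nrow(person_responses) != 1L)
      stop_rk("impute_and_measure takes a single person",
              "raschkey_validation_error")
    v <- stats::setNames(as.integer(person_responses[1, ]),
                         colnames(person_responses))
  } else v <- person_responses
  if (is.null(names(v)) || !setequal(names(v), ids))
    stop_rk("person_responses must be named by the scale's item ids",
            "raschkey_validation_error")
  v <- v[ids]
  miss <- names(v)[is.na(v)]
  if (length(miss) == length(v))
    stop_rk("all ratings are missing", "raschkey_validation_error")
  if (length(miss) > 4L)
    stop_rk(sprintf(
      "%d ratings are missing; imputation is limited to at most 4 missing values",
      length(miss)), "raschkey_imputation_error")
  m <- item_categories(spec)
  for (i in names(v)[!is.na(v)])
    if (v[[i]] < 0L || v[[i]] > m[[i]] - 1L)
      stop_rk(sprintf("rating %d outside 0..%d for item '%s'",
                      v[[i]], m[[i]] - 1L, i), "raschkey_validation_error")

  answered <- names(v)[!is.na(v)]
  theta0 <- if (method == "anchored_ml") {
    anchored_theta(v[answered], calib, control)
  } else {
    keyform_L1_theta(v[answered], calib)
  }

  completed <- v
  imputed <- data.frame(item_id = character(0), category = integer(0),
                        probability = numeric(0))
  for (i in miss) {
    p <- category_probabilities(theta0, i, calib)
    j <- which(p == max(p))[1] - 1L   # tie -> lower category
    completed[[i]] <- as.integer(j)
    imputed <- rbind(imputed, data.frame(item_id = i, category = j,
                                         probability = unname(max(p))))
  }
  mat <- matrix(completed, nrow = 1, dimnames = list("person", ids))
  measure <- score_persons(response_matrix(mat, spec), calib, control)
  measure$n_missing <- length(miss)
  structure(list(measure = measure, provisional_theta = theta0,
                 imputed = imputed, method = method, completed = completed),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("Imputed measure (%s): theta = %.2f (SE %.2f), raw %d, %d imputed item(s)\n",
              x$method, x$measure$theta, x$measure$se, x$measure$raw_score,
              nrow(x$imputed)))
  if (nrow(x$imputed)) print(x$imputed, row.names = FALSE)
  invisible(x)
}

# anchored ML theta for a named complete sub-vector of ratings
anchored_theta <- function(v, calib, control = rasch_control()) {
  items <- names(v)
  m <- item_categories(calib$spec, items)
  smax <- sum(m - 1L); r <- sum(v)
  adj <- control$extreme_score_adjustment
  target <- min(max(r, adj), smax - adj)
  obs <- matrix(TRUE, 1, length(items), dimnames = list(NULL, items))
  solve_theta(target, obs, calib)
}

# key-form L1 reading: theta minimizing sum |x_i - E_i(theta)|, located on a
# 0.001-logit lattice (coarse scan then local refinement; the loss is
# continuous with a single minimizing region). A flat minimizing interval
# resolves to its midpoint.
keyform_L1_theta <- function(v, calib) {
  items <- names(v)
  l1 <- function(grid) {
    mom <- item_moments(grid, calib, items)
    rowSums(abs(sweep(mom$E, 2, as.numeric(v))))
  }
  coarse <- seq(-10, 10, by = 0.01)
  lc <- l1(coarse)
  hit <- range(coarse[lc <= min(lc) + 1e-9])
  fine <- seq(hit[1] - 0.02, hit[2] + 0.02, by = 0.001)
  lf <- l1(fine)
  best <- which(lf <= min(lf) + 1e-12)
  mean(range(fine[best]))
}
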