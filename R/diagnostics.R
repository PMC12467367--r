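#' Item fit statistics (infit/outfit mean squares and standardized fit)
#'
#' For every observed cell the standardized residual is
#' \eqn{z_{ni} = (x_{ni} - E_{ni})/\sqrt{W_{ni}}}. Per item,
#' outfit MnSq is the unweighted mean of \eqn{z^2} and infit MnSq the
#' information-weighted form \eqn{\sum (x-E)^2 / \sum W}. The standardized
#' statistics (ZSTD) use the Wilson-Hilferty cube-root transform
#' \eqn{z = (MnSq^{1/3} - 1)(3/q) + q/3}, where \eqn{q^2} is the model
#' variance of the mean square: \eqn{q_u^2 = \sum(C/W^2)/N^2 - 1/N} for
#' outfit and \eqn{q_v^2 = \sum(C - W^2)/(\sum W)^2} for infit, with
#' \eqn{C} the fourth central moment of the category distribution.
#' Persons with extreme raw scores carry no misfit information and are
#' excluded; items with fewer than 2 usable observations are reported as
#' `NA` and flagged undefined.
#'
#' @param responses a [response_matrix()] (or coercible).
#' @param calib a [calibration()].
#' @param persons optional person-measure table from [score_persons()]
#'   (recomputed when absent).
#' @param mnsq_max,z_min combined misfit rule: an item is flagged when
#'   MnSq `>= mnsq_max` *and* ZSTD `>= z_min` (on either infit or outfit).
#' @return Data frame with one row per item: `item_id`, `n_obs`,
#'   `infit_mnsq`, `outfit_mnsq`, `infit_z`, `outfit_z`, `misfit`,
#'   `undefined`.
#' @export
item_fit <- function(responses, calib, persons = NULL, mnsq_max = 1.4,
                     z_min = 2) {
  spec <- calib$spec
  if (!inherits(responses, "response_matrix"))
    responses <- response_matrix(responses, spec)
  x <- unclass(responses)
  if (is.null(persons)) persons <- score_persons(responses, calib)
  use <- !persons$extreme_flag
  xs <- x[use, , drop = FALSE]
  mom <- item_moments(persons$theta[use], calib, colnames(x))
  obs <- !is.na(xs)
  R2 <- (xs - mom$E)^2
  R2[!obs] <- 0
  W <- mom$W * obs
  C <- mom$C * obs
  n_obs <- colSums(obs)
  sumZ2 <- colSums(R2 / pmax(mom$W, 1e-12) * obs)

  outfit <- ifelse(n_obs > 0, sumZ2 / n_obs, NA_real_)
  infit <- ifelse(n_obs > 0, colSums(R2) / pmax(colSums(W), 1e-12), NA_real_)
  q2_out <- colSums((C / pmax(mom$W, 1e-12)^2) * obs) / n_obs^2 - 1 / n_obs
  q2_in <- colSums(C - W^2 * obs) / pmax(colSums(W), 1e-12)^2
  wh <- function(mnsq, q2) {
    q <- sqrt(pmax(q2, 1e-12))
    (mnsq^(1 / 3) - 1) * (3 / q) + q / 3
  }
  outfit_z <- wh(outfit, q2_out)
  infit_z <- wh(infit, q2_in)
  undefined <- n_obs < 2L
  outfit[undefined] <- infit[undefined] <- NA_real_
  outfit_z[undefined] <- infit_z[undefined] <- NA_real_
  misfit <- !undefined &
    ((infit >= mnsq_max & infit_z >= z_min) |
       (outfit >= mnsq_max & outfit_z >= z_min))
  data.frame(item_id = colnames(x), n_obs = as.integer(n_obs),
             infit_mnsq = infit, outfit_mnsq = outfit,
             infit_z = infit_z, outfit_z = outfit_z,
             misfit = misfit, undefined = undefined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Point-measure correlations
#'
#' Pearson correlation between each item's observed ratings and the measures
#' of the persons who answered it. Items below the removal threshold are
#' flagged; items with constant ratings have undefined correlation and are
#' flagged for removal review.
#'
#' @inheritParams item_fit
#' @param threshold flagging threshold (items with `r < threshold` are
#'   inconsistent with the scale's construct).
#' @return Data frame: `item_id`, `n_obs`, `r`, `flagged`, `undefined`.
#' @export
point_measure_correlation <- function(responses, persons, threshold = 0.12) {
  x <- unclass(responses)
  theta <- persons$theta
  out <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    keep <- !is.na(v)
    if (sum(keep) < 2L || length(unique(v[keep])) < 2L ||
        stats::sd(theta[keep]) == 0)
      return(data.frame(item_id = colnames(x)[j], n_obs = sum(keep),
                        r = NA_real_, flagged = TRUE, undefined = TRUE))
    r <- stats::cor(v[keep], theta[keep])
    data.frame(item_id = colnames(x)[j], n_obs = sum(keep), r = r,
               flagged = r < threshold, undefined = FALSE)
  })
  do.call(rbind, out)
}

#' Rating-category diagnostics
#'
#' Evaluates, for every category-count group, the five standard
#' rating-scale quality criteria: (1) at least `min_count` observations per
#' category, (2) average measures of the persons choosing each category
#' advance monotonically with the category, (3) category outfit MnSq at most
#' `outfit_max`, (4) thresholds ordered, and (5) adjacent thresholds
#' advancing by at least `advance_min` logits. An empty category is a
#' count-criterion failure, not an error.
#'
#' Category outfit here is the ratio of the observed to the model-expected
#' sum of squared standardized rating residuals over the responses in the
#' category, so its expectation is 1 under the model for every category —
#' including rarely used ones in a cohort far from the items, where the raw
#' conditional mean of squared residuals is structurally inflated.
#'
#' @inheritParams item_fit
#' @param min_count,outfit_max,advance_min criterion constants (defaults
#'   10 observations, 1.5, 1.4 logits).
#' @return An object of class `category_diagnostics`: per group, a category
#'   table plus per-criterion pass/fail.
#' @export
category_diagnostics <- function(responses, calib, persons = NULL,
                                 min_count = 10, outfit_max = 1.5,
                                 advance_min = 1.4) {
  spec <- calib$spec
  if (!inherits(responses, "response_matrix"))
    responses <- response_matrix(responses, spec)
  x <- unclass(responses)
  if (is.null(persons)) persons <- score_persons(responses, calib)
  mom <- item_moments(persons$theta, calib, colnames(x))

  groups <- lapply(stats::setNames(spec$groups$group_id,
                                   spec$groups$group_id), function(g) {
    cols <- which(spec$items$group_id == g)
    mg <- spec$groups$n_categories[spec$groups$group_id == g]
    xg <- x[, cols, drop = FALSE]
    th <- matrix(persons$theta, nrow(x), length(cols))
    Eg <- mom$E[, cols, drop = FALSE]
    Wg <- pmax(mom$W[, cols, drop = FALSE], 1e-12)
    pg <- prob_array(persons$theta, calib$difficulty[colnames(x)[cols]],
                     eff_tau(calib$thresholds[[g]], mg))
    tab <- lapply(seq_len(mg) - 1L, function(j) {
      sel <- !is.na(xg) & xg == j
      # observed-to-expected ratio of squared standardized rating residuals
      # for responses in this category; expectation 1 under the model
      z2j <- (j - Eg)^2 / Wg
      expected <- sum((pg[, , j + 1L] * z2j)[!is.na(xg)])
      data.frame(category = j, count = sum(sel),
                 avg_measure = if (any(sel)) mean(th[sel]) else NA_real_,
                 outfit_mnsq = if (any(sel) && expected > 0)
                   sum(z2j[sel]) / expected else NA_real_)
    })
    tab <- do.call(rbind, tab)
    tau <- calib$thresholds[[g]]
    advance <- if (length(tau) >= 2L) diff(tau) else numeric(0)
    am <- tab$avg_measure[!is.na(tab$avg_measure)]
    crit <- list(
      count = all(tab$count >= min_count),
      monotone_measures = length(am) == mg && !is.unsorted(am, strictly = TRUE),
      outfit = all(is.na(tab$outfit_mnsq) | tab$outfit_mnsq <= outfit_max) &&
        !anyNA(tab$outfit_mnsq),
      ordered_thresholds = !length(tau) || !is.unsorted(tau, strictly = TRUE),
      threshold_advance = !length(advance) || all(advance >= advance_min))
    list(group_id = g, n_categories = mg, table = tab, thresholds = tau,
         advance = advance, criteria = crit, pass = all(unlist(crit)))
  })
  structure(list(groups = groups,
                 criteria_constants = list(min_count = min_count,
                                           outfit_max = outfit_max,
                                           advance_min = advance_min),
                 pass = all(vapply(groups, `[[`, logical(1), "pass"))),
            class = "category_diagnostics")
}

#' @export
print.category_diagnostics <- function(x, ...) {
  for (g in x$groups) {
    cat(sprintf("Group '%s' (%d categories)%s\n", g$group_id, g$n_categories,
                if (g$pass) ": all criteria met" else ": CRITERIA NOT MET"))
    print(transform(g$table, avg_measure = round(avg_measure, 2),
                    outfit_mnsq = round(outfit_mnsq, 2)), row.names = FALSE)
    if (length(g$thresholds))
      cat(sprintf("  thresholds: %s (advance %s)\n",
                  paste(round(g$thresholds, 2), collapse = ", "),
                  paste(round(g$advance, 2), collapse = ", ")))
    fails <- names(g$criteria)[!unlist(g$criteria)]
    if (length(fails)) cat("  failed:", paste(fails, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Principal components analysis of standardized residuals
#'
#' Unidimensionality diagnostic: eigendecomposition of the item-by-item
#' correlation matrix of standardized residuals (missing cells excluded
#' pairwise). Under the model the residuals are uncorrelated noise and no
#' contrast dominates; a first contrast explaining more than the threshold
#' share of residual variance signals a secondary dimension.
#'
#' @inheritParams item_fit
#' @param share_max pass/fail threshold for the first contrast's share of
#'   residual variance, in percent (default 10).
#' @return An object of class `pca_report`: `eigenvalues` (non-increasing),
#'   `first_contrast` (eigenvalue, in item units), `first_contrast_share`
#'   (percent of residual variance), `loadings` of the first contrast,
#'   `pass`.
#' @export
pca_residuals <- function(responses, calib, persons = NULL, share_max = 10) {
  spec <- calib$spec
  if (!inherits(responses, "response_matrix"))
    responses <- response_matrix(responses, spec)
  if (ncol(responses) < 3L)
    stop_rk("residual PCA needs at least 3 items", "raschkey_validation_error")
  Z <- standardized_residuals(responses, calib, persons)
  R <- suppressWarnings(stats::cor(Z, use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0
  diag(R) <- 1
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  values <- ev$values
  share <- values / sum(values) * 100
  structure(list(eigenvalues = values,
                 first_contrast = values[1],
                 first_contrast_share = share[1],
                 shares = share,
                 loadings = stats::setNames(ev$vectors[, 1], colnames(Z)),
                 share_max = share_max,
                 pass = share[1] <= share_max),
            class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  cat(sprintf(
    "Residual PCA: first contrast %.2f item units = %.1f%% of residual variance (threshold %.0f%%) -> %s\n",
    x$first_contrast, x$first_contrast_share, x$share_max,
    if (x$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Separation and reliability of a set of measures
#'
#' From observed measures and their model standard errors: the root mean
#' square error \eqn{RMSE = \sqrt{\mathrm{mean}(SE^2)}}, the noise-adjusted
#' ("true") spread \eqn{SD_{adj}^2 = \max(SD_{obs}^2 - RMSE^2, 0)}, the
#' separation index \eqn{G = SD_{adj}/RMSE}, reliability
#' \eqn{R = G^2/(1+G^2)} and the strata index \eqn{(4G+1)/3}. A separation
#' above 2 indicates the measures distinguish more than three statistically
#' distinct performance layers. Zero observed variance yields G = 0, R = 0.
#'
#' @param measures data frame with columns `theta` and `se` (a person table
#'   from [score_persons()] works directly; for items, pass difficulties and
#'   their SEs).
#' @param extremes include rows flagged `extreme_flag` (default drops them,
#'   the "real"-style convention)?
#' @return A list of class `reliability_report`: `n`, `observed_sd`, `rmse`,
#'   `mean_se`, `adjusted_sd`, `separation`, `reliability`, `strata`.
#' @export
reliability_separation <- function(measures, extremes = FALSE) {
  df <- as.data.frame(measures)
  if (!extremes && !is.null(df$extreme_flag))
    df <- df[!df$extreme_flag, , drop = FALSE]
  df <- df[is.finite(df$theta) & is.finite(df$se), , drop = FALSE]
  if (nrow(df) < 2L)
    stop_rk("need at least 2 finite measures", "raschkey_validation_error")
  sd_obs <- stats::sd(df$theta)
  rmse <- sqrt(mean(df$se^2))
  adj <- sqrt(max(sd_obs^2 - rmse^2, 0))
  G <- adj / rmse
  structure(list(n = nrow(df), observed_sd = sd_obs, rmse = rmse,
                 mean_se = mean(df$se), adjusted_sd = adj, separation = G,
                 reliability = G^2 / (1 + G^2), strata = (4 * G + 1) / 3),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(
    "n = %d: observed SD %.2f, RMSE %.2f, true SD %.2f -> separation %.2f, reliability %.2f, strata %.2f\n",
    x$n, x$observed_sd, x$rmse, x$adjusted_sd, x$separation, x$reliability,
    x$strata))
  invisible(x)
}

#' Default criteria for scale validation
#'
#' The published screening constants: point-measure threshold 0.12;
#' combined misfit rule MnSq >= 1.4 with ZSTD >= 2, applied one item at a
#' time only while more than 5 percent of items misfit (the share expected
#' by chance); rating-category criteria (10 observations, monotone average
#' measures, category outfit <= 1.5, ordered thresholds advancing >= 1.4
#' logits); residual first contrast <= 10 percent; person separation >= 2
#' and reliability >= 0.8.
#'
#' @param ... overrides for individual constants.
#' @return Named list of criterion constants.
#' @export
validation_criteria <- function(...) {
  crit <- list(pm_threshold = 0.12, mnsq_max = 1.4, z_min = 2,
               chance_misfit_share = 0.05, min_count = 10,
               cat_outfit_max = 1.5, advance_min = 1.4, pca_share_max = 10,
               separation_min = 2, reliability_min = 0.8, min_items = 10)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(crit))
  if (length(bad))
    stop_rk(sprintf("unknown criteria: %s", paste(bad, collapse = ", ")),
            "raschkey_validation_error")
  utils::modifyList(crit, overrides)
}

#' Run the full scale-validation pipeline
#'
#' The published sequence: calibrate; rating-category diagnostics;
#' point-measure screening with one-at-a-time removal and refit; item-fit
#' screening with one-at-a-time removal of the worst misfit (worst outfit
#' MnSq, ties by worse ZSTD then item id), honoring the 5-percent-by-chance
#' allowance; residual PCA; separation and reliability. Produces an ordered
#' removal log and a summary in the style of a psychometric properties
#' table.
#'
#' @param responses a [response_matrix()] (or coercible).
#' @param spec a [scale_spec()].
#' @param criteria a [validation_criteria()] list.
#' @param model,control passed to [rasch()].
#' @return An object of class `validation_report`: `fit` (final
#'   [rasch()] fit), `categories`, `point_measure`, `item_fit`, `pca`,
#'   `person_reliability`, `item_reliability`, `removals` (log data frame),
#'   `summary` (named list of headline numbers), `criteria`, `pass`,
#'   `aborted`.
#' @export
validate_scale <- function(responses, spec, criteria = validation_criteria(),
                           model = "group", control = rasch_control()) {
  if (!inherits(responses, "response_matrix"))
    responses <- response_matrix(responses, spec)
  cur_spec <- spec
  cur_resp <- responses
  removals <- data.frame(step = integer(0), item_id = character(0),
                         reason = character(0), value = numeric(0))
  aborted <- FALSE
  step <- 0L

  drop_item <- function(spec, resp, item) {
    items <- spec$items[spec$items$item_id != item, , drop = FALSE]
    groups <- spec$groups[spec$groups$group_id %in% items$group_id, ,
                          drop = FALSE]
    sp <- scale_spec(spec$scale_id, items, groups, polarity = spec$polarity,
                     domain_vocabulary = spec$domain_vocabulary)
    keep <- rowSums(!is.na(unclass(resp)[, items$item_id, drop = FALSE])) > 0
    list(spec = sp,
         resp = response_matrix(unclass(resp)[keep, items$item_id,
                                              drop = FALSE], sp))
  }

  fit <- rasch(cur_resp, cur_spec, model = model, control = control)
  cats <- category_diagnostics(fit$responses, fit$calibration,
                               persons = fit$persons,
                               min_count = criteria$min_count,
                               outfit_max = criteria$cat_outfit_max,
                               advance_min = criteria$advance_min)

  # point-measure screening, one at a time, worst (lowest/undefined r) first
  repeat {
    pm <- point_measure_correlation(fit$responses, fit$persons,
                                    threshold = criteria$pm_threshold)
    bad <- pm[pm$flagged, , drop = FALSE]
    if (!nrow(bad)) break
    if (ncol(fit$responses) <= criteria$min_items) { aborted <- TRUE; break }
    ord <- order(ifelse(bad$undefined, -Inf, bad$r), bad$item_id)
    worst <- bad[ord[1], ]
    step <- step + 1L
    removals <- rbind(removals, data.frame(
      step = step, item_id = worst$item_id,
      reason = if (worst$undefined) "point_measure_undefined"
               else "point_measure_low",
      value = worst$r))
    upd <- drop_item(cur_spec, cur_resp, worst$item_id)
    cur_spec <- upd$spec; cur_resp <- upd$resp
    fit <- rasch(cur_resp, cur_spec, model = model, control = control)
  }

  # item-fit screening under the chance allowance
  repeat {
    ifit <- item_fit(fit$responses, fit$calibration, persons = fit$persons,
                     mnsq_max = criteria$mnsq_max, z_min = criteria$z_min)
    mis <- ifit[ifit$misfit, , drop = FALSE]
    allowance <- criteria$chance_misfit_share * nrow(ifit)
    if (nrow(mis) <= allowance) break
    if (ncol(fit$responses) <= criteria$min_items) { aborted <- TRUE; break }
    ord <- order(-mis$outfit_mnsq, -mis$outfit_z, mis$item_id)
    worst <- mis[ord[1], ]
    step <- step + 1L
    removals <- rbind(removals, data.frame(
      step = step, item_id = worst$item_id, reason = "misfit",
      value = worst$outfit_mnsq))
    upd <- drop_item(cur_spec, cur_resp, worst$item_id)
    cur_spec <- upd$spec; cur_resp <- upd$resp
    fit <- rasch(cur_resp, cur_spec, model = model, control = control)
  }

  pm <- point_measure_correlation(fit$responses, fit$persons,
                                  threshold = criteria$pm_threshold)
  ifit <- item_fit(fit$responses, fit$calibration, persons = fit$persons,
                   mnsq_max = criteria$mnsq_max, z_min = criteria$z_min)
  pca <- pca_residuals(fit$responses, fit$calibration, persons = fit$persons,
                       share_max = criteria$pca_share_max)
  rel_p <- reliability_separation(fit$persons)
  rel_i <- reliability_separation(
    data.frame(theta = fit$calibration$difficulty, se = fit$calibration$se),
    extremes = TRUE)
  espec <- fit$calibration$spec
  ncat <- sort(unique(espec$groups$n_categories))
  infit_misfit <- sum(ifit$infit_mnsq >= criteria$mnsq_max &
                        ifit$infit_z >= criteria$z_min, na.rm = TRUE)
  outfit_misfit <- sum(ifit$outfit_mnsq >= criteria$mnsq_max &
                         ifit$outfit_z >= criteria$z_min, na.rm = TRUE)
  summ <- list(
    n_persons = nrow(fit$persons),
    n_items = ncol(fit$responses),
    categories = paste(ncat, collapse = ", "),
    total_categories = sum(ncat),
    infit_misfit = infit_misfit,
    outfit_misfit = outfit_misfit,
    pca_first_contrast_pct = pca$first_contrast_share,
    person_separation = rel_p$separation,
    person_reliability = rel_p$reliability,
    item_reliability = rel_i$reliability,
    mean_se_persons = rel_p$mean_se,
    rmse_persons = rel_p$rmse,
    mean_se_items = rel_i$mean_se,
    rmse_items = rel_i$rmse,
    score_range = paste0("0-", max_raw_score(espec)))
  pass <- list(
    categories = cats$pass,
    point_measure = !any(pm$flagged),
    item_fit = (infit_misfit + outfit_misfit) == 0 ||
      max(infit_misfit, outfit_misfit) <=
        criteria$chance_misfit_share * nrow(ifit),
    pca = pca$pass,
    separation = rel_p$separation >= criteria$separation_min,
    reliability = rel_p$reliability >= criteria$reliability_min)

  structure(list(fit = fit, categories = cats, point_measure = pm,
                 item_fit = ifit, pca = pca, person_reliability = rel_p,
                 item_reliability = rel_i, removals = removals,
                 summary = summ, criteria = criteria, pass = pass,
                 all_pass = all(unlist(pass)) && !aborted, aborted = aborted),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Scale validation of '%s'%s\n",
              x$fit$calibration$spec$scale_id,
              if (x$aborted) " [ABORTED at minimum item count]" else ""))
  if (nrow(x$removals)) {
    cat("Removals (in order):\n")
    print(x$removals, row.names = FALSE)
  } else cat("No items removed.\n")
  rows <- c(
    sprintf("Number of persons            %d", s$n_persons),
    sprintf("Item number                  %d", s$n_items),
    sprintf("Number of categories         %s = %d", s$categories,
            s$total_categories),
    sprintf("Item infit misfit            %d", s$infit_misfit),
    sprintf("Item outfit misfit           %d", s$outfit_misfit),
    sprintf("PCA: first contrast          %.1f%%", s$pca_first_contrast_pct),
    sprintf("Person separation            %.2f", s$person_separation),
    sprintf("Person reliability           %.2f", s$person_reliability),
    sprintf("Item reliability             %.2f", s$item_reliability),
    sprintf("Mean SE / RMSE persons       %.2f / %.2f", s$mean_se_persons,
            s$rmse_persons),
    sprintf("Mean SE / RMSE items         %.2f / %.2f", s$mean_se_items,
            s$rmse_items),
    sprintf("Score range                  %s", s$score_range))
  cat(paste(rows, collapse = "\n"), "\n")
  fails <- names(x$pass)[!unlist(x$pass)]
  cat(if (length(fails)) paste("Criteria NOT met:", paste(fails, collapse = ", "))
      else "All validation criteria met.", "\n")
  invisible(x)
}
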