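#' Control parameters for Rasch estimation
#'
#' @param max_iterations maximum joint-maximum-likelihood iterations.
#' @param convergence_tol convergence tolerance: largest absolute parameter
#'   change (logits) at which iteration stops.
#' @param extreme_score_adjustment interior adjustment (score units, in
#'   (0, 0.5]) applied to all-minimum / all-maximum raw scores so that
#'   extreme persons still receive finite measures.
#' @param step_max largest Newton step (logits) taken for any parameter in
#'   one sweep; damping guard, not a tuning knob.
#' @param bound hard bound (logits) on person and item parameters.
#' @param bias_correction apply the first-order joint-maximum-likelihood
#'   spread correction (shrink centered item parameters by (I-1)/I) after
#'   convergence? Off by default to mirror the reference implementation the
#'   published measures came from.
#' @return A list of class `rasch_control`.
#' @export
rasch_control <- function(max_iterations = 200L, convergence_tol = 1e-4,
                          extreme_score_adjustment = 0.3, step_max = 1,
                          bound = 12, bias_correction = FALSE) {
  if (convergence_tol <= 0)
    stop_rk("convergence_tol must be > 0", "raschkey_validation_error")
  if (extreme_score_adjustment <= 0 || extreme_score_adjustment > 0.5)
    stop_rk("extreme_score_adjustment must be in (0, 0.5]",
            "raschkey_validation_error")
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 extreme_score_adjustment = extreme_score_adjustment,
                 step_max = step_max, bound = bound,
                 bias_correction = isTRUE(bias_correction)),
            class = "rasch_control")
}

# regroup a scale for the requested model variant; returns a scale_spec
effective_spec <- function(spec, model) {
  m <- item_categories(spec)
  switch(model,
    group = spec,
    dichotomous = {
      if (any(m != 2L))
        stop_rk("dichotomous model requires every item to have 2 categories",
                "raschkey_validation_error")
      spec
    },
    rating_scale = {
      if (length(unique(m)) != 1L)
        stop_rk("rating-scale model requires all items to share one category count",
                "raschkey_validation_error")
      items <- spec$items; items$group_id <- "all"
      scale_spec(spec$scale_id, items,
                 data.frame(group_id = "all", n_categories = unname(m[1])),
                 polarity = spec$polarity,
                 domain_vocabulary = spec$domain_vocabulary)
    },
    partial_credit = {
      items <- spec$items; items$group_id <- items$item_id
      scale_spec(spec$scale_id, items,
                 data.frame(group_id = items$item_id,
                            n_categories = unname(m[items$item_id])),
                 polarity = spec$polarity,
                 domain_vocabulary = spec$domain_vocabulary)
    },
    stop_rk(sprintf("unknown model '%s'", model), "raschkey_validation_error"))
}

#' Fit a Rasch model by joint maximum likelihood
#'
#' Calibrates item difficulties, group category thresholds and person
#' measures by alternating damped Newton-Raphson sweeps over the person and
#' item facets (the estimation scheme of the standard Rasch software this
#' toolkit mirrors; no bias correction is applied by default). Persons with
#' fully extreme raw scores carry no information about items and are set
#' aside during calibration; their measures are estimated afterwards from an
#' interior-adjusted raw score and flagged. Items answered only by extreme
#' persons are dropped with a warning. Missing cells contribute to no
#' sufficient statistic.
#'
#' Identification: item difficulties are mean-centered within the scale and
#' thresholds are mean-centered within each group; compensating shifts keep
#' the likelihood unchanged.
#'
#' @param responses a [response_matrix()] (or coercible matrix/data frame).
#' @param spec a [scale_spec()].
#' @param model Rasch variant: `"group"` (thresholds shared within
#'   category-count groups; the default), `"rating_scale"` (one threshold
#'   set for all items), `"partial_credit"` (one set per item) or
#'   `"dichotomous"`.
#' @param control a [rasch_control()].
#' @param start optional [calibration()] used as starting values.
#' @return An object of class `rasch_fit`: list with elements
#'   `calibration`, `persons` (person-measure data frame, see
#'   [score_persons()]), `iterations`, `converged`, `logLik`, `dropped_items`,
#'   `model`, `control`.
#' @seealso [score_persons()] for anchored scoring against a fixed
#'   calibration; [summary.rasch_fit()] for fit diagnostics.
#' @export
rasch <- function(responses, spec,
                  model = c("group", "rating_scale", "partial_credit",
                            "dichotomous"),
                  control = rasch_control(), start = NULL) {
  model <- match.arg(model)
  if (!inherits(responses, "response_matrix"))
    responses <- response_matrix(responses, spec)
  espec <- effective_spec(spec, model)
  x <- unclass(responses)

  m <- item_categories(espec)
  maxcat <- m - 1L
  obs <- !is.na(x)
  raw <- rowSums(x, na.rm = TRUE)
  rmax <- as.vector(obs %*% maxcat)
  extreme <- raw == 0L | raw == rmax
  if (!any(!extreme))
    stop_rk("no non-extreme persons: every response vector is all-minimum or all-maximum",
            "raschkey_estimation_error")

  # items informative only through non-extreme persons
  keep <- colSums(obs[!extreme, , drop = FALSE]) > 0L
  dropped <- colnames(x)[!keep]
  if (length(dropped)) {
    warning(sprintf("dropping item(s) answered only by extreme persons: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    espec <- scale_spec(espec$scale_id,
                        espec$items[keep, , drop = FALSE],
                        espec$groups[espec$groups$group_id %in%
                                       espec$items$group_id[keep], ,
                                     drop = FALSE],
                        polarity = espec$polarity,
                        domain_vocabulary = espec$domain_vocabulary)
    x <- x[, keep, drop = FALSE]
    obs <- obs[, keep, drop = FALSE]
    m <- item_categories(espec); maxcat <- m - 1L
    raw <- rowSums(x, na.rm = TRUE); rmax <- as.vector(obs %*% maxcat)
    extreme <- raw == 0L | raw == rmax
  }
  if (!any(!extreme))
    stop_rk("no non-extreme persons: every response vector is all-minimum or all-maximum",
            "raschkey_estimation_error")

  # every category of every group must be observed in the estimation sample
  xs <- x[!extreme, , drop = FALSE]
  for (g in espec$groups$group_id) {
    cols <- espec$items$group_id == g
    mg <- espec$groups$n_categories[espec$groups$group_id == g]
    cnt <- tabulate(as.vector(xs[, cols, drop = FALSE]) + 1L, nbins = mg)
    if (any(cnt == 0L))
      stop_rk(sprintf(
        paste("group '%s' has zero observations in category %s;",
              "collapse categories or regroup items (see category_diagnostics)"),
        g, paste(which(cnt == 0L) - 1L, collapse = ", ")),
        "raschkey_category_error")
  }

  fit <- jmle(xs, espec, control, start)
  if (control$bias_correction) {
    shrink <- (ncol(xs) - 1) / ncol(xs)
    fit$difficulty <- fit$difficulty * shrink
    fit$thresholds <- lapply(fit$thresholds, function(t) t * shrink)
  }

  calib <- calibration(espec, fit$difficulty, thresholds = fit$thresholds,
                       se = fit$item_se, threshold_se = fit$threshold_se,
                       model = model,
                       note = sprintf("JMLE, %d iteration(s), converged = %s",
                                      fit$iterations, fit$converged))
  resp_all <- response_matrix(x, espec)
  persons <- score_persons(resp_all, calib, control)

  structure(list(calibration = calib, persons = persons,
                 iterations = fit$iterations, converged = fit$converged,
                 logLik = fit$logLik, dropped_items = dropped,
                 model = model, control = control,
                 responses = resp_all),
            class = "rasch_fit")
}

# core alternating Newton-Raphson; x has no extreme persons, no all-missing
# rows/columns
jmle <- function(x, espec, control, start = NULL) {
  n <- nrow(x); k <- ncol(x)
  ids <- espec$items$item_id
  gid <- espec$items$group_id
  groups <- espec$groups
  obs <- !is.na(x)
  maxcat <- item_categories(espec) - 1L
  raw <- rowSums(x, na.rm = TRUE)
  rmax <- as.vector(obs %*% maxcat)
  s_item <- colSums(x, na.rm = TRUE)

  # starting values: logit of score fractions, or a supplied calibration
  theta <- log((raw + 0.5) / (rmax - raw + 0.5))
  if (is.null(start)) {
    frac <- (s_item + 0.5) / (colSums(obs) * maxcat + 1)
    delta <- log((1 - frac) / frac)
    delta <- delta - mean(delta)
    tau <- lapply(stats::setNames(groups$group_id, groups$group_id),
                  function(g) {
                    mg <- groups$n_categories[groups$group_id == g]
                    rep(0, mg - 1L)
                  })
  } else {
    stopifnot(inherits(start, "calibration"))
    delta <- start$difficulty[ids]
    tau <- start$thresholds[groups$group_id]
  }

  # observed threshold counts per group: O_gk = #(x >= k)
  O <- lapply(stats::setNames(groups$group_id, groups$group_id), function(g) {
    cols <- gid == g
    mg <- groups$n_categories[groups$group_id == g]
    if (mg == 2L) return(numeric(0))
    v <- as.vector(x[, cols, drop = FALSE])
    vapply(seq_len(mg - 1L), function(kk) sum(v >= kk, na.rm = TRUE),
           numeric(1))
  })

  clamp <- function(z, b) pmin(pmax(z, -b), b)
  bound <- control$bound; smax <- control$step_max
  converged <- FALSE; iter <- 0L

  repeat {
    iter <- iter + 1L
    delta0 <- delta; theta0 <- theta
    tau0 <- tau

    calib <- calibration(espec, delta, thresholds = tau, model = "group")

    # person sweep
    mom <- item_moments(theta, calib, ids)
    sumE <- rowSums(mom$E * obs); sumW <- rowSums(mom$W * obs)
    theta <- clamp(theta + clamp((raw - sumE) / pmax(sumW, 1e-8), smax), bound)

    # item sweep (at updated thetas)
    mom <- item_moments(theta, calib, ids, tails = TRUE)
    colE <- colSums(mom$E * obs); colW <- colSums(mom$W * obs)
    delta <- clamp(delta + clamp((colE - s_item) / pmax(colW, 1e-8), smax),
                   bound)

    # threshold sweep per polytomous group
    calib <- calibration(espec, delta - mean(delta),
                         thresholds = tau, model = "group")
    mom <- item_moments(theta - mean(delta), calib, ids, tails = TRUE)
    for (g in groups$group_id) {
      if (!length(O[[g]])) next
      tl <- mom$tails[[g]]
      cols <- tl$cols
      for (kk in seq_along(O[[g]])) {
        S <- tl$tails[, , kk][obs[, cols, drop = FALSE]]
        f <- sum(S) - O[[g]][kk]   # d logL / d tau_k
        fp <- sum(S * (1 - S))     # -d2 logL / d tau_k2
        tau[[g]][kk] <- clamp(tau[[g]][kk] + clamp(f / pmax(fp, 1e-8), smax),
                              10)
      }
    }

    # exact renormalization: center tau within groups (compensated by the
    # group's item difficulties), then center difficulties (compensated by
    # theta) -- the likelihood is unchanged
    for (g in groups$group_id) {
      if (!length(tau[[g]])) next
      tbar <- mean(tau[[g]])
      tau[[g]] <- tau[[g]] - tbar
      delta[gid == g] <- delta[gid == g] + tbar
    }
    dbar <- mean(delta)
    delta <- delta - dbar
    theta <- theta - dbar

    maxchg <- max(abs(delta - delta0), abs(theta - theta0),
                  if (length(unlist(tau))) abs(unlist(tau) - unlist(tau0))
                  else 0)
    if (maxchg < control$convergence_tol) { converged <- TRUE; break }
    if (iter >= control$max_iterations) break
  }

  calib <- calibration(espec, delta, thresholds = tau, model = "group")
  mom <- item_moments(theta, calib, ids, tails = TRUE)
  item_se <- 1 / sqrt(pmax(colSums(mom$W * obs), 1e-12))
  names(item_se) <- ids
  threshold_se <- lapply(stats::setNames(groups$group_id, groups$group_id),
                         function(g) {
    if (!length(tau[[g]])) return(numeric(0))
    tl <- mom$tails[[g]]
    vapply(seq_along(tau[[g]]), function(kk) {
      S <- tl$tails[, , kk][obs[, tl$cols, drop = FALSE]]
      1 / sqrt(pmax(sum(S * (1 - S)), 1e-12))
    }, numeric(1))
  })

  # log-likelihood over observed cells of the estimation sample
  ll <- 0
  for (g in groups$group_id) {
    cols <- which(gid == g)
    p <- prob_array(theta, delta[cols],
                    eff_tau(tau[[g]],
                            groups$n_categories[groups$group_id == g]))
    for (jj in seq_len(dim(p)[3])) {
      sel <- which(x[, cols, drop = FALSE] == jj - 1L)
      if (length(sel)) ll <- ll + sum(log(p[, , jj][sel]))
    }
  }

  list(difficulty = delta, thresholds = tau, item_se = item_se,
       threshold_se = threshold_se, theta = theta, iterations = iter,
       converged = converged, logLik = ll)
}

#' Score persons against a fixed calibration
#'
#' Anchored maximum-likelihood scoring: for each person the measure
#' \eqn{\theta} solves \eqn{\sum_i E_i(\theta) = r} over the person's
#' answered items (raw score `r`), and the standard error is
#' \eqn{1/\sqrt{I(\theta)}}. All-minimum and all-maximum raw scores are
#' first pulled into the interior by the extreme-score adjustment and
#' flagged. Two persons with the same raw score on the same answered-item
#' set always receive identical measures and standard errors.
#'
#' @param responses a [response_matrix()] on the calibration's scale (or
#'   coercible).
#' @param calib a [calibration()].
#' @param control a [rasch_control()] (only the extreme-score adjustment is
#'   used).
#' @return Data frame with one row per person: `person_id`, `theta`, `se`,
#'   `raw_score`, `max_score`, `n_missing`, `extreme_flag`.
#' @export
score_persons <- function(responses, calib, control = rasch_control()) {
  stopifnot(inherits(calib, "calibration"))
  spec <- calib$spec
  if (!inherits(responses, "response_matrix"))
    responses <- response_matrix(responses, spec)
  x <- unclass(responses)
  obs <- !is.na(x)
  maxcat <- item_categories(spec) - 1L
  raw <- rowSums(x, na.rm = TRUE)
  rmax <- as.vector(obs %*% maxcat)
  nmiss <- rowSums(!obs)
  adj <- control$extreme_score_adjustment
  extreme <- raw == 0L | raw == rmax
  target <- ifelse(raw == 0L, adj, ifelse(raw == rmax, rmax - adj, raw))

  theta <- solve_theta(target, obs, calib)
  se <- person_se(theta, obs, calib)
  data.frame(person_id = rownames(x), theta = theta, se = se,
             raw_score = as.integer(raw), max_score = as.integer(rmax),
             n_missing = as.integer(nmiss), extreme_flag = extreme,
             stringsAsFactors = FALSE)
}

# vectorized safeguarded Newton: solve sum_i E_i(theta_n) = target_n over
# each person's answered items
solve_theta <- function(target, obs, calib, tol = 1e-9, max_iter = 200L) {
  ids <- colnames(obs)
  n <- nrow(obs)
  theta <- rep(0, n)
  lo <- rep(-30, n); hi <- rep(30, n)
  for (it in seq_len(max_iter)) {
    mom <- item_moments(theta, calib, ids)
    f <- rowSums(mom$E * obs) - target
    if (all(abs(f) < tol)) break
    hi <- ifelse(f > 0, pmin(hi, theta), hi)
    lo <- ifelse(f < 0, pmax(lo, theta), lo)
    step <- -f / pmax(rowSums(mom$W * obs), 1e-10)
    step <- pmin(pmax(step, -2), 2)
    theta_new <- theta + step
    # bisect where Newton leaves the bracket
    oob <- theta_new <= lo | theta_new >= hi
    theta_new[oob] <- (lo[oob] + hi[oob]) / 2
    theta <- theta_new
  }
  theta
}

person_se <- function(theta, obs, calib) {
  mom <- item_moments(theta, calib, colnames(obs))
  1 / sqrt(pmax(rowSums(mom$W * obs), 1e-12))
}
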