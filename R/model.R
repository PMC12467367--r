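# Polytomous Rasch category weights for one category-count group.
#
# For an item i in group g with m categories coded 0..m-1, the category
# weight is exp(sum_{k<=j} (theta - delta_i - tau_{g,k})), empty sum = 0,
# i.e. exp(j*(theta - delta_i) - cumsum(tau)_j). Probabilities are the
# normalized weights. Computed on the log scale with a rowwise max shift
# for numerical stability.
#
# theta: numeric n; delta: numeric k (items of the group); tau: numeric m-1.
# Returns an n x k x m array of probabilities.
# effective threshold vector of a group: the stored list is empty for a
# dichotomous group, whose single centered threshold is implicitly 0
eff_tau <- function(tau, n_categories) {
  if (n_categories == 2L && !length(tau)) 0 else tau
}

prob_array <- function(theta, delta, tau) {
  n <- length(theta); k <- length(delta); m <- length(tau) + 1L
  a <- outer(theta, delta, "-")                       # n x k
  ct <- c(0, cumsum(tau))                             # length m
  lw <- array(0, dim = c(n, k, m))
  for (j in seq_len(m) - 1L) lw[, , j + 1L] <- j * a - ct[j + 1L]
  mx <- apply(lw, c(1, 2), max)
  w <- exp(lw - as.vector(mx))
  w / as.vector(rowSums(w, dims = 2))
}

# First, second and fourth central moments of the category distribution for
# every (theta, item) pair, plus P(X >= j) tails (used by JMLE threshold
# updates). Items may come from different groups.
# Returns list(E, W, C) of n x k matrices (k = length(item_ids)) and,
# if tails = TRUE, a per-group list of tail-sum arrays.
item_moments <- function(theta, calib, item_ids = names(calib$difficulty),
                         tails = FALSE) {
  spec <- calib$spec
  idx <- match(item_ids, spec$items$item_id)
  if (anyNA(idx))
    stop_rk(sprintf("unknown items: %s",
                    paste(item_ids[is.na(idx)], collapse = ", ")),
            "raschkey_config_error")
  gid <- spec$items$group_id[idx]
  n <- length(theta); k <- length(item_ids)
  E <- W <- C <- matrix(0, n, k, dimnames = list(NULL, item_ids))
  tail_list <- list()
  for (g in unique(gid)) {
    cols <- which(gid == g)
    mg <- spec$groups$n_categories[spec$groups$group_id == g]
    tau <- eff_tau(calib$thresholds[[g]], mg)
    m <- length(tau) + 1L
    p <- prob_array(theta, calib$difficulty[item_ids[cols]], tau)
    j <- seq_len(m) - 1L
    e <- matrix(0, n, length(cols))
    for (jj in seq_len(m)) e <- e + j[jj] * p[, , jj]
    w <- cc <- matrix(0, n, length(cols))
    for (jj in seq_len(m)) {
      d2 <- (j[jj] - e)^2
      w <- w + d2 * p[, , jj]
      cc <- cc + d2 * d2 * p[, , jj]
    }
    E[, cols] <- e; W[, cols] <- w; C[, cols] <- cc
    if (tails) {
      s <- array(0, dim = c(n, length(cols), m - 1L))
      if (m > 1L)
        for (kk in seq_len(m - 1L))
          s[, , kk] <- apply(p[, , (kk + 1L):m, drop = FALSE], c(1, 2), sum)
      tail_list[[g]] <- list(cols = cols, tails = s)
    }
  }
  out <- list(E = E, W = W, C = C)
  if (tails) out$tails <- tail_list
  out
}

#' Rasch category probabilities
#'
#' Probability of each rating category for an item, given a person measure
#' and a calibration. Uses the polytomous Rasch form
#' \eqn{P(X=j) \propto \exp\{j(\theta-\delta_i) - \sum_{k \le j}
#' \tau_{g(i),k}\}} with the empty sum equal to 0; for a dichotomous item
#' this reduces to the logistic \eqn{P(X=1) = 1/(1+e^{-(\theta-\delta)})}.
#'
#' @param theta person measure(s) in logits.
#' @param item a single item id present in the calibration's scale.
#' @param calib a [calibration()].
#' @return For scalar `theta`, a named probability vector over categories
#'   `0..m-1`; otherwise a matrix with one row per `theta`.
#' @examples
#' spec <- scale_spec("toy",
#'   items  = data.frame(item_id = c("a", "b"), group_id = c("g2", "g3")),
#'   groups = data.frame(group_id = c("g2", "g3"), n_categories = c(2, 3)))
#' cal <- calibration(spec, c(a = 0.5, b = -0.5),
#'                    thresholds = list(g2 = numeric(0), g3 = c(-1, 1)))
#' category_probabilities(0, "b", cal)
#' @export
category_probabilities <- function(theta, item, calib) {
  stopifnot(inherits(calib, "calibration"))
  spec <- calib$spec
  idx <- match(item, spec$items$item_id)
  if (length(item) != 1L || is.na(idx))
    stop_rk(sprintf("unknown item '%s'", paste(item, collapse = ",")),
            "raschkey_config_error")
  g <- spec$items$group_id[idx]
  if (!g %in% names(calib$thresholds))
    stop_rk(sprintf("no thresholds for group '%s' in the calibration", g),
            "raschkey_config_error")
  tau <- eff_tau(calib$thresholds[[g]],
                 spec$groups$n_categories[spec$groups$group_id == g])
  p <- prob_array(theta, calib$difficulty[item], tau)
  out <- matrix(p, nrow = length(theta),
                dimnames = list(NULL, seq_len(dim(p)[3]) - 1L))
  if (length(theta) == 1L) out[1, ] else out
}

#' Expected score and score variance of an item
#'
#' `expected_score` is the model-expected rating \eqn{E = \sum_j j P_j};
#' it is strictly increasing in `theta` and runs from 0 to m-1.
#' `score_variance` returns the second and fourth central moments
#' \eqn{W = \sum_j (j-E)^2 P_j} and \eqn{C = \sum_j (j-E)^4 P_j}, the
#' building blocks of information and of the mean-square fit statistics.
#'
#' @inheritParams category_probabilities
#' @return `expected_score`: numeric vector along `theta`.
#'   `score_variance`: list with components `variance` and `kurtosis`.
#' @export
expected_score <- function(theta, item, calib) {
  mom <- item_moments(theta, calib, item)
  as.vector(mom$E[, 1])
}

#' @rdname expected_score
#' @export
score_variance <- function(theta, item, calib) {
  mom <- item_moments(theta, calib, item)
  list(variance = as.vector(mom$W[, 1]), kurtosis = as.vector(mom$C[, 1]))
}

#' Test information and model standard error
#'
#' Fisher information of a set of items at a person measure,
#' \eqn{I(\theta) = \sum_i W_i(\theta)}, and the model standard error
#' \eqn{SE = 1/\sqrt{I(\theta)}}.
#'
#' @inheritParams category_probabilities
#' @param items character vector of item ids (default: the whole scale).
#' @return Numeric vector along `theta`.
#' @export
test_information <- function(theta, calib, items = names(calib$difficulty)) {
  if (!length(items))
    stop_rk("empty item set", "raschkey_validation_error")
  mom <- item_moments(theta, calib, items)
  rowSums(mom$W)
}

#' @rdname test_information
#' @export
model_se <- function(theta, calib, items = names(calib$difficulty)) {
  1 / sqrt(test_information(theta, calib, items))
}
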