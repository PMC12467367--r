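#' Canonical 49-item neurobehavioral stroke (CVA) scale fixture
#'
#' A synthetic stand-in for the calibrated 49-item CVA impairment-impact
#' subscale, used as the package's reference simulation target. Its
#' structure matches the published scale totals: 49 items in three
#' category-count groups — 31 dichotomous items (18 of them pervasive-type),
#' 8 three-category items and 10 four-category items — giving 2 + 3 + 4 = 9
#' category labels and a maximum raw score of 77. (Any split (a, b, c) with
#' a + b + c = 49 and b + 2c = 28 matches those totals; 31/8/10 is this
#' package's documented canonical choice.) Generating difficulties span
#' roughly -2.8 to +1.1 logits, placed so that every item and every rating
#' category remains observable in a cohort centered 1.8 logits below the
#' item mean (the instrument's own calibration achieved at least ten
#' observations per category and acceptable point-measure correlations on
#' such a cohort, which bounds how far above the cohort an item can sit).
#' The four motor-type items sit at the most frequently impacted
#' (lowest-difficulty) extreme of the hierarchy, mirroring the clinical
#' finding that motor impairments are the most frequently detected after
#' stroke. The scale's polarity is `higher_is_worse`: larger measures mean
#' more impairment impact.
#'
#' @return List with elements `spec` (a [scale_spec()]) and `calibration`
#'   (the generating [calibration()]).
#' @export
cva_scale_fixture <- function() {
  dom <- c("D", "G", "T", "F", "C")
  items <- rbind(
    data.frame(item_id = sprintf("mot%d", 1:4),
               label = sprintf("Motor impairment %d", 1:4),
               domain_tag = "T", group_id = "cat4"),
    data.frame(item_id = sprintf("spec%02d", 1:6),
               label = sprintf("Specific impairment %d", 1:6),
               domain_tag = dom[(0:5 %% 5) + 1], group_id = "cat4"),
    data.frame(item_id = sprintf("spec%02d", 7:14),
               label = sprintf("Specific impairment %d", 7:14),
               domain_tag = dom[(6:13 %% 5) + 1], group_id = "cat3"),
    data.frame(item_id = sprintf("spec%02d", 15:27),
               label = sprintf("Specific impairment %d", 15:27),
               domain_tag = dom[(14:26 %% 5) + 1], group_id = "cat2"),
    data.frame(item_id = sprintf("perv%02d", 1:18),
               label = sprintf("Pervasive impairment %d", 1:18),
               domain_tag = "P", group_id = "cat2"))
  groups <- data.frame(group_id = c("cat2", "cat3", "cat4"),
                       n_categories = c(2L, 3L, 4L))
  spec <- scale_spec("cva_synthetic", items, groups,
                     polarity = "higher_is_worse")
  delta <- c(
    seq(-2.8, -2.2, length.out = 4),        # motor: most frequently impacted
    seq(-1.2, 0.8, length.out = 6),         # remaining four-category items
    seq(-1.0, 1.1, length.out = 8),         # three-category items
    seq(-0.45, 0.93, length.out = 13),      # dichotomous specific items
    seq(0.1, 0.75, length.out = 18))        # dichotomous pervasive items
  names(delta) <- items$item_id
  delta <- delta - mean(delta)
  calib <- calibration(spec, delta,
                       thresholds = list(cat2 = numeric(0),
                                         cat3 = c(-0.9, 0.9),
                                         cat4 = c(-1.6, 0, 1.6)),
                       model = "group",
                       note = "synthetic generating parameters")
  list(spec = spec, calibration = calib)
}

#' Canonical 20-item ADL scale fixture
#'
#' A synthetic stand-in for the 20-item activities-of-daily-living scale:
#' one rating-scale group for all items with 4 effective ordinal categories
#' (the instrument's five labels with the documented collapse of two
#' adjacent ones applied). Polarity is `higher_is_better`: larger measures
#' mean more independent performance.
#'
#' @return List with elements `spec` and generating `calibration`.
#' @export
adl_scale_fixture <- function() {
  items <- data.frame(item_id = sprintf("adl%02d", 1:20),
                      label = sprintf("ADL task %d", 1:20),
                      domain_tag = c("D", "G", "T", "F", "C")[(0:19 %% 5) + 1],
                      group_id = "all")
  spec <- scale_spec("adl_synthetic", items,
                     data.frame(group_id = "all", n_categories = 4L),
                     polarity = "higher_is_better")
  delta <- seq(-2.5, 2.5, length.out = 20)
  names(delta) <- items$item_id
  calib <- calibration(spec, delta - mean(delta),
                       thresholds = list(all = c(-2, 0, 2)),
                       model = "rating_scale",
                       note = "synthetic generating parameters")
  list(spec = spec, calibration = calib)
}

#' Configure a response simulation
#'
#' @param spec a [scale_spec()].
#' @param calib the generating [calibration()] (true item parameters).
#' @param n_persons number of persons to simulate.
#' @param person_mean,person_sd normal distribution of true person measures
#'   in logits. The defaults (-1.8, 1.0) echo the first-evaluation CVA
#'   cohort mean of the study conditions this generator emulates.
#' @param theta optional vector of true person measures (overrides the
#'   distribution; its length overrides `n_persons`).
#' @param missingness `NULL` (complete data), or
#'   `list(type = "per_person", count = k)` masking exactly `k` (at most 4)
#'   cells per person, or `list(type = "rate", rate = p)` masking cells
#'   independently with probability `p`.
#' @param seed mandatory integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(spec, calib, n_persons,
                              person_mean = -1.8, person_sd = 1,
                              theta = NULL, missingness = NULL, seed) {
  stopifnot(inherits(spec, "scale_spec"), inherits(calib, "calibration"))
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop_rk("a seed is mandatory for simulation", "raschkey_validation_error")
  if (!is.null(theta)) n_persons <- length(theta)
  if (n_persons < 1L)
    stop_rk("n_persons must be >= 1", "raschkey_validation_error")
  if (!is.null(missingness)) {
    if (!is.list(missingness) || is.null(missingness$type) ||
        !missingness$type %in% c("per_person", "rate"))
      stop_rk("missingness must be NULL or list(type = 'per_person'|'rate', ...)",
              "raschkey_validation_error")
    if (missingness$type == "per_person") {
      k <- missingness$count
      if (is.null(k) || k < 0L || k > 4L)
        stop_rk("per-person missingness count must be between 0 and 4",
                "raschkey_validation_error")
    } else if (is.null(missingness$rate) || missingness$rate < 0 ||
               missingness$rate >= 1)
      stop_rk("missingness rate must be in [0, 1)",
              "raschkey_validation_error")
  }
  structure(list(spec = spec, calibration = calib,
                 n_persons = as.integer(n_persons),
                 person_mean = person_mean, person_sd = person_sd,
                 theta = theta, missingness = missingness,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a response matrix from known Rasch parameters
#'
#' Draws every cell's rating category from the model probabilities
#' [category_probabilities()] at the true person and item parameters, then
#' injects the requested missingness (only the targeted cells change).
#' Reproducible: the same configuration (including seed) always yields the
#' same matrix.
#'
#' @param config a [simulation_config()].
#' @return List with `responses` (a [response_matrix()]), `theta` (true
#'   person measures) and `config`.
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  spec <- config$spec; calib <- config$calibration
  set.seed(config$seed)
  n <- config$n_persons
  theta <- config$theta %||% rnorm(n, config$person_mean, config$person_sd)
  ids <- spec$items$item_id
  x <- matrix(NA_integer_, n, length(ids),
              dimnames = list(sprintf("P%04d", seq_len(n)), ids))
  for (g in spec$groups$group_id) {
    cols <- which(spec$items$group_id == g)
    p <- prob_array(theta, calib$difficulty[ids[cols]],
                    eff_tau(calib$thresholds[[g]],
                            spec$groups$n_categories[
                              spec$groups$group_id == g]))
    m <- dim(p)[3]
    for (jc in seq_along(cols)) {
      u <- runif(n)
      acc <- rep(0, n); cat <- integer(n)
      for (j in seq_len(m - 1L)) {
        acc <- acc + p[, jc, j]
        cat <- cat + (u > acc)
      }
      x[, cols[jc]] <- cat
    }
  }
  miss <- config$missingness
  if (!is.null(miss)) {
    k <- length(ids)
    if (miss$type == "per_person" && miss$count > 0L) {
      for (i in seq_len(n))
        x[i, sample.int(k, miss$count)] <- NA_integer_
    } else if (miss$type == "rate" && miss$rate > 0) {
      mask <- matrix(runif(n * k) < miss$rate, n, k)
      # never blank a person's final answered item
      keep_one <- apply(mask, 1, all)
      if (any(keep_one)) mask[cbind(which(keep_one), 1L)] <- FALSE
      x[mask] <- NA_integer_
    }
  }
  list(responses = response_matrix(x, spec), theta = theta, config = config)
}
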