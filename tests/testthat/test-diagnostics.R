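test_that("infit/outfit/ZSTD match the brute-force double-loop oracle", {
  cal <- toy_mixed_calib()
  sim <- simulate_responses(simulation_config(
    toy_mixed_spec(), cal, 18, missingness = list(type = "rate", rate = 0.15),
    seed = 8))
  persons <- score_persons(sim$responses, cal)
  got <- item_fit(sim$responses, cal, persons = persons)
  use <- !persons$extreme_flag
  orc <- oracle_item_fit(unclass(sim$responses)[use, , drop = FALSE],
                         persons$theta[use], cal)
  expect_equal(got$infit_mnsq, orc$infit, tolerance = 1e-10)
  expect_equal(got$outfit_mnsq, orc$outfit, tolerance = 1e-10)
  expect_equal(got$infit_z, orc$infit_z, tolerance = 1e-10)
  expect_equal(got$outfit_z, orc$outfit_z, tolerance = 1e-10)
})

test_that("a response one model-SD above expectation has unit squared residual", {
  spec <- toy_dich_spec(2)
  cal <- calibration(spec, c(i1 = 0, i2 = 0), thresholds = list(g = numeric(0)))
  x <- matrix(c(1L, 0L), 1, 2, dimnames = list("p", c("i1", "i2")))
  # raw score 1 of 2 on identical items -> theta = 0 = delta, E = 0.5,
  # sqrt(W) = 0.5, so x = 1 = E + sqrt(W) gives z^2 = 1 exactly
  z <- standardized_residuals(response_matrix(x, spec), cal)
  expect_equal(unname(z[1, ]), c(1, -1), tolerance = 1e-9)
})

test_that("mean outfit is near 1 for model-true data", {
  fx <- adl_scale_fixture()
  means <- vapply(1:10, function(s) {
    sim <- simulate_responses(simulation_config(fx$spec, fx$calibration, 1000,
                                                person_mean = 0.12,
                                                person_sd = 1.2, seed = s))
    fit <- item_fit(sim$responses, fx$calibration)
    mean(fit$outfit_mnsq)
  }, numeric(1))
  expect_true(all(abs(means - 1) < 0.1))
})

test_that("point-measure correlation matches the textbook formula", {
  theta <- c(-3, -1, 1, 3, -3, -1, 1, 3)
  persons <- data.frame(person_id = sprintf("p%d", 1:8), theta = theta,
                        se = 0.4, extreme_flag = FALSE)
  # ratings linear in the measures -> r = 1; reversed -> r = -1
  x <- cbind(up = as.integer((theta + 3) / 2), down = 0L, flat = 1L)
  x[, "down"] <- 3L - x[, "up"]
  rownames(x) <- persons$person_id
  pm <- point_measure_correlation(x, persons)
  expect_equal(pm$r[pm$item_id == "up"], 1, tolerance = 1e-12)
  expect_equal(pm$r[pm$item_id == "down"], -1, tolerance = 1e-12)
  expect_true(pm$undefined[pm$item_id == "flat"])
  expect_true(pm$flagged[pm$item_id == "flat"])

  cal <- toy_mixed_calib()
  sim <- simulate_responses(simulation_config(toy_mixed_spec(), cal, 40,
                                              seed = 14))
  pers <- score_persons(sim$responses, cal)
  pm2 <- point_measure_correlation(sim$responses, pers)
  for (i in seq_len(nrow(pm2))) {
    v <- unclass(sim$responses)[, pm2$item_id[i]]
    expect_equal(pm2$r[i], oracle_pearson(v, pers$theta), tolerance = 1e-12)
  }
})

test_that("category diagnostics tally observations and screen thresholds", {
  fx <- cva_scale_fixture()
  sim <- simulate_responses(simulation_config(fx$spec, fx$calibration, 300,
                                              seed = 2))
  pers <- score_persons(sim$responses, fx$calibration)
  cd <- category_diagnostics(sim$responses, fx$calibration, persons = pers)
  x <- unclass(sim$responses)
  for (g in fx$spec$groups$group_id) {
    cols <- fx$spec$items$group_id == g
    tab <- cd$groups[[g]]$table
    expect_equal(sum(tab$count), sum(!is.na(x[, cols])))
    for (j in tab$category) {
      sel <- which(!is.na(x[, cols]) & x[, cols] == j)
      expect_equal(tab$count[tab$category == j], length(sel))
      th <- matrix(pers$theta, nrow(x), sum(cols))
      expect_equal(tab$avg_measure[tab$category == j], mean(th[sel]),
                   tolerance = 1e-12)
    }
  }
  # generating thresholds are ordered with advance >= 1.4 -> criteria 4, 5 pass
  expect_true(cd$groups$cat3$criteria$ordered_thresholds)
  expect_equal(cd$groups$cat3$advance, 1.8, tolerance = 1e-12)
  expect_true(cd$groups$cat3$criteria$threshold_advance)

  # a disordered threshold set fails the ordering criterion
  spec <- scale_spec("dis", data.frame(item_id = c("a", "b"), group_id = "g"),
                     data.frame(group_id = "g", n_categories = 3L))
  cal_dis <- calibration(spec, c(a = 0, b = 0),
                         thresholds = list(g = c(0.5, -0.5)))
  x2 <- matrix(c(0L, 1L, 2L, 1L, 2L, 0L, 1L, 1L), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  cd2 <- category_diagnostics(response_matrix(x2, spec), cal_dis)
  expect_false(cd2$groups$g$criteria$ordered_thresholds)
  expect_false(cd2$groups$g$pass)
})

test_that("residual PCA sees noise as noise and structure as structure", {
  fx <- cva_scale_fixture()
  k <- nrow(fx$spec$items)
  sim <- simulate_responses(simulation_config(fx$spec, fx$calibration, 2000,
                                              seed = 6))
  pca <- pca_residuals(sim$responses, fx$calibration)
  # model-true residuals: first contrast near the 100/K% noise floor
  expect_lt(pca$first_contrast_share, 3 * 100 / k)
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  expect_equal(sum(pca$shares), 100, tolerance = 1e-8)

  # eigenvalues agree with an independent brute-force decomposition
  cal <- toy_mixed_calib()
  sm <- simulate_responses(simulation_config(toy_mixed_spec(), cal, 40,
                                             seed = 23))
  pers <- score_persons(sm$responses, cal)
  pca2 <- pca_residuals(sm$responses, cal, persons = pers)
  xm <- unclass(sm$responses)
  taus <- oracle_item_tau(cal)
  Z <- xm
  for (i in seq_len(nrow(xm))) for (j in seq_len(ncol(xm))) {
    mo <- oracle_moments(pers$theta[i], cal$difficulty[[j]], taus[[j]])
    Z[i, j] <- (xm[i, j] - mo$E) / sqrt(mo$W)
  }
  R <- diag(ncol(Z))
  for (a in seq_len(ncol(Z))) for (b in seq_len(ncol(Z)))
    if (a != b) R[a, b] <- oracle_pearson(Z[, a], Z[, b])
  expect_equal(pca2$eigenvalues, svd(R)$d, tolerance = 1e-8)
})

test_that("two injected residual clusters dominate the first contrast", {
  # persons answer 6 items; items 1-3 and 4-6 each share an extra latent
  # nuisance dimension with opposite sign
  spec <- toy_dich_spec(6)
  set.seed(31)
  n <- 600
  theta <- rnorm(n, 0, 1.2)
  nuis <- rnorm(n, 0, 1.2)
  delta <- seq(-1, 1, length.out = 6); delta <- delta - mean(delta)
  x <- sapply(1:6, function(j) {
    lin <- theta + (if (j <= 3) nuis else -nuis) - delta[j]
    as.integer(runif(n) < plogis(lin))
  })
  colnames(x) <- sprintf("i%d", 1:6)
  fit <- rasch(x, spec)
  pca <- pca_residuals(fit$responses, fit$calibration, persons = fit$persons)
  expect_false(pca$pass)
  expect_gt(pca$first_contrast_share, 20)
  signs <- sign(pca$loadings)
  expect_equal(length(unique(signs[1:3])), 1L)
  expect_equal(length(unique(signs[4:6])), 1L)
  expect_true(signs[1] != signs[4])
})

test_that("reliability and separation follow their defining identities", {
  same <- data.frame(theta = rep(1.3, 5), se = 0.4)
  r0 <- reliability_separation(same)
  expect_equal(r0$separation, 0)
  expect_equal(r0$reliability, 0)

  # observed SD = RMSE * sqrt(2) -> G = 1, R = 0.5, strata = 5/3
  two <- data.frame(theta = c(-1, 1), se = 1)   # sd = sqrt(2), RMSE = 1
  r1 <- reliability_separation(two)
  expect_equal(r1$separation, 1, tolerance = 1e-12)
  expect_equal(r1$reliability, 0.5, tolerance = 1e-12)
  expect_equal(r1$strata, 5 / 3, tolerance = 1e-12)

  fx <- cva_scale_fixture()
  sim <- simulate_responses(simulation_config(fx$spec, fx$calibration, 250,
                                              seed = 17))
  rel <- reliability_separation(score_persons(sim$responses, fx$calibration))
  expect_equal(rel$reliability,
               rel$separation^2 / (1 + rel$separation^2), tolerance = 1e-9)
  expect_equal(rel$adjusted_sd^2,
               max(rel$observed_sd^2 - rel$rmse^2, 0), tolerance = 1e-9)
})

test_that("validation pipeline keeps a model-true scale intact", {
  fx <- cva_scale_fixture()
  sim <- simulate_responses(simulation_config(fx$spec, fx$calibration, 300,
                                              seed = 4))
  rep <- validate_scale(sim$responses, fx$spec)
  expect_equal(nrow(rep$removals), 0L)
  expect_false(rep$aborted)
  expect_equal(rep$summary$n_items, 49L)
  expect_equal(rep$summary$score_range, "0-77")
  expect_equal(rep$summary$categories, "2, 3, 4")
})

test_that("noise items are removed at the screening stage, in order", {
  fx <- cva_scale_fixture()
  sim <- simulate_responses(simulation_config(fx$spec, fx$calibration, 300,
                                              seed = 19))
  x <- unclass(sim$responses)
  set.seed(99)
  noisy <- c("spec18", "spec21", "perv09")   # dichotomous items -> coin flips
  for (it in noisy) x[, it] <- sample(0:1, nrow(x), replace = TRUE)
  rep <- validate_scale(response_matrix(x, fx$spec), fx$spec)
  expect_gte(nrow(rep$removals), 3L)
  first3 <- rep$removals$item_id[1:3]
  expect_setequal(intersect(first3, noisy), noisy)
  # screening happens before fit analysis: the first removals carry a
  # point-measure reason
  expect_true(all(grepl("point_measure", rep$removals$reason[1:3])))
  expect_equal(rep$summary$n_items, 49L - nrow(rep$removals))
})

test_that("the pipeline aborts instead of shrinking below the item floor", {
  spec <- toy_dich_spec(4)
  set.seed(55)
  n <- 200
  theta <- rnorm(n)
  x <- sapply(1:4, function(j) as.integer(runif(n) < plogis(theta)))
  colnames(x) <- sprintf("i%d", 1:4)
  x[, "i4"] <- 1L - x[, "i4"]   # reversed item: strongly negative r
  keep <- rowSums(x) > 0 & rowSums(x) < 4
  rep <- validate_scale(x[keep, ], spec,
                        criteria = validation_criteria(min_items = 4))
  expect_true(rep$aborted)
  expect_equal(nrow(rep$removals), 0L)
  expect_true(any(rep$point_measure$flagged))
})
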