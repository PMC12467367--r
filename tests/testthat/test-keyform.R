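test_that("conversion table maps scores to measures and back", {
  # symmetric 2-item dichotomous scale: raw 1 sits exactly at 0 logits
  spec <- toy_dich_spec(2)
  cal <- calibration(spec, c(i1 = -1, i2 = 1),
                     thresholds = list(g = numeric(0)))
  tab <- conversion_table(cal)
  expect_equal(tab$raw_score, 0:2)
  expect_equal(tab$measure[tab$raw_score == 1], 0, tolerance = 1e-9)
  expect_equal(tab$extreme_flag, c(TRUE, FALSE, TRUE))

  fx <- cva_scale_fixture()
  full <- conversion_table(fx$calibration)
  expect_equal(full$raw_score, 0:77)
  expect_true(all(diff(full$measure) > 0))
  expect_true(all(full$se > 0))
  # every interior row round-trips through the test characteristic curve
  interior <- full[!full$extreme_flag, ]
  for (i in seq_len(nrow(interior))) {
    tot <- sum(vapply(names(fx$calibration$difficulty), function(it)
      expected_score(interior$measure[i], it, fx$calibration), numeric(1)))
    expect_equal(tot, interior$raw_score[i], tolerance = 1e-6)
  }
  # SE largest at the adjusted extreme rows, smallest near the peak
  expect_true(which.max(full$se) %in% c(1L, nrow(full)))
  expect_true(min(full$se) < full$se[2] && min(full$se) < full$se[77])
})

test_that("conversion measures agree with the lattice oracle", {
  cal <- toy_mixed_calib()
  tab <- conversion_table(cal)
  m <- item_categories(cal$spec)
  smax <- sum(m - 1L)
  for (s in tab$raw_score) {
    target <- min(max(s, 0.3), smax - 0.3)
    expect_equal(tab$measure[tab$raw_score == s],
                 oracle_table_measure(target, cal, cal$spec$items$item_id),
                 tolerance = 1e-3)
  }
})

test_that("keyform lays out boundaries along the difficulty hierarchy", {
  spec <- scale_spec("kf",
    items = data.frame(item_id = c("hard4", "easy2", "mid2"),
                       group_id = c("g4", "g2", "g2")),
    groups = data.frame(group_id = c("g2", "g4"), n_categories = c(2L, 4L)))
  cal <- calibration(spec, c(hard4 = 1, easy2 = -1.5, mid2 = 0.5),
                     thresholds = list(g2 = numeric(0), g4 = c(-2, 0, 2)))
  kf <- keyform(cal)
  expect_equal(kf$items$item_id, c("easy2", "mid2", "hard4"))
  expect_equal(kf$boundaries$easy2, -1.5)
  expect_equal(kf$boundaries$hard4, c(-1, 1, 3))

  fx <- cva_scale_fixture()
  kf2 <- keyform(fx$calibration)
  expect_equal(kf2$items$item_id,
               names(sort(fx$calibration$difficulty)))
  expect_equal(kf2$items$item_id[1:4], paste0("mot", 1:4))

  f <- withr::local_tempfile(fileext = ".json")
  write_keyform(kf2, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(parsed$items$item_id, kf2$items$item_id)

  pdf_file <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_no_error(plot(kf2, person = data.frame(theta = -1.2, se = 0.35)))
  grDevices::dev.off()
  expect_true(file.size(pdf_file) > 0)
})

test_that("imputation with no missing ratings equals plain scoring", {
  cal <- toy_mixed_calib()
  v <- c(d1 = 1L, d2 = 0L, t1 = 2L, t2 = 0L, q1 = 2L)
  res <- impute_and_measure(v, cal)
  direct <- score_persons(matrix(v, 1, dimnames = list("p", names(v))), cal)
  expect_equal(res$measure$theta, direct$theta, tolerance = 1e-12)
  expect_equal(res$measure$se, direct$se, tolerance = 1e-12)
  expect_equal(nrow(res$imputed), 0L)
})

test_that("more than four missing ratings are refused by name", {
  fx <- cva_scale_fixture()
  v <- stats::setNames(rep(0L, 49), fx$spec$items$item_id)
  v[1:5] <- NA
  err <- expect_error(impute_and_measure(v, fx$calibration),
                      class = "raschkey_imputation_error")
  expect_match(conditionMessage(err), "5")
  expect_match(conditionMessage(err), "4 missing")
  v[1:5] <- 0L   # exactly 4 missing is allowed
  v[10:13] <- NA
  expect_no_error(impute_and_measure(v, fx$calibration))
  v[] <- NA
  expect_error(impute_and_measure(v, fx$calibration), "all ratings")
})

test_that("single-missing imputation matches the enumeration oracle", {
  cal <- toy_mixed_calib()
  patterns <- list(
    c(d1 = 1L, d2 = NA, t1 = 2L, t2 = 0L, q1 = 2L),
    c(d1 = 0L, d2 = 0L, t1 = NA, t2 = 0L, q1 = 1L),
    c(d1 = 1L, d2 = 0L, t1 = 2L, t2 = 2L, q1 = NA))
  for (v in patterns) {
    res <- impute_and_measure(v, cal, method = "anchored_ml")
    miss <- names(v)[is.na(v)]
    answered <- v[!is.na(v)]
    th0 <- oracle_anchored_grid(answered, cal)
    expect_equal(res$provisional_theta, th0, tolerance = 1e-3)
    taus <- oracle_item_tau(cal)
    i <- match(miss, cal$spec$items$item_id)
    p <- oracle_probs(th0, cal$difficulty[[i]], taus[[i]])
    expect_equal(res$imputed$category, which.max(p) - 1L)
    expect_equal(res$imputed$item_id, miss)
    expect_equal(res$completed[[miss]], which.max(p) - 1L)
  }
})

test_that("an exact probability tie imputes the lower category", {
  # two identical dichotomous items answered 1 and 0 put the measure exactly
  # at the missing item's difficulty: P(0) = P(1) = 0.5
  spec <- toy_dich_spec(3)
  cal <- calibration(spec, c(i1 = 0, i2 = 0, i3 = 0),
                     thresholds = list(g = numeric(0)))
  v <- c(i1 = 1L, i2 = 0L, i3 = NA)
  res <- impute_and_measure(v, cal)
  expect_equal(res$provisional_theta, 0, tolerance = 1e-9)
  expect_equal(res$imputed$category, 0L)
  expect_equal(res$imputed$probability, 0.5, tolerance = 1e-9)
})

test_that("keyform L1 reading minimizes its loss and respects symmetry", {
  cal <- toy_mixed_calib()
  set.seed(26)
  sim <- simulate_responses(simulation_config(toy_mixed_spec(), cal, 25,
                                              seed = 26))
  x <- unclass(sim$responses)
  for (i in seq_len(nrow(x))) {
    v <- stats::setNames(x[i, ], colnames(x))
    got <- impute_and_measure(v, cal, method = "keyform_L1")$provisional_theta
    # independent lattice scan of the same L1 loss
    grid <- seq(-10, 10, by = 0.001)
    taus <- oracle_item_tau(cal)
    loss <- rep(0, length(grid))
    for (j in seq_along(v))
      loss <- loss + abs(v[[j]] - vapply(grid, function(t)
        oracle_moments(t, cal$difficulty[[j]], taus[[j]])$E, numeric(1)))
    best <- grid[which(loss <= min(loss) + 1e-12)]
    expect_equal(got, mean(range(best)), tolerance = 2e-3)
  }

  # perfectly balanced profile on a symmetric scale: both readings give 0
  spec <- toy_dich_spec(2)
  cal2 <- calibration(spec, c(i1 = -1, i2 = 1),
                      thresholds = list(g = numeric(0)))
  v <- c(i1 = 1L, i2 = 0L)
  l1 <- impute_and_measure(v, cal2, method = "keyform_L1")$provisional_theta
  ml <- impute_and_measure(v, cal2, method = "anchored_ml")$provisional_theta
  expect_equal(l1, 0, tolerance = 1e-3)
  expect_equal(ml, 0, tolerance = 1e-6)
})

test_that("imputed measures stay within one SE of complete-data measures", {
  fx <- cva_scale_fixture()
  sim <- simulate_responses(simulation_config(fx$spec, fx$calibration, 200,
                                              seed = 12))
  complete <- score_persons(sim$responses, fx$calibration)
  x <- unclass(sim$responses)
  for (method in c("anchored_ml", "keyform_L1")) {
    set.seed(101)
    ok <- vapply(seq_len(nrow(x)), function(i) {
      v <- stats::setNames(x[i, ], colnames(x))
      v[sample.int(length(v), sample(1:4, 1))] <- NA
      res <- impute_and_measure(v, fx$calibration, method = method)
      abs(res$measure$theta - complete$theta[i]) < complete$se[i]
    }, logical(1))
    expect_gte(mean(ok), 0.9)
  }
})
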