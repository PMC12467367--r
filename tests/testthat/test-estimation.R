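# 8-person, 3-item dichotomous toy: all six non-extreme patterns plus two
# repeats so that the item totals differ
toy_matrix_8x3 <- function() {
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
             c(1, 0, 0), c(1, 1, 0))
  colnames(m) <- c("i1", "i2", "i3")
  m
}

test_that("exchanging two items' responses mirrors their difficulties", {
  spec <- toy_dich_spec(2)
  x <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  colnames(x) <- c("i1", "i2")
  f1 <- rasch(x, spec)
  xs <- x[, c(2, 1)]; colnames(xs) <- c("i1", "i2")  # swapped responses
  f2 <- rasch(xs, spec)
  d1 <- coef(f1); d2 <- coef(f2)
  expect_equal(unname(d1["i1"]), unname(d2["i2"]), tolerance = 1e-6)
  expect_equal(unname(d1["i1"]), -unname(d1["i2"]), tolerance = 1e-9)
  expect_lt(d1[["i1"]], d1[["i2"]])   # item 1 endorsed more often -> easier
})

test_that("JMLE estimates match the lattice likelihood maximizer", {
  spec <- toy_dich_spec(3)
  x <- toy_matrix_8x3()
  fit <- rasch(x, spec)
  orc <- oracle_jmle_grid(x, step = 0.001)
  expect_equal(unname(coef(fit)), orc$delta, tolerance = 1e-3)
  ok <- !fit$persons$extreme_flag
  expect_equal(fit$persons$theta[ok], orc$theta, tolerance = 1e-3)
})

test_that("anchored measures maximize the anchored likelihood", {
  cal <- toy_mixed_calib()
  v1 <- c(d1 = 1L, d2 = 0L, t1 = 2L, t2 = 0L, q1 = 1L)
  v2 <- c(d1 = 1L, d2 = 1L, t1 = 2L, t2 = 1L, q1 = 3L)
  for (v in list(v1, v2)) {
    got <- score_persons(matrix(v, 1, dimnames = list("p", names(v))), cal)
    expect_equal(got$theta, oracle_anchored_grid(v, cal), tolerance = 1e-3)
  }
})

test_that("raw score is sufficient and measures increase with it", {
  fx <- cva_scale_fixture()
  sim <- simulate_responses(simulation_config(fx$spec, fx$calibration, 200,
                                              seed = 21))
  pers <- score_persons(sim$responses, fx$calibration)
  # identical raw score on the identical (complete) item set -> identical
  # theta and SE
  sp <- split(pers[c("theta", "se")], pers$raw_score)
  for (grp in sp) {
    expect_lt(diff(range(grp$theta)), 1e-7)
    expect_lt(diff(range(grp$se)), 1e-7)
  }
  agg <- unique(pers[order(pers$raw_score), c("raw_score", "theta")])
  expect_true(all(diff(agg$theta) > 0))
})

test_that("refitting from the returned calibration is a fixed point", {
  spec <- toy_dich_spec(3)
  x <- toy_matrix_8x3()
  fit <- rasch(x, spec)
  refit <- rasch(x, spec, start = fit$calibration)
  expect_true(refit$converged)
  expect_lt(max(abs(coef(refit) - coef(fit))), 2e-4)
  expect_lte(refit$iterations, 5L)
})

test_that("extreme persons get adjusted finite measures and flags", {
  spec <- toy_dich_spec(3)
  x <- rbind(toy_matrix_8x3(), c(0, 0, 0), c(1, 1, 1))
  fit <- rasch(x, spec)
  p <- fit$persons
  expect_equal(sum(p$extreme_flag), 2L)
  expect_true(all(is.finite(p$theta)))
  expect_lt(p$theta[p$raw_score == 0], min(p$theta[!p$extreme_flag]))
  expect_gt(p$theta[p$raw_score == 3], max(p$theta[!p$extreme_flag]))
})

test_that("missing cells contribute nothing to the sufficient statistics", {
  spec <- toy_dich_spec(3)
  x <- toy_matrix_8x3()
  # add a person whose only answer is missing-free on items 1-2
  x2 <- rbind(x, c(1L, 0L, NA))
  f_base <- rasch(x, spec)
  f_aug <- rasch(x2, spec)
  # item 3's total/count unchanged -> its relative position moves only through
  # the joint refit; check the raw tallies directly instead
  expect_equal(colSums(x2, na.rm = TRUE) - colSums(x), c(i1 = 1, i2 = 0, i3 = 0))
  expect_equal(nrow(f_aug$persons), 9L)
  expect_true(all(is.finite(coef(f_aug))))
})

test_that("estimation degeneracies raise the documented errors", {
  spec <- toy_dich_spec(2)
  all_extreme <- rbind(c(0, 0), c(1, 1))
  colnames(all_extreme) <- c("i1", "i2")
  expect_error(rasch(all_extreme, spec), class = "raschkey_estimation_error")

  spec3 <- scale_spec("z", data.frame(item_id = c("a", "b"), group_id = "g"),
                      data.frame(group_id = "g", n_categories = 3L))
  x <- rbind(c(0, 1), c(1, 0), c(1, 1), c(0, 1))
  colnames(x) <- c("a", "b")   # category 2 never observed
  expect_error(rasch(x, spec3), class = "raschkey_category_error")

  # an item answered only by an extreme person is dropped with a warning
  spec2 <- toy_dich_spec(3)
  y <- rbind(c(1, 0, NA), c(0, 1, NA), c(1, 1, NA), c(0, 1, NA), c(0, 0, 0))
  colnames(y) <- c("i1", "i2", "i3")
  expect_warning(fit <- rasch(y, spec2), "answered only by extreme")
  expect_identical(fit$dropped_items, "i3")
  expect_identical(names(coef(fit)), c("i1", "i2"))
})

test_that("shifting the person distribution leaves item difficulties fixed", {
  fx <- cva_scale_fixture()
  shift <- 0.7
  set.seed(77)
  theta0 <- rnorm(1000, 0, 1)   # centered on the items so every item is informed
  s1 <- simulate_responses(simulation_config(fx$spec, fx$calibration,
                                             theta = theta0, seed = 13))
  s2 <- simulate_responses(simulation_config(fx$spec, fx$calibration,
                                             theta = theta0 + shift,
                                             seed = 13))
  f1 <- rasch(s1$responses, fx$spec)
  f2 <- rasch(s2$responses, fx$spec)
  d <- coef(f2) - coef(f1)
  expect_equal(mean(d), 0, tolerance = 1e-12)   # exact, by centering
  expect_lt(mean(abs(d)), 0.05)                 # invariance up to cell noise
  expect_gt(cor(coef(f1), coef(f2)), 0.995)
  ok <- !(f1$persons$extreme_flag | f2$persons$extreme_flag)
  expect_equal(mean(f2$persons$theta[ok] - f1$persons$theta[ok]), shift,
               tolerance = 0.05)
})

test_that("parameter recovery on the canonical fixture meets its bounds", {
  fx <- cva_scale_fixture()
  sim <- simulate_responses(simulation_config(fx$spec, fx$calibration, 300,
                                              seed = 42))
  fit <- rasch(sim$responses, fx$spec)
  expect_true(fit$converged)
  d <- coef(fit)[names(fx$calibration$difficulty)]
  expect_lt(sqrt(mean((d - fx$calibration$difficulty)^2)), 0.25)
  expect_gt(cor(d, fx$calibration$difficulty), 0.97)
  ok <- !fit$persons$extreme_flag
  expect_lt(sqrt(mean((fit$persons$theta[ok] - sim$theta[ok])^2)), 0.55)
})
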