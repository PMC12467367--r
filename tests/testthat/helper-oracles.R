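# Independent oracle implementations used to check the production code.
# Everything here is deliberately written the slow, literal way (explicit
# loops, direct formula evaluation) and shares no code with R/.

# category probabilities by direct evaluation of the polytomous form
oracle_probs <- function(theta, delta, tau) {
  m <- length(tau) + 1L
  logw <- vapply(seq_len(m) - 1L, function(j) {
    if (j == 0) 0 else sum(theta - delta - tau[seq_len(j)])
  }, numeric(1))
  w <- exp(logw)
  w / sum(w)
}

oracle_moments <- function(theta, delta, tau) {
  p <- oracle_probs(theta, delta, tau)
  j <- seq_along(p) - 1
  E <- sum(j * p)
  W <- sum((j - E)^2 * p)
  C <- sum((j - E)^4 * p)
  list(E = E, W = W, C = C, p = p)
}

# per-item tau vectors for a calibration (dichotomous -> tau = 0)
oracle_item_tau <- function(calib) {
  spec <- calib$spec
  lapply(seq_len(nrow(spec$items)), function(i) {
    g <- spec$items$group_id[i]
    mg <- spec$groups$n_categories[spec$groups$group_id == g]
    tau <- calib$thresholds[[g]]
    if (mg == 2L && !length(tau)) 0 else tau
  })
}

# joint log-likelihood of a complete/incomplete dichotomous matrix
oracle_loglik_dich <- function(x, theta, delta) {
  ll <- 0
  for (n in seq_len(nrow(x))) for (i in seq_len(ncol(x))) {
    if (is.na(x[n, i])) next
    p <- 1 / (1 + exp(-(theta[n] - delta[i])))
    ll <- ll + if (x[n, i] == 1) log(p) else log(1 - p)
  }
  ll
}

# lattice maximizer of the joint dichotomous likelihood: coordinate ascent
# over a `step` grid, items constrained to mean zero (last difficulty is
# implied), iterated to a lattice fixed point
oracle_jmle_grid <- function(x, step = 0.001, span = 6) {
  n <- nrow(x); k <- ncol(x)
  theta <- rep(0, n); delta <- rep(0, k)
  grid <- seq(-span, span, by = step)
  for (sweep in 1:60) {
    old <- c(theta, delta)
    for (p in seq_len(n)) {
      ll <- vapply(grid, function(t) {
        th <- theta; th[p] <- t
        oracle_loglik_dich(x[p, , drop = FALSE], t, delta)
      }, numeric(1))
      theta[p] <- grid[which.max(ll)]
    }
    for (i in seq_len(k - 1L)) {
      ll <- vapply(grid, function(d) {
        dd <- delta; dd[i] <- d
        dd[k] <- -sum(dd[-k])
        oracle_loglik_dich(x, theta, dd)
      }, numeric(1))
      delta[i] <- grid[which.max(ll)]
      delta[k] <- -sum(delta[-k])
    }
    if (max(abs(c(theta, delta) - old)) < step / 2) break
  }
  list(theta = theta, delta = delta)
}

# lattice maximizer of one person's anchored likelihood
oracle_anchored_grid <- function(v, calib, step = 0.001, span = 8) {
  taus <- oracle_item_tau(calib)
  idx <- match(names(v), calib$spec$items$item_id)
  grid <- seq(-span, span, by = step)
  ll <- vapply(grid, function(t) {
    s <- 0
    for (j in seq_along(v)) {
      if (is.na(v[j])) next
      p <- oracle_probs(t, calib$difficulty[[idx[j]]], taus[[idx[j]]])
      s <- s + log(p[v[j] + 1])
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

# item fit statistics by explicit double loop (Wright-Masters forms plus
# the Wilson-Hilferty standardization)
oracle_item_fit <- function(x, theta, calib) {
  taus <- oracle_item_tau(calib)
  ids <- calib$spec$items$item_id
  out <- data.frame(item_id = ids, infit = NA_real_, outfit = NA_real_,
                    infit_z = NA_real_, outfit_z = NA_real_)
  for (i in seq_along(ids)) {
    num <- 0; den <- 0; z2 <- 0; n <- 0; sCW2 <- 0; sCmW2 <- 0
    for (p in seq_len(nrow(x))) {
      if (is.na(x[p, i])) next
      mo <- oracle_moments(theta[p], calib$difficulty[[i]], taus[[i]])
      r2 <- (x[p, i] - mo$E)^2
      num <- num + r2; den <- den + mo$W
      z2 <- z2 + r2 / mo$W; n <- n + 1
      sCW2 <- sCW2 + mo$C / mo$W^2
      sCmW2 <- sCmW2 + (mo$C - mo$W^2)
    }
    if (n == 0) next
    outfit <- z2 / n; infit <- num / den
    qo <- sqrt(max(sCW2 / n^2 - 1 / n, 1e-12))
    qi <- sqrt(max(sCmW2 / den^2, 1e-12))
    out$outfit[i] <- outfit; out$infit[i] <- infit
    out$outfit_z[i] <- (outfit^(1 / 3) - 1) * 3 / qo + qo / 3
    out$infit_z[i] <- (infit^(1 / 3) - 1) * 3 / qi + qi / 3
  }
  out
}

# textbook Pearson correlation
oracle_pearson <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# paired t by the closed-form formula
oracle_paired_t <- function(x, y) {
  d <- x - y; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# expected total score of an item set at theta, by direct summation
oracle_expected_total <- function(theta, calib, items = calib$spec$items$item_id) {
  taus <- oracle_item_tau(calib)
  idx <- match(items, calib$spec$items$item_id)
  sum(vapply(idx, function(i)
    oracle_moments(theta, calib$difficulty[[i]], taus[[i]])$E, numeric(1)))
}

# grid solver for the raw-score -> measure mapping on a 0.0005 lattice
oracle_table_measure <- function(target, calib, items, span = 8,
                                 step = 5e-4) {
  grid <- seq(-span, span, by = step)
  taus <- oracle_item_tau(calib)
  idx <- match(items, calib$spec$items$item_id)
  tot <- rep(0, length(grid))
  for (i in idx) {
    E <- vapply(grid, function(t)
      oracle_moments(t, calib$difficulty[[i]], taus[[i]])$E, numeric(1))
    tot <- tot + E
  }
  grid[which.min(abs(tot - target))]
}

toy_dich_spec <- function(k = 3) {
  scale_spec("toy_dich",
             items = data.frame(item_id = sprintf("i%d", seq_len(k)),
                                group_id = "g"),
             groups = data.frame(group_id = "g", n_categories = 2L))
}

toy_mixed_spec <- function() {
  scale_spec("toy_mixed",
             items = data.frame(item_id = c("d1", "d2", "t1", "t2", "q1"),
                                group_id = c("g2", "g2", "g3", "g3", "g4")),
             groups = data.frame(group_id = c("g2", "g3", "g4"),
                                 n_categories = c(2L, 3L, 4L)))
}

toy_mixed_calib <- function() {
  spec <- toy_mixed_spec()
  d <- c(d1 = -1, d2 = 0.5, t1 = -0.5, t2 = 1.2, q1 = -0.2)
  calibration(spec, d - mean(d),
              thresholds = list(g2 = numeric(0), g3 = c(-0.9, 0.9),
                                g4 = c(-1.6, 0.1, 1.5)))
}
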