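test_that("ROR matches the closed form and a generic odds-ratio oracle", {
  r <- ror(contingency_table(10, 10, 10, 10))
  expect_equal(unname(r["ror"]), 1)
  expect_lt(unname(r["lo95"]), 1)
  expect_gt(unname(r["hi95"]), 1)

  r <- ror(contingency_table(25, 75, 100, 9800))
  expect_equal(unname(r["ror"]), 32.67, tolerance = 1e-3)
  expect_equal(unname(r["lo95"]), 19.94, tolerance = 1e-3)
  expect_equal(unname(r["hi95"]), 53.52, tolerance = 1e-3)

  # independent oracle: saturated binomial GLM log-odds-ratio + Wald CI
  glm_or <- function(a, b, c, d) {
    fit <- stats::glm(
      cbind(c(a, c), c(b, d)) ~ c(1, 0),
      family = stats::binomial()
    )
    est <- stats::coef(fit)[2]
    se <- sqrt(diag(stats::vcov(fit)))[2]
    exp(c(est, est - 1.96 * se, est + 1.96 * se))
  }
  set.seed(1)
  for (i in 1:25) {
    cells <- rmultinom(1, 2000, prob = c(0.05, 0.15, 0.2, 0.6))[, 1] + 1
    got <- ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    want <- glm_or(cells[1], cells[2], cells[3], cells[4])
    expect_equal(unname(got), unname(want), tolerance = 1e-6)
  }
})

test_that("zero cells error without correction and get Haldane +0.5 with it", {
  t0 <- contingency_table(0, 100, 50, 9850)
  expect_error(ror(t0, correction = "none"), "undefined statistic")
  expect_message(r <- ror(t0), "Haldane")
  manual <- (0.5 * 9850.5) / (100.5 * 50.5)
  expect_equal(unname(r["ror"]), manual)
})

test_that("PRR and chi-square match hand arithmetic and the chi-square oracle", {
  p <- prr(contingency_table(10, 90, 100, 9900))
  expect_equal(unname(p["prr"]), 10)
  want <- suppressWarnings(stats::chisq.test(
    matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
    correct = FALSE
  ))$statistic
  expect_equal(unname(p["chi2"]), unname(want), tolerance = 1e-9)
  expect_equal(unname(p["chi2"]), 74.45, tolerance = 1e-2)

  # exact independence: prr = 1, chi2 = 0 (real-valued cells via internals)
  ind <- pvsignal:::prr_stats(20, 80, 180, 720)
  expect_equal(ind$prr, 1)
  expect_equal(ind$chi2, 0)

  expect_error(prr(contingency_table(0, 0, 10, 10)), "zero margin")

  # oracle equivalence across random tables, with and without Yates
  set.seed(2)
  for (i in 1:200) {
    cells <- rmultinom(1, 500, prob = runif(4, 0.05, 1))[, 1] + 1
    m <- matrix(cells, 2, byrow = TRUE)
    got <- prr(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(unname(got["chi2"]),
      unname(stats::chisq.test(m, correct = FALSE)$statistic),
      tolerance = 1e-9
    )
    got_y <- prr(contingency_table(cells[1], cells[2], cells[3], cells[4]), yates = TRUE)
    expect_equal(unname(got_y["chi2"]),
      unname(stats::chisq.test(m, correct = TRUE)$statistic),
      tolerance = 1e-9
    )
  }
})

test_that("information component matches the closed form and its limits", {
  # a = E -> IC exactly 0
  ic0 <- bcpnn_ic(contingency_table(100, 900, 900, 8100))
  expect_equal(unname(ic0["ic"]), 0)

  icx <- bcpnn_ic(contingency_table(25, 75, 100, 9800))
  expect_equal(unname(icx["ic"]), log2(25.5 / 1.75), tolerance = 1e-12)
  expect_equal(unname(icx["ic"]), 3.87, tolerance = 1e-2)
  expect_equal(unname(icx["ic025"]), 3.20, tolerance = 1e-2)

  # the credibility penalty is strictly positive for any count
  for (a in c(0, 1, 3, 10, 1000)) {
    t <- pvsignal:::ic_stats(a, 50, 50, 5000)
    expect_lt(t$ic025, t$ic)
  }

  # Monte-Carlo check of the shrunk point estimate: with a ~ Poisson(E*rr),
  # log2((a + .5)/(E + .5)) concentrates near log2(rr) for large E
  set.seed(3)
  a_mc <- rpois(20000, 40) # E = 10, rr = 4
  ic_mc <- mean(log2((a_mc + 0.5) / 10.5))
  t_big <- pvsignal:::ic_stats(40, 960, 960, 98040) # E = 1000*1000/1e5 = 10
  expect_equal(t_big$ic, log2(40.5 / 10.5), tolerance = 1e-12)
  expect_equal(ic_mc, t_big$ic, tolerance = 0.05)

  # Bate posterior-moment variant agrees with the closed form asymptotically
  bate <- bcpnn_ic(contingency_table(400, 600, 600, 98400), method = "bate")
  closed <- bcpnn_ic(contingency_table(400, 600, 600, 98400))
  expect_equal(unname(bate["ic"]), unname(closed["ic"]), tolerance = 0.05)
  expect_lt(unname(bate["ic025"]), unname(bate["ic"]))
})

test_that("EBGM under a degenerate prior matches special-function and MC oracles", {
  prior <- gps_prior(1, 1, 1, 1, w = 1)
  t <- contingency_table(25, 75, 100, 9800) # E = 1.25, posterior Gamma(26, 2.25)
  e <- ebgm(t, prior)
  expect_equal(unname(e["ebgm"]), exp(digamma(26) - log(2.25)), tolerance = 1e-12)
  expect_equal(unname(e["ebgm"]), 11.33, tolerance = 1e-2)
  expect_equal(unname(e["ebgm05"]), qgamma(0.05, 26, rate = 2.25), tolerance = 1e-8)
  expect_equal(unname(e["ebgm05"]), 8.10, tolerance = 1e-2)

  set.seed(4)
  draws <- rgamma(1e6, 26, rate = 2.25)
  expect_equal(unname(e["ebgm"]), exp(mean(log(draws))), tolerance = 0.01)
  expect_equal(unname(e["ebgm05"]), unname(quantile(draws, 0.05)), tolerance = 0.01)
})

test_that("EBGM05 root-finding matches MC percentiles for a genuine mixture", {
  prior <- gps_prior(0.5, 0.3, 4, 2, w = 0.4)
  set.seed(5)
  for (cell in list(c(a = 12, E = 3), c(a = 3, E = 6), c(a = 80, E = 20))) {
    post <- pvsignal:::gps_posterior(cell["a"], cell["E"], prior)
    comp <- rbinom(4e5, 1, 1 - post$q1)
    draws <- ifelse(comp == 0,
      rgamma(4e5, post$shape1, rate = post$rate1),
      rgamma(4e5, post$shape2, rate = post$rate2)
    )
    got <- pvsignal:::ebgm_stats(unname(cell["a"]), unname(cell["E"]), prior)
    expect_equal(got$ebgm, exp(mean(log(draws))), tolerance = 0.01)
    expect_equal(got$ebgm05, unname(quantile(draws, 0.05)), tolerance = 0.01)
    expect_lt(got$ebgm05, got$ebgm)
    q95 <- pvsignal:::gps_quantile(
      0.95, post$q1, post$shape1, post$rate1,
      post$shape2, post$rate2
    )
    expect_gt(q95, got$ebgm)
  }
})

test_that("IC and EBGM converge to log2(a/E) and a/E as counts grow", {
  # a = 1e5, E = 5e4 (observed/expected ratio 2) at consistent margins
  t <- contingency_table(1e5, 0, 1e6, 11e5)
  icv <- bcpnn_ic(t)
  expect_equal(unname(icv["ic"]), 1, tolerance = 0.01)
  prior <- gps_prior(0.2, 0.1, 2, 4, w = 1 / 3)
  e <- pvsignal:::ebgm_stats(1e5, 5e4, prior)
  expect_equal(e$ebgm, 2, tolerance = 0.01)
  # shrinkage vanishes entirely at a = E = 1e6
  e1 <- pvsignal:::ebgm_stats(1e6, 1e6, prior)
  expect_equal(e1$ebgm, 1, tolerance = 1e-3)
})

test_that("statistics are monotone in a and ROR/PRR order correctly", {
  prior <- gps_prior(1, 1, 2, 4, w = 0.5)
  set.seed(6)
  for (i in 1:20) {
    b <- sample(50:500, 1)
    c_ <- sample(50:500, 1)
    d <- sample(5000:20000, 1)
    a1 <- sample(3:50, 1)
    a2 <- a1 + sample(1:30, 1)
    s1 <- list(
      ror = pvsignal:::ror_stats(a1, b, c_, d)$ror,
      prr = pvsignal:::prr_stats(a1, b, c_, d)$prr,
      ic = pvsignal:::ic_stats(a1, b, c_, d)$ic,
      ebgm = pvsignal:::ebgm_stats(a1, (a1 + b) * (a1 + c_) / (a1 + b + c_ + d), prior)$ebgm
    )
    s2 <- list(
      ror = pvsignal:::ror_stats(a2, b, c_, d)$ror,
      prr = pvsignal:::prr_stats(a2, b, c_, d)$prr,
      ic = pvsignal:::ic_stats(a2, b, c_, d)$ic,
      ebgm = pvsignal:::ebgm_stats(a2, (a2 + b) * (a2 + c_) / (a2 + b + c_ + d), prior)$ebgm
    )
    for (k in names(s1)) expect_gt(s2[[k]], s1[[k]])
    # ROR > PRR iff a/b > c/d
    expect_equal(s1$ror > s1$prr, a1 / b > c_ / d)
  }
  # exact independence: ROR = PRR = 1
  ind <- pvsignal:::ror_stats(20, 80, 180, 720)
  expect_equal(ind$ror, 1)
})

test_that("the gamma-mixture prior is recovered from simulated cells", {
  # truth: single Gamma(2, 4); the fit should collapse to one component
  set.seed(7)
  n <- 50000
  E <- exp(runif(n, log(0.5), log(50)))
  lam <- rgamma(n, 2, rate = 4)
  cells <- data.frame(a = rpois(n, lam * E), E = E)
  fit <- fit_gps_prior(cells)
  expect_gte(fit$w, 0.9)
  expect_lt(abs(fit$alpha1 - 2) / 2, 0.15)
  expect_lt(abs(fit$beta1 - 4) / 4, 0.15)

  # permutation invariance
  perm <- sample(n)
  fit2 <- fit_gps_prior(cells[perm, ])
  expect_equal(
    unlist(fit[c("alpha1", "beta1", "alpha2", "beta2", "w")]),
    unlist(fit2[c("alpha1", "beta1", "alpha2", "beta2", "w")]),
    tolerance = 1e-6
  )
})

test_that("the four-threshold gate behaves at the count gate, the null and a strong signal", {
  th <- da_thresholds()
  strong_but_rare <- tibble::tibble(
    a = 2, ror_lo95 = 50, prr = 40, chi2 = 500, ic025 = 4, ebgm05 = 30
  )
  expect_false(evaluate_signal(strong_but_rare, th))

  null_row <- tibble::tibble(
    a = 100, ror_lo95 = 0.8, prr = 1, chi2 = 0, ic025 = -0.5, ebgm05 = 0.9
  )
  expect_false(evaluate_signal(null_row, th))

  # a synthetic strong-signal table evaluated end to end through the statistics
  t <- contingency_table(429, 4625, 1200, 7474000)
  prior <- gps_prior(1, 1, 2, 4, w = 0.5)
  n <- sum(t)
  row <- tibble::tibble(
    a = 429,
    ror_lo95 = ror(t)["lo95"],
    prr = prr(t)["prr"], chi2 = prr(t)["chi2"],
    ic025 = bcpnn_ic(t)["ic025"],
    ebgm05 = ebgm(t, prior)["ebgm05"]
  )
  expect_true(evaluate_signal(row, th))

  # each gate is individually necessary
  for (col in c("ror_lo95", "prr", "chi2", "ic025", "ebgm05")) {
    broken <- row
    broken[[col]] <- c(ror_lo95 = 0.9, prr = 1, chi2 = 1, ic025 = -1, ebgm05 = 1)[[col]]
    expect_false(evaluate_signal(broken, th))
  }
})
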