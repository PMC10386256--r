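test_that("slack frontier recovers dominant inefficiency and the pure-noise null", {
  ## nearly all variance from the half-normal component
  d <- simulate_slack_data(500, c(1, 0.5), sigma_u = 2, sigma_v = 0.05, seed = 21)
  f <- fit_slack_frontier(d$slacks, d$Z)
  expect_gt(f$gamma, 0.9)

  ## no inefficiency at all: gamma pinned near zero, LR negligible
  d0 <- simulate_slack_data(500, c(1, 0.5), sigma_u = 0, sigma_v = 1, seed = 22)
  f0 <- fit_slack_frontier(d0$slacks, d0$Z)
  expect_lt(f0$gamma, 0.1)
  expect_lt(f0$lr_stat, 3)
  expect_false(lr_test_gamma(f0, alpha = 0.05)$reject)
})

test_that("the residual decomposition reproduces observed slacks exactly", {
  d <- simulate_slack_data(300, c(2, -0.3, 0.7), sigma_u = 1.5, sigma_v = 0.8,
                           seed = 23)
  f <- fit_slack_frontier(d$slacks, d$Z)
  expect_equal(f$fitted + f$nu_hat + f$mu_hat, d$slacks, tolerance = 1e-10)
  expect_true(all(f$mu_hat >= 0))
  expect_gt(f$sigma2, 0)
  expect_true(f$gamma >= 0 && f$gamma <= 1)
  expect_gte(f$lr_stat, 0)
})

test_that("estimates tighten from n = 200 to n = 1000", {
  truth <- c(2, -0.3, 0.7); g_true <- 4 / (4 + 1)
  err <- sapply(c(200, 1000), function(n) {
    e <- sapply(1:5, function(s) {
      d <- simulate_slack_data(n, truth, sigma_u = 2, sigma_v = 1, seed = 100 + s)
      f <- fit_slack_frontier(d$slacks, d$Z)
      c(mean(abs(f$beta - truth)), abs(f$gamma - g_true))
    })
    rowMeans(e)
  })
  expect_lt(err[1, 2], err[1, 1])  # beta error shrinks
  expect_lt(err[2, 2], 0.15)       # gamma error small at n = 1000
})

test_that("jondrow separation matches quadrature and its analytic limits", {
  for (e in c(-2, -0.5, 0.5, 2)) for (su in c(0.5, 2)) for (sv in c(0.5, 2)) {
    jd <- jondrow_separate(e, su, sv)
    dens <- function(mu) 2 / su * stats::dnorm(mu / su) *
      stats::dnorm((e - mu) / sv) / sv
    nrm <- stats::integrate(dens, 0, 60, rel.tol = 1e-12)$value
    qv <- stats::integrate(function(mu) mu * dens(mu), 0, 60,
                           rel.tol = 1e-12)$value / nrm
    expect_equal(jd, qv, tolerance = 1e-6)
    expect_gt(jd, 0)
  }
  ## monotone in the residual; vanishing inefficiency limit; degenerate noise
  expect_gt(jondrow_separate(2, 1, 1), jondrow_separate(-2, 1, 1))
  expect_equal(jondrow_separate(0.7, 0, 1), 0)
  expect_lt(jondrow_separate(0.7, 1e-6, 1), 1e-5)
  expect_error(jondrow_separate(0.5, 1, 0), "sigma_v")
  ## gamma -> 1: conditional mean approaches max(eps, 0) pointwise
  eps <- c(-1, -0.1, 0.2, 1.5)
  expect_equal(jondrow_separate(eps, 1, 1e-3), pmax(eps, 0), tolerance = 5e-3)
})

test_that("input adjustment applies the worst-environment/best-luck formula", {
  fits <- list(fake_fit(fitted = c(1, 2, 3), nu_hat = c(0.5, 0, -0.5)))
  XA <- adjust_inputs(matrix(10, 3, 1), fits)
  expect_equal(drop(XA), c(12, 11.5, 11))

  ## identical environment and luck: adjustment vanishes
  fits0 <- list(fake_fit(fitted = rep(2, 3), nu_hat = rep(0.1, 3)))
  expect_equal(drop(adjust_inputs(matrix(10, 3, 1), fits0)), rep(10, 3))

  ## on a panel: adjusted inputs never fall below originals and stay positive
  p <- random_panel(24, n_dmu = 5, n_periods = 3)
  s <- score_panel(p)
  fit <- fit_slack_frontier(s$s_in_x1, p$Z)
  fits_p <- list(fit, NULL)
  adj <- adjust_inputs(p, fits_p)
  expect_true(all(adj$X >= p$X - 1e-12))
  expect_identical(adj$X[, 2], p$X[, 2])
  expect_true(all(adj$X > 0))
  ## the adjusted panel still validates as a panel
  expect_s3_class(panel_dataset(adj$data, adj$schema), "panel_dataset")
  expect_error(adjust_inputs(p, fits_p[1]), "one slack frontier fit per input")
})

test_that("the gamma LR test uses the boundary-mixture null", {
  f <- fake_fit(1:3, 1:3); f$lr_stat <- 0; class(f) <- "slack_frontier_fit"
  t0 <- lr_test_gamma(f, alpha = 0.05)
  expect_false(t0$reject)
  expect_equal(t0$p_value, 1)
  ## mixture critical value at the 1% level sits between 5.41 and 5.42
  f$lr_stat <- 5.41
  expect_false(lr_test_gamma(f, alpha = 0.01)$reject)
  f$lr_stat <- 5.42
  expect_true(lr_test_gamma(f, alpha = 0.01)$reject)
  expect_equal(lr_test_gamma(f, alpha = 0.01)$critical,
               stats::qchisq(0.98, 1), tolerance = 1e-12)
})

test_that("the LR test holds its size under the gamma = 0 null", {
  rej <- vapply(1:200, function(s) {
    d <- simulate_slack_data(500, c(1, 0.5), sigma_u = 0, sigma_v = 1,
                             seed = 5000 + s)
    f <- fit_slack_frontier(d$slacks, d$Z, n_starts = 3)
    lr_test_gamma(f, alpha = 0.05)$reject
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})
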