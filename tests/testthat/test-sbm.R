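test_that("a unit evaluated against itself is efficient with zero slacks", {
  pr <- sbm_program(x0 = 2, y0 = 3, b0 = 1, X_ref = matrix(2),
                    Y_ref = matrix(3), B_ref = matrix(1))
  r <- solve_sbm(pr)
  expect_equal(r$te, 1, tolerance = 1e-9)
  expect_equal(unname(c(r$input_slacks, r$output_slacks, r$bad_slacks)),
               c(0, 0, 0), tolerance = 1e-9)
})

test_that("plain SBM score matches the fractional grid oracle", {
  ## two DMUs, one input / one output: A=(1,2), B=(2,2); score B under CRS
  X <- matrix(c(1, 2)); Y <- matrix(c(2, 2))
  pr <- sbm_program(x0 = 2, y0 = 2, X_ref = X, Y_ref = Y)
  r <- solve_sbm(pr)
  ## fractional objective searched over the efficient peer's intensity at
  ## step 1e-4 (the evaluated unit's own intensity is zero at the optimum,
  ## confirmed by a coarse two-dimensional sweep)
  oracle <- sbm_grid_oracle(2, 2, numeric(0), X, Y,
                            matrix(numeric(0), 2, 0),
                            cbind(seq(0, 10, 1e-4), 0))
  oracle2d <- sbm_grid_oracle(2, 2, numeric(0), X, Y,
                              matrix(numeric(0), 2, 0),
                              as.matrix(expand.grid(seq(0, 4, 5e-3),
                                                    seq(0, 2, 5e-3))))
  expect_lte(oracle, oracle2d + 1e-12)
  expect_lt(r$te, 1)
  expect_equal(r$te, oracle, tolerance = 1e-4)
  expect_equal(r$te, 0.5, tolerance = 1e-6)  # known value for this geometry
})

test_that("scores are invariant to rescaling any column", {
  p <- random_panel(11, n_dmu = 5, n_periods = 2)
  s1 <- score_panel(p)
  p2 <- p
  p2$X[, 1] <- p2$X[, 1] * 1000
  p2$Y[, 2] <- p2$Y[, 2] * 0.01
  p2$B[, 1] <- p2$B[, 1] * 50
  s2 <- score_panel(p2)
  expect_equal(s2$te, s1$te, tolerance = 1e-9)
  expect_equal(s2$pte, s1$pte, tolerance = 1e-9)
})

test_that("adding a dominated observation never raises another unit's score", {
  X <- matrix(c(1, 2, 3)); Y <- matrix(c(2, 2.5, 1.5))
  base <- solve_sbm(sbm_program(x0 = 2, y0 = 2.5, X_ref = X, Y_ref = Y))
  ## dominated point: more input, less output than row 1
  X2 <- rbind(X, 4); Y2 <- rbind(Y, 1)
  aug <- solve_sbm(sbm_program(x0 = 2, y0 = 2.5, X_ref = X2, Y_ref = Y2))
  expect_lte(aug$te, base$te + 1e-9)
})

test_that("global-frontier scores never exceed contemporaneous scores", {
  p <- random_panel(12, n_dmu = 5, n_periods = 3)
  sg <- score_panel(p, technology_spec(frontier = "global"))
  sc <- score_panel(p, technology_spec(frontier = "contemporaneous"))
  expect_true(all(sg$te <= sc$te + 1e-9))
  expect_true(all(sg$pte <= sc$pte + 1e-9))
})

test_that("super-efficiency matches the two-dimensional grid oracle", {
  ## A=(1,2) scored against B=(2,2), C=(4,2) under CRS
  r <- solve_super_sbm(sbm_program(x0 = 1, y0 = 2,
                                   X_ref = matrix(c(2, 4)),
                                   Y_ref = matrix(c(2, 2)),
                                   exclude_self = TRUE))
  g <- expand.grid(lB = seq(0, 2, 1e-3), lC = seq(0, 1, 1e-3))
  sx <- pmax(0, 2 * g$lB + 4 * g$lC - 1)
  sy <- pmax(0, 2 - (2 * g$lB + 2 * g$lC))
  den <- 1 - sy / 2
  obj <- ifelse(den > 0, (1 + sx) / den, Inf)
  expect_equal(r$te, min(obj), tolerance = 1e-4)
  expect_gte(r$te, 1 - 1e-9)
})

test_that("a twin observation pins super-efficiency at one", {
  r <- solve_super_sbm(sbm_program(x0 = 2, y0 = 3, X_ref = matrix(2),
                                   Y_ref = matrix(3), exclude_self = TRUE))
  expect_equal(r$te, 1, tolerance = 1e-9)
})

test_that("super-efficiency scoring refuses inefficient units", {
  pr <- sbm_program(x0 = 2, y0 = 2, X_ref = matrix(1), Y_ref = matrix(2),
                    exclude_self = TRUE)
  expect_error(solve_super_sbm(pr, nonsuper_te = 0.5), "contract")
  expect_error(solve_super_sbm(sbm_program(x0 = 1, y0 = 1, X_ref = matrix(1),
                                           Y_ref = matrix(1))),
               "exclude_self")
  expect_error(solve_sbm(pr), "exclude_self|solve_super_sbm")
})

test_that("panel scoring satisfies the te = pte * se identity and ray-frontier cases", {
  ## all DMUs scalar multiples of one technology: y = 2x, b = x
  d <- expand.grid(dmu = letters[1:4], period = c("p1", "p2"),
                   stringsAsFactors = FALSE)
  d$x <- c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5)
  d$y <- 2 * d$x; d$b <- d$x
  p <- panel_dataset(d, list(dmu = "dmu", period = "period", input = "x",
                             desirable = "y", undesirable = "b"))
  s <- score_panel(p, technology_spec(frontier = "global"))
  expect_equal(s$te, rep(1, 8), tolerance = 1e-9)
  expect_equal(s$pte, rep(1, 8), tolerance = 1e-9)
  expect_equal(s$se, rep(1, 8), tolerance = 1e-9)

  p2 <- random_panel(13, n_dmu = 10, n_periods = 3)
  s2 <- score_panel(p2, technology_spec(super_efficiency = TRUE))
  expect_equal(s2$se, s2$te / s2$pte, tolerance = 1e-12)
  expect_equal(s2$te, s2$pte * s2$se, tolerance = 1e-12)
  ## plain score 1 implies super score >= 1; plain score < 1 left untouched
  eff <- s2$te_nonsuper >= 1 - 1e-6
  expect_true(all(s2$te[eff] >= 1 - 1e-9))
  expect_equal(s2$te[!eff], s2$te_nonsuper[!eff], tolerance = 1e-12)
})

test_that("efficiency equals one exactly when all slacks vanish", {
  p <- random_panel(14, n_dmu = 6, n_periods = 2)
  s <- score_panel(p)
  slack_cols <- grep("^s_(in|out|bad)_", names(s))
  tot <- rowSums(abs(as.matrix(s[, slack_cols])))
  expect_true(all((s$te_nonsuper > 1 - 1e-7) == (tot < 1e-6)))
})

test_that("zero undesirable column degrades gracefully to the classic SBM", {
  d <- tiny_panel_df(); d$deaths <- 0
  p <- panel_dataset(d, tiny_schema())
  expect_warning(s <- score_panel(p), "all zero")
  d2 <- d; s2sch <- tiny_schema(); s2sch$undesirable <- character(0)
  p2 <- panel_dataset(d2, s2sch)
  s2 <- score_panel(p2)
  expect_equal(s$te, s2$te, tolerance = 1e-9)
})

test_that("zero entries in evaluated outputs are dropped from the objective average", {
  ## y2 = 0 for the evaluated unit: objective averages over remaining terms
  X <- matrix(c(1, 2), 2, 1)
  Y <- cbind(c(2, 2), c(1, 0))
  pr <- sbm_program(x0 = 2, y0 = c(2, 0), X_ref = X, Y_ref = Y)
  r <- solve_sbm(pr)
  expect_true(is.finite(r$te))
  expect_gt(r$te, 0)
  expect_lte(r$te, 1)
})
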