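test_that("a minimal well-formed panel validates and normalizes", {
  p <- panel_dataset(tiny_panel_df(), tiny_schema())
  expect_s3_class(p, "panel_dataset")
  expect_equal(nrow(p$X), 4)
  expect_equal(p$periods, c("2009", "2010"))
  ## rows normalized to (period, dmu)
  expect_equal(p$dmu, c("A", "B", "A", "B"))
})

test_that("schema and balance violations are rejected with informative errors", {
  d <- tiny_panel_df(); s <- tiny_schema()
  expect_error(panel_dataset(d[-2, ], s), "unbalanced")
  d2 <- rbind(d, d[1, ])
  expect_error(panel_dataset(d2, s), "duplicated")
  d3 <- d; d3$beds[2] <- 0
  expect_error(panel_dataset(d3, s), "non-positive input.*beds")
  d4 <- d; d4$visits[1] <- -1
  expect_error(panel_dataset(d4, s), "negative desirable")
  s2 <- s; s2$flavour <- "beds"
  expect_error(panel_dataset(d, s2), "unknown schema role")
  s3 <- s; s3$input <- "nonexistent"
  expect_error(panel_dataset(d, s3), "absent column")
  s4 <- s; s4$input <- character(0)
  expect_error(panel_dataset(d, s4), "at least one input")
})

test_that("period order follows the supplied list, not lexical sort", {
  d <- tiny_panel_df()
  d$year <- rep(c("2010/2011", "2009/2010"), each = 2)
  s <- tiny_schema(); s$period_order <- c("2009/2010", "2010/2011")
  p <- panel_dataset(d, s)
  expect_equal(p$periods, c("2009/2010", "2010/2011"))
  expect_equal(p$period[1], "2009/2010")
})

test_that("panel read/write round-trips identically", {
  for (seed in 1:3) {
    p <- random_panel(seed)
    f <- withr::local_tempfile(fileext = ".csv")
    write_panel(p, f)
    p2 <- read_panel(f, p$schema)
    expect_identical(p2$X, p$X)
    expect_identical(p2$Y, p$Y)
    expect_identical(p2$B, p$B)
    expect_identical(p2$Z, p$Z)
    expect_identical(p2$dmu, p$dmu)
    ## second cycle is a fixed point
    f2 <- withr::local_tempfile(fileext = ".csv")
    write_panel(p2, f2)
    expect_identical(read_panel(f2, p$schema)$X, p$X)
  }
})

test_that("result records serialize with presentation columns and full precision", {
  p <- random_panel(4, n_dmu = 3, n_periods = 2)
  rec <- score_panel(p, technology_spec(super_efficiency = TRUE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(rec, f)
  raw <- utils::read.csv(f, check.names = FALSE)
  expect_true(all(c("te", "te_3dp", "pte_3dp", "se_3dp") %in% names(raw)))
  back <- read_results(f)
  expect_identical(back$te, rec$te)
  expect_identical(back$pte, rec$pte)
  ## presentation convention: three decimals
  expect_identical(raw$te_3dp[1], as.numeric(formatC(round(rec$te[1], 3),
                                                     format = "f", digits = 3)))
  ## mixed record types refuse to serialize together
  gm <- gml_panel(p)
  expect_error(write_results(list(rec, gm), f), "mixed record types")
  expect_error(write_results(data.frame(a = 1), f), "efficiency_records or gml_records")
})

test_that("the shipped region partition has the 11/8/12 structure", {
  rm <- read_region_map()
  expect_length(rm, 31)
  expect_equal(unname(table(rm)[c("east", "central", "west")]),
               c(11L, 8L, 12L), ignore_attr = TRUE)
  expect_equal(unname(rm["Beijing"]), "east")
  expect_equal(unname(rm["Henan"]), "central")
  expect_equal(unname(rm["Xizang"]), "west")
})
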