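test_that("distance is one on the frontier and global never exceeds contemporaneous", {
  p <- random_panel(31, n_dmu = 5, n_periods = 3)
  X <- p$X; Y <- p$Y; B <- p$B
  all_idx <- seq_len(nrow(X))
  for (j in c(1, 7)) {
    per <- which(p$period == p$period[j])
    dg <- dea_distance(X[j, ], Y[j, ], B[j, ], X, Y, B)
    dc <- dea_distance(X[j, ], Y[j, ], B[j, ], X[per, ], Y[per, ], B[per, ])
    expect_lte(dg, dc + 1e-9)
    expect_lte(dc, 1 + 1e-9)
  }
  ## self-reference: on its own frontier
  d1 <- dea_distance(X[1, ], Y[1, ], B[1, ], X[1, , drop = FALSE],
                     Y[1, , drop = FALSE], B[1, , drop = FALSE])
  expect_equal(d1, 1, tolerance = 1e-9)
})

test_that("radial output distance matches the ray-frontier closed form", {
  ## frontier ray through (1, 2): unit (2, 2) can expand output to 4
  d <- dea_distance(x0 = 2, y0 = 2, X_ref = matrix(c(1, 2)),
                    Y_ref = matrix(c(2, 2)), measure = "radial_output")
  expect_equal(d, 0.5, tolerance = 1e-9)
})

test_that("productivity records satisfy the ec x bpc identity and known constructions", {
  p <- random_panel(32, n_dmu = 6, n_periods = 3)
  g <- gml_panel(p)
  expect_equal(g$hsgi, g$ec * g$bpc, tolerance = 1e-12)
  expect_true(all(g$hsgi > 0 & g$ec > 0 & g$bpc > 0))

  ## identical data in both periods: no change anywhere
  d <- expand.grid(dmu = letters[1:3], period = c("p1", "p2"),
                   stringsAsFactors = FALSE)
  d$x <- rep(c(1, 2, 3), 2); d$y <- rep(c(2, 2.5, 2), 2)
  ps <- panel_dataset(d, list(dmu = "dmu", period = "period",
                              input = "x", desirable = "y"))
  gs <- gml_panel(ps)
  expect_equal(gs$hsgi, rep(1, 3), tolerance = 1e-9)
  expect_equal(gs$ec, rep(1, 3), tolerance = 1e-9)

  ## static frontier, one unit moves onto it: pure catch-up
  d2 <- d; d2$y[d2$dmu == "c" & d2$period == "p2"] <- 6  # onto ray y = 2x
  g2 <- gml_panel(panel_dataset(d2, list(dmu = "dmu", period = "period",
                                         input = "x", desirable = "y")))
  rc <- g2[g2$dmu == "c", ]
  expect_gt(rc$ec, 1)
  expect_equal(rc$bpc, 1, tolerance = 1e-9)
  expect_equal(rc$hsgi, rc$ec, tolerance = 1e-12)

  ## doubling every output: pure frontier shift, no catch-up
  d3 <- d; d3$y[d3$period == "p2"] <- 2 * d3$y[d3$period == "p2"]
  g3 <- gml_panel(panel_dataset(d3, list(dmu = "dmu", period = "period",
                                         input = "x", desirable = "y")))
  expect_equal(g3$ec, rep(1, 3), tolerance = 1e-9)
  expect_equal(g3$hsgi, g3$bpc, tolerance = 1e-12)
})

test_that("the global index is circular over consecutive transitions", {
  p <- random_panel(33, n_dmu = 5, n_periods = 4)
  g <- gml_panel(p)
  for (dm in p$dmu_ids) {
    r <- g[g$dmu == dm, ]
    direct <- r$d_global_t1[nrow(r)] / r$d_global_t[1]
    expect_equal(prod(r$hsgi), direct, tolerance = 1e-9)
  }
})

test_that("regional aggregation follows the published conventions", {
  rec <- data.frame(dmu = c("a", "b"), from_period = "p1", to_period = "p2",
                    hsgi = c(1.2, 0.8), ec = c(1, 1), bpc = c(1.2, 0.8))
  class(rec) <- c("gml_records", "data.frame")
  ar <- aggregate_gml(rec)
  expect_equal(ar$hsgi[ar$transition == "p1/p2"], 1.0)
  ge <- aggregate_gml(rec, scheme = "geometric")
  expect_equal(ge$hsgi[ge$transition == "p1/p2"], sqrt(0.96), tolerance = 1e-9)

  ## single-record group: the mean is the record
  one <- aggregate_gml(rec[1, ], groups = c(a = "solo"))
  expect_equal(one$hsgi, c(1.2, 1.2))
  expect_error(aggregate_gml(rec, groups = c(a = "g1")), "missing from the group map")

  p <- random_panel(34, n_dmu = 6, n_periods = 3)
  g <- gml_panel(p)
  agg <- aggregate_gml(g, groups = p$region)
  ## study-period row is the mean of the per-transition group means
  for (grp in unique(agg$group)) {
    rows <- agg[agg$group == grp & agg$transition != "mean", ]
    mrow <- agg[agg$group == grp & agg$transition == "mean", ]
    expect_equal(mrow$hsgi, mean(rows$hsgi), tolerance = 1e-12)
    expect_equal(mrow$bpc, mean(rows$bpc), tolerance = 1e-12)
  }
  expect_match(attr(agg, "note"), "arithmetic")
})
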