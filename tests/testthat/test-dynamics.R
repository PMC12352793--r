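test_that("rest points yield stationary trajectories", {
  p <- baseline_params()
  for (start in list(c(0, 0), c(1, 1), c(0.5, 0.5))) {
    tr <- integrate_replicator(p, start[1], start[2], t_end = 5)
    g <- glance(tr)
    expect_equal(g$terminal, "at_rest")
    expect_equal(c(g$x_final, g$y_final), start, tolerance = 1e-8)
  }
})

test_that("starts inside and outside the basin reach the predicted corner", {
  p <- baseline_params()
  expect_equal(glance(integrate_replicator(p, 0.05, 0.05))$terminal, "to_OO")
  expect_equal(glance(integrate_replicator(p, 0.95, 0.95))$terminal, "to_KK")
  # raising beta to 0.6 pulls the saddle to (1/3, 1/3): the centre start
  # now lies in the cooperation basin
  p6 <- set_params(p, beta = 0.6)
  expect_equal(glance(integrate_replicator(p6, 0.5, 0.5))$terminal, "to_KK")
})

test_that("trajectories stay in the unit square up to solver tolerance", {
  withr::local_seed(501)
  for (p in regime_params(6, "cost_dominant_bistable", seed = 51)) {
    tr <- integrate_replicator(p, runif(1, 0.05, 0.95), runif(1, 0.05, 0.95),
                               rtol = 1e-8)
    expect_true(all(tr$x >= 0 & tr$x <= 1))
    expect_true(all(tr$y >= 0 & tr$y <= 1))
    expect_lt(attr(tr, "clip_max"), 1e-7)
    expect_true(all(diff(tr$time) > 0))
  }
})

test_that("cooperation share is monotone when the bracket keeps its sign", {
  # subsidy-dominant: both brackets positive on the whole square
  p <- set_params(baseline_params(), H = 3)
  tr <- integrate_replicator(p, 0.2, 0.3)
  expect_true(all(diff(tr$x) >= -1e-10))
  expect_true(all(diff(tr$y) >= -1e-10))
  # synergy too weak: brackets negative, shares decay
  q <- game_params(H = 0, C = 5, beta = 0.1)
  trq <- integrate_replicator(q, 0.8, 0.7)
  expect_true(all(diff(trq$x) <= 1e-10))
  expect_true(all(diff(trq$y) <= 1e-10))
  expect_equal(attr(trq, "terminal"), "to_OO")
})

test_that("trajectory behaviour matches the stability classification", {
  p <- baseline_params()
  # starts within 1e-3 of an ESS stay within 1e-2 of it
  for (ess in list(c(0, 0), c(1, 1))) {
    s0 <- abs(ess - 1e-3)
    tr <- integrate_replicator(p, s0[1], s0[2])
    expect_true(all(abs(tr$x - ess[1]) < 1e-2))
    expect_true(all(abs(tr$y - ess[2]) < 1e-2))
  }
  # a start near the unstable corner F(0,1) leaves its neighbourhood
  trf <- integrate_replicator(p, 0.01, 0.99)
  dist_f <- sqrt((trf$x - 0)^2 + (trf$y - 1)^2)
  expect_gt(max(dist_f), 0.5)
})

test_that("terminal classification is robust to the solver tolerance", {
  withr::local_seed(502)
  draws <- c(regime_params(6, "cost_dominant_bistable", seed = 52),
             regime_params(3, "subsidy_dominant", seed = 53))
  mismatches <- 0L
  for (p in draws) {
    x0 <- runif(1, 0.05, 0.95)
    y0 <- runif(1, 0.05, 0.95)
    t1 <- glance(integrate_replicator(p, x0, y0, rtol = 1e-8))$terminal
    t2 <- glance(integrate_replicator(p, x0, y0, rtol = 5e-9))$terminal
    mismatches <- mismatches + (t1 != t2)
  }
  expect_equal(mismatches, 0L)
})

test_that("the beta sweep flips outcomes where the saddle crosses the start", {
  sw <- sweep_parameter(baseline_params(), "beta", seq(0.1, 0.9, by = 0.1))
  ord <- sw[order(sw$value), ]
  expect_true(all(ord$terminal[ord$value < 0.4] == "to_OO"))
  expect_true(all(ord$terminal[ord$value > 0.4] == "to_KK"))
  # at beta = 0.4 the start IS the saddle: documented degenerate case
  expect_equal(ord$terminal[ord$value == 0.4], "at_rest")
  flip <- attr(sw, "flip_interval")
  expect_true(flip[1] < 0.4 && 0.4 <= flip[2])
})

test_that("the reward-punishment sweep reproduces the regime sequence", {
  sw <- sweep_parameter(baseline_params(), "H", c(0, 1, 2, 3))
  expect_equal(sw$terminal, c("to_OO", "to_OO", "at_rest", "to_KK"))
})

test_that("cost sweeps inside the subsidy regime always cooperate", {
  p <- set_params(baseline_params(), H = 3)
  sw <- sweep_parameter(p, "C", c(1, 2, 3, 4, 5))  # 2H = 6 > C throughout
  expect_true(all(sw$terminal == "to_KK"))
  expect_null(attr(sw, "flip_interval"))
})

test_that("joint rho sweeps vary both players together", {
  sw <- sweep_parameter(baseline_params(), "rho", c(0.3, 0.7))
  # rho = 0.3 puts the saddle at 1/(4*0.3) = 0.833 > 0.5: compete
  expect_equal(sw$terminal, c("to_OO", "to_KK"))
  expect_error(sweep_parameter(baseline_params(), "alpha", 1),
               "unknown sweep parameter")
  expect_error(sweep_parameter(baseline_params(), "beta", numeric(0)),
               "non-empty")
})

test_that("empirical basin fraction hits the regime extremes", {
  expect_equal(
    empirical_basin_fraction(set_params(baseline_params(), H = 3),
                             grid_n = 5),
    1
  )
  expect_equal(
    empirical_basin_fraction(game_params(H = 0, C = 5, beta = 0.1),
                             grid_n = 5),
    0
  )
})

test_that("empirical basin fraction tracks the symmetric analytic area", {
  frac <- empirical_basin_fraction(baseline_params(), grid_n = 9)
  expect_lt(abs(frac - basin_area(baseline_params())$area), 0.15)
})

test_that("basin fraction moves in the same direction as the area proxy", {
  p <- baseline_params()
  up <- set_params(p, H = 2.3)     # area rises
  down <- set_params(p, H = 1.7)   # area falls
  f0 <- empirical_basin_fraction(p, grid_n = 9)
  expect_gt(empirical_basin_fraction(up, grid_n = 9), f0)
  expect_lt(empirical_basin_fraction(down, grid_n = 9), f0)
})

test_that("trajectory accessors expose a tidy record", {
  tr <- integrate_replicator(baseline_params(), 0.9, 0.8, t_end = 10)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("time", "x", "y"))
  g <- glance(tr)
  expect_named(g, c("x0", "y0", "terminal", "t_final", "x_final",
                    "y_final", "clip_max"))
  grid <- basin_grid(baseline_params(), grid_n = 3, t_end = 20)
  expect_equal(nrow(grid), 9L)
  expect_named(grid, c("x0", "y0", "terminal", "x_final", "y_final"))
})
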