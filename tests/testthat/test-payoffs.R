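cell <- function(tb, a, b, who) {
  tb[tb$strategy_A == a & tb$strategy_B == b, ][[paste0("payoff_", who)]]
}

test_that("baseline payoff table matches hand-computed cell values", {
  tb <- payoff_table(baseline_params())
  # A: 0.25 * (500*20 + 0.4*800*20) + 800*2 - 800*5 etc.
  expect_equal(cell(tb, "cooperate", "cooperate", "A"), 1700)
  expect_equal(cell(tb, "cooperate", "compete", "A"), -2400)
  expect_equal(cell(tb, "compete", "cooperate", "A"), 900)
  expect_equal(cell(tb, "compete", "compete", "A"), -1600)
  expect_equal(cell(tb, "cooperate", "cooperate", "B"), 3500)
  expect_equal(cell(tb, "cooperate", "compete", "B"), 3000)
  expect_equal(cell(tb, "compete", "cooperate", "B"), -1500)
  expect_equal(cell(tb, "compete", "compete", "B"), -1000)
})

test_that("degenerate parameter sets collapse the table as expected", {
  # every increment vanishes: all entries are the original revenues
  p0 <- game_params(r_A = 1, r_B = 1, beta = 0, rho_A = 0, rho_B = 0,
                    mu_A = 0, mu_B = 0, I = 0, C = 0, H = 0,
                    R_A = 10, R_B = 7)
  tb <- payoff_table(p0)
  expect_true(all(tb$payoff_A == 10))
  expect_true(all(tb$payoff_B == 7))

  # A gains through no channel: its payoff depends only on its own strategy
  p1 <- game_params(H = 0, C = 0, beta = 0, rho_A = 0, R_A = 4)
  tb1 <- payoff_table(p1)
  expect_equal(cell(tb1, "cooperate", "cooperate", "A"), 4)
  expect_equal(cell(tb1, "cooperate", "compete", "A"), 4)
  expect_equal(cell(tb1, "compete", "cooperate", "A"), 4)
  expect_equal(cell(tb1, "compete", "compete", "A"), 4)
})

test_that("structural payoff identities hold on random parameter sets", {
  for (p in random_params(25, seed = 11)) {
    q <- unclass(p)
    tb <- payoff_table(p)
    # mutual competition: original revenue minus the fine, exactly
    expect_identical(cell(tb, "compete", "compete", "A"),
                     q$R_A - q$r_A * q$H)
    expect_identical(cell(tb, "compete", "compete", "B"),
                     q$R_B - q$r_B * q$H)
    # A's gain from B's cooperation, holding A's strategy at cooperate
    expect_equal(
      cell(tb, "cooperate", "cooperate", "A") -
        cell(tb, "cooperate", "compete", "A"),
      q$rho_A * q$mu_A * (q$r_B * q$I + q$beta * q$r_A * q$I)
    )
  }
})

test_that("expected payoffs reduce correctly at degenerate mixtures", {
  p <- baseline_params()
  tb <- payoff_table(p)
  e1 <- expected_payoffs(p, x = 0.3, y = 1)
  expect_equal(e1$E_A_coop, cell(tb, "cooperate", "cooperate", "A"))
  expect_equal(e1$E_A_comp, cell(tb, "compete", "cooperate", "A"))
  e0 <- expected_payoffs(p, x = 0, y = 0)
  expect_equal(e0$E_A_avg, cell(tb, "compete", "compete", "A"))
  expect_equal(e0$E_B_avg, cell(tb, "compete", "compete", "B"))
})

test_that("average expected payoff matches its collapsed closed form", {
  withr::local_seed(201)
  # independent oracle: E_A_avg = R_A + x rA(2H-C) + y(x beta rA + rB) rhoA muA I - rA H
  for (p in random_params(25, seed = 12)) {
    q <- unclass(p)
    x <- runif(1)
    y <- runif(1)
    e <- expected_payoffs(p, x, y)
    expect_equal(
      e$E_A_avg,
      q$R_A + x * q$r_A * (2 * q$H - q$C) +
        y * (x * q$beta * q$r_A + q$r_B) * q$rho_A * q$mu_A * q$I -
        q$r_A * q$H,
      tolerance = 1e-12
    )
    expect_equal(
      e$E_B_avg,
      q$R_B + y * q$r_B * (2 * q$H - q$C) +
        x * (q$r_A + y * q$beta * q$r_B) * q$rho_B * q$mu_B * q$I -
        q$r_B * q$H,
      tolerance = 1e-12
    )
  }
})

test_that("baseline start sits exactly on the interior rest point", {
  e <- expected_payoffs(baseline_params(), 0.5, 0.5)
  expect_equal(e$E_A_coop - e$E_A_comp, 0)
  expect_equal(e$E_B_coop - e$E_B_comp, 0)
  d <- replicator_rhs(baseline_params(), 0.5, 0.5)
  expect_equal(d$dx_dt, 0)
  expect_equal(d$dy_dt, 0)
})

test_that("boundaries of the unit square are invariant", {
  withr::local_seed(202)
  for (p in random_params(20, seed = 13)) {
    y <- runif(3)
    expect_true(all(replicator_rhs(p, 0, y)$dx_dt == 0))
    expect_true(all(replicator_rhs(p, 1, y)$dx_dt == 0))
    x <- runif(3)
    expect_true(all(replicator_rhs(p, x, 0)$dy_dt == 0))
    expect_true(all(replicator_rhs(p, x, 1)$dy_dt == 0))
  }
})

test_that("closed-form rhs agrees with the payoff-expectation route", {
  withr::local_seed(203)
  for (p in random_params(50, seed = 14)) {
    x <- runif(4)
    y <- runif(4)
    d <- replicator_rhs(p, x, y)
    e <- expected_payoffs(p, x, y)
    expect_equal(d$dx_dt, x * (e$E_A_coop - e$E_A_avg), tolerance = 1e-12)
    expect_equal(d$dy_dt, y * (e$E_B_coop - e$E_B_avg), tolerance = 1e-12)
  }
})

test_that("interior flow follows the sign of the payoff gap", {
  withr::local_seed(204)
  for (p in random_params(20, seed = 15)) {
    x <- runif(5, 0.01, 0.99)
    y <- runif(5, 0.01, 0.99)
    d <- replicator_rhs(p, x, y)
    e <- expected_payoffs(p, x, y)
    expect_identical(sign(d$dx_dt), sign(e$E_A_coop - e$E_A_comp))
    expect_identical(sign(d$dy_dt), sign(e$E_B_coop - e$E_B_comp))
  }
})

test_that("the dynamics are invariant to the original revenues", {
  withr::local_seed(205)
  for (p in random_params(10, seed = 16)) {
    x <- runif(3)
    y <- runif(3)
    base <- replicator_rhs(p, x, y)
    shifted <- replicator_rhs(set_params(p, R_A = 1e6, R_B = 3e5), x, y)
    expect_identical(base$dx_dt, shifted$dx_dt)
    expect_identical(base$dy_dt, shifted$dy_dt)
  }
})

test_that("swapping player labels swaps the two replicator components", {
  withr::local_seed(206)
  for (p in random_params(15, seed = 17)) {
    x <- runif(1)
    y <- runif(1)
    d <- replicator_rhs(p, x, y)
    ds <- replicator_rhs(swap_players(p), y, x)
    expect_equal(ds$dx_dt, d$dy_dt, tolerance = 1e-12)
    expect_equal(ds$dy_dt, d$dx_dt, tolerance = 1e-12)
  }
})

test_that("invalid states are rejected with a domain error", {
  p <- baseline_params()
  expect_error(replicator_rhs(p, -0.1, 0.5), "x must lie in")
  expect_error(replicator_rhs(p, 0.5, 1.1), "y must lie in")
  expect_error(expected_payoffs(p, NA, 0.5), "finite")
})
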