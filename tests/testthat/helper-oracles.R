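# Shared oracles and generators for the suite.

# Unconstrained random parameter sets (no regime restriction), seeded.
random_params <- function(n, seed = 2024) {
  rg <- default_ranges()
  rg$R_A <- c(0, 500)
  rg$R_B <- c(0, 500)
  ehrgame:::with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      do.call(game_params, lapply(rg, function(r) runif(1, r[1], r[2])))
    })
  })
}

# Regime-constrained sets as a list of game_params.
regime_params <- function(n, regime, seed = 99) {
  draws <- sample_scenarios(n, regime = regime, seed = seed)
  lapply(seq_len(nrow(draws)), function(i) as_game_params(draws[i, ]))
}

# Central finite-difference Jacobian of the replicator rhs at (x, y).
fd_jacobian <- function(params, x, y, h = 1e-6) {
  f <- function(x, y) {
    d <- replicator_rhs(params, x, y)
    c(d$dx_dt, d$dy_dt)
  }
  cbind(
    (f(x + h, y) - f(x - h, y)) / (2 * h),
    (f(x, y + h) - f(x, y - h)) / (2 * h)
  )
}

# Central finite difference of the basin area w.r.t. one parameter.
fd_basin_sens <- function(params, which, h = NULL) {
  v <- unclass(params)[[which]]
  if (is.null(h)) h <- 1e-6 * max(1, abs(v))
  perturb <- function(delta) {
    do.call(set_params, c(list(params), stats::setNames(list(v + delta), which)))
  }
  (basin_area(perturb(h))$area - basin_area(perturb(-h))$area) / (2 * h)
}

# Swap all A-subscripted and B-subscripted parameters.
swap_players <- function(params) {
  p <- unclass(params)
  game_params(
    r_A = p$r_B, r_B = p$r_A, beta = p$beta,
    rho_A = p$rho_B, rho_B = p$rho_A,
    mu_A = p$mu_B, mu_B = p$mu_A,
    I = p$I, C = p$C, H = p$H, R_A = p$R_B, R_B = p$R_A
  )
}
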