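#' Pure-strategy payoff table
#'
#' Computes the four pure-strategy payoff pairs of the co-opetition game.
#' When both hospitals cooperate each earns its original revenue plus the
#' value-added benefit of using the partner's records and the synergy term,
#' plus the unit-resource subsidy, minus the integration cost. A hospital
#' that competes while the partner cooperates free-rides on the shared
#' records but is fined `H` per record-unit; mutual competition leaves each
#' with its original revenue minus the fine.
#'
#' @param params a [game_params()] object.
#' @return A four-row tibble with columns `strategy_A`, `strategy_B` (each
#'   `"cooperate"` or `"compete"`), `payoff_A`, `payoff_B`.
#' @examples
#' payoff_table(baseline_params())
#' @export
payoff_table <- function(params) {
  stopifnot(inherits(params, "game_params"))
  p <- unclass(params)
  cells <- payoff_cells(p)
  tibble::tibble(
    strategy_A = c("cooperate", "cooperate", "compete", "compete"),
    strategy_B = c("cooperate", "compete", "cooperate", "compete"),
    payoff_A = c(cells$cc_A, cells$cd_A, cells$dc_A, cells$dd_A),
    payoff_B = c(cells$cc_B, cells$cd_B, cells$dc_B, cells$dd_B)
  )
}

# The eight cells as named scalars; cd = A cooperates / B competes,
# dc = A competes / B cooperates.
payoff_cells <- function(p) {
  list(
    cc_A = p$R_A + p$rho_A * p$mu_A * (p$r_B * p$I + p$beta * p$r_A * p$I) +
      p$r_A * p$H - p$r_A * p$C,
    cd_A = p$R_A + p$r_A * p$H - p$r_A * p$C,
    dc_A = p$R_A + p$rho_A * p$mu_A * p$r_B * p$I - p$r_A * p$H,
    dd_A = p$R_A - p$r_A * p$H,
    cc_B = p$R_B + p$rho_B * p$mu_B * (p$r_A * p$I + p$beta * p$r_B * p$I) +
      p$r_B * p$H - p$r_B * p$C,
    cd_B = p$R_B + p$rho_B * p$mu_B * p$r_A * p$I - p$r_B * p$H,
    dc_B = p$R_B + p$r_B * p$H - p$r_B * p$C,
    dd_B = p$R_B - p$r_B * p$H
  )
}

#' Expected payoffs under mixed strategies
#'
#' Given cooperation probabilities `x` (hospital A) and `y` (hospital B),
#' computes each hospital's expected payoff from cooperating, from
#' competing, and on average, by expectation over the four pure profiles of
#' [payoff_table()].
#'
#' @param params a [game_params()] object.
#' @param x,y cooperation probabilities in \[0, 1\]; vectors are recycled to
#'   a common length.
#' @return A tibble with one row per (x, y) pair and columns `x`, `y`,
#'   `E_A_coop`, `E_A_comp`, `E_A_avg`, `E_B_coop`, `E_B_comp`, `E_B_avg`.
#' @examples
#' expected_payoffs(baseline_params(), x = 0.5, y = 0.5)
#' @export
expected_payoffs <- function(params, x, y) {
  stopifnot(inherits(params, "game_params"))
  s <- check_state(x, y)
  cells <- payoff_cells(unclass(params))
  E_A_coop <- s$y * cells$cc_A + (1 - s$y) * cells$cd_A
  E_A_comp <- s$y * cells$dc_A + (1 - s$y) * cells$dd_A
  E_B_coop <- s$x * cells$cc_B + (1 - s$x) * cells$dc_B
  E_B_comp <- s$x * cells$cd_B + (1 - s$x) * cells$dd_B
  tibble::tibble(
    x = s$x, y = s$y,
    E_A_coop = E_A_coop,
    E_A_comp = E_A_comp,
    E_A_avg = s$x * E_A_coop + (1 - s$x) * E_A_comp,
    E_B_coop = E_B_coop,
    E_B_comp = E_B_comp,
    E_B_avg = s$y * E_B_coop + (1 - s$y) * E_B_comp
  )
}

#' Replicator right-hand side
#'
#' Evaluates the two-population replicator dynamics in closed form:
#' \deqn{dx/dt = x(1-x)\,[r_A(2H - C) + y\,\beta \rho_A \mu_A r_A I]}
#' \deqn{dy/dt = y(1-y)\,[r_B(2H - C) + x\,\beta \rho_B \mu_B r_B I]}
#' A strategy's share grows in proportion to its payoff advantage over the
#' population average, so these brackets equal the cooperate-minus-compete
#' expected payoff gaps of [expected_payoffs()]; the original revenues
#' `R_A`, `R_B` cancel and never enter.
#'
#' @inheritParams expected_payoffs
#' @return A tibble with columns `x`, `y`, `dx_dt`, `dy_dt`.
#' @examples
#' replicator_rhs(baseline_params(), x = 0.5, y = 0.5)  # rest point
#' @export
replicator_rhs <- function(params, x, y) {
  stopifnot(inherits(params, "game_params"))
  s <- check_state(x, y)
  d <- rhs_raw(unclass(params), s$x, s$y)
  tibble::tibble(x = s$x, y = s$y, dx_dt = d$dx, dy_dt = d$dy)
}

# Bare numeric version used by the ODE solver and equilibrium search;
# no validation, no tibble overhead.
rhs_raw <- function(p, x, y) {
  bx <- p$r_A * (2 * p$H - p$C) + y * p$beta * p$rho_A * p$mu_A * p$r_A * p$I
  by <- p$r_B * (2 * p$H - p$C) + x * p$beta * p$rho_B * p$mu_B * p$r_B * p$I
  list(dx = x * (1 - x) * bx, dy = y * (1 - y) * by)
}

# Characteristic payoff magnitude, used to scale zero-tolerances.
payoff_scale <- function(p) {
  max(1, p$r_A, p$r_B) *
    max(1, abs(2 * p$H - p$C) + p$beta * p$I)
}
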