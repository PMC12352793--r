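#' Integrate the replicator dynamics
#'
#' Numerically integrates the two-population replicator system from an
#' initial pair of cooperation probabilities using an adaptive solver
#' (`deSolve::lsodar`), stopping early once the system is quiescent
#' (`max(|dx/dt|, |dy/dt|) < stop_tol`). The unit square is invariant under
#' the exact flow (both boundaries are rest lines), so states are clipped
#' to \[0, 1\]^2 after each output step only to absorb solver round-off;
#' the largest clip applied is recorded and must stay below the solver
#' tolerance.
#'
#' @param params a [game_params()] object.
#' @param x0,y0 initial cooperation probabilities in \[0, 1\].
#' @param t_end integration horizon (time units of the replicator clock).
#' @param rtol,atol relative / absolute solver tolerances.
#' @param n_out number of output times (evenly spaced on \[0, t_end\]).
#' @param stop_tol quiescence threshold on `max(|dx/dt|, |dy/dt|)`.
#' @return An `ehr_trajectory`: a tibble with columns `time`, `x`, `y` and
#'   attributes `terminal` (one of `"to_OO"`, `"to_KK"`, `"to_FG_corner"`,
#'   `"at_rest"`, `"nonconverged"`), `x0`, `y0`, `clip_max`, `params`.
#'   On solver failure the partial trajectory is returned with terminal
#'   `"nonconverged"` and attribute `solver_error` holding the message.
#' @examples
#' tr <- integrate_replicator(baseline_params(), 0.9, 0.9)
#' glance(tr)  # converges to mutual cooperation
#' @export
integrate_replicator <- function(params, x0 = 0.5, y0 = 0.5,
                                 t_end = 50, rtol = 1e-8, atol = 1e-10,
                                 n_out = 201, stop_tol = 1e-10) {
  stopifnot(inherits(params, "game_params"), t_end > 0, n_out >= 2)
  check_state(x0, y0)
  p <- unclass(params)

  d0 <- rhs_raw(p, x0, y0)
  if (max(abs(d0$dx), abs(d0$dy)) < stop_tol) {
    # already at (numerical) rest: stationary trajectory
    tb <- tibble::tibble(time = c(0, t_end), x = x0, y = y0)
    return(new_trajectory(tb, params, x0, y0, terminal = "at_rest",
                          clip_max = 0))
  }

  func <- function(t, state, parms) {
    s <- pmin(pmax(state, 0), 1)
    d <- rhs_raw(p, s[1], s[2])
    list(c(d$dx, d$dy))
  }
  rootfun <- function(t, state, parms) {
    d <- rhs_raw(p, state[1], state[2])
    max(abs(d$dx), abs(d$dy)) - stop_tol
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- tryCatch(
    deSolve::lsodar(y = c(x = x0, y = y0), times = times, func = func,
                    rootfunc = rootfun, rtol = rtol, atol = atol),
    error = function(e) e
  )
  if (inherits(sol, "error")) {
    tb <- tibble::tibble(time = 0, x = x0, y = y0)
    out <- new_trajectory(tb, params, x0, y0, terminal = "nonconverged",
                          clip_max = 0)
    attr(out, "solver_error") <- conditionMessage(sol)
    return(out)
  }
  m <- unclass(sol)
  xs <- m[, "x"]
  ys <- m[, "y"]
  clip_max <- max(0, -min(xs, ys), max(xs, ys) - 1)
  xs <- pmin(pmax(xs, 0), 1)
  ys <- pmin(pmax(ys, 0), 1)
  tb <- tibble::tibble(time = m[, "time"], x = xs, y = ys)
  terminal <- classify_terminal(p, x0, y0,
                                xs[length(xs)], ys[length(ys)], stop_tol)
  new_trajectory(tb, params, x0, y0, terminal = terminal, clip_max = clip_max)
}

# Terminal state against corners with absolute tolerance 1e-4.
classify_terminal <- function(p, x0, y0, xf, yf, stop_tol, tol = 1e-4) {
  moved <- max(abs(xf - x0), abs(yf - y0))
  d0 <- rhs_raw(p, x0, y0)
  if (moved < tol && max(abs(d0$dx), abs(d0$dy)) < 1e-6 * payoff_scale(p)) {
    return("at_rest")
  }
  if (max(abs(xf - 1), abs(yf - 1)) < tol) return("to_KK")
  if (max(abs(xf), abs(yf)) < tol) return("to_OO")
  if ((abs(xf) < tol && abs(yf - 1) < tol) ||
      (abs(xf - 1) < tol && abs(yf) < tol)) {
    return("to_FG_corner")
  }
  df <- rhs_raw(p, xf, yf)
  if (max(abs(df$dx), abs(df$dy)) < 10 * stop_tol) return("at_rest")
  "nonconverged"
}

new_trajectory <- function(tb, params, x0, y0, terminal, clip_max) {
  structure(
    tb,
    class = c("ehr_trajectory", class(tb)),
    params = params, x0 = x0, y0 = y0,
    terminal = terminal, clip_max = clip_max
  )
}

#' @export
print.ehr_trajectory <- function(x, ...) {
  cat("<ehr_trajectory> start (", attr(x, "x0"), ", ", attr(x, "y0"),
      ")  terminal: ", attr(x, "terminal"), "\n", sep = "")
  NextMethod()
}

#' One-row summary of a trajectory
#'
#' @param x an `ehr_trajectory`.
#' @param ... unused.
#' @return A one-row tibble: `x0`, `y0`, `terminal`, `t_final`, `x_final`,
#'   `y_final`, `clip_max`.
#' @export
glance.ehr_trajectory <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    x0 = attr(x, "x0"), y0 = attr(x, "y0"),
    terminal = attr(x, "terminal"),
    t_final = x$time[n], x_final = x$x[n], y_final = x$y[n],
    clip_max = attr(x, "clip_max")
  )
}

#' @export
tidy.ehr_trajectory <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("time", "x", "y")])
}

#' Single-parameter sweep of terminal outcomes
#'
#' Re-integrates the system from a fixed initial state for each value of
#' one parameter, all others held fixed — the numerical sweep experiment
#' behind the influence-effect analysis. The joint names `"rho"` and
#' `"mu"` vary both hospitals together (the default experimental design);
#' per-player names (`"rho_A"` etc.) are also accepted.
#'
#' @param params a [game_params()] object (values for the swept parameter
#'   are overridden per run).
#' @param parameter one of `"beta"`, `"rho"`, `"mu"`, `"C"`, `"I"`, `"H"`,
#'   `"rho_A"`, `"rho_B"`, `"mu_A"`, `"mu_B"`.
#' @param values non-empty numeric grid of parameter values.
#' @param x0,y0 initial state, default (0.5, 0.5).
#' @inheritParams integrate_replicator
#' @return An `ehr_sweep` tibble: `parameter`, `value`, `terminal`,
#'   `x_final`, `y_final`, `t_final`. Attribute `flip_interval` holds
#'   `c(lo, hi)` bracketing the value at which the terminal outcome flips
#'   between all-compete and all-cooperate (ordered by increasing value;
#'   `NULL` when no flip occurs).
#' @examples
#' sw <- sweep_parameter(baseline_params(), "beta", seq(0.1, 0.9, by = 0.1))
#' attr(sw, "flip_interval")  # brackets beta = 0.4
#' @export
sweep_parameter <- function(params, parameter, values,
                            x0 = 0.5, y0 = 0.5, t_end = 50, rtol = 1e-8) {
  stopifnot(inherits(params, "game_params"))
  allowed <- c("beta", "rho", "mu", "C", "I", "H",
               "rho_A", "rho_B", "mu_A", "mu_B")
  if (length(parameter) != 1L || !parameter %in% allowed) {
    stop("unknown sweep parameter '", parameter, "' (supported: ",
         paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  if (length(values) == 0) stop("'values' must be non-empty", call. = FALSE)

  apply_value <- function(v) {
    switch(parameter,
      rho = set_params(params, rho_A = v, rho_B = v),
      mu = set_params(params, mu_A = v, mu_B = v),
      do.call(set_params,
              c(list(params), rlang::set_names(list(v), parameter)))
    )
  }
  rows <- purrr::map(values, function(v) {
    tr <- integrate_replicator(apply_value(v), x0 = x0, y0 = y0,
                               t_end = t_end, rtol = rtol, n_out = 2)
    g <- glance(tr)
    tibble::tibble(parameter = parameter, value = v,
                   terminal = g$terminal, x_final = g$x_final,
                   y_final = g$y_final, t_final = g$t_final)
  })
  out <- dplyr::bind_rows(rows)
  ord <- out[order(out$value), ]
  oo <- ord$value[ord$terminal == "to_OO"]
  kk <- ord$value[ord$terminal == "to_KK"]
  flip <- NULL
  if (length(oo) > 0 && length(kk) > 0) {
    if (max(oo) < min(kk)) flip <- c(max(oo), min(kk))
    else if (max(kk) < min(oo)) flip <- c(max(kk), min(oo))
  }
  structure(out, class = c("ehr_sweep", class(out)),
            flip_interval = flip, x0 = x0, y0 = y0)
}

#' Empirical basin of attraction on a lattice of initial states
#'
#' Integrates the system from every point of a `grid_n` x `grid_n` lattice
#' of strictly interior initial states (at coordinates `i / (grid_n + 1)`)
#' and records each terminal outcome. The fraction converging to mutual
#' cooperation is the numerical counterpart of the analytic area statistic
#' [basin_area()]; the two generally differ because the true separatrix is
#' curved, but they respond in the same direction to any single-parameter
#' change.
#'
#' @param params a [game_params()] object.
#' @param grid_n lattice resolution per axis, >= 2.
#' @inheritParams integrate_replicator
#' @return `basin_grid()` returns an `ehr_basin_grid` tibble with columns
#'   `x0`, `y0`, `terminal`, `x_final`, `y_final`;
#'   `empirical_basin_fraction()` returns the scalar fraction of lattice
#'   starts with terminal `"to_KK"`.
#' @examples
#' empirical_basin_fraction(baseline_params(), grid_n = 7)
#' @export
basin_grid <- function(params, grid_n = 21, t_end = 50, rtol = 1e-8) {
  stopifnot(inherits(params, "game_params"), grid_n >= 2)
  coords <- seq_len(grid_n) / (grid_n + 1)
  grid <- tidyr::expand_grid(x0 = coords, y0 = coords)
  rows <- purrr::pmap(grid, function(x0, y0) {
    glance(integrate_replicator(params, x0 = x0, y0 = y0,
                                t_end = t_end, rtol = rtol, n_out = 2))
  })
  out <- dplyr::bind_rows(rows)[, c("x0", "y0", "terminal",
                                    "x_final", "y_final")]
  structure(out, class = c("ehr_basin_grid", class(out)),
            grid_n = grid_n, params = params)
}

#' @rdname basin_grid
#' @export
empirical_basin_fraction <- function(params, grid_n = 21, t_end = 50,
                                     rtol = 1e-8) {
  g <- basin_grid(params, grid_n = grid_n, t_end = t_end, rtol = rtol)
  mean(g$terminal == "to_KK")
}
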