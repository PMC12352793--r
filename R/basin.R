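#' Interior saddle point of the replicator system
#'
#' The interior rest point sits at
#' `x* = (C - 2H) / (beta * rho_B * mu_B * I)`,
#' `y* = (C - 2H) / (beta * rho_A * mu_A * I)` (cross-subscripted: A's
#' willingness and ability set the threshold on B's axis and vice versa).
#' The point is a genuine interior saddle only when both coordinates lie
#' strictly inside (0, 1); otherwise the formula value (when computable) is
#' still reported with `valid = FALSE` and a reason.
#'
#' @param params a [game_params()] object.
#' @return A one-row tibble: `x_star`, `y_star` (NA when a denominator is
#'   zero), `valid`, `reason` (NA when valid).
#' @examples
#' saddle_point(baseline_params())  # (0.5, 0.5)
#' @export
saddle_point <- function(params) {
  stopifnot(inherits(params, "game_params"))
  p <- unclass(params)
  k <- p$C - 2 * p$H
  dB <- p$beta * p$rho_B * p$mu_B * p$I
  dA <- p$beta * p$rho_A * p$mu_A * p$I
  if (dB == 0 || dA == 0) {
    return(tibble::tibble(
      x_star = NA_real_, y_star = NA_real_, valid = FALSE,
      reason = "degenerate denominator: beta * rho * mu * I is zero"
    ))
  }
  x_star <- k / dB
  y_star <- k / dA
  eps <- 1e-9
  inside <- x_star >= eps && x_star <= 1 - eps &&
    y_star >= eps && y_star <= 1 - eps
  reason <- if (inside) {
    NA_character_
  } else if (k < 0) {
    "2H > C: interior point has negative coordinates"
  } else if (k == 0) {
    "2H = C: interior point collapses onto the origin"
  } else {
    "synergy condition fails: a coordinate is outside (0, 1)"
  }
  tibble::tibble(x_star = x_star, y_star = y_star, valid = inside,
                 reason = reason)
}

#' Basin-of-cooperation area statistic
#'
#' Area of the straight-edged quadrilateral with vertices F(0,1), T, G(1,0)
#' and K(1,1):
#' \deqn{S_{FTGK} = 1 - \tfrac{1}{2}(x^* + y^*)}
#' In the bistable regime it is the analytic proxy for the probability that
#' the system evolves to mutual cooperation: initial states above the
#' polyline F-T-G converge to K(1,1). The true basin boundary is the
#' saddle's stable manifold, which is generally curved, so the
#' quadrilateral is an approximation (see
#' [empirical_basin_fraction()] for the numerical counterpart).
#'
#' @param params a [game_params()] object.
#' @return A one-row tibble: `x_star`, `y_star`, `area`, `valid`,
#'   `boundary` (`TRUE` exactly at 2H = C, where the area degenerates to 1
#'   with `valid = FALSE`).
#' @examples
#' basin_area(baseline_params())  # area 0.5
#' @export
basin_area <- function(params) {
  stopifnot(inherits(params, "game_params"))
  p <- unclass(params)
  sp <- saddle_point(params)
  boundary <- (p$C - 2 * p$H) == 0 && !is.na(sp$x_star)
  area <- if (!is.na(sp$x_star)) 1 - (sp$x_star + sp$y_star) / 2 else NA_real_
  tibble::tibble(
    x_star = sp$x_star, y_star = sp$y_star,
    area = area, valid = sp$valid, boundary = boundary
  )
}

sensitivity_names <- function() {
  c("beta", "C", "H", "I", "rho_A", "rho_B", "mu_A", "mu_B")
}

# Closed-form partial derivative of S_FTGK for a single parameter name.
sensitivity_one <- function(p, which) {
  k <- p$C - 2 * p$H
  dA <- p$beta * p$rho_A * p$mu_A * p$I   # sets y*
  dB <- p$beta * p$rho_B * p$mu_B * p$I   # sets x*
  switch(which,
    beta = (k / 2) * (1 / (p$beta * dB) + 1 / (p$beta * dA)),
    C = -(1 / 2) * (1 / dB + 1 / dA),
    H = 1 / dB + 1 / dA,
    I = (k / 2) * (1 / (p$I * dB) + 1 / (p$I * dA)),
    rho_A = (k / 2) / (p$rho_A * dA),
    rho_B = (k / 2) / (p$rho_B * dB),
    mu_A = (k / 2) / (p$mu_A * dA),
    mu_B = (k / 2) / (p$mu_B * dB)
  )
}

#' Closed-form sensitivities of the basin area
#'
#' Partial derivatives of `S_FTGK` with respect to the parameters that move
#' the saddle. In the bistable regime the area is strictly increasing in
#' the complementarity `beta`, the willingness `rho_i`, the ability
#' `mu_i`, the unit revenue `I` and the reward/punishment `H`, and strictly
#' decreasing in the unit cost `C`; original revenues `R_i` and stocks
#' `r_i` do not appear at all. For instance
#' \deqn{\partial S/\partial H = \frac{1}{\beta \rho_B \mu_B I} +
#'       \frac{1}{\beta \rho_A \mu_A I} > 0, \qquad
#'       \partial S/\partial C = -\tfrac{1}{2}\,\partial S/\partial H < 0.}
#'
#' @param params a [game_params()] object; the interior saddle must exist
#'   (regime `"cost_dominant_bistable"`).
#' @param which parameter names, a subset of
#'   `c("beta", "C", "H", "I", "rho_A", "rho_B", "mu_A", "mu_B")`; default
#'   all eight.
#' @return A tibble with columns `parameter` and `derivative`.
#' @examples
#' basin_sensitivity(baseline_params(), "H")  # 1.0
#' basin_sensitivity(baseline_params())
#' @export
basin_sensitivity <- function(params, which = sensitivity_names()) {
  stopifnot(inherits(params, "game_params"))
  bad <- setdiff(which, sensitivity_names())
  if (length(bad) > 0) {
    stop("sensitivity not defined for parameter(s): ",
         paste(bad, collapse = ", "),
         " (supported: ", paste(sensitivity_names(), collapse = ", "), ")",
         call. = FALSE)
  }
  sp <- saddle_point(params)
  if (!isTRUE(sp$valid)) {
    stop("basin sensitivities are defined only when the interior saddle ",
         "exists (regime 'cost_dominant_bistable'); ",
         if (is.na(sp$reason)) "" else sp$reason, call. = FALSE)
  }
  p <- unclass(params)
  tibble::tibble(
    parameter = which,
    derivative = vapply(which, function(w) sensitivity_one(p, w),
                        numeric(1), USE.NAMES = FALSE)
  )
}

#' Minimum initial cooperation probabilities for convergence to cooperation
#'
#' In the bistable regime, initial states with `x > x*` and `y > y*` lie in
#' the FTGK region and evolve to mutual cooperation (1, 1); the thresholds
#' are exactly the saddle coordinates. When `2H >= C` the cooperation
#' bracket is non-negative everywhere, so any interior start converges to
#' cooperation and both thresholds are 0. When the saddle formula puts the
#' point outside the unit square for other reasons the thresholds are not
#' applicable.
#'
#' @param params a [game_params()] object.
#' @return A one-row tibble: `x_min`, `y_min`, `applicable`.
#' @examples
#' cooperation_thresholds(baseline_params())  # (0.5, 0.5)
#' @export
cooperation_thresholds <- function(params) {
  stopifnot(inherits(params, "game_params"))
  p <- unclass(params)
  if (p$C - 2 * p$H <= 0) {
    return(tibble::tibble(x_min = 0, y_min = 0, applicable = TRUE))
  }
  sp <- saddle_point(params)
  if (isTRUE(sp$valid)) {
    tibble::tibble(x_min = sp$x_star, y_min = sp$y_star, applicable = TRUE)
  } else {
    tibble::tibble(x_min = NA_real_, y_min = NA_real_, applicable = FALSE)
  }
}
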