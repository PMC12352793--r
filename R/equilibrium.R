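#' Jacobian of the replicator system
#'
#' Analytic Jacobian of the replicator right-hand side with respect to the
#' state (x, y):
#' \deqn{J_{11} = (1-2x)[r_A(2H-C) + y \beta \rho_A \mu_A r_A I], \quad
#'       J_{12} = x(1-x)\,\beta \rho_A \mu_A r_A I}
#' \deqn{J_{21} = y(1-y)\,\beta \rho_B \mu_B r_B I, \quad
#'       J_{22} = (1-2y)[r_B(2H-C) + x \beta \rho_B \mu_B r_B I]}
#'
#' @param params a [game_params()] object.
#' @param x,y a single state in \[0, 1\].
#' @return A 2x2 numeric matrix with dimnames `c("dx", "dy")` by
#'   `c("x", "y")`.
#' @examples
#' replicator_jacobian(baseline_params(), 0, 0)  # diag(-800, -500)
#' @export
replicator_jacobian <- function(params, x, y) {
  stopifnot(inherits(params, "game_params"), length(x) == 1L, length(y) == 1L)
  check_state(x, y)
  p <- unclass(params)
  gA <- p$beta * p$rho_A * p$mu_A * p$r_A * p$I
  gB <- p$beta * p$rho_B * p$mu_B * p$r_B * p$I
  bx <- p$r_A * (2 * p$H - p$C) + y * gA
  by <- p$r_B * (2 * p$H - p$C) + x * gB
  matrix(
    c((1 - 2 * x) * bx, x * (1 - x) * gA,
      y * (1 - y) * gB, (1 - 2 * y) * by),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("dx", "dy"), c("x", "y"))
  )
}

sign_label <- function(v, tol) {
  if (v > tol) "+" else if (v < -tol) "-" else "0"
}

#' Classify a rest point of the replicator system
#'
#' Evaluates the Jacobian at a rest point and classifies it by the signs of
#' its determinant and trace: an evolutionarily stable strategy (ESS) has
#' det(J) > 0 and tr(J) < 0, an unstable node has det(J) > 0 and
#' tr(J) > 0, and det(J) < 0 marks a saddle. When the trace sign alone is
#' inconclusive (det > 0, trace within tolerance of zero) the eigenvalues
#' decide; if the determinant itself vanishes to tolerance the point is
#' reported as `"degenerate"`, never silently promoted to ESS.
#'
#' @param params a [game_params()] object.
#' @param x,y coordinates of the candidate point; must satisfy
#'   `replicator_rhs` = (0, 0) within `tol_rest`.
#' @param tol_rest absolute tolerance (relative to the payoff scale) for
#'   accepting the point as a rest point.
#' @return A one-row tibble: `x`, `y`, `det`, `tr`, `det_sign`, `tr_sign`
#'   (labels in `"+"`, `"-"`, `"0"`), `classification` (one of `"ESS"`,
#'   `"unstable"`, `"saddle"`, `"degenerate"`), `interior`.
#' @examples
#' classify_equilibrium(baseline_params(), 0, 0)    # ESS
#' classify_equilibrium(baseline_params(), 0.5, 0.5) # interior saddle
#' @export
classify_equilibrium <- function(params, x, y, tol_rest = NULL) {
  stopifnot(inherits(params, "game_params"))
  p <- unclass(params)
  scale <- payoff_scale(p)
  if (is.null(tol_rest)) tol_rest <- 1e-8 * scale
  d <- rhs_raw(p, x, y)
  if (max(abs(d$dx), abs(d$dy)) > tol_rest) {
    stop("(", x, ", ", y, ") is not a rest point: |rhs| = ",
         signif(max(abs(d$dx), abs(d$dy)), 3), call. = FALSE)
  }
  J <- replicator_jacobian(params, x, y)
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  trJ <- J[1, 1] + J[2, 2]
  tol_tr <- 1e-9 * scale
  tol_det <- 1e-9 * scale^2
  det_sign <- sign_label(detJ, tol_det)
  tr_sign <- sign_label(trJ, tol_tr)
  classification <-
    if (det_sign == "-") {
      "saddle"
    } else if (det_sign == "+" && tr_sign == "-") {
      "ESS"
    } else if (det_sign == "+" && tr_sign == "+") {
      "unstable"
    } else if (det_sign == "+") {
      # tr ~ 0 with det > 0: purely imaginary pair, not hyperbolic
      "degenerate"
    } else {
      # det ~ 0: fall back on eigenvalues, which may still be conclusive
      ev <- Re(eigen(J, only.values = TRUE)$values)
      if (all(ev < -tol_tr)) "ESS"
      else if (all(ev > tol_tr)) "unstable"
      else "degenerate"
    }
  eps <- 1e-9
  tibble::tibble(
    x = x, y = y, det = detJ, tr = trJ,
    det_sign = det_sign, tr_sign = tr_sign,
    classification = classification,
    interior = (x > eps && x < 1 - eps && y > eps && y < 1 - eps)
  )
}

#' Find and classify all rest points
#'
#' The replicator system always has the four corner rest points O(0,0),
#' F(0,1), G(1,0) and K(1,1). An interior rest point
#' \deqn{T = \left(\frac{C - 2H}{\beta \rho_B \mu_B I},
#'                 \frac{C - 2H}{\beta \rho_A \mu_A I}\right)}
#' exists when both coordinates lie strictly inside (0, 1); note the
#' cross-subscripting — T's x-coordinate is set by B's parameters and its
#' y-coordinate by A's. Each reported point is verified to annihilate the
#' replicator right-hand side.
#'
#' @param params a [game_params()] object.
#' @return A tibble with one row per rest point: `point` (`"O"`, `"F"`,
#'   `"G"`, `"K"`, `"T"`), the [classify_equilibrium()] columns, and
#'   `regime` (constant, from [classify_regime()]). When T is absent the
#'   attribute `"interior_note"` states why.
#' @examples
#' find_equilibria(baseline_params())            # 5 points, 2 ESS
#' find_equilibria(set_params(baseline_params(), H = 3))  # K unique ESS
#' @export
find_equilibria <- function(params) {
  stopifnot(inherits(params, "game_params"))
  corners <- list(O = c(0, 0), F = c(0, 1), G = c(1, 0), K = c(1, 1))
  sp <- saddle_point(params)
  note <- NULL
  pts <- corners
  if (isTRUE(sp$valid)) {
    pts$T <- c(sp$x_star, sp$y_star)
  } else {
    note <- sp$reason
  }
  out <- purrr::imap(pts, function(xy, nm) {
    dplyr::mutate(
      classify_equilibrium(params, xy[1], xy[2]),
      point = nm, .before = 1
    )
  })
  out <- dplyr::bind_rows(out)
  out$regime <- classify_regime(params)
  if (!is.null(note)) attr(out, "interior_note") <- note
  out
}

#' Label the stability regime of a parameter set
#'
#' The sign of `2H - C` splits the parameter space:
#' \describe{
#'   \item{`"subsidy_dominant"`}{`2H > C`: cooperating is worthwhile even
#'     without the partner; K(1,1) is the unique ESS.}
#'   \item{`"cost_dominant_bistable"`}{`2H < C` and the synergy condition
#'     `beta * rho_i * mu_i * I > C - 2H` holds for both hospitals: O and K
#'     are both ESS, separated by an interior saddle.}
#'   \item{`"cost_dominant_invalid"`}{`2H < C` but the synergy condition
#'     fails for at least one hospital: no interior saddle inside the unit
#'     square.}
#'   \item{`"boundary"`}{`2H = C` exactly.}
#' }
#'
#' @param params a [game_params()] object.
#' @return A single string, one of the four labels above.
#' @examples
#' classify_regime(baseline_params())  # "cost_dominant_bistable"
#' @export
classify_regime <- function(params) {
  stopifnot(inherits(params, "game_params"))
  p <- unclass(params)
  k <- p$C - 2 * p$H
  if (k < 0) return("subsidy_dominant")
  if (k == 0) return("boundary")
  dA <- p$beta * p$rho_A * p$mu_A * p$I
  dB <- p$beta * p$rho_B * p$mu_B * p$I
  if (dA > k && dB > k) "cost_dominant_bistable" else "cost_dominant_invalid"
}

#' Serialize equilibrium reports
#'
#' Writes the tibble returned by [find_equilibria()] to a flat CSV (one row
#' per equilibrium) or a JSON array of objects.
#'
#' @param equilibria a tibble from [find_equilibria()].
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_equilibria <- function(equilibria, path,
                             format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(equilibria), path, row.names = FALSE)
  } else {
    jsonlite::write_json(equilibria, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
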