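#' Full analysis of one parameter set
#'
#' Composes the whole pipeline: regime label, pure-strategy payoff table,
#' all rest points with their stability classification, and — where the
#' interior saddle exists — the basin-area statistic, its eight parameter
#' sensitivities and the cooperation thresholds.
#'
#' @param x a [game_params()] object, or the path of a flat-JSON parameter
#'   file as read by [read_game_params()].
#' @param partial passed to [read_game_params()] when `x` is a path.
#' @return An `ehr_analysis` object: a list with elements `params`,
#'   `regime`, `payoffs`, `equilibria`, `basin`, `sensitivities` (`NULL`
#'   outside the bistable regime), `thresholds`. Has `print()`, [tidy()]
#'   and [glance()] methods.
#' @examples
#' rep <- analyze_game(baseline_params())
#' glance(rep)
#' @export
analyze_game <- function(x, partial = FALSE) {
  params <- if (inherits(x, "game_params")) {
    x
  } else if (is.character(x) && length(x) == 1L) {
    read_game_params(x, partial = partial)
  } else {
    stop("'x' must be a game_params object or a parameter file path",
         call. = FALSE)
  }
  regime <- classify_regime(params)
  basin <- basin_area(params)
  sens <- if (isTRUE(basin$valid)) basin_sensitivity(params) else NULL
  structure(
    list(
      params = params,
      regime = regime,
      payoffs = payoff_table(params),
      equilibria = find_equilibria(params),
      basin = basin,
      sensitivities = sens,
      thresholds = cooperation_thresholds(params)
    ),
    class = "ehr_analysis"
  )
}

#' @export
print.ehr_analysis <- function(x, ...) {
  cat("== EHR co-opetition game analysis ==\n")
  cat("regime:", x$regime, "\n\n")
  cat("payoff table:\n")
  print(as.data.frame(x$payoffs), row.names = FALSE)
  cat("\nequilibria:\n")
  eq <- x$equilibria
  print(as.data.frame(eq[, c("point", "x", "y", "det_sign", "tr_sign",
                             "classification")]),
        row.names = FALSE)
  if (!is.null(attr(eq, "interior_note"))) {
    cat("  (interior point absent: ", attr(eq, "interior_note"), ")\n",
        sep = "")
  }
  cat("\nbasin of cooperation:\n")
  if (isTRUE(x$basin$valid)) {
    cat(sprintf("  saddle (x*, y*) = (%.4g, %.4g), area S_FTGK = %.4g\n",
                x$basin$x_star, x$basin$y_star, x$basin$area))
    s <- x$sensitivities
    cat("  sensitivities: ",
        paste(sprintf("dS/d%s = %.4g", s$parameter, s$derivative),
              collapse = ", "), "\n")
  } else {
    cat("  not applicable in regime '", x$regime, "'\n", sep = "")
  }
  th <- x$thresholds
  if (isTRUE(th$applicable)) {
    cat(sprintf("  cooperation thresholds: x > %.4g, y > %.4g\n",
                th$x_min, th$y_min))
  }
  invisible(x)
}

#' Tidy an analysis report
#'
#' @param x an `ehr_analysis` object.
#' @param ... unused.
#' @return The equilibrium tibble of the report (one row per rest point).
#' @export
tidy.ehr_analysis <- function(x, ...) x$equilibria

#' One-row summary of an analysis report
#'
#' @param x an `ehr_analysis` object.
#' @param ... unused.
#' @return A one-row tibble: `regime`, `n_equilibria`, `n_ess`, `x_star`,
#'   `y_star`, `area`, `basin_valid`.
#' @export
glance.ehr_analysis <- function(x, ...) {
  tibble::tibble(
    regime = x$regime,
    n_equilibria = nrow(x$equilibria),
    n_ess = sum(x$equilibria$classification == "ESS"),
    x_star = x$basin$x_star,
    y_star = x$basin$y_star,
    area = x$basin$area,
    basin_valid = x$basin$valid
  )
}

#' Serialize an analysis report to JSON
#'
#' @param report an `ehr_analysis` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_analysis <- function(report, path) {
  stopifnot(inherits(report, "ehr_analysis"))
  obj <- list(
    params = unclass(report$params),
    regime = report$regime,
    payoffs = report$payoffs,
    equilibria = report$equilibria,
    basin = report$basin,
    sensitivities = report$sensitivities,
    thresholds = report$thresholds
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
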