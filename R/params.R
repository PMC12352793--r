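#' Construct a game parameter set
#'
#' Bundles and validates the full parameter vector of the hospital
#' co-opetition game. The defaults are the baseline scenario used throughout
#' the numerical experiments: two hospitals with EHR stocks of 800 and 500
#' record-units, moderate resource complementarity, and a reward/punishment
#' intensity below half the unit sharing cost (the bistable regime).
#'
#' Parameter roles:
#' \describe{
#'   \item{r_A, r_B}{stock of shareable EHR resources held by the superior
#'     (A) and subordinate (B) hospital, record-units, strictly positive.}
#'   \item{beta}{complementarity of the two EHR stocks (non-overlap of
#'     content), dimensionless, >= 0.}
#'   \item{rho_A, rho_B}{willingness to use the partner's EHR, in \[0, 1\].}
#'   \item{mu_A, mu_B}{ability to use the partner's EHR, in \[0, 1\].}
#'   \item{I}{average revenue per unit EHR resource, currency per
#'     record-unit.}
#'   \item{C}{average input cost per unit EHR resource when cooperating.}
#'   \item{H}{government reward (when cooperating) or penalty (when
#'     competing) per unit EHR resource.}
#'   \item{R_A, R_B}{original revenue earned before any integration. These
#'     cancel from the replicator dynamics and default to 0.}
#' }
#'
#' Currency units are abstract; the model is jointly scale-covariant in
#' (R, I, C, H), so no normalisation is applied.
#'
#' @param r_A,r_B EHR stocks, > 0.
#' @param beta complementarity, >= 0 (no upper bound is imposed).
#' @param rho_A,rho_B willingness to use EHR, in \[0, 1\].
#' @param mu_A,mu_B ability to use EHR, in \[0, 1\].
#' @param I,C,H unit revenue, unit cost, unit reward/punishment, all >= 0.
#' @param R_A,R_B original revenues, >= 0.
#'
#' @return An object of class `game_params`: a validated named list of the
#'   twelve scalars above.
#' @examples
#' p <- game_params()            # baseline scenario
#' p2 <- game_params(H = 3)      # subsidy-dominant variant (2H > C)
#' @seealso [baseline_params()], [set_params()], [classify_regime()]
#' @export
game_params <- function(r_A = 800, r_B = 500, beta = 0.4,
                        rho_A = 0.5, rho_B = 0.5,
                        mu_A = 0.5, mu_B = 0.5,
                        I = 20, C = 5, H = 2,
                        R_A = 0, R_B = 0) {
  p <- list(
    r_A = r_A, r_B = r_B, beta = beta,
    rho_A = rho_A, rho_B = rho_B, mu_A = mu_A, mu_B = mu_B,
    I = I, C = C, H = H, R_A = R_A, R_B = R_B
  )
  p <- lapply(p, as.double)
  validate_game_params(p)
  structure(p, class = "game_params")
}

#' The baseline parameter set
#'
#' Returns the parameter values of the reference simulation scenario:
#' `r_A = 800`, `r_B = 500`, `beta = 0.4`, `rho_A = rho_B = 0.5`,
#' `mu_A = mu_B = 0.5`, `I = 20`, `C = 5`, `H = 2` (and `R_A = R_B = 0`,
#' which do not enter the dynamics). This set lies in the cost-dominant
#' bistable regime with the interior saddle exactly at (0.5, 0.5).
#'
#' @return A `game_params` object.
#' @export
baseline_params <- function() game_params()

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params a `game_params` object.
#' @param ... named scalar replacements, e.g. `beta = 0.6`.
#' @return A `game_params` object.
#' @examples
#' set_params(baseline_params(), H = 3, C = 5)
#' @export
set_params <- function(params, ...) {
  stopifnot(inherits(params, "game_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad) > 0) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(game_params, utils::modifyList(unclass(params), repl))
}

param_names <- function() {
  c("r_A", "r_B", "beta", "rho_A", "rho_B", "mu_A", "mu_B",
    "I", "C", "H", "R_A", "R_B")
}

validate_game_params <- function(p) {
  for (nm in param_names()) {
    v <- p[[nm]]
    if (is.null(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  for (nm in c("rho_A", "rho_B", "mu_A", "mu_B")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("parameter '", nm, "' must lie in [0, 1], got ", p[[nm]],
           call. = FALSE)
    }
  }
  for (nm in c("r_A", "r_B")) {
    if (p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be > 0, got ", p[[nm]], call. = FALSE)
    }
  }
  for (nm in c("beta", "I", "C", "H", "R_A", "R_B")) {
    if (p[[nm]] < 0) {
      stop("parameter '", nm, "' must be >= 0, got ", p[[nm]], call. = FALSE)
    }
  }
  invisible(p)
}

# Shared check for strategy probabilities; vectorised, recycles x against y.
check_state <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("state probabilities must be non-empty", call. = FALSE)
  }
  n <- max(length(x), length(y))
  x <- rep_len(as.double(x), n)
  y <- rep_len(as.double(y), n)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("state probabilities must be finite", call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop("cooperation probability x must lie in [0, 1]", call. = FALSE)
  }
  if (any(y < 0 | y > 1)) {
    stop("cooperation probability y must lie in [0, 1]", call. = FALSE)
  }
  list(x = x, y = y)
}

#' @export
print.game_params <- function(x, ...) {
  cat("<game_params>\n")
  v <- unlist(unclass(x))
  cat("  EHR stocks       r_A =", v[["r_A"]], " r_B =", v[["r_B"]], "\n")
  cat("  complementarity  beta =", v[["beta"]], "\n")
  cat("  willingness      rho_A =", v[["rho_A"]], " rho_B =", v[["rho_B"]], "\n")
  cat("  ability          mu_A =", v[["mu_A"]], " mu_B =", v[["mu_B"]], "\n")
  cat("  unit rev/cost    I =", v[["I"]], " C =", v[["C"]], " H =", v[["H"]], "\n")
  cat("  original revenue R_A =", v[["R_A"]], " R_B =", v[["R_B"]], "\n")
  cat("  regime:", classify_regime(x), "\n")
  invisible(x)
}

#' @export
as.list.game_params <- function(x, ...) unclass(x)

#' Coerce a parameter set to a one-row tibble
#'
#' @param x a `game_params` object.
#' @param ... unused.
#' @return A one-row tibble with one column per parameter.
#' @export
tidy.game_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Coerce a one-row data frame (or named list) to `game_params`
#'
#' Convenience for working with scenario tables: each row of the tibble
#' returned by [sample_scenarios()] can be turned back into a parameter
#' object.
#'
#' @param x a named list, or a data frame with exactly one row, containing
#'   all twelve parameter columns.
#' @return A `game_params` object.
#' @examples
#' draws <- sample_scenarios(3, regime = "cost_dominant_bistable", seed = 1)
#' as_game_params(draws[1, ])
#' @export
as_game_params <- function(x) {
  if (inherits(x, "game_params")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      stop("as_game_params() needs exactly one row, got ", nrow(x),
           call. = FALSE)
    }
    x <- as.list(x)
  }
  do.call(game_params, x[param_names()])
}

#' Read / write parameter sets as flat JSON
#'
#' Parameter files are flat JSON objects keyed by the symbol names
#' (`r_A`, `beta`, `rho_A`, ..., `H`). Unknown keys are rejected so typos
#' fail loudly; missing keys fall back to the baseline defaults only when
#' `partial = TRUE`.
#'
#' @param path file path.
#' @param partial if `TRUE`, keys absent from the file take their
#'   [game_params()] defaults; if `FALSE` (default) all twelve keys must be
#'   present.
#' @return `read_game_params()` returns a `game_params` object;
#'   `write_game_params()` returns `path` invisibly.
#' @export
read_game_params <- function(path, partial = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop("could not parse parameter file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.list(obj) || is.null(names(obj)) || length(obj) == 0) {
    stop("parameter file '", path,
         "' must be a JSON object keyed by parameter names", call. = FALSE)
  }
  bad <- setdiff(names(obj), param_names())
  if (length(bad) > 0) {
    stop("unknown key(s) in '", path, "': ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!partial) {
    missing <- setdiff(param_names(), names(obj))
    if (length(missing) > 0) {
      stop("missing key(s) in '", path, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  do.call(game_params, obj)
}

#' @rdname read_game_params
#' @param params a `game_params` object.
#' @export
write_game_params <- function(params, path) {
  stopifnot(inherits(params, "game_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
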