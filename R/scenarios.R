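#' Default sampling ranges for scenario generation
#'
#' Uniform sampling intervals bracketing the baseline values by roughly an
#' order of magnitude: `r_i` in \[100, 1000\], `beta` in \[0.1, 0.9\],
#' `rho_i` and `mu_i` in \[0.1, 1\], `I` in \[5, 50\], `C` in \[1, 10\],
#' `H` in \[0, 5\]. Original revenues are fixed at 0 by default (they
#' cancel from the dynamics).
#'
#' @return A named list of length-2 numeric ranges, one per parameter.
#' @export
default_ranges <- function() {
  list(
    r_A = c(100, 1000), r_B = c(100, 1000),
    beta = c(0.1, 0.9),
    rho_A = c(0.1, 1), rho_B = c(0.1, 1),
    mu_A = c(0.1, 1), mu_B = c(0.1, 1),
    I = c(5, 50), C = c(1, 10), H = c(0, 5),
    R_A = c(0, 0), R_B = c(0, 0)
  )
}

#' Sample random parameter sets constrained to a stability regime
#'
#' Draws parameter sets uniformly from per-parameter ranges and keeps those
#' whose regime (see [classify_regime()]) matches the request — seeded
#' rejection sampling, so the same seed always reproduces the same draws.
#' Every accepted set satisfies the [game_params()] invariants and the
#' requested regime's defining inequalities.
#'
#' @param n number of parameter sets to return, >= 1.
#' @param regime target regime label: `"cost_dominant_bistable"`,
#'   `"subsidy_dominant"` or `"cost_dominant_invalid"`.
#' @param seed integer seed; identical seed, ranges and `n` give
#'   identical output.
#' @param ranges named list of length-2 ranges as in [default_ranges()];
#'   entries replace the defaults.
#' @param max_draws cap on total draws before declaring the regime
#'   infeasible within the ranges.
#' @return A tibble with `n` rows, one column per parameter, plus a
#'   `regime` column; attribute `"n_draws"` records how many raw draws the
#'   rejection sampler used. Rows convert back to parameter objects with
#'   [as_game_params()].
#' @examples
#' draws <- sample_scenarios(5, "cost_dominant_bistable", seed = 42)
#' classify_regime(as_game_params(draws[1, ]))
#' @export
sample_scenarios <- function(n, regime = c("cost_dominant_bistable",
                                           "subsidy_dominant",
                                           "cost_dominant_invalid"),
                             seed = 1L, ranges = list(),
                             max_draws = 10000L * n) {
  regime <- match.arg(regime)
  stopifnot(n >= 1)
  rg <- utils::modifyList(default_ranges(), ranges)
  for (nm in param_names()) {
    if (length(rg[[nm]]) != 2L || rg[[nm]][1] > rg[[nm]][2]) {
      stop("range for '", nm, "' must be c(lo, hi) with lo <= hi",
           call. = FALSE)
    }
  }

  with_local_seed(seed, {
    accepted <- vector("list", n)
    n_acc <- 0L
    n_draws <- 0L
    reject_why <- c(sign_2H_C = 0L, synergy = 0L)
    while (n_acc < n && n_draws < max_draws) {
      n_draws <- n_draws + 1L
      draw <- lapply(rg[param_names()],
                     function(r) stats::runif(1, r[1], r[2]))
      p <- do.call(game_params, draw)
      lab <- classify_regime(p)
      if (lab == regime) {
        n_acc <- n_acc + 1L
        accepted[[n_acc]] <- tidy.game_params(p)
      } else if (startsWith(lab, "cost_dominant") !=
                 startsWith(regime, "cost_dominant")) {
        reject_why[["sign_2H_C"]] <- reject_why[["sign_2H_C"]] + 1L
      } else {
        reject_why[["synergy"]] <- reject_why[["synergy"]] + 1L
      }
    }
    if (n_acc < n) {
      binding <- names(which.max(reject_why))
      msg <- switch(binding,
        sign_2H_C = "the sign constraint on 2H - C cannot be met within the H and C ranges",
        synergy = "the synergy condition beta * rho_i * mu_i * I vs C - 2H cannot be met within the ranges"
      )
      stop("regime '", regime, "' infeasible: only ", n_acc, " of ", n,
           " sets found after ", n_draws, " draws; binding constraint: ",
           msg, call. = FALSE)
    }
    out <- dplyr::bind_rows(accepted)
    out$regime <- regime
    attr(out, "n_draws") <- n_draws
    out
  })
}

# Run code with a temporary RNG state, restoring the caller's state after.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
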