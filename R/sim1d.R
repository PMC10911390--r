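#' Analytic steady states of the simple 1D force-balance model
#'
#' In the simple model each aster generates a force potential following its
#' microtubule distribution, `F(x) = F0 * exp(-x / lambda)` with `x` the
#' distance from the boundary. On the diameter `[0, 2R]`, one aster balances
#' at the center, `x = R`. For a pair, each aster pushes on the other just
#' as it pushes on a boundary: by symmetry the midplane between equal
#' asters acts as a mirror wall, so the neighbour interaction is evaluated
#' at the half-separation `(x2 - x1) / 2`. The system is solved by
#' bracketed root finding (residual forces below 1e-12) and yields
#' `x1 = R/2`, `x2 = 3R/2` -- asters spaced half the explant diameter --
#' for any `F0`, `lambda`, `R`.
#'
#' @param n_asters 1 or 2.
#' @param F0 Force amplitude. Default 1 (the steady state does not depend
#'   on it).
#' @param lambda Decay length (um). Default 15.
#' @param R Explant radius (um).
#' @return Numeric vector of steady-state positions on `[0, 2R]` (um).
#' @examples
#' simple_steady_states(2, R = 40)  # c(20, 60)
#' @export
simple_steady_states <- function(n_asters, F0 = 1, lambda = 15, R) {
  stopifnot(n_asters %in% c(1, 2), R > 0, F0 > 0, lambda > 0)
  if (n_asters == 1) return(R)
  L <- 2 * R
  # inner balance: F1(x1; x2) = F0 e^(-x1/lam) - F0 e^(-(x2-x1)/(2 lam)) = 0
  # (neighbour interaction at the midplane distance (x2 - x1)/2)
  x1_of_x2 <- function(x2) {
    stats::uniroot(function(x1)
      exp(-x1 / lambda) - exp(-(x2 - x1) / (2 * lambda)),
      lower = 1e-12 * L, upper = x2 - 1e-12 * L,
      tol = 1e-15 * L)$root
  }
  # outer: F2(x2) = -F0 e^(-(2R-x2)/lam) + F0 e^(-(x2-x1)/(2 lam)) = 0
  f2 <- function(x2) {
    x1 <- x1_of_x2(x2)
    -exp(-(L - x2) / lambda) + exp(-(x2 - x1) / (2 * lambda))
  }
  x2 <- stats::uniroot(f2, lower = L / 2 + 1e-9 * L, upper = L - 1e-9 * L,
                       tol = 1e-15 * L)$root
  x1 <- x1_of_x2(x2)
  res <- c(F0 * (exp(-x1 / lambda) - exp(-(x2 - x1) / (2 * lambda))),
           F0 * (-exp(-(L - x2) / lambda) + exp(-(x2 - x1) / (2 * lambda))))
  stopifnot(all(abs(res) < 1e-12 * F0 + 1e-12))
  c(x1, x2)
}

#' Stochastic 1D aster ensembles on a diameter
#'
#' Euler-Maruyama integration of one or two asters on `[0, 2R]` under the
#' full slip-inhibited force law. Each aster feels its nearest endpoint (the
#' 1D analogue of the mirror charge used in 2D) and, for pairs, the mutual
#' repulsion; noise is `delta_f * xi` per step with `xi` standard normal (or
#' +/-1 Bernoulli), and both endpoints reflect. Runs share a fixed horizon
#' so all final positions sit on one time grid.
#'
#' @param n_asters 1 or 2.
#' @param R Explant radius (um); the domain is `[0, 2R]`.
#' @param params An [aster_params()].
#' @param n_runs Number of independent runs.
#' @param n_steps Steps per run. Default 2.5e6 (model time 2.5e5 at
#'   `dt` = 0.1), long enough for boundary escape across the explant sizes
#'   studied.
#' @param seed Integer seed.
#' @param start Initial position(s): default 1 um from the near boundary for
#'   one aster, and 1 um either side of the midpoint for a pair.
#' @param noise `"normal"` (default) or `"bernoulli"`.
#' @return An object of class `ensemble_1d`: `finals` (tibble: `run`,
#'   `aster_id`, `position`, `boundary_distance`), `R`, `n_runs`, `summary`
#'   (tibble with mean/sd of final boundary distance).
#' @examples
#' simulate_1d_ensemble(1, R = 40, n_runs = 3, n_steps = 1e4, seed = 1)
#' @export
simulate_1d_ensemble <- function(n_asters = 1, R, params = aster_params(),
                                 n_runs = 100, n_steps = 2.5e6, seed = NULL,
                                 start = NULL,
                                 noise = c("normal", "bernoulli")) {
  stopifnot(n_asters %in% c(1, 2), R > 0, n_runs >= 1)
  noise <- match.arg(noise)
  if (is.null(start)) {
    start <- if (n_asters == 1) 1 else c(R - 1, R + 1)
  }
  stopifnot(length(start) == n_asters, all(start >= 0), all(start <= 2 * R))
  fin <- with_seed(seed, sim1d_engine(
    as.integer(n_asters), R,
    params$f0, params$f1, params$lambda_wall, params$lambda_aster,
    params$x0_wall, params$x0_aster, params$delta_f, params$gamma,
    params$dt, as.integer(n_runs), as.integer(n_steps),
    as.numeric(start), noise == "bernoulli",
    identical(params$wall_distance_mode, "image")))
  finals <- tibble(
    run = rep(seq_len(n_runs), times = n_asters),
    aster_id = rep(seq_len(n_asters), each = n_runs),
    position = as.vector(fin))
  finals$boundary_distance <- pmin(finals$position, 2 * R - finals$position)
  summary <- finals |>
    dplyr::group_by(.data$aster_id) |>
    dplyr::summarise(mean_b = mean(.data$boundary_distance),
                     sd_b = sd(.data$boundary_distance), .groups = "drop")
  structure(list(finals = finals, R = R, n_runs = n_runs, summary = summary,
                 params = params, seed = seed, n_steps = n_steps),
            class = "ensemble_1d")
}

#' @export
print.ensemble_1d <- function(x, ...) {
  cat(sprintf("<ensemble_1d> R = %g um, %d run(s), %g steps\n",
              x$R, x$n_runs, x$n_steps))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ensemble_1d <- function(x, ...) x$finals

#' @export
glance.ensemble_1d <- function(x, ...) {
  tibble(R = x$R, n_runs = x$n_runs, n_steps = x$n_steps,
         mean_b = mean(x$finals$boundary_distance),
         sd_b = sd(x$finals$boundary_distance))
}

#' Final aster position as a function of explant size
#'
#' Runs [simulate_1d_ensemble()] for each radius and tabulates the mean and
#' spread of the final boundary distance. The mean grows roughly in
#' proportion to `R` while the drift can carry the aster to the center
#' within the horizon, and saturates for larger explants.
#'
#' @param R_list Radii to sweep (um).
#' @param params An [aster_params()].
#' @param n_runs Runs per radius.
#' @param seed Base seed; radius k uses `seed + k`.
#' @param n_steps Steps per run (see [simulate_1d_ensemble()]).
#' @return A tibble with columns `R`, `mean_b`, `sd_b`, `n_runs`.
#' @export
position_vs_size_curve <- function(R_list, params = aster_params(),
                                   n_runs = 300, seed = 1, n_steps = 2.5e6) {
  purrr::map_dfr(seq_along(R_list), function(k) {
    ens <- simulate_1d_ensemble(1, R = R_list[k], params = params,
                                n_runs = n_runs, n_steps = n_steps,
                                seed = seed + k)
    tibble(R = R_list[k],
           mean_b = mean(ens$finals$boundary_distance),
           sd_b = sd(ens$finals$boundary_distance),
           n_runs = n_runs)
  })
}
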