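#' Simulate aster dynamics in a 2D disk
#'
#' Integrates the overdamped equation of motion `v = gamma * F` by the Euler
#' method for 1-8 point asters in a circular domain. Forces follow
#' [net_forces()]: mirror-charge wall repulsion, pairwise slip-inhibited
#' repulsion, and a noise force of amplitude `delta_f` along a fresh random
#' unit vector per aster per step. The run stops at `max_steps` or when every
#' aster's displacement over a trailing window stays below `steady_tol`.
#' A step that would carry an aster outside the disk is clamped 0.5 um
#' inside along the radial (counted and reported).
#'
#' @param initial Data frame with columns `x`, `y` (um), one row per aster,
#'   all strictly inside the disk. An optional `id` column labels asters.
#' @param disk An [explant_disk()]. Default radius 40 um.
#' @param params An [aster_params()].
#' @param max_steps Maximum number of Euler steps. Default 1e6.
#' @param seed Integer seed for the noise generator.
#' @param record_every Record positions every this many steps. Default 20.
#' @param steady_tol,steady_window Plateau detection: stop once every aster
#'   moved less than `steady_tol` um over the last `steady_window` steps.
#' @return An object of class `aster_sim` with elements `trajectories`
#'   (tibble: `step`, `time`, `aster_id`, `x`, `y`), `final` (tibble of final
#'   positions), `steady_state_time` (model time, or `NA` if never reached),
#'   `n_clamped`, `params`, `disk`, `seed`.
#' @examples
#' sim <- simulate_asters(data.frame(x = -39, y = 0), seed = 1,
#'                        max_steps = 2000)
#' tail(tidy(sim))
#' @export
simulate_asters <- function(initial, disk = explant_disk(40),
                            params = aster_params(), max_steps = 1e6,
                            seed = NULL, record_every = 20,
                            steady_tol = 0.015, steady_window = 10000) {
  stopifnot(is.data.frame(initial), inherits(disk, "explant_disk"),
            inherits(params, "aster_params"))
  if (!all(c("x", "y") %in% names(initial)))
    abort("`initial` must have columns `x` and `y`.")
  n <- nrow(initial)
  if (n < 1 || n > 8) abort("Between 1 and 8 asters are supported.")
  r0 <- sqrt((initial$x - disk$center[1])^2 + (initial$y - disk$center[2])^2)
  if (any(r0 >= disk$radius))
    abort("All initial positions must lie strictly inside the disk.")
  if (steady_window < 2) abort("`steady_window` must be >= 2.")
  ids <- if ("id" %in% names(initial)) initial$id else seq_len(n)

  res <- with_seed(seed, sim2d_engine(
    as.matrix(initial[, c("x", "y")]),
    disk$center[1], disk$center[2], disk$radius,
    params$f0, params$f1, params$lambda_wall, params$lambda_aster,
    params$x0_wall, params$x0_aster, params$delta_f, params$gamma,
    params$dt, as.integer(max_steps), as.integer(record_every),
    steady_tol, as.integer(steady_window),
    identical(params$wall_distance_mode, "image"), params$noise_sqrt_dt))

  traj <- tibble(
    step = as.integer(res$traj[, 1]),
    time = res$traj[, 1] * params$dt,
    aster_id = ids[res$traj[, 2]],
    x = res$traj[, 3], y = res$traj[, 4])
  fin <- tibble(aster_id = ids, x = res$final[, 1], y = res$final[, 2])
  if (res$n_clamped > 0)
    inform(sprintf("%d step(s) clamped 0.5 um inside the boundary.",
                   res$n_clamped))
  structure(
    list(trajectories = traj, final = fin,
         steady_state_time = if (res$steady_step > 0)
           res$steady_step * params$dt else NA_real_,
         n_clamped = res$n_clamped,
         params = params, disk = disk, seed = seed),
    class = "aster_sim")
}

#' @export
print.aster_sim <- function(x, ...) {
  cat(sprintf("<aster_sim> %d aster(s), R = %g um, %s\n",
              nrow(x$final), x$disk$radius,
              if (is.na(x$steady_state_time)) "steady state not reached"
              else sprintf("steady state at t = %g", x$steady_state_time)))
  print(x$final)
  invisible(x)
}

#' @describeIn simulate_asters Tidy the recorded trajectories into a tibble.
#' @param x,... An `aster_sim` object; unused extra arguments.
#' @export
tidy.aster_sim <- function(x, ...) x$trajectories

#' @describeIn simulate_asters One-row summary (n asters, steady-state time,
#'   final boundary distances).
#' @export
glance.aster_sim <- function(x, ...) {
  b <- x$disk$radius -
    sqrt((x$final$x - x$disk$center[1])^2 + (x$final$y - x$disk$center[2])^2)
  tibble(n_asters = nrow(x$final),
         radius = x$disk$radius,
         steady_state_time = x$steady_state_time,
         mean_boundary_distance = mean(b),
         n_clamped = x$n_clamped)
}

#' @export
autoplot.aster_sim <- function(object, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  edge <- tibble(x = object$disk$center[1] + object$disk$radius * cos(th),
                 y = object$disk$center[2] + object$disk$radius * sin(th))
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(.data$x, .data$y,
                               colour = factor(.data$aster_id))) +
    ggplot2::geom_path(data = edge, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = object$final, size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "aster") +
    ggplot2::theme_minimal()
}

#' Split one aster into a symmetric daughter pair
#'
#' Daughters are placed symmetrically about `position` along `orientation`,
#' `separation` um apart, emulating centrosome duplication and disengagement.
#'
#' @param position Length-2 numeric (um).
#' @param separation Daughter separation (um). Default 2.
#' @param orientation Division axis angle (radians).
#' @param disk Optional [explant_disk()]; when supplied both daughters must
#'   fall strictly inside it.
#' @return A tibble with columns `id`, `x`, `y` (two rows).
#' @examples
#' divide_aster(c(0, 0), 2, 0)
#' @export
divide_aster <- function(position, separation = 2, orientation = 0,
                         disk = NULL) {
  stopifnot(is.numeric(position), length(position) == 2,
            is.numeric(separation), separation >= 0)
  u <- c(cos(orientation), sin(orientation))
  a <- position + u * separation / 2
  b <- position - u * separation / 2
  if (!is.null(disk)) {
    for (p in list(a, b)) {
      if (sqrt(sum((p - disk$center)^2)) >= disk$radius)
        abort("A daughter aster would fall outside the disk.")
    }
  }
  tibble(id = 1:2, x = c(a[1], b[1]), y = c(a[2], b[2]))
}

#' Detect a positional steady state in a trajectory table
#'
#' Returns the first recorded index at which every aster's maximum
#' displacement over the trailing `window` samples is below `tol`.
#'
#' @param traj A tibble as in `aster_sim$trajectories` (columns `step` or
#'   `time`, `aster_id`, `x`, `y`), on a shared time grid.
#' @param tol Displacement tolerance (um).
#' @param window Number of trailing samples. Must be >= 2 and no longer than
#'   the trajectory.
#' @return The integer sample index (per aster time grid) of the first
#'   steady sample, or `NA_integer_` if never steady.
#' @export
detect_steady_state <- function(traj, tol = 0.1, window = 500) {
  stopifnot(is.data.frame(traj))
  if (window < 2) abort("`window` must be >= 2.")
  key <- if ("step" %in% names(traj)) "step" else "time"
  grid <- sort(unique(traj[[key]]))
  nt <- length(grid)
  if (window > nt) abort("`window` is longer than the trajectory.")
  wide <- traj[order(traj[[key]], traj$aster_id), ]
  ids <- unique(wide$aster_id)
  xm <- matrix(wide$x, nrow = length(ids))
  ym <- matrix(wide$y, nrow = length(ids))
  for (t in seq.int(window, nt)) {
    win <- seq.int(t - window + 1, t)
    dx <- xm[, win, drop = FALSE] - xm[, t]
    dy <- ym[, win, drop = FALSE] - ym[, t]
    if (max(sqrt(dx^2 + dy^2)) < tol) return(t)
  }
  NA_integer_
}

#' Interior-angle statistics of an aster configuration
#'
#' Orders the points along their convex hull and returns the interior angle
#' at each hull vertex, a 5-degree-binned histogram (bins centered on
#' multiples of 5 degrees, so a tight equilateral cluster peaks at 60), and
#' the histogram mode. Interior (non-hull) points contribute no angle but
#' are counted.
#'
#' @param positions Data frame with columns `x`, `y`; at least 3 points.
#' @return An object of class `angle_stats`: `angles` (degrees), `histogram`
#'   (tibble `mid`, `count`), `mode_deg`, `n_hull`, `n_interior`,
#'   `degenerate` flag.
#' @examples
#' angle_statistics(data.frame(x = c(0, 1, 0), y = c(0, 0, 1)))
#' @export
angle_statistics <- function(positions) {
  stopifnot(is.data.frame(positions), nrow(positions) >= 3)
  pts <- as.matrix(positions[, c("x", "y")])
  hull <- grDevices::chull(pts)
  degenerate <- length(hull) < 3
  if (degenerate) {
    warn("Collinear configuration: angles degenerate at {0, 180}.")
    angles <- c(0, rep(180, nrow(pts) - 2), 0)[seq_len(nrow(pts))]
  } else {
    hp <- pts[hull, , drop = FALSE]
    k <- nrow(hp)
    angles <- vapply(seq_len(k), function(i) {
      p <- hp[i, ]
      a <- hp[if (i == 1) k else i - 1, ]
      b <- hp[if (i == k) 1 else i + 1, ]
      u <- a - p; v <- b - p
      cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }, numeric(1))
  }
  hist <- angle_histogram(angles)
  structure(list(
    angles = angles,
    histogram = hist,
    mode_deg = hist$mid[which.max(hist$count)],
    n_hull = if (degenerate) NA_integer_ else length(hull),
    n_interior = if (degenerate) NA_integer_ else nrow(pts) - length(hull),
    degenerate = degenerate),
    class = "angle_stats")
}

# 5-degree bins centered on multiples of 5 (edges at 2.5, 7.5, ...)
angle_histogram <- function(angles) {
  edges <- seq(-2.5, 182.5, by = 5)
  mids <- seq(0, 180, by = 5)
  idx <- findInterval(angles, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(mids))
  tibble(mid = mids, count = counts)
}

#' @export
print.angle_stats <- function(x, ...) {
  cat(sprintf("<angle_stats> %d hull angle(s), mode %g deg\n",
              length(x$angles), x$mode_deg))
  invisible(x)
}

#' @export
tidy.angle_stats <- function(x, ...) x$histogram

#' @export
glance.angle_stats <- function(x, ...) {
  tibble(mode_deg = x$mode_deg, n_angles = length(x$angles),
         n_hull = x$n_hull, n_interior = x$n_interior,
         degenerate = x$degenerate)
}

#' Classify a four-aster steady-state configuration
#'
#' A configuration whose convex hull has 3 vertices with one interior aster
#' is a `"Y"`; a 4-vertex hull with every interior angle within `angle_tol`
#' of 90 degrees and side-length ratio max/min below `side_ratio_max` is a
#' `"square"`; anything else is `"other"`.
#'
#' @param positions Data frame with columns `x`, `y`; exactly 4 distinct
#'   points.
#' @param angle_tol Tolerance around 90 degrees. Default 15.
#' @param side_ratio_max Maximum allowed max/min side-length ratio. Default
#'   1.5.
#' @return `"square"`, `"Y"`, or `"other"`.
#' @export
classify_configuration <- function(positions, angle_tol = 15,
                                   side_ratio_max = 1.5) {
  stopifnot(is.data.frame(positions), nrow(positions) == 4)
  pts <- as.matrix(positions[, c("x", "y")])
  if (anyDuplicated(round(pts, 9))) abort("Duplicate points.")
  hull <- grDevices::chull(pts)
  if (length(hull) == 3) return("Y")
  if (length(hull) == 4) {
    hp <- pts[hull, ]
    st <- angle_statistics(as.data.frame(hp) |> setNames(c("x", "y")))
    sides <- sqrt(rowSums((hp - hp[c(2:4, 1), ])^2))
    if (all(abs(st$angles - 90) <= angle_tol) &&
        max(sides) / min(sides) < side_ratio_max) return("square")
  }
  "other"
}

#' Run seeded multi-aster simulations from random initial positions
#'
#' Convenience ensemble driver: draws random initial positions, runs
#' [simulate_asters()] per seed, and collects final configurations, pooled
#' hull angles, and (for 4 asters) classifications. Two seeding modes:
#' `"uniform"` (default) draws positions uniformly in the concentric disk of
#' radius `R - margin`; `"ring"` places asters at uniform random angles at a
#' fixed `margin` inside the boundary.
#'
#' @param n_asters Number of asters per run.
#' @param n_runs Number of independent runs.
#' @param seed Base integer seed; run k uses `seed + k`.
#' @param disk,params,max_steps Passed to [simulate_asters()].
#' @param init `"uniform"` (default) or `"ring"`.
#' @param margin Initial positions stay this far inside the boundary (um).
#' @return A list with `finals` (tibble: `run`, `aster_id`, `x`, `y`),
#'   `angles` (pooled hull angles, degrees), `histogram`, `mode_deg`, and
#'   `classification` (for 4 asters; `NA` otherwise).
#' @export
simulate_configurations <- function(n_asters, n_runs = 20, seed = 1,
                                    disk = explant_disk(40),
                                    params = aster_params(),
                                    max_steps = 1e6,
                                    init = c("uniform", "ring"),
                                    margin = 5) {
  init <- match.arg(init)
  # independent per-run seeds derived from the base seed, so nearby base
  # seeds give unrelated ensembles
  run_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_runs))
  finals <- purrr::map_dfr(seq_len(n_runs), function(k) {
    init_pos <- with_seed(run_seeds[k],
      if (init == "ring") ring_positions(n_asters, disk, margin)
      else random_positions(n_asters, disk, margin))
    sim <- simulate_asters(init_pos, disk, params, max_steps = max_steps,
                           seed = run_seeds[k])
    dplyr::mutate(sim$final, run = k, .before = 1)
  })
  angles <- unlist(lapply(split(finals, finals$run), function(d)
    angle_statistics(d)$angles))
  hist <- angle_histogram(angles)
  classification <- if (n_asters == 4) {
    vapply(split(finals, finals$run),
           function(d) classify_configuration(d), "")
  } else NA
  list(finals = finals, angles = unname(angles), histogram = hist,
       mode_deg = hist$mid[which.max(hist$count)],
       classification = classification)
}

# random angles at a fixed boundary offset
ring_positions <- function(n, disk, margin = 5) {
  r0 <- disk$radius - margin
  th <- runif(n, 0, 2 * pi)
  tibble(id = seq_len(n),
         x = disk$center[1] + r0 * cos(th),
         y = disk$center[2] + r0 * sin(th))
}

# uniform positions in the concentric disk of radius R - margin
random_positions <- function(n, disk, margin = 5) {
  rmax <- disk$radius - margin
  r <- rmax * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  tibble(id = seq_len(n),
         x = disk$center[1] + r * cos(th),
         y = disk$center[2] + r * sin(th))
}
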