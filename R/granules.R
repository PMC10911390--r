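#' Mean-squared displacement with anomalous-exponent fit
#'
#' Computes the time-averaged MSD per track over lags up to
#' `max_lag_fraction` of the track length, ensemble-averages across tracks,
#' and fits the power law `a * t^c` by least squares on log-log values over
#' the fit range (by default from the 2nd lag to one third of the shortest
#' usable track). The exponent `c` (the anomalous-diffusion exponent alpha)
#' distinguishes diffusive (~1) from directed (>1) motion.
#'
#' @param tracks A track table: tibble with columns `track_id`, `t` (s),
#'   `x`, `y` (um). At least 5 tracks; tracks shorter than 3 frames are
#'   dropped with a message.
#' @param max_lag_fraction Longest lag per track, as a fraction of its
#'   length. Default 0.5.
#' @param fit_range Optional integer range (in lag indices) for the
#'   power-law fit; default `2:floor(n_shortest / 3)`.
#' @return An object of class `msd_fit`: `msd` (tibble `lag_s`, `msd`, `n`),
#'   `exponent`, `exponent_se`, `amplitude`, `amplitude_se`, `fit_range`.
#' @export
compute_msd <- function(tracks, max_lag_fraction = 0.5, fit_range = NULL) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "t", "x", "y") %in% names(tracks)))
  byid <- split(tracks[order(tracks$track_id, tracks$t), ],
                tracks$track_id[order(tracks$track_id, tracks$t)])
  lens <- vapply(byid, nrow, integer(1))
  short <- sum(lens < 3)
  if (short > 0) {
    inform(sprintf("Dropping %d track(s) shorter than 3 frames.", short))
    byid <- byid[lens >= 3]
  }
  if (length(byid) < 5) abort("At least 5 usable tracks are required.")
  dt <- median(unlist(lapply(byid, function(d) diff(d$t))))
  per_track <- lapply(byid, function(d) {
    n <- nrow(d)
    maxlag <- max(1L, floor(n * max_lag_fraction))
    vapply(seq_len(maxlag), function(k) {
      i <- seq_len(n - k)
      mean((d$x[i + k] - d$x[i])^2 + (d$y[i + k] - d$y[i])^2)
    }, numeric(1))
  })
  maxlag <- max(lengths(per_track))
  ens <- vapply(seq_len(maxlag), function(k) {
    vals <- unlist(lapply(per_track, function(m) if (k <= length(m)) m[k]))
    c(mean(vals), length(vals))
  }, numeric(2))
  msd_tbl <- tibble(lag = seq_len(maxlag), lag_s = seq_len(maxlag) * dt,
                    msd = ens[1, ], n = as.integer(ens[2, ]))
  if (is.null(fit_range)) {
    upper <- max(3L, floor(min(lengths(per_track)) / 3))
    fit_range <- 2:min(upper, maxlag)
  }
  sub <- msd_tbl[msd_tbl$lag %in% fit_range & msd_tbl$msd > 0, ]
  fit <- lm(log(msd) ~ log(lag_s), data = sub)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(
    msd = msd_tbl,
    exponent = unname(coef(fit)[2]), exponent_se = unname(se[2]),
    amplitude = unname(exp(coef(fit)[1])),
    amplitude_se = unname(exp(coef(fit)[1])) * unname(se[1]),
    fit_range = range(fit_range), n_tracks = length(byid)),
    class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> %d tracks; a * t^c with c = %.3f +/- %.3f\n",
              x$n_tracks, x$exponent, x$exponent_se))
  invisible(x)
}

#' @export
tidy.msd_fit <- function(x, ...) x$msd

#' @export
glance.msd_fit <- function(x, ...) {
  tibble(exponent = x$exponent, exponent_se = x$exponent_se,
         amplitude = x$amplitude, n_tracks = x$n_tracks,
         fit_lag_min = x$fit_range[1], fit_lag_max = x$fit_range[2])
}

#' @export
autoplot.msd_fit <- function(object, ...) {
  ggplot2::ggplot(object$msd, ggplot2::aes(.data$lag_s, .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble(lag_s = object$msd$lag_s,
                    msd = object$amplitude * object$msd$lag_s^object$exponent),
      colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' Granule exclusion-zone test around asters
#'
#' For each explant, measures the distance from the aster to its nearest
#' granule and from `n_random` uniform random positions inside the explant
#' (re-drawn whenever a random position falls inside a granule footprint) to
#' their nearest granules, then compares the pooled aster distances against
#' the pooled random distances with a two-sided Mann-Whitney rank test.
#'
#' @param granules Tibble of granule positions at the evaluation time:
#'   columns `explant`, `x`, `y` (um).
#' @param asters Tibble of aster positions: columns `explant`, `x`, `y`.
#' @param disks Tibble of explant geometries: columns `explant`, `cx`, `cy`,
#'   `R` (um).
#' @param n_random Random positions per explant. Default 4.
#' @param footprint_radius Granule footprint radius for the re-draw rule
#'   (um). Default 2.
#' @param seed Integer seed for the random placements.
#' @return An object of class `exclusion_test`: `distances` (tibble:
#'   `explant`, `kind`, `dist`), `rank_test` (`htest`), `p_value`,
#'   `median_aster`, `median_random`.
#' @export
exclusion_zone_test <- function(granules, asters, disks, n_random = 4,
                                footprint_radius = 2, seed = NULL) {
  stopifnot(all(c("explant", "x", "y") %in% names(granules)),
            all(c("explant", "x", "y") %in% names(asters)),
            all(c("explant", "cx", "cy", "R") %in% names(disks)))
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(asters)), function(i) {
      ex <- asters$explant[i]
      g <- granules[granules$explant == ex, ]
      if (nrow(g) == 0) abort(sprintf("Explant %s has no granules.", ex))
      dk <- disks[disks$explant == ex, ]
      nearest <- function(px, py) min(sqrt((g$x - px)^2 + (g$y - py)^2))
      d_aster <- nearest(asters$x[i], asters$y[i])
      d_rand <- vapply(seq_len(n_random), function(j) {
        repeat {
          r <- dk$R * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
          px <- dk$cx + r * cos(th); py <- dk$cy + r * sin(th)
          if (nearest(px, py) >= footprint_radius) return(nearest(px, py))
        }
      }, numeric(1))
      tibble(explant = ex,
             kind = c("aster", rep("random", n_random)),
             dist = c(d_aster, d_rand))
    })
    ht <- wilcox.test(dist ~ kind, data = rows, exact = FALSE)
    structure(list(distances = rows, rank_test = ht, p_value = ht$p.value,
                   median_aster = median(rows$dist[rows$kind == "aster"]),
                   median_random = median(rows$dist[rows$kind == "random"])),
              class = "exclusion_test")
  })
}

#' @export
print.exclusion_test <- function(x, ...) {
  cat(sprintf(paste0("<exclusion_test> median nearest-granule distance: ",
                     "aster %.2f um, random %.2f um; p = %.3g\n"),
              x$median_aster, x$median_random, x$p_value))
  invisible(x)
}

#' @export
tidy.exclusion_test <- function(x, ...) x$distances

#' @export
glance.exclusion_test <- function(x, ...) {
  tibble(median_aster = x$median_aster, median_random = x$median_random,
         p_value = x$p_value)
}

#' Granule velocity field in the moving-aster frame
#'
#' Expresses granule step displacements in a frame whose origin tracks the
#' aster and which is rotated so the aster's (moving-average smoothed)
#' velocity points along -y. Vectors are binned on a square grid and
#' averaged over frames; frames where the aster speed is zero are skipped.
#'
#' @param tracks Granule track table (`track_id`, `t`, `x`, `y`).
#' @param aster_track Aster trajectory (`t`, `x`, `y`) on the same clock.
#' @param grid_spacing Grid bin size (um). Default 5.
#' @param smooth_frames Moving-average window for the aster velocity.
#'   Default 5.
#' @return A tibble with columns `gx`, `gy` (bin centers, um), `vx`, `vy`
#'   (mean granule velocity, um/s), `speed`, `n` (steps per bin).
#' @export
aster_frame_velocity_field <- function(tracks, aster_track,
                                       grid_spacing = 5, smooth_frames = 5) {
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(tracks)),
            all(c("t", "x", "y") %in% names(aster_track)))
  at <- aster_track[order(aster_track$t), ]
  k <- max(1L, as.integer(smooth_frames))
  sm <- function(v) as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  ax_s <- sm(at$x); ay_s <- sm(at$y)
  n <- nrow(at)
  avx <- c(NA, (ax_s[-(1:2)] - ax_s[1:(n - 2)]) /
             (at$t[-(1:2)] - at$t[1:(n - 2)]), NA)
  avy <- c(NA, (ay_s[-(1:2)] - ay_s[1:(n - 2)]) /
             (at$t[-(1:2)] - at$t[1:(n - 2)]), NA)
  skipped <- 0L
  rows <- purrr::map_dfr(split(tracks[order(tracks$t), ], tracks$track_id[order(tracks$t)]),
    function(g) {
      if (nrow(g) < 2) return(NULL)
      i <- seq_len(nrow(g) - 1)
      # match granule step midpoints to aster frames
      fidx <- vapply(g$t[i], function(ti) which.min(abs(at$t - ti)),
                     integer(1))
      sp <- sqrt(avx[fidx]^2 + avy[fidx]^2)
      ok <- is.finite(sp) & sp > 0
      skipped <<- skipped + sum(!ok)
      if (!any(ok)) return(NULL)
      i <- i[ok]; fidx <- fidx[ok]
      # rotation taking the aster velocity onto -y
      ux <- avx[fidx] / sp[ok]; uy <- avy[fidx] / sp[ok]
      rel_x <- g$x[i] - at$x[fidx]; rel_y <- g$y[i] - at$y[fidx]
      # velocity relative to the moving origin (the aster)
      vx <- (g$x[i + 1] - g$x[i]) / (g$t[i + 1] - g$t[i]) - avx[fidx]
      vy <- (g$y[i + 1] - g$y[i]) / (g$t[i + 1] - g$t[i]) - avy[fidx]
      # rotate by the angle sending (ux, uy) to (0, -1):
      # R = [[-uy, ux], [-ux, -uy]]
      rvx <- -uy * vx + ux * vy
      rvy <- -ux * vx - uy * vy
      tibble(px = -uy * rel_x + ux * rel_y,
             py = -ux * rel_x - uy * rel_y,
             vx = rvx, vy = rvy)
    })
  if (skipped > 0)
    inform(sprintf("Skipped %d step(s) with zero/undefined aster speed.",
                   skipped))
  rows |>
    dplyr::mutate(gx = (floor(.data$px / grid_spacing) + 0.5) * grid_spacing,
                  gy = (floor(.data$py / grid_spacing) + 0.5) * grid_spacing) |>
    dplyr::group_by(.data$gx, .data$gy) |>
    dplyr::summarise(vx = mean(.data$vx), vy = mean(.data$vy),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(speed = sqrt(.data$vx^2 + .data$vy^2))
}
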