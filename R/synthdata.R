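#' Synthetic aster tracks from the 2D simulator
#'
#' Runs the 2D repulsion model for the requested scenario, resamples the
#' trajectory at the imaging frame interval, and adds Gaussian localization
#' noise, producing a track table shaped like a tracking export. Scenarios:
#' `single_aster` starts one aster 1 um from the boundary; `two_aster`
#' starts a pair 2 um apart centered in the explant (division orientation
#' drawn from the seed); `three_aster`/`four_aster` start from random
#' positions.
#'
#' @param scenario One of `"single_aster"`, `"two_aster"`, `"three_aster"`,
#'   `"four_aster"`.
#' @param disk An [explant_disk()]. Default radius 40 um.
#' @param params An [aster_params()].
#' @param frame_interval Sampling interval (model time units per frame).
#'   Default 15.
#' @param loc_noise_sd Localization noise SD (um). Default 0.2.
#' @param max_steps Simulation cap. Default 1e6.
#' @param seed Integer seed (drives division orientation, initial
#'   positions, simulation noise, and localization noise).
#' @return A tibble with columns `track_id`, `frame`, `t`, `x`, `y`, with
#'   ground truth in attribute `truth` (the `aster_sim`, the disk and the
#'   generator parameters).
#' @export
gen_aster_tracks <- function(scenario = c("single_aster", "two_aster",
                                          "three_aster", "four_aster"),
                             disk = explant_disk(40),
                             params = aster_params(),
                             frame_interval = 15, loc_noise_sd = 0.2,
                             max_steps = 1e6, seed = 1) {
  scenario <- match.arg(scenario)
  R <- disk$radius
  init <- with_seed(seed, switch(scenario,
    single_aster = tibble(id = 1L, x = disk$center[1] - (R - 1),
                          y = disk$center[2]),
    two_aster = divide_aster(disk$center, separation = 2,
                             orientation = runif(1, 0, 2 * pi), disk = disk),
    three_aster = random_positions(3, disk),
    four_aster = random_positions(4, disk)))
  record_every <- max(1L, round(frame_interval / params$dt))
  sim <- simulate_asters(init, disk, params, max_steps = max_steps,
                         seed = seed, record_every = record_every)
  traj <- sim$trajectories
  traj <- traj[traj$step %% record_every == 0, ]
  frames <- traj$step %/% record_every
  noisy <- with_seed(seed + 1L, {
    tibble(track_id = as.integer(traj$aster_id),
           frame = as.integer(frames),
           t = frames * frame_interval,
           x = traj$x + rnorm(nrow(traj), 0, loc_noise_sd),
           y = traj$y + rnorm(nrow(traj), 0, loc_noise_sd))
  })
  attr(noisy, "truth") <- list(sim = sim, disk = disk, params = params,
                               scenario = scenario,
                               frame_interval = frame_interval,
                               loc_noise_sd = loc_noise_sd, seed = seed)
  noisy
}

# fractional Gaussian noise (increments of fBm with Hurst index H) via
# Cholesky factorisation of the exact autocovariance; exponent c = 2H
fgn_matrix <- function(n_steps, n_series, hurst, sd = 1) {
  k <- 0:(n_steps - 1)
  g <- sd^2 / 2 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                     abs(k - 1)^(2 * hurst))
  C <- stats::toeplitz(g)
  L <- chol(C + diag(1e-12 * sd^2, n_steps))
  matrix(rnorm(n_steps * n_series), n_series, n_steps) %*% L
}

#' Synthetic yolk-granule tracks
#'
#' Generates tracers whose diffusive component is fractional Brownian
#' motion with MSD exponent `exponent` (`2` switches to ballistic tracks
#' with random headings), optionally advected by a moving aster: a
#' slip-inhibited exponential repulsion plus a hard exclusion core of the
#' configured radius. This generative model is a synthetic construction --
#' the minimal process reproducing the three experimental signatures
#' (exclusion zone, counter-streaming in the aster frame, and the
#' anomalous-exponent gap) -- not a mechanistic claim.
#'
#' @param n_tracks Number of granule tracks. Default 120.
#' @param n_frames Frames per track. Default 200.
#' @param frame_interval Seconds per frame. Default 15.
#' @param step_sd Per-frame diffusive step SD (um). Default 0.3.
#' @param exponent Target MSD exponent of the diffusive component (= 2H).
#'   Default 1.
#' @param preset `"paper_with_aster"` (exponent 1.3, aster present) or
#'   `"paper_no_aster"` (exponent 1.5, no aster); overrides `exponent` and
#'   `with_aster`.
#' @param with_aster Include a moving aster. Default `FALSE`.
#' @param aster_track Optional aster trajectory (`t`, `x`, `y`); default a
#'   straight path from 1 um inside the boundary to the center over the
#'   movie.
#' @param exclusion_radius Hard-core exclusion radius around the aster
#'   (um). Default 10.
#' @param repulsion_speed Peak advection speed of the soft repulsion
#'   (um/s). Default 0.1.
#' @param disk An [explant_disk()].
#' @param loc_noise_sd Localization noise SD (um). Default 0.2.
#' @param seed Integer seed.
#' @return A track table (`track_id`, `frame`, `t`, `x`, `y`) with ground
#'   truth in attribute `truth` (including the aster track when present).
#' @export
gen_granule_tracks <- function(n_tracks = 120, n_frames = 200,
                               frame_interval = 15, step_sd = 0.3,
                               exponent = 1, preset = NULL,
                               with_aster = FALSE, aster_track = NULL,
                               exclusion_radius = 10, repulsion_speed = 0.1,
                               disk = explant_disk(40), loc_noise_sd = 0.2,
                               seed = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper_with_aster", "paper_no_aster"))
    exponent <- if (preset == "paper_with_aster") 1.3 else 1.5
    with_aster <- preset == "paper_with_aster"
  }
  stopifnot(exponent > 0, exponent <= 2)
  R <- disk$radius
  with_seed(seed, {
    if (with_aster && is.null(aster_track)) {
      tt <- (seq_len(n_frames) - 1) * frame_interval
      frac <- tt / max(tt)
      aster_track <- tibble(t = tt,
                            x = disk$center[1] - (R - 1) * (1 - frac),
                            y = disk$center[2])
    }
    # diffusive increments
    if (exponent >= 2) {
      th <- runif(n_tracks, 0, 2 * pi)
      dx <- matrix(step_sd * cos(th), n_tracks, n_frames - 1)
      dy <- matrix(step_sd * sin(th), n_tracks, n_frames - 1)
    } else {
      h <- exponent / 2
      dx <- fgn_matrix(n_frames - 1, n_tracks, h, step_sd)
      dy <- fgn_matrix(n_frames - 1, n_tracks, h, step_sd)
    }
    # initial positions uniform in the disk (outside the core, if any)
    px <- py <- numeric(n_tracks)
    for (i in seq_len(n_tracks)) {
      repeat {
        r <- R * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
        px[i] <- disk$center[1] + r * cos(a)
        py[i] <- disk$center[2] + r * sin(a)
        if (!with_aster) break
        if (sqrt((px[i] - aster_track$x[1])^2 +
                 (py[i] - aster_track$y[1])^2) >= exclusion_radius) break
      }
    }
    X <- matrix(NA_real_, n_tracks, n_frames)
    Y <- matrix(NA_real_, n_tracks, n_frames)
    X[, 1] <- px; Y[, 1] <- py
    for (f in 2:n_frames) {
      px <- px + dx[, f - 1]; py <- py + dy[, f - 1]
      if (with_aster) {
        ax <- aster_track$x[f]; ay <- aster_track$y[f]
        rx <- px - ax; ry <- py - ay
        r <- pmax(sqrt(rx^2 + ry^2), 1e-9)
        push <- repulsion_speed * frame_interval *
          slip_factor(r, 15) * mt_density(r, 15)
        px <- px + push * rx / r; py <- py + push * ry / r
        # hard exclusion core
        rx <- px - ax; ry <- py - ay
        r <- pmax(sqrt(rx^2 + ry^2), 1e-9)
        inside <- r < exclusion_radius
        px[inside] <- ax + rx[inside] / r[inside] * exclusion_radius
        py[inside] <- ay + ry[inside] / r[inside] * exclusion_radius
      }
      # keep tracers inside the explant
      cx <- px - disk$center[1]; cy <- py - disk$center[2]
      rr <- sqrt(cx^2 + cy^2)
      out <- rr > R
      px[out] <- disk$center[1] + cx[out] / rr[out] * R
      py[out] <- disk$center[2] + cy[out] / rr[out] * R
      X[, f] <- px; Y[, f] <- py
    }
    tracks <- tibble(
      track_id = rep(seq_len(n_tracks), each = n_frames),
      frame = rep(seq_len(n_frames) - 1L, n_tracks),
      t = rep((seq_len(n_frames) - 1) * frame_interval, n_tracks),
      x = as.vector(t(X)) + rnorm(n_tracks * n_frames, 0, loc_noise_sd),
      y = as.vector(t(Y)) + rnorm(n_tracks * n_frames, 0, loc_noise_sd))
    attr(tracks, "truth") <- list(
      exponent = exponent, step_sd = step_sd, with_aster = with_aster,
      aster_track = aster_track, exclusion_radius = exclusion_radius,
      repulsion_speed = repulsion_speed, disk = disk,
      loc_noise_sd = loc_noise_sd, frame_interval = frame_interval,
      seed = seed, preset = preset)
    tracks
  })
}

#' Synthetic radial intensity profile
#'
#' Samples `C * 1(r < r_c) + A * exp(-r / lambda) + B + noise` on a regular
#' distance grid: a centrosome peak (two leading bins by default) on top of
#' a mono-exponential microtubule decay and a constant background.
#'
#' @param lambda Decay length (um). Default 11.8.
#' @param A,B Amplitude and background. Defaults 1 and 0.05.
#' @param centrosome_peak Extra intensity C in the leading bins. Default
#'   0.5.
#' @param peak_radius Extent r_c of the centrosome peak (um). Default 0.4
#'   (two 0.2-um bins).
#' @param noise_sd Additive Gaussian noise SD (normalized units). Default
#'   0.03.
#' @param max_radius Profile extent (um). Default 40.
#' @param bin_width Sample spacing (um). Default 0.2.
#' @param seed Integer seed.
#' @return A tibble (`r`, `intensity`) with ground truth in attribute
#'   `truth`.
#' @export
gen_radial_profile <- function(lambda = 11.8, A = 1, B = 0.05,
                               centrosome_peak = 0.5, peak_radius = 0.4,
                               noise_sd = 0.03, max_radius = 40,
                               bin_width = 0.2, seed = 1) {
  stopifnot(lambda > 0)
  r <- seq(bin_width / 2, max_radius, by = bin_width)
  with_seed(seed, {
    intensity <- A * exp(-r / lambda) + B +
      centrosome_peak * (r < peak_radius) +
      rnorm(length(r), 0, noise_sd)
    out <- tibble(r = r, intensity = intensity)
    attr(out, "truth") <- list(lambda = lambda, A = A, B = B,
                               centrosome_peak = centrosome_peak,
                               peak_radius = peak_radius,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Synthetic separation movie: line profiles between two receding asters
#'
#' Simulates a dividing aster pair, resamples at the frame interval, and
#' renders per-frame line intensities along the inter-aster axis as the sum
#' of two exponential aster profiles plus background and noise, paired with
#' the ground-truth separation series.
#'
#' @param disk,params,frame_interval,max_steps,seed As in
#'   [gen_aster_tracks()].
#' @param lambda_profile Intensity decay length of each aster (um). Default
#'   12.
#' @param background Constant background. Default 0.05.
#' @param noise_sd Additive noise SD on the line profiles. Default 0.02.
#' @param pos_step Sampling step along the line (um). Default 0.5.
#' @param margin Line extension beyond each aster (um). Default 10.
#' @return A list: `frames` (tibble `frame`, `pos_um`, `intensity`),
#'   `separation` (tibble `frame`, `t`, `d`), `truth`.
#' @export
gen_separation_movie <- function(disk = explant_disk(40),
                                 params = aster_params(),
                                 frame_interval = 15, max_steps = 1e6,
                                 lambda_profile = 12, background = 0.05,
                                 noise_sd = 0.02, pos_step = 0.5,
                                 margin = 10, seed = 1) {
  init <- with_seed(seed, divide_aster(disk$center, separation = 2,
                                       orientation = runif(1, 0, 2 * pi),
                                       disk = disk))
  record_every <- max(1L, round(frame_interval / params$dt))
  sim <- simulate_asters(init, disk, params, max_steps = max_steps,
                         seed = seed, record_every = record_every)
  traj <- sim$trajectories
  traj <- traj[traj$step %% record_every == 0, ]
  a1 <- traj[traj$aster_id == 1, ]
  a2 <- traj[traj$aster_id == 2, ]
  d <- sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2)
  frames_id <- a1$step %/% record_every
  sep <- tibble(frame = as.integer(frames_id),
                t = frames_id * frame_interval, d = d)
  frames <- with_seed(seed + 1L, purrr::map_dfr(seq_len(nrow(sep)), function(i) {
    pos <- seq(-margin, sep$d[i] + margin, by = pos_step)
    inten <- exp(-abs(pos) / lambda_profile) +
      exp(-abs(pos - sep$d[i]) / lambda_profile) + background +
      rnorm(length(pos), 0, noise_sd)
    tibble(frame = sep$frame[i], pos_um = pos, intensity = inten)
  }))
  list(frames = frames, separation = sep,
       truth = list(sim = sim, lambda_profile = lambda_profile,
                    background = background, noise_sd = noise_sd,
                    frame_interval = frame_interval, seed = seed))
}
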