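test_that("MSD exponent is exact for ballistic tracks", {
  tr <- gen_granule_tracks(n_tracks = 30, n_frames = 120, exponent = 2,
                           loc_noise_sd = 0, seed = 2,
                           disk = explant_disk(500))
  fit <- compute_msd(tr)
  expect_equal(fit$exponent, 2, tolerance = 0.01)
})

test_that("MSD estimator is unbiased on Brownian tracks", {
  tr <- gen_granule_tracks(n_tracks = 100, n_frames = 200, exponent = 1,
                           loc_noise_sd = 0, seed = 3,
                           disk = explant_disk(500))
  fit <- compute_msd(tr)
  expect_equal(fit$exponent, 1, tolerance = 0.1)
  # MSD = 4 D t with D = step_sd^2 / (2 * frame_interval)
  D_true <- 0.3^2 / (2 * 15)
  D_fit <- fit$amplitude / 4
  expect_lt(abs(D_fit - D_true) / D_true, 0.1)
})

test_that("anomalous exponents 1.3 and 1.5 are recovered within 0.1", {
  for (ex in c(1.3, 1.5)) {
    est <- vapply(1:3, function(k) {
      tr <- gen_granule_tracks(n_tracks = 80, n_frames = 150,
                               exponent = ex, loc_noise_sd = 0,
                               seed = 20 + k, disk = explant_disk(500))
      compute_msd(tr)$exponent
    }, numeric(1))
    expect_true(all(abs(est - ex) <= 0.1))
  }
})

test_that("short tracks are dropped with a message and few tracks error", {
  tr <- gen_granule_tracks(n_tracks = 6, n_frames = 50, seed = 1,
                           disk = explant_disk(500), loc_noise_sd = 0)
  short <- tibble::tibble(track_id = 999, frame = 0:1, t = c(0, 15),
                          x = c(0, 1), y = c(0, 1))
  expect_message(compute_msd(rbind(tr, short)), "Dropping 1 track")
  expect_error(compute_msd(tr[tr$track_id <= 3, ]), "5 usable")
})

make_exclusion_data <- function(exclude_um, n_explants = 7, n_gran = 60,
                                seed = 1) {
  set.seed(seed)
  out <- list(granules = NULL, asters = NULL, disks = NULL)
  for (e in seq_len(n_explants)) {
    ax <- runif(1, -10, 10); ay <- runif(1, -10, 10)
    gx <- gy <- numeric(0)
    while (length(gx) < n_gran) {
      r <- 40 * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
      px <- r * cos(th); py <- r * sin(th)
      if (sqrt((px - ax)^2 + (py - ay)^2) >= exclude_um) {
        gx <- c(gx, px); gy <- c(gy, py)
      }
    }
    out$granules <- rbind(out$granules,
                          tibble::tibble(explant = e, x = gx, y = gy))
    out$asters <- rbind(out$asters,
                        tibble::tibble(explant = e, x = ax, y = ay))
    out$disks <- rbind(out$disks,
                       tibble::tibble(explant = e, cx = 0, cy = 0, R = 40))
  }
  out
}

test_that("a 10-um granule-free zone around the aster is detected", {
  d <- make_exclusion_data(10)
  res <- exclusion_zone_test(d$granules, d$asters, d$disks, seed = 42)
  aster_d <- res$distances$dist[res$distances$kind == "aster"]
  expect_true(all(aster_d >= 10))
  expect_lt(res$median_random, 10)
  expect_lt(res$p_value, 0.05)
})

test_that("the exclusion statistic is exchangeable under granule relabeling", {
  d <- make_exclusion_data(10)
  res1 <- exclusion_zone_test(d$granules, d$asters, d$disks, seed = 7)
  perm <- d$granules[sample(nrow(d$granules)), ]
  res2 <- exclusion_zone_test(perm, d$asters, d$disks, seed = 7)
  expect_equal(res1$distances$dist, res2$distances$dist, tolerance = 1e-12)
  expect_equal(res1$p_value, res2$p_value)
})

test_that("a granule at the aster gives zero aster distance", {
  gran <- tibble::tibble(explant = 1, x = 5, y = 5)
  ast <- tibble::tibble(explant = 1, x = 5, y = 5)
  dk <- tibble::tibble(explant = 1, cx = 0, cy = 0, R = 40)
  res <- exclusion_zone_test(gran, ast, dk, seed = 1)
  expect_equal(res$distances$dist[res$distances$kind == "aster"], 0)
  expect_true(all(res$distances$dist >= 0))
  expect_error(exclusion_zone_test(gran[0, ], ast, dk, seed = 1),
               "no granules")
})

test_that("synthetic granules around a moving aster show the exclusion zone", {
  grans <- asters <- disks <- NULL
  for (e in 1:7) {
    tr <- gen_granule_tracks(n_tracks = 70, n_frames = 60,
                             preset = "paper_with_aster", seed = e)
    truth <- attr(tr, "truth")
    at <- truth$aster_track
    # evaluate when the aster is 15 um from the boundary
    fi <- which.min(abs((40 - sqrt(at$x^2 + at$y^2)) - 15))
    g <- tr[tr$frame == fi - 1, ]
    grans <- rbind(grans, tibble::tibble(explant = e, x = g$x, y = g$y))
    asters <- rbind(asters, tibble::tibble(explant = e, x = at$x[fi],
                                           y = at$y[fi]))
    disks <- rbind(disks, tibble::tibble(explant = e, cx = 0, cy = 0,
                                         R = 40))
  }
  res <- exclusion_zone_test(grans, asters, disks, seed = 11)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$median_aster, 10, tolerance = 0.15)
})

test_that("the aster-frame velocity field has the expected topology", {
  t <- seq(0, 600, by = 15)
  aster <- tibble::tibble(t = t, x = 0.05 * t, y = 0)  # moving +x at 0.05
  set.seed(9)
  # static granules scattered around the path
  tracks <- purrr::map_dfr(1:40, function(id) {
    tibble::tibble(track_id = id, t = t,
                   x = runif(1, -10, 40), y = runif(1, -25, 25))
  })
  field <- suppressMessages(
    aster_frame_velocity_field(tracks, aster, grid_spacing = 10))
  # static granules in the lab appear moving opposite to the aster: +y
  expect_true(all(field$vy > 0))
  expect_equal(mean(field$vy), 0.05, tolerance = 1e-6)
  expect_equal(max(abs(field$vx)), 0, tolerance = 1e-6)
  # co-moving granules give a zero field
  co <- purrr::map_dfr(1:20, function(id) {
    tibble::tibble(track_id = id, t = t, x = 0.05 * t + id, y = id %% 7)
  })
  f2 <- suppressMessages(
    aster_frame_velocity_field(co, aster, grid_spacing = 10))
  expect_lt(max(abs(c(f2$vx, f2$vy))), 1e-9)
})

test_that("granules ahead of and behind a repulsive aster counter-stream", {
  tr <- gen_granule_tracks(n_tracks = 150, n_frames = 100,
                           preset = "paper_with_aster", loc_noise_sd = 0,
                           seed = 14)
  at <- attr(tr, "truth")$aster_track
  field <- suppressMessages(
    aster_frame_velocity_field(tr, at, grid_spacing = 10))
  ahead <- field[field$gy < -5 & abs(field$gx) <= 15 & field$n > 20, ]
  behind <- field[field$gy > 5 & abs(field$gx) <= 15 & field$n > 20, ]
  # the aster moves along -y in this frame; granules stream along +y
  expect_gt(mean(ahead$vy), 0)
  expect_gt(mean(behind$vy), 0)
})
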