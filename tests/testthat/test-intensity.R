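test_that("radial profiles bin and normalize correctly", {
  # uniform intensity: flat profile at 1
  d <- expand.grid(x = seq(-20, 20, 0.5), y = seq(-20, 20, 0.5))
  d$intensity <- 5
  prof <- radial_profile(d, center = c(0, 0), max_radius = 15)
  expect_true(all(prof$intensity == 1, na.rm = TRUE))
  # synthetic aster: generator curve recovered within bin resolution
  r <- seq(0.05, 30, by = 0.05)
  prof2 <- radial_profile(data.frame(r = r,
                                     intensity = exp(-r / 12) + 0.02),
                          bin_width = 0.2, stat = "mean")
  expected <- (exp(-prof2$r / 12) + 0.02) / (exp(-prof2$r[1] / 12) + 0.02)
  expect_lt(max(abs(prof2$intensity - expected), na.rm = TRUE), 0.01)
  expect_true(max(prof2$intensity, na.rm = TRUE) <= 1)
})

test_that("empty bins are missing, not zero", {
  prof <- radial_profile(data.frame(r = c(0.1, 0.3, 5.1),
                                    intensity = c(1, 1, 0.5)),
                         max_radius = 6)
  expect_true(any(is.na(prof$intensity)))
  expect_false(any(prof$intensity == 0, na.rm = TRUE))
})

test_that("radial profiles are rotation invariant", {
  set.seed(1)
  n <- 4000
  r <- 25 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  d <- data.frame(x = r * cos(th), y = r * sin(th),
                  intensity = exp(-r / 12))
  rot <- 37 * pi / 180
  d2 <- data.frame(x = d$x * cos(rot) - d$y * sin(rot),
                   y = d$x * sin(rot) + d$y * cos(rot),
                   intensity = d$intensity)
  p1 <- radial_profile(d, center = c(0, 0))
  p2 <- radial_profile(d2, center = c(0, 0))
  expect_lt(max(abs(p1$intensity - p2$intensity), na.rm = TRUE), 1e-6)
})

test_that("matrix images are accepted with a pixel size", {
  img <- matrix(0, 41, 41)
  xs <- (col(img) - 0.5); ys <- (row(img) - 0.5)
  img[] <- exp(-sqrt((xs - 20.5)^2 + (ys - 20.5)^2) / 8)
  prof <- radial_profile(img, center = c(20.5, 20.5), max_radius = 15,
                         bin_width = 1, stat = "mean")
  fit <- fit_exponential_decay(prof, exclude_first = 0)
  expect_equal(fit$lambda, 8, tolerance = 0.12)  # pixel-binning bias ~10%
})

test_that("mono-exponential fit recovers exact parameters without noise", {
  r <- seq(0.1, 40, by = 0.2)
  prof <- data.frame(r = r, intensity = 0.9 * exp(-r / 11.8) + 0.05)
  fit <- fit_exponential_decay(prof)
  expect_equal(fit$lambda, 11.8, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.9, tolerance = 1e-6)
  expect_equal(fit$background, 0.05, tolerance = 1e-6)
  expect_lt(fit$lambda_se, 1e-6)
})

test_that("excluding the first two bins removes the centrosome peak", {
  r <- seq(0.1, 40, by = 0.2)
  clean <- data.frame(r = r, intensity = exp(-r / 11.8))
  spiked <- clean
  spiked$intensity[1:2] <- spiked$intensity[1:2] * 3
  f_clean <- fit_exponential_decay(clean, exclude_first = 2)
  f_spiked <- fit_exponential_decay(spiked, exclude_first = 2)
  expect_equal(f_spiked$lambda, f_clean$lambda, tolerance = 1e-9)
  expect_equal(f_spiked$excluded, 2)
})

test_that("decay fit is scale equivariant", {
  prof <- gen_radial_profile(seed = 33)
  f1 <- fit_exponential_decay(prof)
  prof2 <- prof
  prof2$intensity <- prof2$intensity * 7
  f2 <- fit_exponential_decay(prof2)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-6)
  expect_equal(f2$amplitude, 7 * f1$amplitude, tolerance = 1e-5)
})

test_that("degenerate profiles are rejected", {
  r <- seq(0.1, 40, by = 0.2)
  set.seed(4)
  flat <- data.frame(r = r, intensity = 0.2 + rnorm(length(r), 0, 0.01))
  expect_error(fit_exponential_decay(flat), "non-identifiable|converge")
  expect_error(fit_exponential_decay(data.frame(r = 1:5, intensity = 1:5)),
               "8 usable")
})

test_that("midline intensity of two superposed asters follows 2 exp(-d/2L)", {
  lambda <- 12
  sep <- tibble::tibble(frame = 1:20, d = seq(4, 30, length.out = 20))
  frames <- purrr::map_dfr(1:20, function(f) {
    pos <- seq(-10, sep$d[f] + 10, by = 0.25)
    tibble::tibble(frame = f, pos_um = pos,
                   intensity = exp(-abs(pos) / lambda) +
                     exp(-abs(pos - sep$d[f]) / lambda))
  })
  res <- midline_series_and_kymograph(frames, sep, window_um = 0.5)
  expect_equal(res$midline$intensity, 2 * exp(-sep$d / (2 * lambda)),
               tolerance = 0.01)
  expect_equal(res$fit$lambda, 2 * lambda, tolerance = 0.5)
  expect_equal(dim(res$kymograph)[1], 20)
})

test_that("constant fields give flat midlines and uniform kymographs", {
  sep <- tibble::tibble(frame = 1:10, d = seq(5, 20, length.out = 10))
  frames <- purrr::map_dfr(1:10, function(f)
    tibble::tibble(frame = f, pos_um = seq(-5, 25, 0.5), intensity = 0.4))
  res <- midline_series_and_kymograph(frames, sep)
  expect_true(all(res$midline$intensity == 0.4))
  expect_true(all(res$kymograph[!is.na(res$kymograph)] == 0.4))
  # frames without profiles are skipped with a message
  expect_message(
    midline_series_and_kymograph(frames[frames$frame <= 8, ], sep),
    "Skipping 2")
})

test_that("the slip velocity model is exactly recovered without noise", {
  d <- seq(2, 38, length.out = 20)
  v <- 0.04 * exp(-d / 12) * d^2 / (15^2 + d^2)
  two <- fit_separation_velocity_model(data.frame(d = d, v = v),
                                       lambda = 12)
  expect_equal(two$x0, 15, tolerance = 1e-6)
  expect_equal(two$amplitude, 0.04, tolerance = 1e-6)
  joint <- fit_separation_velocity_model(data.frame(d = d, v = v),
                                         mode = "joint")
  expect_equal(joint$x0, 15, tolerance = 1e-4)
  expect_equal(joint$lambda, 12, tolerance = 1e-4)
  # joint and two-step agree to < 1% on clean data
  expect_lt(abs(joint$x0 - two$x0) / two$x0, 0.01)
})

test_that("dropping the slip term fits slip-generated data strictly worse", {
  set.seed(6)
  d <- seq(2, 38, length.out = 20)
  v <- 0.04 * exp(-d / 12) * d^2 / (225 + d^2) * (1 + rnorm(20, 0, 0.02))
  full <- fit_separation_velocity_model(data.frame(d = d, v = v),
                                        lambda = 12)
  rss_full <- sum(stats::residuals(full$fit)^2)
  # nested alternative x0 -> 0: v proportional to the density alone
  nested <- lm(v ~ 0 + I(exp(-d / 12)))
  expect_gt(sum(stats::residuals(nested)^2), rss_full)
})

test_that("separation-velocity fits flag non-identifiable data", {
  d <- seq(30, 38, length.out = 9)  # no rise-and-fall coverage
  v <- rep(1e-4, 9)
  expect_error(fit_separation_velocity_model(data.frame(d = d, v = v),
                                             lambda = 12),
               "identifiable|wider")
  expect_error(fit_separation_velocity_model(
    data.frame(d = 1:4, v = 1:4), lambda = 12), "8")
})

test_that("x0 is recovered within 20% from noisy velocity data", {
  ok <- vapply(1:40, function(k) {
    set.seed(300 + k)
    d <- seq(2, 38, length.out = 20)
    v <- 0.04 * exp(-d / 12) * d^2 / (225 + d^2) * (1 + rnorm(20, 0, 0.05))
    fit <- fit_separation_velocity_model(data.frame(d = d, v = v),
                                         lambda = 12)
    abs(fit$x0 - 15) <= 3
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
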