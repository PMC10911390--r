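test_that("central-difference velocity matches hand evaluation", {
  lin <- instantaneous_velocity(data.frame(t = 0:3, d = c(0, 2, 4, 6)))
  expect_equal(lin$velocity[2:3], c(2, 2))
  expect_equal(lin$one_sided, c(TRUE, FALSE, FALSE, TRUE))
  const <- instantaneous_velocity(data.frame(t = 0:5, d = rep(3, 6)))
  expect_equal(const$velocity, rep(0, 6))
  quad <- instantaneous_velocity(data.frame(t = 0:3, d = c(0, 1, 4, 9)))
  expect_equal(quad$velocity[2], (4 - 0) / 2)
  expect_equal(quad$velocity[3], (9 - 1) / 2)
  expect_error(instantaneous_velocity(data.frame(t = c(0, 2, 1),
                                                 d = 1:3)),
               "increasing")
  expect_error(instantaneous_velocity(data.frame(t = 0:1, d = 0:1)),
               "3 samples")
})

test_that("central differences are exact for quadratic motion at interior points", {
  t <- seq(0, 10, by = 0.5)
  d <- 3 + 2 * t - 0.25 * t^2
  v <- instantaneous_velocity(data.frame(t = t, d = d))
  expect_equal(v$velocity[!v$one_sided], (2 - 0.5 * t)[!v$one_sided],
               tolerance = 1e-12)
})

test_that("separation series handles stationary, receding and 3D tracks", {
  t <- seq(0, 300, by = 15)
  a <- data.frame(t = t, x = 0, y = 0)
  b <- data.frame(t = t, x = 10, y = 0)
  ss <- separation_series(a, b, tail_frames = 5)
  expect_equal(ss$d, rep(10, length(t)))
  expect_equal(ss$d_norm, rep(1, length(t)))
  expect_equal(ss$velocity, rep(0, length(t)))
  # receding at 0.05 um/s (the observed single-aster velocity scale)
  b2 <- data.frame(t = t, x = 10 + 0.05 * t, y = 0)
  ss2 <- separation_series(a, b2, tail_frames = 5)
  expect_equal(ss2$velocity, rep(0.05, length(t)), tolerance = 1e-12)
  # z contributes to the Euclidean separation when present
  a3 <- data.frame(t = t, x = 0, y = 0, z = 0)
  b3 <- data.frame(t = t, x = 3, y = 0, z = 4)
  expect_equal(separation_series(a3, b3, tail_frames = 5)$d,
               rep(5, length(t)))
})

test_that("steady-state geometry reproduces the equal-partition arithmetic", {
  disk <- explant_disk(30)
  g <- steady_state_geometry(data.frame(x = c(-10, 10), y = 0), disk)
  expect_equal(g$b1, 20)
  expect_equal(g$b2, 20)
  expect_equal(g$d, 20)   # = 2R/3: space partitioned equally
  expect_equal(g$M, 20)
  g1 <- steady_state_geometry(data.frame(x = 0, y = 0), disk)
  expect_equal(g1$b1, 30)
  g2 <- steady_state_geometry(
    data.frame(x = c(20, 0), y = c(0, -25)), disk)
  expect_equal(g2$M, 2 * 30 - 10 - 5)
  expect_error(steady_state_geometry(data.frame(x = 31, y = 0), disk),
               "inside")
})

test_that("steady-state geometry is invariant under rigid motion about the center", {
  disk <- explant_disk(30)
  pts <- data.frame(x = c(5, -8), y = c(12, 3))
  g0 <- steady_state_geometry(pts, disk)
  th <- 1.234
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- as.data.frame(as.matrix(pts) %*% t(Rm)) |> setNames(c("x", "y"))
  g1 <- steady_state_geometry(rot, disk)
  expect_equal(unlist(g0), unlist(g1), tolerance = 1e-9)
  # translating points and center together changes nothing
  disk2 <- explant_disk(30, center = c(100, -50))
  shifted <- data.frame(x = pts$x + 100, y = pts$y - 50)
  g2 <- steady_state_geometry(shifted, disk2)
  expect_equal(unlist(g0), unlist(g2), tolerance = 1e-9)
})

make_group <- function(group, slope, nrep, t, sd, seed) {
  purrr::map_dfr(seq_len(nrep), function(r) {
    set.seed(seed + r)
    tibble::tibble(group = group, replicate = r, t = t,
                   d = 20 + slope * pmax(t - 100, 0) + rnorm(length(t), 0, sd))
  })
}

test_that("perturbation alignment recovers slopes and detects separation", {
  t <- seq(0, 400, by = 15)
  ctrl <- make_group("control", 0.1, 4, t, 0.01, 1)
  drug <- make_group("drug", -0.1, 4, t, 0.01, 100)
  res <- align_and_test_perturbation(rbind(ctrl, drug), t_perturb = 100,
                                     slope_window = 120)
  sl <- res$slopes
  expect_equal(sl$slope[sl$group == "control"], 0.1, tolerance = 0.02)
  expect_equal(sl$slope[sl$group == "drug"], -0.1, tolerance = 0.02)
  expect_true(all(sl$ci_lo < sl$slope & sl$slope < sl$ci_hi))
  expect_true(res$significant)
  # independent regression oracle: closed-form least squares on one window
  w <- res$aligned[res$aligned$group == "control" &
                     res$aligned$t > 0 & res$aligned$t <= 120, ]
  beta <- sum((w$t - mean(w$t)) * (w$d - mean(w$d))) /
    sum((w$t - mean(w$t))^2)
  expect_equal(sl$slope[sl$group == "control"], beta, tolerance = 1e-12)
})

test_that("identical groups are not flagged as different", {
  t <- seq(0, 400, by = 15)
  g1 <- make_group("a", 0.05, 3, t, 0.05, 7)
  g2 <- make_group("b", 0.05, 3, t, 0.05, 7)  # same seeds: same trajectories
  res <- align_and_test_perturbation(rbind(g1, g2), t_perturb = 100,
                                     slope_window = 120)
  sl <- res$slopes
  expect_true(sl$ci_lo[1] < sl$ci_hi[2] && sl$ci_lo[2] < sl$ci_hi[1])
  expect_false(res$significant)
  expect_error(align_and_test_perturbation(rbind(g1, g2), t_perturb = 100,
                                           slope_window = 1e-9),
               "window")
})

test_that("force removal stalls or reverts separation in the simulator", {
  # colchicine-like perturbation: all microtubule forces switched off at t0
  p <- aster_params()
  pre <- quiet_sim(divide_aster(c(0, 0), 2, 0), params = p, seed = 8,
                   max_steps = 4e5, steady_tol = 1e-12, record_every = 150)
  start2 <- pre$final
  post <- quiet_sim(start2, params = aster_params(f0 = 0, f1 = 0),
                    seed = 9, max_steps = 1e5, steady_tol = 1e-12,
                    record_every = 150)
  d_of <- function(sim) {
    tr <- sim$trajectories
    a <- tr[tr$aster_id == 1, ]; b <- tr[tr$aster_id == 2, ]
    sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  }
  d_pre <- d_of(pre); d_post <- d_of(post)
  expect_gt(d_pre[length(d_pre)] - d_pre[1], 5)  # separating before
  # after force removal the separation stops growing (pure noise jitter)
  expect_lt(abs(d_post[length(d_post)] - d_post[1]), 0.5)
})

test_that("ablation displacements are expressed in the ellipse frame", {
  t <- seq(0, 300, by = 15)
  stat <- purrr::map_dfr(1:3, function(r)
    tibble::tibble(replicate = r, t = t, x = 5, y = -2))
  res <- ablation_displacement(stat, t_ablation = 150)
  expect_true(all(res$series$dx == 0))
  expect_true(all(res$series$dy == 0))
  # drift along the major axis only
  ax <- c(1 / sqrt(2), 1 / sqrt(2))
  axes <- rbind(ax, c(-ax[2], ax[1]))
  drift <- purrr::map_dfr(1:3, function(r)
    tibble::tibble(replicate = r, t = t, x = 0.1 * t * ax[1],
                   y = 0.1 * t * ax[2]))
  res2 <- ablation_displacement(drift, t_ablation = 150, ellipse_axes = axes)
  expect_equal(max(abs(res2$series$dy)), 0, tolerance = 1e-9)
  post <- res2$series[res2$series$t >= 0, ]
  fitslope <- coef(lm(dx ~ t, data = post))[["t"]]
  expect_equal(fitslope, 0.1, tolerance = 1e-9)
  expect_error(ablation_displacement(stat, t_ablation = 30), "5 frames")
  expect_error(ablation_displacement(stat, t_ablation = 150,
                                     ellipse_axes = diag(2) * 2),
               "orthogonal unit")
})

test_that("asymmetric force removal displaces the aster toward the ablated side", {
  # emulate an asymmetric UV ablation: a steady aster whose wall force is
  # deleted on the left half-plane should drift left (pushing model sign)
  p <- aster_params()
  disk <- explant_disk(40)
  pos <- c(0, 0)
  set.seed(2)
  dt <- p$dt
  xs <- numeric(5000)
  for (i in seq_len(5000)) {
    b <- disk$radius - sqrt(sum(pos^2))
    # microtubules to the left of the aster ablated: keep only the push
    # from the right-hand boundary, which points in -x
    f <- -force_magnitude("wall", 2 * (disk$radius - abs(pos[1])), p)
    th <- runif(1, 0, 2 * pi)
    pos <- pos + p$gamma * dt * (c(f, 0) + p$delta_f * c(cos(th), sin(th)))
    xs[i] <- pos[1]
  }
  traj <- tibble::tibble(replicate = 1, t = seq_len(5000) * dt,
                         x = xs, y = 0)
  res <- ablation_displacement(traj, t_ablation = 10 * dt)
  expect_lt(mean(res$series$dx[res$series$t > 0]), 0)
})
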