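#' Instantaneous velocity by central differences
#'
#' Computes `v_i = (d[i+1] - d[i-1]) / (t[i+1] - t[i-1])` at interior
#' samples; endpoints use one-sided differences and are flagged.
#'
#' @param data A data frame holding the series.
#' @param time,value Column names (strings) of time (s) and the measured
#'   quantity (um). Defaults `"t"` and `"d"`.
#' @return The input as a tibble with added columns `velocity` (um/s) and
#'   `one_sided` (logical endpoint flag).
#' @examples
#' instantaneous_velocity(data.frame(t = 0:3, d = c(0, 1, 4, 9)))
#' @export
instantaneous_velocity <- function(data, time = "t", value = "d") {
  stopifnot(is.data.frame(data))
  t <- data[[time]]; d <- data[[value]]
  if (is.null(t) || is.null(d))
    abort(sprintf("Columns `%s` and `%s` are required.", time, value))
  n <- length(t)
  if (n < 3) abort("At least 3 samples are required.")
  if (any(diff(t) <= 0)) abort("Times must be strictly increasing.")
  v <- numeric(n)
  i <- 2:(n - 1)
  v[i] <- (d[i + 1] - d[i - 1]) / (t[i + 1] - t[i - 1])
  v[1] <- (d[2] - d[1]) / (t[2] - t[1])
  v[n] <- (d[n] - d[n - 1]) / (t[n] - t[n - 1])
  out <- as_tibble(data)
  out$velocity <- v
  out$one_sided <- c(TRUE, rep(FALSE, n - 2), TRUE)
  out
}

#' Inter-aster separation series
#'
#' Pairs two aster trajectories on a common time grid (nearest-frame
#' resampling of the second onto the first when grids differ), computes the
#' Euclidean separation (3D when a `z` column is present), normalizes it by
#' the final steady-state separation (mean of the last `tail_frames`
#' samples), and derives the separation velocity by central differences.
#'
#' @param track_a,track_b Data frames with columns `t`, `x`, `y` and
#'   optionally `z` (um, s).
#' @param tail_frames Number of trailing samples defining the final
#'   separation. Default 12.
#' @return An object of class `separation_series`: a tibble with columns
#'   `t`, `d`, `d_norm`, `velocity`, `one_sided`, with the final separation
#'   in attribute `d_final`.
#' @export
separation_series <- function(track_a, track_b, tail_frames = 12) {
  for (tr in list(track_a, track_b))
    if (!all(c("t", "x", "y") %in% names(tr)))
      abort("Tracks need columns `t`, `x`, `y`.")
  use_z <- "z" %in% names(track_a) && "z" %in% names(track_b)
  t <- track_a$t
  if (length(t) < max(3, tail_frames))
    abort(sprintf("Need at least %d samples.", max(3, tail_frames)))
  # nearest-frame resample of b onto a's grid
  idx <- vapply(t, function(ti) which.min(abs(track_b$t - ti)), integer(1))
  dx <- track_a$x - track_b$x[idx]
  dy <- track_a$y - track_b$y[idx]
  dz <- if (use_z) track_a$z - track_b$z[idx] else 0
  d <- sqrt(dx^2 + dy^2 + dz^2)
  d_final <- mean(utils::tail(d, tail_frames))
  out <- instantaneous_velocity(tibble(t = t, d = d))
  out$d_norm <- out$d / d_final
  out <- out[, c("t", "d", "d_norm", "velocity", "one_sided")]
  attr(out, "d_final") <- d_final
  class(out) <- c("separation_series", class(out))
  out
}

#' @export
autoplot.separation_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$d_norm, .data$velocity)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "normalized separation d / d_final",
                  y = "separation velocity (um/s)") +
    ggplot2::theme_minimal()
}

#' Steady-state geometry of one or two asters in an explant
#'
#' Boundary distances use the projected (x, y) radial distance,
#' `b_i = R - |p_i - center|`; the inter-aster distance `d` is Euclidean
#' (3D when `z` is present); `M = 2R - b1 - b2` is the maximum projected
#' inter-aster distance.
#'
#' @param positions Data frame of 1 or 2 aster positions, columns `x`, `y`
#'   and optionally `z` (um).
#' @param disk An [explant_disk()].
#' @return A one-row tibble: `R`, `b1` (and `b2`, `d`, `M` for a pair).
#' @examples
#' steady_state_geometry(data.frame(x = c(-10, 10), y = 0), explant_disk(30))
#' @export
steady_state_geometry <- function(positions, disk) {
  stopifnot(is.data.frame(positions), nrow(positions) %in% c(1, 2),
            inherits(disk, "explant_disk"))
  r <- sqrt((positions$x - disk$center[1])^2 +
              (positions$y - disk$center[2])^2)
  if (any(r > disk$radius))
    abort("Positions must lie inside the disk (projected).")
  b <- disk$radius - r
  if (nrow(positions) == 1)
    return(tibble(R = disk$radius, b1 = b[1]))
  dz <- if ("z" %in% names(positions))
    positions$z[1] - positions$z[2] else 0
  d <- sqrt(diff(positions$x)^2 + diff(positions$y)^2 + dz^2)
  tibble(R = disk$radius, b1 = b[1], b2 = b[2], d = d,
         M = 2 * disk$radius - b[1] - b[2])
}

#' Align perturbation-response series and test group differences
#'
#' Time-aligns replicate separation series to the perturbation instant
#' (t = 0), estimates each group's initial response slope by least-squares
#' regression of `d` on `t` over `(0, slope_window]` (with a confidence
#' interval), and compares final separations between the two groups by a
#' two-sided rank test on the pooled last `tail_frames` samples per
#' replicate. Significance level 0.05, fixed a priori.
#'
#' @param data Tibble with columns `group`, `replicate`, `t` (s), `d` (um).
#'   Two groups; at least 3 replicates each.
#' @param t_perturb Perturbation time on the input clock (s).
#' @param slope_window Length of the initial-response window (s).
#' @param tail_frames Trailing samples per replicate pooled for the final-
#'   distance comparison. Default 12.
#' @param paired Use the paired signed-rank variant instead of the unpaired
#'   rank-sum (requires equal replicate structure). Default `FALSE`.
#' @return An object of class `perturbation_test`: `aligned` (tibble),
#'   `slopes` (per group: estimate, ci_lo, ci_hi), `rank_test` (`htest`),
#'   `p_value`, `significant` (at 0.05).
#' @export
align_and_test_perturbation <- function(data, t_perturb, slope_window,
                                        tail_frames = 12, paired = FALSE) {
  stopifnot(is.data.frame(data),
            all(c("group", "replicate", "t", "d") %in% names(data)))
  groups <- unique(data$group)
  if (length(groups) != 2) abort("Exactly two groups are required.")
  nrep <- tapply(data$replicate, data$group,
                 function(r) length(unique(r)))
  if (any(nrep < 3)) abort("At least 3 replicates per group are required.")
  if (slope_window <= 0) abort("`slope_window` must be positive.")
  aligned <- dplyr::mutate(as_tibble(data), t = .data$t - t_perturb)
  slopes <- aligned |>
    dplyr::filter(.data$t > 0, .data$t <= slope_window) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) abort("Empty or too-short slope window.")
      fit <- lm(d ~ t, data = d)
      ci <- confint(fit, "t", level = 0.95)
      tibble(slope = coef(fit)[["t"]], ci_lo = ci[1], ci_hi = ci[2])
    }) |>
    dplyr::ungroup()
  tails <- aligned |>
    dplyr::group_by(.data$group, .data$replicate) |>
    dplyr::slice_tail(n = tail_frames) |>
    dplyr::ungroup()
  d1 <- tails$d[tails$group == groups[1]]
  d2 <- tails$d[tails$group == groups[2]]
  ht <- if (paired) wilcox.test(d1, d2, paired = TRUE, exact = FALSE)
        else wilcox.test(d1, d2, exact = FALSE)
  structure(list(aligned = aligned, slopes = slopes, rank_test = ht,
                 p_value = ht$p.value, significant = ht$p.value < 0.05,
                 alpha = 0.05),
            class = "perturbation_test")
}

#' @export
print.perturbation_test <- function(x, ...) {
  cat("<perturbation_test>\n")
  print(x$slopes)
  cat(sprintf("rank test p = %.4g (%ssignificant at 0.05)\n", x$p_value,
              if (x$significant) "" else "not "))
  invisible(x)
}

#' @export
tidy.perturbation_test <- function(x, ...) x$slopes

#' @export
glance.perturbation_test <- function(x, ...) {
  tibble(p_value = x$p_value, significant = x$significant,
         method = x$rank_test$method)
}

#' Aster displacement after UV ablation, in the ablation-ellipse frame
#'
#' For each replicate the origin is the aster position five frames before
#' the ablation; subsequent positions are expressed in the coordinate frame
#' spanned by the two ellipse axes. The per-time mean and SD across
#' replicates are returned alongside the per-replicate series.
#'
#' @param data Tibble with columns `replicate`, `t` (s), `x`, `y` (um), on a
#'   shared frame grid.
#' @param t_ablation Ablation time (s); at least 5 frames must precede it in
#'   every replicate.
#' @param ellipse_axes 2 x 2 matrix whose rows are the orthogonal unit major
#'   and minor axes of the ablation ellipse. Default the identity (lab
#'   frame).
#' @return A list with `series` (tibble: `replicate`, `t`, `dx`, `dy`) and
#'   `summary` (tibble: `t`, `mean_dx`, `sd_dx`, `mean_dy`, `sd_dy`).
#' @export
ablation_displacement <- function(data, t_ablation,
                                  ellipse_axes = diag(2)) {
  stopifnot(is.data.frame(data),
            all(c("replicate", "t", "x", "y") %in% names(data)))
  ellipse_axes <- as.matrix(ellipse_axes)
  stopifnot(dim(ellipse_axes) == c(2, 2))
  nrm <- sqrt(rowSums(ellipse_axes^2))
  if (any(abs(nrm - 1) > 1e-8) ||
      abs(sum(ellipse_axes[1, ] * ellipse_axes[2, ])) > 1e-8)
    abort("`ellipse_axes` rows must be orthogonal unit vectors.")
  series <- data |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$t), ]
      pre <- which(d$t < t_ablation)
      if (length(pre) < 5)
        abort("At least 5 frames before the ablation are required.")
      o <- pre[length(pre) - 4]  # 5 frames before ablation
      rel <- cbind(d$x - d$x[o], d$y - d$y[o])
      proj <- rel %*% t(ellipse_axes)
      tibble(t = d$t - t_ablation, dx = proj[, 1], dy = proj[, 2])
    }) |>
    dplyr::ungroup()
  summary <- series |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(mean_dx = mean(.data$dx), sd_dx = sd(.data$dx),
                     mean_dy = mean(.data$dy), sd_dy = sd(.data$dy),
                     .groups = "drop")
  list(series = series, summary = summary)
}
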