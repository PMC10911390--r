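#' Microtubule density profile
#'
#' The radial microtubule distribution of an aster, modelled as a
#' mono-exponential decay `exp(-r / lambda)`. This single profile underlies
#' both the measured intensity decay (fitted decay length ~12 um) and the
#' repulsive force laws.
#'
#' @param r Distance from the aster center (um), non-negative. Vectorised.
#' @param lambda Decay length (um), positive.
#' @return Density values in (0, 1].
#' @examples
#' mt_density(0, 15)          # 1 at the centrosome
#' mt_density(15, 15)         # 1/e at one decay length
#' @export
mt_density <- function(r, lambda) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0))
    abort("`r` must be non-negative (um).")
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    abort("`lambda` must be a single positive number (um).")
  exp(-r / lambda)
}

#' Short-range slip (inhibition) factor
#'
#' Force generation is inhibited at short range: microtubules shorter than
#' the slip length `x0` push inefficiently (buckling/slippage), captured by
#' the factor `r^2 / (x0^2 + r^2)`, which vanishes at contact and approaches
#' 1 at long range.
#'
#' @param r Distance (um), non-negative. Vectorised.
#' @param x0 Slip length (um), positive.
#' @return Values in `[0, 1)`.
#' @examples
#' slip_factor(0, 15)   # 0 at contact
#' slip_factor(15, 15)  # 0.5 at r = x0
#' @export
slip_factor <- function(r, x0) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0))
    abort("`r` must be non-negative (um).")
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) || x0 <= 0)
    abort("`x0` must be a single positive number (um).")
  r^2 / (x0^2 + r^2)
}

#' Repulsive force magnitude
#'
#' The magnitude of the effective repulsion at a given separation:
#' amplitude x slip factor x microtubule density. `kind = "wall"` uses the
#' boundary parameters (`f0`, `lambda_wall`, `x0_wall`); `kind = "pair"` the
#' aster–aster parameters (`f1`, `lambda_aster`, `x0_aster`). The profile is
#' zero at contact, rises to a single interior maximum, and decays
#' exponentially at long range.
#'
#' @param kind `"wall"` or `"pair"`.
#' @param distance Separation (um), non-negative. Vectorised.
#' @param params An [aster_params()] object.
#' @return Non-negative force magnitudes (model force units).
#' @examples
#' force_magnitude("wall", 15, aster_params())
#' @export
force_magnitude <- function(kind = c("wall", "pair"), distance,
                            params = aster_params()) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "aster_params"))
  if (kind == "wall") {
    params$f0 * slip_factor(distance, params$x0_wall) *
      mt_density(distance, params$lambda_wall)
  } else {
    params$f1 * slip_factor(distance, params$x0_aster) *
      mt_density(distance, params$lambda_aster)
  }
}

#' Net force on each aster in a disk
#'
#' Sums, for each aster: (i) the wall repulsion, acting through the mirror
#' charge at the nearest boundary point and directed inward along the radial,
#' with magnitude [force_magnitude()] at the boundary separation b (or, in
#' `"image"` mode, the pair law at the image distance 2b); (ii) the pairwise
#' repulsion along each inter-aster axis, obeying Newton's third law; and
#' (iii) an optional noise force `delta_f` along the supplied unit vectors.
#' At the exact disk center the inward direction is degenerate and the wall
#' force is zero (continuity limit of the radial field).
#'
#' @param asters A data frame with columns `x`, `y` (um), one row per aster;
#'   all strictly inside the disk.
#' @param disk An [explant_disk()].
#' @param params An [aster_params()].
#' @param noise_vectors Optional n x 2 matrix of unit vectors, one row per
#'   aster; `NULL` (default) applies no noise.
#' @return A tibble with columns `id`, `fx`, `fy` (model force units).
#' @examples
#' disk <- explant_disk(40)
#' net_forces(data.frame(x = 25, y = 0), disk, aster_params())
#' @export
net_forces <- function(asters, disk, params = aster_params(),
                       noise_vectors = NULL) {
  stopifnot(is.data.frame(asters), inherits(disk, "explant_disk"),
            inherits(params, "aster_params"))
  if (!all(c("x", "y") %in% names(asters)))
    abort("`asters` must have columns `x` and `y`.")
  n <- nrow(asters)
  px <- asters$x - disk$center[1]
  py <- asters$y - disk$center[2]
  r <- sqrt(px^2 + py^2)
  if (any(r >= disk$radius))
    abort("All asters must lie strictly inside the disk.")
  fx <- numeric(n); fy <- numeric(n)
  # wall term
  for (i in seq_len(n)) {
    if (r[i] > 1e-12) {
      b <- disk$radius - r[i]
      mag <- if (params$wall_distance_mode == "image")
        params$f0 * slip_factor(2 * b, params$x0_wall) *
          mt_density(2 * b, params$lambda_wall)
      else force_magnitude("wall", b, params)
      fx[i] <- fx[i] - mag * px[i] / r[i]
      fy[i] <- fy[i] - mag * py[i] / r[i]
    }
  }
  # pair terms
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        dx <- asters$x[i] - asters$x[j]
        dy <- asters$y[i] - asters$y[j]
        d <- sqrt(dx^2 + dy^2)
        if (d > 1e-12) {
          mag <- force_magnitude("pair", d, params)
          fx[i] <- fx[i] + mag * dx / d; fy[i] <- fy[i] + mag * dy / d
          fx[j] <- fx[j] - mag * dx / d; fy[j] <- fy[j] - mag * dy / d
        }
      }
    }
  }
  if (!is.null(noise_vectors)) {
    noise_vectors <- as.matrix(noise_vectors)
    stopifnot(nrow(noise_vectors) == n, ncol(noise_vectors) == 2)
    nrm <- sqrt(rowSums(noise_vectors^2))
    if (any(abs(nrm - 1) > 1e-8))
      abort("`noise_vectors` rows must have unit length.")
    fx <- fx + params$delta_f * noise_vectors[, 1]
    fy <- fy + params$delta_f * noise_vectors[, 2]
  }
  tibble(id = if ("id" %in% names(asters)) asters$id else seq_len(n),
         fx = fx, fy = fy)
}
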