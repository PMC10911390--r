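#' Model parameters for the repulsive aster potential
#'
#' Bundles every constant of the slip-inhibited exponential repulsion model:
#' the boundary and aster–aster force amplitudes, the decay lengths of the
#' underlying microtubule density, the slip lengths below which force
#' generation is inhibited, the noise amplitude, the mobility mapping force
#' to velocity, and the Euler integration step. Defaults are the published
#' model values.
#'
#' @param f0 Boundary (wall) force amplitude, model force units. Default 0.007.
#' @param f1 Aster–aster force amplitude, model force units. Default 0.005.
#' @param lambda_wall Decay length of the aster–boundary interaction density
#'   (um). Default 15.
#' @param lambda_aster Decay length of the aster–aster interaction density
#'   (um). Default 12.
#' @param x0_wall Slip length for aster–boundary interactions (um); the
#'   repulsion is suppressed by `r^2 / (x0^2 + r^2)` below this scale.
#'   Default 15.
#' @param x0_aster Slip length for aster–aster interactions (um). Default 15.
#' @param delta_f Noise force amplitude, model force units. Default 5e-4.
#' @param gamma Effective mobility (inverse drag), so velocity = gamma * force.
#'   Default 1 (model units; no mapping to seconds is attempted).
#' @param dt Euler integration step, model time units. Default 0.1.
#' @param wall_distance_mode How the wall force is evaluated: `"image"`
#'   (default) evaluates the wall force law at the full mirror-image distance
#'   2b, where b is the perpendicular boundary separation -- the reading under
#'   which a centered aster pair 2 um apart separates as observed, rather than
#'   being crushed together by the centering wall force; `"separation"`
#'   evaluates it at b itself, the mirror image defining direction only.
#' @param noise_sqrt_dt If `TRUE`, the noise displacement is scaled by
#'   `sqrt(dt)` (diffusive scaling) instead of `dt` (the published scheme).
#'
#' @return An object of class `aster_params` (a named list).
#' @examples
#' p <- aster_params()
#' p$f0 / p$f1  # boundary repulsion is 40% stronger than aster-aster
#' @export
aster_params <- function(f0 = 0.007, f1 = 0.005,
                         lambda_wall = 15, lambda_aster = 12,
                         x0_wall = 15, x0_aster = 15,
                         delta_f = 5e-4, gamma = 1, dt = 0.1,
                         wall_distance_mode = c("image", "separation"),
                         noise_sqrt_dt = FALSE) {
  wall_distance_mode <- match.arg(wall_distance_mode)
  for (nm in c("lambda_wall", "lambda_aster", "x0_wall", "x0_aster")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      abort(sprintf("`%s` must be a single positive number.", nm))
  }
  for (nm in c("f0", "f1", "delta_f", "gamma", "dt")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort(sprintf("`%s` must be a single non-negative number.", nm))
  }
  structure(
    list(f0 = f0, f1 = f1,
         lambda_wall = lambda_wall, lambda_aster = lambda_aster,
         x0_wall = x0_wall, x0_aster = x0_aster,
         delta_f = delta_f, gamma = gamma, dt = dt,
         wall_distance_mode = wall_distance_mode,
         noise_sqrt_dt = noise_sqrt_dt),
    class = "aster_params")
}

#' @export
print.aster_params <- function(x, ...) {
  cat("<aster_params>\n")
  num <- vapply(x, function(v) is.numeric(v), logical(1))
  for (nm in names(x)) {
    cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Circular explant domain
#'
#' @param radius Disk radius R (um), positive.
#' @param center Length-2 numeric, disk center (um). Default the origin.
#' @return An object of class `explant_disk`.
#' @examples
#' explant_disk(40)
#' @export
explant_disk <- function(radius, center = c(0, 0)) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    abort("`radius` must be a single positive number (um).")
  if (!is.numeric(center) || length(center) != 2L || anyNA(center))
    abort("`center` must be a numeric vector of length 2.")
  structure(list(center = as.numeric(center), radius = radius),
            class = "explant_disk")
}

#' @export
print.explant_disk <- function(x, ...) {
  cat(sprintf("<explant_disk> center (%g, %g), radius %g um\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Read model parameters from a flat YAML config file
#'
#' The file holds flat keys named exactly as the [aster_params()] arguments;
#' unknown keys raise an error, missing keys take the package defaults. The
#' resolved parameter set is reported via `message()` so every run logs the
#' configuration actually used.
#'
#' @param path Path to a YAML file.
#' @param quiet If `TRUE`, suppress the resolved-parameter log line.
#' @return An `aster_params` object.
#' @export
read_model_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(aster_params))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    abort(sprintf("Unknown config keys: %s (expected a subset of: %s)",
                  paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  p <- do.call(aster_params, vals)
  if (!quiet)
    inform(paste0("Resolved model parameters: ",
                  paste(sprintf("%s=%s", names(p),
                                vapply(p, function(v) format(v)[1], "")),
                        collapse = ", ")))
  p
}
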