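# shared fixtures, built in code

quiet_sim <- function(...) suppressMessages(simulate_asters(...))

params_sep <- function(...) aster_params(wall_distance_mode = "separation", ...)

# deterministic default parameter set (no noise)
params_det <- function(...) aster_params(delta_f = 0, ...)

# n points at given radii/angles around the origin
polar_points <- function(r, theta) {
  tibble::tibble(x = r * cos(theta), y = r * sin(theta))
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
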