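#' Construct the shared environmental state
#'
#' A single scalar optimum, initialized at 70, moves directionally at
#' `dEdt` units per generation inside the closed range `[0, 140]`. All
#' patches experience the identical trajectory. At the rates studied
#' (8e-3 down to 2e-4 units/generation) the optimum drifts at most 8 units
#' over a 1000-generation run, so the bounds are unreachable in practice;
#' they are enforced by reflection for robustness with user-chosen rates.
#'
#' @param value starting optimum (default 70).
#' @param dEdt per-generation rate of change (non-negative; the signed
#'   direction is carried separately and flips on reflection).
#' @param bounds length-2 numeric range (default `c(0, 140)`).
#' @param direction +1 (increasing, default) or -1.
#' @return an object of class `gn_environment`.
#' @export
environment_state <- function(value = 70, dEdt = 8e-3, bounds = c(0, 140),
                              direction = 1) {
  check_scalar(dEdt, "dEdt", lo = 0)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2], direction %in% c(-1, 1))
  check_scalar(value, "value", lo = bounds[1], hi = bounds[2])
  structure(list(value = value, dEdt = dEdt, bounds = as.numeric(bounds),
                 direction = direction),
            class = "gn_environment")
}

#' Advance the environment by one generation
#'
#' Adds `direction * dEdt` to the optimum; if the result would leave the
#' bounds the trajectory reflects off the boundary and the direction
#' reverses.
#'
#' @param env a [environment_state()] object.
#' @return the updated `gn_environment`.
#' @export
step_environment <- function(env) {
  stopifnot(inherits(env, "gn_environment"))
  v <- env$value + env$direction * env$dEdt
  if (v > env$bounds[2]) {
    v <- 2 * env$bounds[2] - v
    env$direction <- -env$direction
  } else if (v < env$bounds[1]) {
    v <- 2 * env$bounds[1] - v
    env$direction <- -env$direction
  }
  env$value <- v
  env
}
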