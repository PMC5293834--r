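# Retrosplenial cortex: head-direction population, allocentric-to-egocentric
# goal-direction transformation, per-strategy confidence dynamics and softmax
# strategy selection.

#' Head-direction state
#'
#' The agent's internal compass: the true heading plus a 360-unit HD
#' population encoding it (sigma = 10, noise + normalization applied).
#'
#' @param heading Allocentric heading, degrees.
#' @param noise A `noise_model`.
#' @return List with `heading` and `population`.
#' @export
head_direction_state <- function(heading, noise = noise_model(0)) {
  structure(list(
    heading = wrap_angle(heading),
    population = add_noise_and_normalize(
      encode_population(heading, sigma = 10, n_units = 360L), noise)),
    class = "head_direction_state")
}

#' Transform an allocentric goal direction to an egocentric one
#'
#' Re-encodes the AGD population relative to the head direction: the EGD
#' population carries `wrap(AGD peak - HD peak)`. 0 means the goal is dead
#' ahead; the sign follows the package's counter-clockwise-positive angle
#' convention (positive = goal counter-clockwise of the heading).
#'
#' @param agd AGD `cell_population`.
#' @param hd A `head_direction_state`.
#' @param noise A `noise_model` for the EGD population.
#' @return EGD `cell_population` (360 units, normalized).
#' @export
transform_to_egocentric <- function(agd, hd, noise = noise_model(0)) {
  egd_dir <- wrap_angle(population_peak(agd) - population_peak(hd$population))
  add_noise_and_normalize(encode_population(egd_dir, sigma = 10, n_units = 360L),
                          noise)
}

#' Per-strategy confidence state
#'
#' Confidence values in \[0, 1\], one per enabled strategy, together with the
#' decay and increment parameters of the confidence dynamics. All strategies
#' start at 0.8.
#'
#' @param strategies Character vector of strategy ids.
#' @param params Named list of dynamics parameters; see [nav_config()].
#' @param initial Initial confidence value.
#' @export
confidence_state <- function(strategies,
                             params = nav_config()$confidence,
                             initial = params$initial) {
  values <- stats::setNames(rep(initial, length(strategies)), strategies)
  structure(list(values = values, params = params), class = "confidence_state")
}

.confidence_events <- c("step", "approaching", "distance_increased",
                        "progress", "heading_aligned", "stuck")

#' Update the confidence state for one time step
#'
#' Dynamics per step: every value decays by `lambda_default`; if the agent's
#' distance to the goal decreased ("approaching") the active strategy gains
#' `u_default`, if it increased the active strategy decays by `lambda_dist`;
#' on route progress the active strategy gains `u_progress`; when the heading
#' is aligned (within 10 degrees) with the goal-cue direction the active
#' strategy gains the alignment bonus (`u_ego` or `u_direction`, selected via
#' `params$u_align`); when stuck the active strategy decays by `lambda_stuck`
#' and all others gain `u_stuck`. Values are clamped to \[0, 1\].
#'
#' @param state A `confidence_state`.
#' @param events Character vector drawn from `step`, `approaching`,
#'   `distance_increased`, `progress`, `heading_aligned`, `stuck`.
#' @param active_strategy Id of the currently applied strategy.
#' @return The updated `confidence_state`.
#' @export
update_confidence <- function(state, events, active_strategy) {
  if (length(bad <- setdiff(events, .confidence_events))) {
    stop("update_confidence: unknown event(s): ", paste(bad, collapse = ", "))
  }
  p <- state$params
  v <- state$values
  act <- active_strategy
  if (!act %in% names(v)) stop("update_confidence: unknown strategy ", act)
  if ("step" %in% events) v <- v * (1 - p$lambda_default)
  if ("approaching" %in% events) v[act] <- v[act] + p$u_default
  if ("distance_increased" %in% events) v[act] <- v[act] * (1 - p$lambda_dist)
  if ("progress" %in% events) v[act] <- v[act] + p$u_progress
  if ("heading_aligned" %in% events) v[act] <- v[act] + p$u_align
  if ("stuck" %in% events) {
    v[act] <- v[act] * (1 - p$lambda_stuck)
    v[setdiff(names(v), act)] <- v[setdiff(names(v), act)] + p$u_stuck
  }
  state$values <- pmin(pmax(v, 0), 1)
  state
}

#' Softmax probabilities over confidence values
#'
#' `p_i = exp(c_i / T) / sum_j exp(c_j / T)`. `T = 1` is the plain softmax;
#' lower temperatures sharpen the choice toward the most trusted strategy.
#'
#' @param state A `confidence_state`.
#' @param temperature Softmax temperature (> 0).
#' @return Named probability vector summing to 1.
#' @export
softmax_probabilities <- function(state, temperature = 1) {
  if (temperature <= 0) stop("softmax_probabilities: temperature must be > 0")
  v <- state$values
  if (length(v) == 0L) stop("softmax_probabilities: no enabled strategies")
  e <- exp((v - max(v)) / temperature)
  e / sum(e)
}

#' Draw a navigation strategy from the softmax distribution
#'
#' Categorical sampling with a single uniform draw over the cumulative
#' partition of \[0, 1\] in strategy-id order. Deterministic given the RNG
#' state, confidence values and temperature.
#'
#' @inheritParams softmax_probabilities
#' @return List with `chosen` (strategy id) and `probabilities`.
#' @export
select_strategy <- function(state, temperature = 1) {
  p <- softmax_probabilities(state, temperature)
  r <- stats::runif(1)
  idx <- min(length(p), findInterval(r, cumsum(p), left.open = TRUE) + 1L)
  chosen <- names(p)[idx]
  list(chosen = chosen, probabilities = p)
}
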