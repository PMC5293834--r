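# Global model configuration. One flat place for every tunable constant;
# experiment runners override individual entries per experiment.

#' Default model configuration
#'
#' Returns the full parameter set of the model. Entries mirror the model's
#' three groups: tuning/noise of the population code, confidence dynamics and
#' arbitration, and the agent's kinematics. Individual values can be
#' overridden via `...` (named, nested lists are merged shallowly per group).
#'
#' Parameter summary (units in brackets):
#' * `sigma` \[deg\]: global tuning width of all populations (10).
#' * `noise_sd`: zero-mean activity noise sd (0.05); `noise_literal` switches
#'   to the activity-centred variance-5 reading (off by default).
#' * `sensory$D` \[length\]: distance-to-activation constant of the cue cells
#'   (3.0); `sensory$field_of_view` \[deg\]: 360 (full surround vision).
#' * `confidence`: decay rates `lambda_*`, increments `u_*`, the initial
#'   value 0.8, the alignment tolerance (10 deg) and the per-experiment
#'   alignment bonus `u_align`.
#' * `arbitration`: decision period `period` (steps between softmax draws),
#'   softmax `temperature`, `stuck_threshold` (steps of dwell near a single
#'   place cell that count as stuck), and the 25/75 initial strategy draw of
#'   the starmaze probe.
#' * `agent`: `body_radius`, `speed_scale` (length per step per unit wheel
#'   velocity), `wheelbase` \[length\].
#' * `capture_radius` \[length\]: radius within which a landmark or cue
#'   counts as reached (0.5).
#' * `turn_align_tol` \[deg\]: tolerance at which a replayed turn command is
#'   considered complete (15).
#'
#' @param ... Named overrides, e.g. `nav_config(noise_sd = 0)` or
#'   `nav_config(arbitration = list(temperature = 0.2))`.
#' @return Nested named list.
#' @export
nav_config <- function(...) {
  cfg <- list(
    sigma = 10,
    n_units = 360L,
    noise_sd = 0.05,
    noise_literal = FALSE,
    sensory = list(D = 3.0, field_of_view = 360),
    confidence = list(
      initial = 0.8,
      lambda_default = 0.02,
      lambda_dist = 0.002,
      lambda_stuck = 0.02,
      u_default = 0.025,
      u_ego = 0.05,
      u_progress = 0.25,
      u_direction = 0.005,
      u_stuck = 0.01,
      u_align = 0.05,
      align_tol = 10
    ),
    arbitration = list(
      period = 10L,
      temperature = 0.0275,
      stuck_threshold = 50L,
      stuck_radius = 1.0,
      initial_draw = c(allocentric = 0.25, route_sequential = 0.75)
    ),
    agent = list(body_radius = 0.15, speed_scale = 0.2, wheelbase = 0.3,
                 wall_turn = 15),
    capture_radius = 0.5,
    turn_align_tol = 15,
    step_budget = list(starmaze = 2000L, vista = 5000L)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

nav_noise <- function(config) {
  noise_model(config$noise_sd, literal = isTRUE(config$noise_literal))
}
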