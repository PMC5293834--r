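# Posterior parietal cortex: sensory cue vectors, egocentric cue direction
# (ECD) cells, goal-modulated EGCD cells, the route strategies' movement
# machinery, movement cells and conjunctive HD x ECD cells.

#' Sense environmental cues
#'
#' For each visible cue, the Euclidean distance and the egocentric direction
#' `wrap(bearing(agent -> cue) - heading)`. Cues outside the field of view
#' are dropped. A cue may not coincide with the agent's position.
#'
#' @param agent An `agent_state` (or any list with `position`, `heading`).
#' @param cues data.frame with columns `id`, `x`, `y`.
#' @param params Sensory parameter list (`D`, `field_of_view`).
#' @return data.frame with columns `id`, `distance`, `direction`.
#' @export
sense_cues <- function(agent, cues, params = nav_config()$sensory) {
  if (nrow(cues) == 0L) {
    return(data.frame(id = character(), distance = numeric(), direction = numeric()))
  }
  dx <- cues$x - agent$position[1]
  dy <- cues$y - agent$position[2]
  d <- sqrt(dx^2 + dy^2)
  if (any(d == 0)) stop("sense_cues: cue at agent position")
  dir <- wrap_angle(atan2(dy, dx) * 180 / pi - agent$heading)
  out <- data.frame(id = as.character(cues$id), distance = d, direction = dir)
  out[abs(out$direction) <= params$field_of_view / 2, , drop = FALSE]
}

#' Egocentric cue direction population
#'
#' Each unit sums a distance-attenuated Gaussian response over all sensed
#' cues: `(D / d_c) * G(pref_i, theta_c, sigma)`. With no cues the population
#' is all-zero and flagged degenerate (no normalization is applied).
#'
#' @param cue_vectors Output of [sense_cues()].
#' @param params Sensory parameter list.
#' @param noise A `noise_model`.
#' @param normalize Apply the noise + max-normalization stage (raw
#'   activations are exposed with `normalize = FALSE`).
#' @return A `cell_population`; attribute `degenerate` is TRUE when empty.
#' @export
ecd_population <- function(cue_vectors, params = nav_config()$sensory,
                           noise = noise_model(0), normalize = TRUE) {
  pref <- 0:359
  if (nrow(cue_vectors) == 0L) {
    pop <- cell_population(pref, rep(0, 360))
    attr(pop, "degenerate") <- TRUE
    return(pop)
  }
  if (any(cue_vectors$distance <= 0)) stop("ecd_population: non-positive distance")
  a <- rep(0, 360)
  for (k in seq_len(nrow(cue_vectors))) {
    a <- a + (params$D / cue_vectors$distance[k]) *
      gaussian_tuning(pref, cue_vectors$direction[k], 10)
  }
  pop <- cell_population(pref, a)
  if (normalize) pop <- add_noise_and_normalize(pop, noise)
  pop
}

# 360 x 360 broad Gaussian weight matrix W[i, m] = G(pref_i, pref_m, 80),
# connecting every EGD unit to every EGCD unit. Built once and cached.
.refnav_cache <- new.env(parent = emptyenv())

egcd_weight_matrix <- function() {
  if (is.null(.refnav_cache$W)) {
    pref <- 0:359
    d <- wrap_angle(outer(pref, pref, "-"))
    .refnav_cache$W <- exp(-d^2 / 80^2)
  }
  .refnav_cache$W
}

#' Goal-modulated egocentric cue direction population (EGCD)
#'
#' Modulates the ECD signal by the EGD signal through a broad (sigma = 80)
#' Gaussian weight matrix: strongly active EGD units (> 0.5) excite EGCD
#' units near their direction, weak EGD units inhibit. Cues angularly close
#' to the goal direction are thereby enhanced, all others suppressed.
#' Negative results are clamped to 0; the population is max-normalized when
#' any activity remains, otherwise flagged degenerate.
#'
#' @param ecd,egd `cell_population`s of 360 units.
#' @return EGCD `cell_population`.
#' @export
egcd_modulate <- function(ecd, egd) {
  if (length(ecd$activities) != 360L || length(egd$activities) != 360L) {
    stop("egcd_modulate: populations must have 360 units")
  }
  W <- egcd_weight_matrix()
  e <- egd$activities
  # sum_m e_m W[i,m] - sum_{m: e_m <= 0.5} e_m   (since e*(W-1) = e*W - e)
  modulation <- as.vector(W %*% e) - sum(e[e <= 0.5])
  a <- ecd$activities * modulation
  a[a < 0] <- 0
  pop <- cell_population(0:359, a)
  if (max(a) > 0) {
    pop$activities <- a / max(a)
  } else {
    attr(pop, "degenerate") <- TRUE
  }
  pop
}

#' EGCD population for the cue-following strategy
#'
#' A pure Gaussian bump (sigma = 10) at the goal cue's egocentric direction;
#' the distance is ignored because route goal cues are taken to be visible
#' from everywhere.
#'
#' @param goal_cue One-row cue vector (needs column `direction`).
#' @return EGCD `cell_population` of 360 units.
#' @export
egcd_cue_following <- function(goal_cue) {
  encode_population(goal_cue$direction[1], sigma = 10, n_units = 360L)
}

#' Route memory
#'
#' Stored route for the two route-centric strategies. For the sequential
#' egocentric kind, `sequence` is a data.frame of choice points with columns
#' `landmark`, `command` (+/-180) and `turn_amount` (the signed bend recorded
#' in training, degrees); replay is positional over junction encounters, so a
#' route trained from one start replays coherently from another. For the
#' cue-following kind, `sequence` is a character vector of landmark/cue ids
#' to visit in order.
#'
#' @param kind `"sequential_egocentric"` or `"cue_following"`.
#' @param sequence See description.
#' @param junction_ids Choice-point landmark ids that trigger command
#'   consumption (sequential kind only).
#' @export
route_memory <- function(kind = c("sequential_egocentric", "cue_following"),
                         sequence, junction_ids = character()) {
  kind <- match.arg(kind)
  if (kind == "sequential_egocentric") {
    stopifnot(is.data.frame(sequence),
              all(c("landmark", "command", "turn_amount") %in% names(sequence)))
    if (nrow(sequence) && !all(sequence$command %in% c(-180, 180))) {
      stop("route_memory: sequential commands must be -180 or +180")
    }
  }
  structure(list(kind = kind, sequence = sequence,
                 junction_ids = junction_ids,
                 progress_index = 0L,
                 turning = FALSE, turn_sign = 0, target_heading = NA_real_,
                 last_trigger = NA_character_),
            class = "route_memory")
}

#' One control step of the sequential egocentric strategy
#'
#' The agent travels straight until it encounters a choice-point landmark;
#' there the next stored turn command is executed as a saturated one-sided
#' drive until the heading has rotated by the stored bend (within
#' `turn_tol`), after which straight travel resumes and the progress index
#' advances. Returns `NULL` once the stored sequence is exhausted.
#'
#' @param route A `route_memory` of the sequential kind.
#' @param agent An `agent_state`.
#' @param map A `cognitive_map` providing landmark positions.
#' @param capture_radius Trigger radius around choice points.
#' @param turn_tol Heading tolerance ending a turn, degrees.
#' @return List with `mv` (a `movement_cell_activity` override or `NULL`
#'   when the sequence is complete) and the updated `route`.
#' @export
sequential_step <- function(route, agent, map, capture_radius = 0.5,
                            turn_tol = 15) {
  stopifnot(inherits(route, "route_memory"),
            route$kind == "sequential_egocentric")
  seq_df <- route$sequence
  if (route$turning) {
    if (abs(wrap_angle(route$target_heading - agent$heading)) <= turn_tol) {
      route$turning <- FALSE
      route$progress_index <- route$progress_index + 1L
    } else {
      mv <- if (route$turn_sign < 0) movement_cell_activity(1, 0, 0)
            else movement_cell_activity(0, 0, 1)
      return(list(mv = mv, route = route))
    }
  }
  if (route$progress_index >= nrow(seq_df)) {
    return(list(mv = NULL, route = route))
  }
  near <- vapply(route$junction_ids, function(id) {
    sqrt(sum((landmark_position(map, id) - agent$position)^2)) <= capture_radius
  }, logical(1))
  hit <- route$junction_ids[near]
  if (length(hit) && !identical(hit[1], route$last_trigger)) {
    i <- route$progress_index + 1L
    route$turning <- TRUE
    route$turn_sign <- sign(seq_df$turn_amount[i])
    route$target_heading <- wrap_angle(agent$heading + seq_df$turn_amount[i])
    route$last_trigger <- hit[1]
    mv <- if (route$turn_sign < 0) movement_cell_activity(1, 0, 0)
          else movement_cell_activity(0, 0, 1)
    return(list(mv = mv, route = route))
  }
  if (!length(hit)) route$last_trigger <- NA_character_
  list(mv = movement_cell_activity(0, 1, 0), route = route)
}

#' Record a sequential egocentric route on a supervised traversal
#'
#' Walks a planned landmark route geometrically and stores a turn command at
#' every intermediate landmark where the route bends by more than
#' `turn_tol`: the choice points and signed bends that the replay machinery
#' of [sequential_step()] consumes.
#'
#' @param map A `cognitive_map`.
#' @param route_ids Ordered landmark ids of the trained traversal.
#' @param junction_ids Choice-point landmarks of the environment.
#' @param turn_tol Minimum bend recorded as a turn, degrees.
#' @return A `route_memory` of the sequential kind.
#' @export
record_sequential_route <- function(map, route_ids, junction_ids,
                                    turn_tol = 15) {
  rows <- list()
  for (i in seq_along(route_ids)[-c(1, length(route_ids))]) {
    p_prev <- landmark_position(map, route_ids[i - 1])
    p_here <- landmark_position(map, route_ids[i])
    p_next <- landmark_position(map, route_ids[i + 1])
    bend <- wrap_angle(bearing(p_here, p_next) - bearing(p_prev, p_here))
    if (abs(bend) > turn_tol) {
      rows[[length(rows) + 1L]] <- data.frame(
        landmark = route_ids[i],
        command = sign(bend) * 180,
        turn_amount = bend)
    }
  }
  sequence <- if (length(rows)) do.call(rbind, rows) else
    data.frame(landmark = character(), command = numeric(), turn_amount = numeric())
  route_memory("sequential_egocentric", sequence, junction_ids)
}

#' Movement-cell activity
#'
#' Three non-negative drives: turn toward negative egocentric angles
#' (`mv_left`), straight ahead (`mv_forward`), turn toward positive
#' egocentric angles (`mv_right`).
#'
#' @param mv_left,mv_forward,mv_right Non-negative activations.
#' @export
movement_cell_activity <- function(mv_left, mv_forward, mv_right) {
  if (any(c(mv_left, mv_forward, mv_right) < 0)) {
    stop("movement_cell_activity: activations must be >= 0")
  }
  structure(list(mv_left = mv_left, mv_forward = mv_forward,
                 mv_right = mv_right),
            class = "movement_cell_activity")
}

# band membership masks over preferred angles 0..359 (unit k of the source
# indexing corresponds to egocentric angle (k - 180): left band -179..0,
# frontal band -54..54, right band 1..180; the bands overlap as printed)
.mv_bands <- local({
  ego <- wrap_angle(0:359)
  list(left = ego >= -179 & ego <= 0,
       forward = ego >= -54 & ego <= 54,
       right = ego >= 1 & ego <= 180)
})

#' Movement cells driven by an egocentric population
#'
#' Band sums over a 360-unit egocentric population (EGCD, or EGD for the
#' allocentric strategy): units with egocentric angles in \[-179, 0\] drive
#' `mv_left`, \[-54, 54\] drive `mv_forward`, \[1, 180\] drive `mv_right`.
#'
#' @param pop A 360-unit egocentric `cell_population`.
#' @return A `movement_cell_activity`.
#' @export
movement_cells <- function(pop) {
  if (length(pop$activities) != 360L) {
    stop("movement_cells: population must have 360 units")
  }
  a <- pop$activities
  movement_cell_activity(sum(a[.mv_bands$left]),
                         sum(a[.mv_bands$forward]),
                         sum(a[.mv_bands$right]))
}

#' Conjunctive head-direction x cue-direction cell response
#'
#' Product of the HD-population activity at the cell's preferred head
#' direction and the ECD-population activity at its preferred egocentric cue
#' direction. Maximal when the agent's heading matches `pref_hd` while a cue
#' sits at `pref_ecd`; noise off, the response factorizes exactly.
#'
#' @param pref_hd Preferred head direction, degrees.
#' @param pref_ecd Preferred egocentric cue direction, degrees.
#' @param hd A `head_direction_state`.
#' @param cue_vectors Output of [sense_cues()].
#' @param params Sensory parameter list.
#' @param noise A `noise_model` for the ECD population.
#' @return Scalar activation.
#' @export
conjunctive_response <- function(pref_hd, pref_ecd, hd, cue_vectors,
                                 params = nav_config()$sensory,
                                 noise = noise_model(0)) {
  ecd <- ecd_population(cue_vectors, params, noise)
  if (isTRUE(attr(ecd, "degenerate"))) return(0)
  population_activity_at(hd$population, pref_hd) *
    population_activity_at(ecd, pref_ecd)
}
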