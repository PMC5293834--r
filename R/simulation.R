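# Experiment orchestration: the per-step sense -> plan -> decide -> move
# loop, the three experiment runners, trial classification and the
# strategy-contribution metric.

# per-trial child seeds; exact in doubles for any 32-bit master seed
child_seed <- function(seed, i) {
  (abs(as.numeric(seed)) * 48271 + i * 7919) %% 2147483629 + 1
}

#' Initialize a simulation state
#'
#' Bundles environment, configuration, enabled strategies, goal and route
#' memory into the mutable world state advanced by [simulation_step()].
#'
#' @param env A `nav_env`.
#' @param config See [nav_config()].
#' @param strategies Enabled strategy ids, in fixed id order (the order of
#'   the softmax partition).
#' @param goal_pos Goal position (length-2).
#' @param goal_landmark Map landmark id nearest the goal (route metric).
#' @param initial_strategy Strategy applied before the first softmax draw.
#' @param route Optional `route_memory` (sequential kind).
#' @param start Start pose (defaults to `env$start`).
#' @param budget Step budget.
#' @param stuck_enabled Raise stuck events on prolonged immobility.
#' @param felt_distance `"euclid"` (straight line to the goal) or `"route"`
#'   (cognitive-map route length), the distance sense feeding the
#'   approaching / receding confidence events.
#' @return A `sim_state`.
#' @export
new_sim_state <- function(env, config, strategies, goal_pos, goal_landmark,
                          initial_strategy, route = NULL, start = env$start,
                          budget = 2000L, stuck_enabled = FALSE,
                          felt_distance = "euclid") {
  agent <- agent_state(start$position, start$heading,
                       body_radius = config$agent$body_radius,
                       speed_scale = config$agent$speed_scale,
                       wheelbase = config$agent$wheelbase)
  conf <- confidence_state(strategies, params = config$confidence)
  nlog <- budget
  log <- matrix(NA_real_, nrow = nlog,
                ncol = 10L + length(strategies),
                dimnames = list(NULL, c("t", "x", "y", "heading", "strategy",
                                        "v_left", "v_right", "route_len",
                                        "aligned", "approaching",
                                        paste0("conf_", strategies))))
  structure(list(
    env = env, config = config, noise = nav_noise(config),
    strategies = strategies, agent = agent, conf = conf,
    strategy = initial_strategy, route = route, cue_targets = NULL,
    goal_pos = goal_pos, goal_landmark = goal_landmark,
    dist_mat = igraph::distances(env$map$graph),
    t = 0L, budget = budget, prev_goal_dist = NA_real_,
    stuck_ref = NULL, dwell_n = 0L, stuck_enabled = stuck_enabled,
    felt_distance = felt_distance,
    pending_progress = FALSE, terminal_dwell_n = integer(),
    terminal = NA_character_, done = FALSE,
    region_entry_t = list(), cue_switches = 0L,
    log = log), class = "sim_state")
}

# centroid-route targets for the cue-following strategy: landmark sequence
# from the current place cell to the goal's landmark, then the goal itself.
# The agent heads for the NEXT region's centroid straight away (its own
# region's centroid is where it already is, place-cell-wise); walls channel
# the approach through the door.
replan_cue_targets <- function(state) {
  pc <- active_place_cell(state$agent$position, state$env$map)
  ids <- tryCatch(plan_route(state$env$map, pc, state$goal_landmark),
                  error = function(e) NULL)
  if (is.null(ids)) return(NULL)
  list(ids = ids, k = if (length(ids) >= 2L) 2L else 1L)
}

target_position <- function(state) {
  ct <- state$cue_targets
  if (is.null(ct)) return(state$goal_pos)
  if (ct$k > length(ct$ids)) return(state$goal_pos)
  landmark_position(state$env$map, ct$ids[ct$k])
}

#' Advance the world by one simulation step
#'
#' One full pass of the architecture: sense active cues; hippocampus
#' activates the winner-take-all place cell and encodes the allocentric goal
#' direction; the retrosplenial stage transforms it to an egocentric goal
#' direction, updates the per-strategy confidences from the step's events
#' and (every `arbitration$period` steps) redraws the strategy via softmax;
#' the parietal stage produces movement-cell activity for the active
#' strategy; the motor stage converts it to wheel velocities and advances
#' the differential-drive agent with wall sliding.
#'
#' @param state A `sim_state`.
#' @return The updated `sim_state` (with `done` set on reaching a terminal).
#' @export
simulation_step <- function(state) {
  cfg <- state$config
  agent <- state$agent
  env <- state$env
  active_cues <- env$cues[env$cues$active, , drop = FALSE]

  pc <- active_place_cell(agent$position, env$map)
  agd <- agd_population(bearing(agent$position, state$goal_pos), state$noise)
  hd <- head_direction_state(agent$heading, state$noise)
  egd <- transform_to_egocentric(agd, hd, state$noise)
  cue_vec <- sense_cues(agent, active_cues, cfg$sensory)
  ecd <- ecd_population(cue_vec, cfg$sensory, state$noise)
  egcd <- if (isTRUE(attr(ecd, "degenerate"))) ecd else egcd_modulate(ecd, egd)

  # --- events -------------------------------------------------------------
  # the "feeling" of getting closer (dead band 1e-6) is judged on a
  # per-experiment distance: straight line to the goal in open/maze worlds,
  # the cognitive-map route length in the multi-region vista world (where
  # straight-line progress is meaningless across walls)
  events <- "step"
  route_len <- sqrt(sum((agent$position - landmark_position(env$map, pc))^2)) +
    state$dist_mat[pc, state$goal_landmark] +
    sqrt(sum((landmark_position(env$map, state$goal_landmark) -
              state$goal_pos)^2))
  goal_dist <- if (identical(state$felt_distance, "route")) route_len else
    sqrt(sum((agent$position - state$goal_pos)^2))
  if (!is.na(state$prev_goal_dist)) {
    if (goal_dist < state$prev_goal_dist - 1e-6) events <- c(events, "approaching")
    if (goal_dist > state$prev_goal_dist + 1e-6) events <- c(events, "distance_increased")
  }
  state$prev_goal_dist <- goal_dist
  if (!isTRUE(attr(egcd, "degenerate")) &&
      abs(wrap_angle(population_peak(egcd))) <= cfg$confidence$align_tol) {
    events <- c(events, "heading_aligned")
  }
  if (is.null(state$stuck_ref) ||
      sqrt(sum((agent$position - state$stuck_ref)^2)) >
        cfg$arbitration$stuck_radius) {
    state$stuck_ref <- agent$position
    state$dwell_n <- 0L
  } else {
    state$dwell_n <- state$dwell_n + 1L
  }
  if (state$stuck_enabled && state$dwell_n > cfg$arbitration$stuck_threshold) {
    events <- c(events, "stuck")
  }
  if (identical(state$strategy, "route_cue") && !is.null(state$cue_targets)) {
    tp <- target_position(state)
    if (state$cue_targets$k <= length(state$cue_targets$ids) &&
        sqrt(sum((agent$position - tp)^2)) <= cfg$capture_radius) {
      state$cue_targets$k <- state$cue_targets$k + 1L
      events <- c(events, "progress")
    }
  }
  if (state$pending_progress) {  # a stored turn completed on the last step
    events <- c(events, "progress")
    state$pending_progress <- FALSE
  }
  state$conf <- update_confidence(state$conf, events, state$strategy)

  # --- periodic strategy arbitration --------------------------------------
  if (state$t > 0L && state$t %% cfg$arbitration$period == 0L) {
    sel <- select_strategy(state$conf, cfg$arbitration$temperature)
    if (!identical(sel$chosen, state$strategy)) {
      state$strategy <- sel$chosen
      if (identical(sel$chosen, "route_cue")) {
        state$cue_targets <- replan_cue_targets(state)
      }
    }
  }

  # --- movement for the active strategy -----------------------------------
  mv <- switch(state$strategy,
    allocentric = movement_cells(egd),
    egocentric = if (isTRUE(attr(egcd, "degenerate")))
      movement_cell_activity(0, 1, 0) else movement_cells(egcd),
    route_sequential = {
      trig_r <- max(cfg$capture_radius, env$alley_width %||% cfg$capture_radius)
      prog0 <- state$route$progress_index
      ss <- sequential_step(state$route, agent, env$map, trig_r,
                            cfg$turn_align_tol)
      state$route <- ss$route
      if (ss$route$progress_index > prog0) state$pending_progress <- TRUE
      if (is.null(ss$mv)) movement_cell_activity(0, 1, 0) else ss$mv
    },
    route_cue = {
      if (is.null(state$cue_targets)) state$cue_targets <- replan_cue_targets(state)
      if (is.null(state$cue_targets)) {
        movement_cells(egd)  # goal unreachable on the map: steer by EGD
      } else {
        tp <- target_position(state)
        ego <- wrap_angle(bearing(agent$position, tp) - agent$heading)
        pop <- add_noise_and_normalize(
          encode_population(ego, sigma = 10, n_units = 360L), state$noise)
        movement_cells(pop)
      }
    },
    stop("simulation_step: unknown strategy ", state$strategy))

  v <- velocity_command(mv)
  # the obstacle-avoidance reflex serves the goal-directed strategies;
  # ballistic route replay stays pressed (that is its terminal behaviour)
  wall_turn <- if (identical(state$strategy, "route_sequential")) 0 else
    cfg$agent$wall_turn
  state$agent <- step_kinematics(agent, v, env$walls, wall_turn = wall_turn)
  state$t <- state$t + 1L

  # --- bookkeeping ---------------------------------------------------------
  state$log[state$t, ] <- c(state$t, state$agent$position[1],
                            state$agent$position[2], state$agent$heading,
                            match(state$strategy, state$strategies),
                            v$v_left, v$v_right, route_len,
                            as.numeric("heading_aligned" %in% events),
                            as.numeric("approaching" %in% events),
                            state$conf$values)
  if (length(env$regions)) {
    reg <- region_of(state$agent$position, env)
    if (!is.na(reg) && is.null(state$region_entry_t[[reg]])) {
      state$region_entry_t[[reg]] <- state$t
    }
  }
  # terminal checks; a terminal may require a dwell (consecutive steps in
  # its zone) before the trial is scored there. A dwell terminal (the empty
  # dead end) only ends the trial while the route strategy is still in
  # charge: an agent that has abandoned the replay there is re-orienting,
  # not finishing.
  if (!is.null(env$terminal_ids)) {
    for (id in env$terminal_ids) {
      inside <- sqrt(sum((state$agent$position -
                          landmark_position(env$map, id))^2)) <=
        (env$alley_width %||% cfg$capture_radius)
      need <- env$terminal_dwell[[id]] %||% 0L
      prev <- state$terminal_dwell_n[id]
      if (is.na(prev)) prev <- 0L
      n <- if (inside) prev + 1L else 0L
      state$terminal_dwell_n[id] <- n
      committed <- need == 0L ||
        identical(state$strategy, "route_sequential")
      if (inside && n > need && committed) {
        state$terminal <- id
        state$done <- TRUE
        break
      }
    }
  } else if (sqrt(sum((state$agent$position - state$goal_pos)^2)) <=
             cfg$capture_radius) {
    state$terminal <- "goal"
    state$done <- TRUE
  }
  if (state$t >= state$budget) state$done <- TRUE
  state
}

run_trial <- function(state) {
  while (!state$done) state <- simulation_step(state)
  state$log <- state$log[seq_len(state$t), , drop = FALSE]
  state
}

#' Classify a starmaze probe trial
#'
#' `egocentric` if the trial terminated at the end of alley 1 (pure replay of
#' the trained sequence), `allocentric` if it terminated at the alley-7 goal
#' without ever entering alley 1, `mixed` if the agent entered alley 1 and
#' then still reached the alley-7 goal, and `timeout` when the step budget
#' ran out with no terminal.
#'
#' @param trial A finished starmaze `sim_state`.
#' @return One of `"egocentric"`, `"allocentric"`, `"mixed"`, `"timeout"`.
#' @export
classify_starmaze_trial <- function(trial) {
  if (is.na(trial$terminal)) return("timeout")
  if (trial$terminal == "E1") return("egocentric")
  if (trial$terminal == "E7") {
    if (!is.null(trial$region_entry_t[["alley1"]])) return("mixed")
    return("allocentric")
  }
  "timeout"
}

#' Strategy contribution to goal progress
#'
#' For every step the shortest-route length from the agent to the goal
#' (straight leg to the active place cell, graph distance to the goal's
#' landmark, straight leg to the goal) is tracked; a step "progresses" when
#' this length strictly decreased. Each strategy's contribution is the
#' percentage of progressing steps taken under it.
#'
#' @param trial A finished `sim_state`.
#' @return Named percentage vector over the enabled strategies (all zero,
#'   with a warning, if no step progressed).
#' @export
strategy_contribution <- function(trial) {
  log <- trial$log
  out <- stats::setNames(rep(0, length(trial$strategies)), trial$strategies)
  if (nrow(log) < 2L) return(out)
  dl <- diff(log[, "route_len"])
  prog <- which(dl < 0) + 1L
  if (!length(prog)) {
    warning("strategy_contribution: no progressing steps")
    return(out)
  }
  tab <- table(factor(trial$strategies[log[prog, "strategy"]],
                      levels = trial$strategies))
  out[names(tab)] <- 100 * as.numeric(tab) / length(prog)
  out
}

#' Run the blinking-light experiment
#'
#' The arbitration machinery is off: the agent runs the egocentric strategy
#' exclusively, steered by the ECD population of the single active light.
#' When the light is captured another one starts blinking. Selected
#' conjunctive cells (preferred head direction x preferred egocentric cue
#' direction) are recorded every step.
#'
#' @param config See [nav_config()].
#' @param steps Number of simulation steps.
#' @param seed Integer seed.
#' @param cells data.frame with columns `pref_hd`, `pref_ecd`.
#' @return List with `log` (data.frame: t, x, y, heading, cue egocentric
#'   direction, conjunctive responses), `cue_switches`, `env`.
#' @export
run_blinking_light <- function(config = nav_config(), steps = 5000L,
                               seed = 1L,
                               cells = data.frame(pref_hd = c(310, 350),
                                                  pref_ecd = c(150, -90))) {
  set.seed(child_seed(seed, 0L))
  env <- build_blinking_light_arena()
  agent <- agent_state(env$start$position, env$start$heading,
                       body_radius = config$agent$body_radius,
                       speed_scale = config$agent$speed_scale,
                       wheelbase = config$agent$wheelbase)
  noise <- nav_noise(config)
  ncell <- nrow(cells)
  log <- matrix(NA_real_, steps, 5L + ncell,
                dimnames = list(NULL, c("t", "x", "y", "heading", "cue_ego",
                                        paste0("cell", seq_len(ncell)))))
  switches <- 0L
  for (t in seq_len(steps)) {
    cue <- env$cues[env$cues$active, , drop = FALSE]
    cv <- sense_cues(agent, cue, config$sensory)
    ecd <- ecd_population(cv, config$sensory, noise)
    hd <- head_direction_state(agent$heading, noise)
    resp <- vapply(seq_len(ncell), function(i) {
      population_activity_at(hd$population, cells$pref_hd[i]) *
        population_activity_at(ecd, cells$pref_ecd[i])
    }, 0)
    log[t, ] <- c(t, agent$position, agent$heading, cv$direction[1], resp)
    mv <- movement_cells(ecd)
    v <- velocity_command(mv)
    agent <- step_kinematics(agent, v, env$walls)
    adv <- advance_blinking_cue(env, agent, config$capture_radius)
    env <- adv$env
    if (adv$switched) switches <- switches + 1L
  }
  list(log = as.data.frame(log), cells = cells, cue_switches = switches,
       env = env)
}

#' Binned conjunctive-cell tuning surface from a recording
#'
#' Mean recorded response over a (head direction x cue direction) grid.
#'
#' @param log Recording from [run_blinking_light()].
#' @param cell Column name of the recorded cell.
#' @param bin Bin width, degrees.
#' @return List with `surface` (matrix), `peak_hd`, `peak_ecd` (bin centres
#'   of the maximum).
#' @export
conjunctive_tuning_surface <- function(log, cell = "cell1", bin = 10) {
  nb <- round(360 / bin)
  hd_bin <- floor(((log$heading + bin / 2) %% 360) / bin)          # centres 0, bin, ...
  ecd_bin <- floor((wrap_angle(log$cue_ego + bin / 2) + 180) / bin)
  ecd_bin[ecd_bin >= nb] <- nb - 1L
  f <- interaction(hd_bin, ecd_bin, drop = TRUE)
  m <- tapply(log[[cell]], f, mean)
  ij <- do.call(rbind, strsplit(names(m), ".", fixed = TRUE))
  surf <- matrix(NA_real_, nb, nb)
  surf[cbind(as.integer(ij[, 1]) + 1L, as.integer(ij[, 2]) + 1L)] <- m
  top <- which(m == max(m, na.rm = TRUE))[1]
  list(surface = surf,
       peak_hd = as.integer(ij[top, 1]) * bin,
       peak_ecd = as.integer(ij[top, 2]) * bin - 180)
}

#' Run the starmaze experiment
#'
#' Trains the sequential egocentric route on a supervised alley-1-to-alley-7
#' traversal, then runs `n_trials` probe trials from alley 5. Each probe
#' draws its first strategy 25/75 (allocentric / sequential egocentric) and
#' thereafter arbitrates by confidence softmax; trials are classified from
#' the trajectory alone.
#'
#' @param config See [nav_config()].
#' @param n_trials Number of probe trials.
#' @param seed Integer master seed (each trial derives a child seed).
#' @param keep_logs Keep the full per-trial trajectory logs.
#' @return An `experiment_result` with per-trial labels, category counts and
#'   percentages, and mean end-of-trial confidences per category.
#' @export
run_starmaze <- function(config = nav_config(), n_trials = 130L, seed = 1L,
                         keep_logs = FALSE) {
  cfg <- config
  # starmaze stuck handling uses the general-form parameters (active decays
  # by lambda_default, the others gain u_default) and a threshold above the
  # alley-end dwell so terminal scoring is unaffected; it rescues agents
  # wedged against walls by an anti-normal goal direction
  cfg$confidence$lambda_stuck <- cfg$confidence$lambda_default
  cfg$confidence$u_stuck <- cfg$confidence$u_default
  cfg$arbitration$stuck_threshold <- 80L
  set.seed(child_seed(seed, 0L))
  env <- build_starmaze()
  route0 <- record_sequential_route(env$map, env$train_route,
                                    env$junction_ids, cfg$turn_align_tol)
  strategies <- c("allocentric", "route_sequential")
  p0 <- cfg$arbitration$initial_draw
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(child_seed(seed, i))
    first <- sample(names(p0), 1L, prob = p0)
    st <- new_sim_state(env, cfg, strategies,
                        goal_pos = landmark_position(env$map, "E7"),
                        goal_landmark = "E7",
                        initial_strategy = first, route = route0,
                        start = env$probe_start,
                        budget = cfg$step_budget$starmaze,
                        stuck_enabled = TRUE)
    st <- run_trial(st)
    trials[[i]] <- list(
      label = classify_starmaze_trial(st),
      first = first, steps = st$t, terminal = st$terminal,
      entered_alley1 = !is.null(st$region_entry_t[["alley1"]]),
      conf_end = st$conf$values,
      log = if (keep_logs) st$log else NULL)
  }
  labels <- vapply(trials, `[[`, "", "label")
  cats <- c("allocentric", "egocentric", "mixed")
  counts <- vapply(cats, function(k) sum(labels == k), 0L)
  n_class <- sum(counts)
  conf_end <- do.call(rbind, lapply(trials, `[[`, "conf_end"))
  structure(list(
    experiment = "starmaze", n_trials = n_trials, seed = seed,
    labels = labels, counts = counts, n_timeout = sum(labels == "timeout"),
    percentages = if (n_class > 0) 100 * counts / n_class else counts * NA,
    mean_conf_end = lapply(stats::setNames(cats, cats), function(k) {
      if (any(labels == k)) colMeans(conf_end[labels == k, , drop = FALSE])
      else NULL
    }),
    trials = trials, config = cfg), class = "experiment_result")
}

#' Run the vista-space experiment
#'
#' Builds the eight-region world (goal cues at random seeded positions) and
#' runs `n_trials` trials, each from the fixed start in region 4 to a
#' randomly drawn goal cue, with full three-strategy arbitration
#' (allocentric, egocentric, route-centric cue following over region
#' centroids), vista confidence rules and stuck handling.
#'
#' @param config See [nav_config()].
#' @param n_trials Number of trials.
#' @param seed Integer master seed.
#' @param block Optional `c(a, b)` region pair whose corridor is blocked.
#' @param remove_edge Also remove the blocked corridor's map edge.
#' @param strategies Enabled strategies.
#' @param keep_logs Keep full per-trial logs.
#' @return An `experiment_result` with per-trial outcomes and mean strategy
#'   contributions.
#' @export
run_vista <- function(config = nav_config(), n_trials = 80L, seed = 1L,
                      block = NULL, remove_edge = FALSE,
                      strategies = c("allocentric", "egocentric", "route_cue"),
                      keep_logs = FALSE) {
  cfg <- config
  cfg$confidence$u_align <- config$confidence$u_direction
  # in the multi-region world the escape from pockets is the confidence
  # system itself (stuck -> route replanning), not a kinematic reflex
  cfg$agent$wall_turn <- 0
  set.seed(child_seed(seed, 0L))
  env <- build_vista_world()
  if (!is.null(block)) env <- block_corridor(env, block[1], block[2],
                                             remove_edge = remove_edge)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(child_seed(seed, i))
    gi <- sample.int(nrow(env$cues), 1L)
    goal_pos <- c(env$cues$x[gi], env$cues$y[gi])
    goal_lm <- paste0("R", region_of(goal_pos, env))
    first <- sample(strategies, 1L)
    st <- new_sim_state(env, cfg, strategies, goal_pos = goal_pos,
                        goal_landmark = goal_lm, initial_strategy = first,
                        budget = cfg$step_budget$vista, stuck_enabled = TRUE,
                        felt_distance = "route")
    if (identical(first, "route_cue")) st$cue_targets <- replan_cue_targets(st)
    st <- run_trial(st)
    trials[[i]] <- list(
      reached = identical(st$terminal, "goal"), steps = st$t,
      goal = env$cues$id[gi],
      contribution = strategy_contribution(st),
      log = if (keep_logs) st$log else NULL)
  }
  reached <- vapply(trials, `[[`, TRUE, "reached")
  contr <- do.call(rbind, lapply(trials, `[[`, "contribution"))
  structure(list(
    experiment = "vista", n_trials = n_trials, seed = seed, env = env,
    reached = reached, completion_rate = 100 * mean(reached),
    mean_contribution = colMeans(contr),
    trials = trials, config = cfg), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s> %d trials, seed %d\n",
              x$experiment, x$n_trials, x$seed))
  if (x$experiment == "starmaze") {
    cat("  counts:", paste(names(x$counts), x$counts, collapse = ", "),
        sprintf("(timeouts %d)\n", x$n_timeout))
    cat("  percentages:",
        paste(names(x$percentages), sprintf("%.1f%%", x$percentages),
              collapse = ", "), "\n")
  } else if (x$experiment == "vista") {
    cat(sprintf("  completion: %.1f%%\n", x$completion_rate))
    cat("  mean contribution:",
        paste(names(x$mean_contribution),
              sprintf("%.1f%%", x$mean_contribution), collapse = ", "), "\n")
  }
  invisible(x)
}
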