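make_probe_state <- function(config, initial = "route_sequential",
                             budget = 2000) {
  env <- build_starmaze()
  route0 <- record_sequential_route(env$map, env$train_route,
                                    env$junction_ids, config$turn_align_tol)
  new_sim_state(env, config, c("allocentric", "route_sequential"),
                goal_pos = landmark_position(env$map, "E7"),
                goal_landmark = "E7", initial_strategy = initial,
                route = route0, start = env$probe_start, budget = budget)
}

test_that("a cue dead ahead under the egocentric strategy drives straight travel", {
  cfg <- nav_config(noise_sd = 0)
  env <- build_blinking_light_arena()
  env$cues$active <- FALSE
  env$cues$active[env$cues$x > 9.9] <- TRUE          # the cue at angle 0
  env$terminal_ids <- NULL
  st <- new_sim_state(env, cfg, "egocentric",
                      goal_pos = c(10, 0), goal_landmark = "centre",
                      initial_strategy = "egocentric", budget = 20)
  st$agent$heading <- 0                                # facing the cue
  for (k in 1:10) st <- simulation_step(st)
  # heading holds near the cue bearing and the agent advances on it
  expect_lte(abs(wrap_angle(st$agent$heading)), 3)
  expect_gt(st$agent$position[1], 0.5)
  expect_lte(abs(st$agent$position[2]), 0.05)
})

test_that("identical seeds give bit-identical experiment results", {
  cfg <- nav_config()
  a <- run_starmaze(cfg, n_trials = 3, seed = 77, keep_logs = TRUE)
  b <- run_starmaze(cfg, n_trials = 3, seed = 77, keep_logs = TRUE)
  expect_identical(a$labels, b$labels)
  expect_identical(a$trials[[2]]$log, b$trials[[2]]$log)
  expect_false(identical(a$labels,
                         run_starmaze(cfg, n_trials = 3, seed = 78)$labels) &&
               identical(a$trials[[1]]$steps,
                         run_starmaze(cfg, n_trials = 3, seed = 78)$trials[[1]]$steps))
})

test_that("with arbitration frozen to the trained route, probes end in alley 1", {
  cfg <- nav_config(arbitration = list(period = 1e9))
  for (seed in 1:3) {
    set.seed(seed)
    st <- run_trial(make_probe_state(cfg))
    expect_identical(st$terminal, "E1")
    expect_identical(classify_starmaze_trial(st), "egocentric")
  }
})

test_that("with arbitration frozen to allocentric, probes end at the alley-7 goal", {
  cfg <- nav_config(arbitration = list(period = 1e9))
  set.seed(1)
  st <- run_trial(make_probe_state(cfg, initial = "allocentric"))
  expect_identical(st$terminal, "E7")
  expect_identical(classify_starmaze_trial(st), "allocentric")
})

test_that("trial classification follows terminal alley and alley-1 history", {
  fake <- function(terminal, entered1) {
    list(terminal = terminal,
         region_entry_t = if (entered1) list(alley1 = 42L) else list())
  }
  expect_identical(classify_starmaze_trial(fake("E1", TRUE)), "egocentric")
  expect_identical(classify_starmaze_trial(fake("E7", FALSE)), "allocentric")
  expect_identical(classify_starmaze_trial(fake("E7", TRUE)), "mixed")
  expect_identical(classify_starmaze_trial(fake(NA_character_, TRUE)), "timeout")
})

test_that("strategy contributions match a hand-worked trace and sum to 100", {
  log <- cbind(t = 1:7, route_len = c(10, 9, 8, 8.5, 7, 7, 6.5),
               strategy = c(1, 1, 2, 2, 2, 1, 1))
  trial <- list(log = log, strategies = c("a", "b"))
  contr <- strategy_contribution(trial)
  # progressing steps: t=2 (a), t=3 (b), t=5 (b), t=7 (a) -> 50 / 50
  expect_equal(unname(contr), c(50, 50))
  expect_equal(sum(contr), 100)
  single <- list(log = cbind(t = 1:3, route_len = c(3, 2, 1),
                             strategy = c(1, 1, 1)),
                 strategies = c("a", "b"))
  expect_equal(unname(strategy_contribution(single)), c(100, 0))
  flat <- list(log = cbind(t = 1:3, route_len = c(3, 3, 3),
                           strategy = c(1, 1, 1)),
               strategies = c("a", "b"))
  expect_warning(z <- strategy_contribution(flat), "no progressing")
  expect_equal(unname(z), c(0, 0))
})

test_that("the route-centric strategy alone completes vista trials", {
  r <- run_vista(nav_config(), n_trials = 3, seed = 5,
                 strategies = "route_cue")
  expect_true(all(r$reached))
  expect_equal(unname(r$mean_contribution["route_cue"]), 100)
})

test_that("blocking a corridor off the route leaves the trajectory unchanged", {
  cfg <- nav_config()
  run_to_region5 <- function(env) {
    st <- new_sim_state(env, cfg, "route_cue", goal_pos = c(15, 5),
                        goal_landmark = "R5", initial_strategy = "route_cue",
                        budget = 1500, stuck_enabled = TRUE,
                        felt_distance = "route")
    set.seed(33)
    run_trial(st)
  }
  set.seed(3); env <- build_vista_world()
  base <- run_to_region5(env)
  blocked <- run_to_region5(block_corridor(env, 9, 1, remove_edge = TRUE))
  expect_identical(base$log, blocked$log)   # 9-1 is never on the 4 -> 5 route
  expect_identical(base$terminal, "goal")
})

test_that("the blinking-light loop keeps exactly one light active and visits many", {
  bl <- run_blinking_light(nav_config(), steps = 2500, seed = 2)
  expect_equal(sum(bl$env$cues$active), 1L)
  expect_gte(bl$cue_switches, 10)
  # approaches are near-straight: most steps drive both wheels equally
  l <- bl$log
  expect_gt(mean(abs(l$cue_ego) < 15), 0.5)
})
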