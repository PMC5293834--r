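test_that("cue sensing returns Euclidean distance and wrapped egocentric bearing", {
  a <- agent_state(c(0, 0), 90)
  cv <- sense_cues(a, data.frame(id = "c", x = 0, y = 5))
  expect_equal(cv$distance, 5)
  expect_equal(cv$direction, 0)
  a0 <- agent_state(c(0, 0), 0)
  cv2 <- sense_cues(a0, data.frame(id = "c", x = 3, y = 4))
  expect_equal(cv2$distance, 5)
  expect_equal(cv2$direction, atan2(4, 3) * 180 / pi, tolerance = 1e-9)
  a180 <- agent_state(c(0, 0), 180)
  cv3 <- sense_cues(a180, data.frame(id = "c", x = 3, y = 4))
  expect_equal(cv3$direction, atan2(4, 3) * 180 / pi - 180, tolerance = 1e-9)
  expect_error(sense_cues(a0, data.frame(id = "c", x = 0, y = 0)), "agent position")
})

test_that("ECD activation scales as D over distance", {
  a <- agent_state(c(0, 0), 0)
  raw3 <- ecd_population(sense_cues(a, data.frame(id = "c", x = 3, y = 0)),
                         normalize = FALSE)
  expect_equal(raw3$activities[raw3$preferred_angles == 0], 1.0)  # D/d = 3/3
  raw6 <- ecd_population(sense_cues(a, data.frame(id = "c", x = 6, y = 0)),
                         normalize = FALSE)
  expect_equal(raw6$activities[raw6$preferred_angles == 0], 0.5)  # D/d = 3/6
  # two identical cues at mirror angles give a population symmetric about 0
  cues <- data.frame(id = c("p", "q"),
                     x = 4 * cos(c(40, -40) * pi / 180),
                     y = 4 * sin(c(40, -40) * pi / 180))
  pop <- ecd_population(sense_cues(a, cues), normalize = FALSE)
  act <- pop$activities
  ang <- wrap_angle(pop$preferred_angles)
  for (d in c(10, 40, 90)) {
    expect_equal(act[ang == d], act[ang == -d], tolerance = 1e-12)
  }
  # no cues: degenerate all-zero population
  none <- ecd_population(sense_cues(a, data.frame(id = character(),
                                                  x = numeric(), y = numeric())))
  expect_true(attr(none, "degenerate"))
  expect_true(all(none$activities == 0))
})

test_that("EGCD modulation equals the brute-force double loop", {
  set.seed(17)
  pref <- 0:359
  for (k in 1:6) {
    ecd <- cell_population(pref, stats::runif(360))
    egd <- cell_population(pref, stats::runif(360))
    got <- egcd_modulate(ecd, egd)
    # independent semi-vectorised oracle, term by term over EGD units
    w_of <- function(i) exp(-wrap_angle(pref[i] - pref)^2 / 80^2)
    raw <- vapply(seq_len(360), function(i) {
      w <- w_of(i)
      term <- ifelse(egd$activities > 0.5,
                     egd$activities * w, egd$activities * (w - 1))
      ecd$activities[i] * sum(term)
    }, 0)
    raw[raw < 0] <- 0
    if (max(raw) > 0) raw <- raw / max(raw)
    expect_equal(got$activities, raw, tolerance = 1e-9)
  }
})

test_that("the goal-closest cue is enhanced, and weak EGD inhibits everything", {
  a <- agent_state(c(0, 0), 0)
  cues <- data.frame(id = c("far", "near"),
                     x = 4 * cos(c(-90, 10) * pi / 180),
                     y = 4 * sin(c(-90, 10) * pi / 180))
  ecd <- ecd_population(sense_cues(a, cues))
  egd <- add_noise_and_normalize(encode_population(0, 10, 360))  # goal dead ahead
  egcd <- egcd_modulate(ecd, egd)
  expect_lte(abs(wrap_angle(population_peak(egcd) - 10)), 3)
  # grid of cue/goal geometries: the angularly closer cue always wins
  for (goal in c(-60, 0, 45)) {
    for (off in c(25, 60, 110)) {
      cue_a <- goal + off / 2            # closer to goal
      cue_b <- goal - off                # further
      cues2 <- data.frame(id = c("a", "b"),
                          x = 5 * cos(c(cue_a, cue_b) * pi / 180),
                          y = 5 * sin(c(cue_a, cue_b) * pi / 180))
      egcd2 <- egcd_modulate(ecd_population(sense_cues(a, cues2)),
                             add_noise_and_normalize(encode_population(goal, 10, 360)))
      pk <- wrap_angle(population_peak(egcd2))
      expect_lt(abs(wrap_angle(pk - cue_a)), abs(wrap_angle(pk - cue_b)))
    }
  }
  # all EGD activity at or below 0.5: pure inhibition, everything clamps to 0
  weak <- cell_population(0:359, rep(0.4, 360))
  out <- egcd_modulate(ecd, weak)
  expect_true(all(out$activities == 0))
  expect_true(attr(out, "degenerate"))
})

test_that("cue-following EGCD is a pure bump at the goal cue direction", {
  gc <- data.frame(id = "g", distance = 42, direction = -120)
  pop <- egcd_cue_following(gc)
  expect_equal(wrap_angle(population_peak(pop)), -120)
  expect_equal(pop$activities, encode_population(-120, 10, 360)$activities)
  gc0 <- data.frame(id = "g", distance = 1, direction = 0)
  expect_equal(population_peak(egcd_cue_following(gc0)), 0)
})

test_that("movement cells sum the printed index bands", {
  bump0 <- encode_population(0, 10, 360)
  mv <- movement_cells(bump0)
  # the two turn bands split the bump's mass evenly up to the single 0-degree
  # unit, which the printed index ranges assign to the left band only
  expect_equal(mv$mv_left - mv$mv_right, 1.0)
  expect_lt(abs(mv$mv_left / mv$mv_right - 1), 0.15)
  bumpL <- encode_population(-120, 10, 360)
  mvL <- movement_cells(bumpL)
  expect_gt(mvL$mv_left, mvL$mv_right)
  unif <- cell_population(0:359, rep(1, 360))
  mvU <- movement_cells(unif)
  expect_equal(mvU$mv_left, mvU$mv_right)
  expect_equal(mvU$mv_forward, 109 / 180 * mvU$mv_left)
  expect_error(movement_cells(encode_population(0, 10, 180)), "360")
})

test_that("conjunctive responses factorize and peak at the preferred pair", {
  cue_at <- function(ego, heading, d = 3) {
    b <- (heading + ego) * pi / 180
    data.frame(id = "c", x = d * cos(b), y = d * sin(b))
  }
  resp <- function(hd_pref, ecd_pref, heading, ego) {
    a <- agent_state(c(0, 0), heading)
    conjunctive_response(hd_pref, ecd_pref, head_direction_state(heading),
                         sense_cues(a, cue_at(ego, heading)))
  }
  expect_equal(resp(310, 150, 310, 150), 1.0)
  expect_lt(resp(310, 150, 40, 150), 1e-20)  # heading 90 degrees off
  # rank-1 (separable) structure: r(h1,c1) r(h2,c2) == r(h1,c2) r(h2,c1)
  r11 <- resp(310, 150, 305, 140); r22 <- resp(310, 150, 320, 155)
  r12 <- resp(310, 150, 305, 155); r21 <- resp(310, 150, 320, 140)
  expect_equal(r11 * r22, r12 * r21, tolerance = 1e-12)
  # response surface over a coarse grid peaks at the preferred pair
  grid <- expand.grid(h = seq(270, 350, by = 10), c = seq(110, 190, by = 10))
  vals <- mapply(function(h, c) resp(310, 150, h, c), grid$h, grid$c)
  expect_equal(unlist(grid[which.max(vals), ]), c(h = 310, c = 150))
})

test_that("sequential route memory replays stored turns at choice points", {
  m <- cognitive_map(
    data.frame(id = c("S", "J", "G"), x = c(0, 10, 10), y = c(0, 0, 10)),
    data.frame(from = c("S", "J"), to = c("J", "G")))
  route <- record_sequential_route(m, c("S", "J", "G"), junction_ids = "J")
  expect_equal(nrow(route$sequence), 1)
  expect_equal(route$sequence$command, 180)      # left bend of +90
  expect_equal(route$sequence$turn_amount, 90)
  # far from the junction: straight override
  far <- agent_state(c(2, 0), 0)
  s1 <- sequential_step(route, far, m, capture_radius = 0.5)
  expect_equal(unlist(s1$mv[c("mv_left", "mv_forward", "mv_right")]),
               c(mv_left = 0, mv_forward = 1, mv_right = 0))
  # at the junction: saturated turn toward the stored side
  at <- agent_state(c(10, 0), 0)
  s2 <- sequential_step(route, at, m, capture_radius = 0.5)
  expect_equal(unlist(s2$mv[c("mv_left", "mv_forward", "mv_right")]),
               c(mv_left = 0, mv_forward = 0, mv_right = 1))
  expect_true(s2$route$turning)
  # a stored -180 saturates the opposite cell
  m2 <- cognitive_map(
    data.frame(id = c("S", "J", "G"), x = c(0, 10, 10), y = c(0, 0, -10)),
    data.frame(from = c("S", "J"), to = c("J", "G")))
  route2 <- record_sequential_route(m2, c("S", "J", "G"), junction_ids = "J")
  expect_equal(route2$sequence$command, -180)
  s3 <- sequential_step(route2, at, m2, capture_radius = 0.5)
  expect_equal(s3$mv$mv_left, 1)
  # once aligned with the outgoing leg the turn completes and progress advances
  turned <- agent_state(c(10, 0.1), 88)
  s4 <- sequential_step(s2$route, turned, m, capture_radius = 0.5)
  expect_false(s4$route$turning)
  expect_equal(s4$route$progress_index, 1L)
})
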