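# Builders for the three experimental worlds, cue scheduling, region
# membership and the environment file format. Geometry is planar, in
# arbitrary length units; walls are straight segments.

wall_segment <- function(x1, y1, x2, y2) c(x1, y1, x2, y2)

walls_matrix <- function(segs) {
  m <- do.call(rbind, segs)
  colnames(m) <- c("x1", "y1", "x2", "y2")
  m
}

# segment a->b with a centred gap of width `gap` (a door); returns the two
# flanking segments
wall_with_gap <- function(a, b, gap) {
  u <- (b - a) / sqrt(sum((b - a)^2))
  mid <- (a + b) / 2
  list(wall_segment(a[1], a[2], mid[1] - u[1] * gap / 2, mid[2] - u[2] * gap / 2),
       wall_segment(mid[1] + u[1] * gap / 2, mid[2] + u[2] * gap / 2, b[1], b[2]))
}

# intersection of lines p1 + t d1 and p2 + s d2
line_intersect <- function(p1, d1, p2, d2) {
  det <- d1[1] * (-d2[2]) - (-d2[1]) * d1[2]
  if (abs(det) < 1e-12) stop("line_intersect: parallel lines")
  rhs <- p2 - p1
  t <- (rhs[1] * (-d2[2]) - (-d2[1]) * rhs[2]) / det
  p1 + t * d1
}

new_nav_env <- function(name, walls, cues, regions, map, goal_id, start,
                        junction_ids = character(), extra = list()) {
  structure(c(list(name = name, walls = walls, cues = cues, regions = regions,
                   map = map, goal_id = goal_id, start = start,
                   junction_ids = junction_ids), extra),
            class = "nav_env")
}

#' @export
print.nav_env <- function(x, ...) {
  cat(sprintf("<nav_env '%s'> %d walls, %d cues, %d regions, goal '%s'\n",
              x$name, nrow(x$walls), nrow(x$cues), length(x$regions),
              x$goal_id))
  invisible(x)
}

#' Blinking-light arena
#'
#' A circular arena with `n_lights` cue lights equally spaced on the
#' boundary, exactly one of which is active ("blinking") at a time; the
#' agent starts at the centre. The initially active light is drawn from the
#' current RNG stream.
#'
#' @param radius Arena radius.
#' @param n_lights Number of boundary lights (>= 2).
#' @return A `nav_env`.
#' @export
build_blinking_light_arena <- function(radius = 10, n_lights = 32L) {
  if (n_lights < 2) stop("build_blinking_light_arena: n_lights must be >= 2")
  nseg <- 72L
  th <- seq(0, 2 * pi, length.out = nseg + 1L)
  segs <- lapply(seq_len(nseg), function(i) {
    wall_segment(radius * cos(th[i]), radius * sin(th[i]),
                 radius * cos(th[i + 1]), radius * sin(th[i + 1]))
  })
  ang <- (seq_len(n_lights) - 1) * 360 / n_lights
  cues <- data.frame(id = paste0("L", seq_len(n_lights)),
                     x = radius * cos(ang * pi / 180),
                     y = radius * sin(ang * pi / 180),
                     active = FALSE)
  cues$active[sample.int(n_lights, 1L)] <- TRUE
  map <- cognitive_map(data.frame(id = "centre", x = 0, y = 0),
                       data.frame(from = character(), to = character()))
  new_nav_env("blinking_light", walls_matrix(segs), cues, list(), map,
              goal_id = NA_character_,
              start = list(position = c(0, 0), heading = 0))
}

#' Advance the blinking cue schedule
#'
#' If the agent is within `capture_radius` of the active light, that light
#' goes dark and a different, uniformly drawn light starts blinking;
#' otherwise nothing changes. Exactly one light is active before and after.
#'
#' @param env The arena.
#' @param agent An `agent_state`.
#' @param capture_radius Capture distance.
#' @return List with the (possibly updated) `env` and `switched` flag.
#' @export
advance_blinking_cue <- function(env, agent, capture_radius = 0.5) {
  act <- which(env$cues$active)
  if (length(act) != 1L) stop("advance_blinking_cue: need exactly one active cue")
  d <- sqrt((env$cues$x[act] - agent$position[1])^2 +
            (env$cues$y[act] - agent$position[2])^2)
  switched <- FALSE
  if (d <= capture_radius) {
    others <- setdiff(seq_len(nrow(env$cues)), act)
    env$cues$active[act] <- FALSE
    env$cues$active[others[sample.int(length(others), 1L)]] <- TRUE
    switched <- TRUE
  }
  list(env = env, switched = switched)
}

#' Five-armed star maze
#'
#' A central pentagonal ring corridor with five radial arms attached at the
#' ring vertices. Alleys are numbered clockwise, radial arms odd (1, 3, 5,
#' 7, 9), ring segments even. Landmarks sit at the five ring junctions
#' (J1, J3, ...) and the five arm ends (E1, E3, ...); four distal allocentric
#' cues surround the maze. Training runs start at the end of alley 1 with
#' the goal at the end of alley 7; probe trials start at the end of alley 5.
#'
#' @param arm_length Radial arm length beyond the ring.
#' @param ring_radius Circumradius of the ring centreline pentagon.
#' @param alley_width Corridor width.
#' @return A `nav_env` with extras `probe_start`, `terminal_ids`,
#'   `trained_route`.
#' @export
build_starmaze <- function(arm_length = 5, ring_radius = 5, alley_width = 1) {
  stopifnot(arm_length > 0, ring_radius > 0, alley_width > 0,
            alley_width < ring_radius)
  R <- ring_radius; L <- arm_length; w <- alley_width
  arms <- c(1, 3, 5, 7, 9)
  phi <- 90 - 36 * (arms - 1)          # clockwise numbering, alley 1 at top
  names(phi) <- arms
  rad <- function(a) a * pi / 180
  unit <- function(a) c(cos(rad(a)), sin(rad(a)))
  a_in <- R * cos(rad(36)) - w / 2     # inner wall apothem
  a_out <- R * cos(rad(36)) + w / 2    # outer wall apothem
  R_in <- a_in / cos(rad(36))
  R_out <- a_out / cos(rad(36))
  V <- lapply(phi, function(p) R * unit(p))          # ring junctions
  U <- lapply(phi, function(p) R_out * unit(p))      # outer wall vertices
  W_in <- lapply(phi, function(p) R_in * unit(p))    # inner wall vertices
  segs <- list()
  # inner pentagon: closed
  for (i in seq_along(arms)) {
    j <- if (i == length(arms)) 1L else i + 1L
    segs[[length(segs) + 1L]] <- wall_segment(W_in[[i]][1], W_in[[i]][2],
                                              W_in[[j]][1], W_in[[j]][2])
  }
  # outer pentagon edges shortened at each vertex where an arm opens, plus
  # arm side walls and end caps
  mouth <- vector("list", length(arms))  # per arm: left/right mouth corners
  for (i in seq_along(arms)) {
    u <- unit(phi[i]); n <- c(-u[2], u[1])
    prev <- if (i == 1L) length(arms) else i - 1L
    nxt <- if (i == length(arms)) 1L else i + 1L
    e1 <- U[[prev]]; e2 <- U[[nxt]]
    m_a <- line_intersect(V[[i]] + n * w / 2, u, U[[i]], e1 - U[[i]])
    m_b <- line_intersect(V[[i]] - n * w / 2, u, U[[i]], e2 - U[[i]])
    mouth[[i]] <- list(a = m_a, b = m_b)
    tip <- (R + L)
    segs[[length(segs) + 1L]] <- wall_segment(m_a[1], m_a[2],
      (V[[i]] + n * w / 2 + u * (tip - R))[1], (V[[i]] + n * w / 2 + u * (tip - R))[2])
    segs[[length(segs) + 1L]] <- wall_segment(m_b[1], m_b[2],
      (V[[i]] - n * w / 2 + u * (tip - R))[1], (V[[i]] - n * w / 2 + u * (tip - R))[2])
    cap_a <- V[[i]] + n * w / 2 + u * (tip - R)
    cap_b <- V[[i]] - n * w / 2 + u * (tip - R)
    segs[[length(segs) + 1L]] <- wall_segment(cap_a[1], cap_a[2], cap_b[1], cap_b[2])
  }
  for (i in seq_along(arms)) {
    nxt <- if (i == length(arms)) 1L else i + 1L
    segs[[length(segs) + 1L]] <- wall_segment(mouth[[i]]$b[1], mouth[[i]]$b[2],
                                              mouth[[nxt]]$a[1], mouth[[nxt]]$a[2])
  }
  lm <- rbind(
    data.frame(id = paste0("J", arms),
               x = vapply(V, `[`, 0, 1), y = vapply(V, `[`, 0, 2),
               is_goal = FALSE),
    data.frame(id = paste0("E", arms),
               x = vapply(seq_along(arms), function(i) ((R + L - w / 2) * unit(phi[i]))[1], 0),
               y = vapply(seq_along(arms), function(i) ((R + L - w / 2) * unit(phi[i]))[2], 0),
               is_goal = paste0("E", arms) == "E7"))
  edges <- rbind(
    data.frame(from = paste0("E", arms), to = paste0("J", arms)),
    data.frame(from = paste0("J", arms),
               to = paste0("J", arms[c(2:length(arms), 1)])))
  map <- cognitive_map(lm, edges)
  cue_ang <- c(45, 135, 225, 315)
  cues <- data.frame(id = paste0("C", cue_ang),
                     x = (R + L + 10) * cos(rad(cue_ang)),
                     y = (R + L + 10) * sin(rad(cue_ang)),
                     active = TRUE)
  regions <- lapply(seq_along(arms), function(i) {
    u <- unit(phi[i]); n <- c(-u[2], u[1])
    p1 <- (R + w) * u + n * w / 2; p2 <- (R + L) * u + n * w / 2
    p3 <- (R + L) * u - n * w / 2; p4 <- (R + w) * u - n * w / 2
    list(id = paste0("alley", arms[i]),
         x = c(p1[1], p2[1], p3[1], p4[1]),
         y = c(p1[2], p2[2], p3[2], p4[2]))
  })
  names(regions) <- paste0("alley", arms)
  e_pos <- function(k) landmark_position(map, paste0("E", k))
  start_of <- function(k) list(position = unname(e_pos(k)),
                               heading = unname(wrap_angle(phi[as.character(k)] + 180)))
  env <- new_nav_env("starmaze", walls_matrix(segs), cues, regions, map,
                     goal_id = "E7", start = start_of(1),
                     junction_ids = paste0("J", arms),
                     extra = list(probe_start = start_of(5),
                                  terminal_ids = c("E1", "E7"),
                                  # the alley-1 end holds no goal: the agent
                                  # lingers there before the trial is scored
                                  terminal_dwell = list(E1 = 50L, E7 = 0L),
                                  alley_width = w,
                                  train_route = plan_route(map, "E1", "E7")))
  env
}

#' Vista-space world
#'
#' Eight square regions on a 3 x 3 grid with the centre cell absent, joined
#' by narrow door openings in the shared walls. Regions are numbered
#' 1, 2, 3, 4, 5, 6, 7, 9 (the label 8 is skipped): the start region 4 sits
#' bottom-left, region 5 (bottom-middle) has doors only to its east and west
#' neighbours and so traps direct northward travel, and region 3
#' (bottom-right) connects northward. Region centroids become the route
#' landmarks of the cognitive map; `n_cues` salient goal cues are placed at
#' random positions (current RNG stream), each belonging to the region that
#' contains it.
#'
#' @param cell_size Side length of one region.
#' @param door_width Width of the door openings.
#' @param n_cues Number of goal cues.
#' @return A `nav_env` with extras `doors` (door table for blocking).
#' @export
build_vista_world <- function(cell_size = 10, door_width = 1.5, n_cues = 8L) {
  S <- cell_size
  # (col, row) -> region number; centre absent
  layout <- rbind(
    data.frame(region = 4, col = 0, row = 0), data.frame(region = 5, col = 1, row = 0),
    data.frame(region = 3, col = 2, row = 0), data.frame(region = 6, col = 0, row = 1),
    data.frame(region = 2, col = 2, row = 1), data.frame(region = 7, col = 0, row = 2),
    data.frame(region = 9, col = 1, row = 2), data.frame(region = 1, col = 2, row = 2))
  segs <- list(
    wall_segment(0, 0, 3 * S, 0), wall_segment(3 * S, 0, 3 * S, 3 * S),
    wall_segment(3 * S, 3 * S, 0, 3 * S), wall_segment(0, 3 * S, 0, 0),
    # centre hole
    wall_segment(S, S, 2 * S, S), wall_segment(2 * S, S, 2 * S, 2 * S),
    wall_segment(2 * S, 2 * S, S, 2 * S), wall_segment(S, 2 * S, S, S))
  doors <- data.frame(region_a = numeric(), region_b = numeric(),
                      x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric())
  add_partition <- function(a, b, ra, rb) {
    segs[c(length(segs) + 1L, length(segs) + 2L)] <<- wall_with_gap(a, b, door_width)
    u <- (b - a) / sqrt(sum((b - a)^2)); mid <- (a + b) / 2
    doors[nrow(doors) + 1L, ] <<- c(ra, rb,
      mid[1] - u[1] * door_width / 2, mid[2] - u[2] * door_width / 2,
      mid[1] + u[1] * door_width / 2, mid[2] + u[2] * door_width / 2)
  }
  add_partition(c(S, 0), c(S, S), 4, 5)
  add_partition(c(2 * S, 0), c(2 * S, S), 5, 3)
  add_partition(c(S, 2 * S), c(S, 3 * S), 7, 9)
  add_partition(c(2 * S, 2 * S), c(2 * S, 3 * S), 9, 1)
  add_partition(c(0, S), c(S, S), 4, 6)
  add_partition(c(2 * S, S), c(3 * S, S), 3, 2)
  add_partition(c(0, 2 * S), c(S, 2 * S), 6, 7)
  add_partition(c(2 * S, 2 * S), c(3 * S, 2 * S), 2, 1)
  cent <- data.frame(id = paste0("R", layout$region),
                     x = layout$col * S + S / 2, y = layout$row * S + S / 2,
                     is_goal = FALSE)
  edges <- data.frame(from = paste0("R", doors$region_a),
                      to = paste0("R", doors$region_b))
  map <- cognitive_map(cent, edges)
  regions <- lapply(seq_len(nrow(layout)), function(i) {
    x0 <- layout$col[i] * S; y0 <- layout$row[i] * S
    list(id = as.character(layout$region[i]),
         x = c(x0, x0 + S, x0 + S, x0), y = c(y0, y0, y0 + S, y0 + S))
  })
  names(regions) <- as.character(layout$region)
  margin <- 1
  pick <- layout[sample.int(nrow(layout), n_cues, replace = TRUE), ]
  cues <- data.frame(
    id = paste0("G", seq_len(n_cues)),
    x = pick$col * S + stats::runif(n_cues, margin, S - margin),
    y = pick$row * S + stats::runif(n_cues, margin, S - margin),
    active = TRUE)
  new_nav_env("vista", walls_matrix(segs), cues, regions, map,
              goal_id = NA_character_,
              start = list(position = c(3, 3), heading = 90),
              extra = list(doors = doors))
}

#' Block a corridor of the vista world
#'
#' Closes the door between two regions with a solid wall segment;
#' `remove_edge = TRUE` also deletes the corresponding cognitive-map edge so
#' that route planning knows about the blockade.
#'
#' @param env A vista `nav_env`.
#' @param a,b Region numbers of the door to block.
#' @param remove_edge Also remove the map edge.
#' @export
block_corridor <- function(env, a, b, remove_edge = FALSE) {
  d <- env$doors
  hit <- which((d$region_a == a & d$region_b == b) |
               (d$region_a == b & d$region_b == a))
  if (length(hit) != 1L) stop("block_corridor: no door between ", a, " and ", b)
  env$walls <- rbind(env$walls,
                     matrix(as.numeric(d[hit, c("x1", "y1", "x2", "y2")]),
                            nrow = 1, dimnames = list(NULL, colnames(env$walls))))
  if (remove_edge) {
    e <- env$map$edges
    keep <- !((e$from == paste0("R", a) & e$to == paste0("R", b)) |
              (e$from == paste0("R", b) & e$to == paste0("R", a)))
    env$map <- cognitive_map(env$map$landmarks, e[keep, c("from", "to")])
  }
  env
}

point_in_polygon <- function(p, px, py) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((py[i] > p[2]) != (py[j] > p[2]) &&
        p[1] < (px[j] - px[i]) * (p[2] - py[i]) / (py[j] - py[i]) + px[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Region containing a position
#'
#' Even-odd point-in-polygon test over the environment's named regions.
#'
#' @param position Length-2 numeric.
#' @param env A `nav_env`.
#' @return The region id, or `NA` if the point lies in no region.
#' @export
region_of <- function(position, env) {
  for (r in env$regions) {
    if (point_in_polygon(position, r$x, r$y)) return(r$id)
  }
  NA_character_
}

#' Write / read an environment spec file
#'
#' Structured-text (YAML) serialization of walls, cues, regions, landmarks,
#' map edges, start pose and goal; numeric values keep full precision so a
#' build -> dump -> load round trip is bit-identical.
#'
#' @param env A `nav_env`.
#' @param path File path.
#' @export
write_environment <- function(env, path) {
  ser <- list(
    name = env$name,
    walls = apply(unname(env$walls), 1, as.list),
    cues = lapply(seq_len(nrow(env$cues)), function(i) as.list(env$cues[i, ])),
    regions = unname(env$regions),
    landmarks = lapply(seq_len(nrow(env$map$landmarks)), function(i)
      as.list(env$map$landmarks[i, c("id", "x", "y", "is_goal")])),
    edges = lapply(seq_len(nrow(env$map$edges)), function(i)
      as.list(env$map$edges[i, c("from", "to")])),
    start = env$start,
    goal_id = env$goal_id,
    junction_ids = as.list(env$junction_ids))
  yaml::write_yaml(ser, path, precision = 17)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  s <- yaml::read_yaml(path)
  walls <- walls_matrix(lapply(s$walls, function(w) unlist(w)))
  cues <- do.call(rbind, lapply(s$cues, as.data.frame))
  lm <- do.call(rbind, lapply(s$landmarks, as.data.frame))
  edges <- if (length(s$edges)) do.call(rbind, lapply(s$edges, as.data.frame))
           else data.frame(from = character(), to = character())
  regions <- s$regions
  names(regions) <- vapply(regions, `[[`, "", "id")
  new_nav_env(s$name, walls, cues, regions, cognitive_map(lm, edges),
              goal_id = if (is.null(s$goal_id)) NA_character_ else s$goal_id,
              start = list(position = unlist(s$start$position),
                           heading = s$start$heading),
              junction_ids = unlist(s$junction_ids) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
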