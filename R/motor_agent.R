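# Motor module: movement-cell activity -> wheel velocities -> differential
# drive pose update with sliding collision resolution against wall segments.

#' Agent state
#'
#' Planar pose plus kinematic constants. `speed_scale` converts mean wheel
#' velocity to length per step; `wheelbase` sets the turn rate.
#'
#' @param position Length-2 numeric.
#' @param heading Allocentric heading, degrees.
#' @param body_radius,speed_scale,wheelbase Kinematic constants (> 0).
#' @export
agent_state <- function(position, heading,
                        body_radius = 0.15, speed_scale = 0.2,
                        wheelbase = 0.3) {
  stopifnot(body_radius > 0, wheelbase > 0)
  structure(list(position = as.numeric(position),
                 heading = wrap_angle(heading),
                 body_radius = body_radius, speed_scale = speed_scale,
                 wheelbase = wheelbase),
            class = "agent_state")
}

#' Wheel velocities from movement-cell activity
#'
#' The forward drive feeds both wheels; each turn drive feeds the wheel on
#' its own side, so the wheel opposite the stronger turn band slows and the
#' agent rotates toward the active band. The raw vector is divided by twice
#' its maximum, so the larger component is exactly 0.5 and both lie in
#' \[0, 0.5\] (the model cannot reverse). All-zero activity yields a zero
#' command (the agent halts for the step).
#'
#' @param mv A `movement_cell_activity`.
#' @return List with `v_left`, `v_right` in \[0, 0.5\].
#' @export
velocity_command <- function(mv) {
  raw_l <- mv$mv_forward + mv$mv_left
  raw_r <- mv$mv_forward + mv$mv_right
  m <- max(raw_l, raw_r)
  if (m <= 0) return(list(v_left = 0, v_right = 0))
  list(v_left = raw_l / (2 * m), v_right = raw_r / (2 * m))
}

# squared distance from points (px, py) to segment (x1,y1)-(x2,y2); inputs
# px/py scalars, segment coordinates vectors (one entry per wall)
.seg_dist <- function(p, walls) {
  vx <- walls[, 3] - walls[, 1]
  vy <- walls[, 4] - walls[, 2]
  wx <- p[1] - walls[, 1]
  wy <- p[2] - walls[, 2]
  len2 <- vx^2 + vy^2
  t <- pmin(1, pmax(0, ifelse(len2 > 0, (wx * vx + wy * vy) / len2, 0)))
  cx <- walls[, 1] + t * vx
  cy <- walls[, 2] + t * vy
  list(dist = sqrt((p[1] - cx)^2 + (p[2] - cy)^2), cx = cx, cy = cy)
}

# push the centre out of every wall it penetrates (closest-point normal);
# a straight drive into a wall thereby slides along the wall tangent
resolve_collisions <- function(pos, walls, body_radius, iterations = 4L) {
  if (is.null(walls) || nrow(walls) == 0L) return(pos)
  for (it in seq_len(iterations)) {
    sd <- .seg_dist(pos, walls)
    pen <- which(sd$dist < body_radius)
    if (!length(pen)) break
    k <- pen[which.min(sd$dist[pen])]
    n <- pos - c(sd$cx[k], sd$cy[k])
    nd <- sqrt(sum(n^2))
    if (nd < 1e-12) {  # centre exactly on the wall: push along wall normal
      v <- c(walls[k, 3] - walls[k, 1], walls[k, 4] - walls[k, 2])
      n <- c(-v[2], v[1])
      nd <- sqrt(sum(n^2))
    }
    pos <- c(sd$cx[k], sd$cy[k]) + n / nd * body_radius
  }
  pos
}

#' Advance the differential-drive agent one step
#'
#' Heading change is proportional to the wheel-velocity difference
#' (`(v_right - v_left) * speed_scale / wheelbase`, counter-clockwise
#' positive), translation to the mean wheel velocity along the new heading.
#' The proposed position is then resolved against the environment's wall
#' segments: penetrating motion is pushed out along the wall normal, which
#' yields sliding along walls rather than stopping.
#'
#' @param agent An `agent_state`.
#' @param v A velocity command from [velocity_command()].
#' @param walls Matrix with columns x1, y1, x2, y2 (one wall per row), or
#'   NULL for an unbounded arena.
#' @param wall_turn Obstacle-avoidance turn rate in degrees per blocked step
#'   (0 disables). When nearly all commanded motion is absorbed by a wall
#'   (a head-on press, where sliding stalls), the heading rotates by this
#'   amount toward the wall tangent closest to the current heading, so the
#'   agent works its way along the wall instead of stalling. Goal-directed
#'   strategies use this; ballistic route-replay overrides do not.
#' @return The updated `agent_state`.
#' @export
step_kinematics <- function(agent, v, walls = NULL, wall_turn = 0) {
  if (v$v_left < 0 || v$v_right < 0) stop("step_kinematics: negative wheel velocity")
  dtheta <- (v$v_right - v$v_left) * agent$speed_scale / agent$wheelbase *
    180 / pi
  agent$heading <- wrap_angle(agent$heading + dtheta)
  ds <- (v$v_left + v$v_right) / 2 * agent$speed_scale
  proposed <- agent$position +
    ds * c(cos(agent$heading * pi / 180), sin(agent$heading * pi / 180))
  resolved <- unname(resolve_collisions(proposed, walls, agent$body_radius))
  if (wall_turn > 0 && ds > 0 && !is.null(walls) && nrow(walls) > 0) {
    moved <- sqrt(sum((resolved - agent$position)^2))
    # head-on press: sliding stalls, so rotate toward the nearer of the
    # pressed wall's two tangent directions until motion resumes
    if (moved < 0.3 * ds) {
      sd <- .seg_dist(resolved, walls)
      k <- which.min(sd$dist)
      tang <- atan2(walls[k, 4] - walls[k, 2], walls[k, 3] - walls[k, 1]) *
        180 / pi
      d1 <- wrap_angle(tang - agent$heading)
      d2 <- wrap_angle(tang + 180 - agent$heading)
      towards <- if (abs(d1) <= abs(d2)) d1 else d2
      agent$heading <- wrap_angle(agent$heading +
                                  sign(towards) * min(wall_turn, abs(towards)))
    }
  }
  agent$position <- resolved
  agent
}
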