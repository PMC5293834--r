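# Hippocampus: topological cognitive map with winner-take-all place cells,
# landmark-graph route search and the 360-unit allocentric goal direction
# (AGD) population. The map is supplied to the agent (no map learning).

#' Allocentric bearing between two points
#'
#' Single bearing convention for the whole package: 0 degrees along +x,
#' counter-clockwise positive, computed with the two-argument arctangent and
#' wrapped into (-180, 180].
#'
#' @param from,to Numeric length-2 coordinates (or matrices with 2 columns).
#' @return Bearing in degrees.
#' @export
bearing <- function(from, to) {
  dx <- to[1] - from[1]
  dy <- to[2] - from[2]
  wrap_angle(atan2(dy, dx) * 180 / pi)
}

#' Construct a cognitive map
#'
#' A cognitive map is a landmark graph: landmarks carry Cartesian positions
#' and goal flags, edges are symmetric and carry the Euclidean distance and
#' allocentric direction between their endpoints (derived from coordinates,
#' never stored independently).
#'
#' @param landmarks data.frame with columns `id` (character, unique), `x`,
#'   `y`, and optionally `is_goal` (logical).
#' @param edges data.frame with columns `from`, `to` (landmark ids).
#' @return A `cognitive_map` object.
#' @export
cognitive_map <- function(landmarks, edges) {
  stopifnot(is.data.frame(landmarks), all(c("id", "x", "y") %in% names(landmarks)))
  landmarks$id <- as.character(landmarks$id)
  if (anyDuplicated(landmarks$id)) stop("cognitive_map: duplicate landmark ids")
  if (is.null(landmarks$is_goal)) landmarks$is_goal <- logical(nrow(landmarks))
  if (nrow(edges)) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    bad <- !(edges$from %in% landmarks$id) | !(edges$to %in% landmarks$id)
    if (any(bad)) stop("cognitive_map: edge endpoint not a landmark")
    i <- match(edges$from, landmarks$id)
    j <- match(edges$to, landmarks$id)
    edges$distance <- sqrt((landmarks$x[i] - landmarks$x[j])^2 +
                           (landmarks$y[i] - landmarks$y[j])^2)
    edges$direction <- wrap_angle(atan2(landmarks$y[j] - landmarks$y[i],
                                        landmarks$x[j] - landmarks$x[i]) * 180 / pi)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        distance = numeric(), direction = numeric())
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = landmarks[, "id", drop = FALSE])
  if (nrow(edges)) igraph::E(g)$weight <- edges$distance
  structure(list(landmarks = landmarks, edges = edges, graph = g),
            class = "cognitive_map")
}

#' @export
print.cognitive_map <- function(x, ...) {
  cat(sprintf("<cognitive_map> %d landmarks, %d edges, %d goal(s)\n",
              nrow(x$landmarks), nrow(x$edges), sum(x$landmarks$is_goal)))
  invisible(x)
}

#' Position of a landmark
#'
#' @param map A `cognitive_map`.
#' @param id Landmark id.
#' @return Length-2 numeric position.
#' @export
landmark_position <- function(map, id) {
  i <- match(id, map$landmarks$id)
  if (is.na(i)) stop("unknown landmark id: ", id)
  c(map$landmarks$x[i], map$landmarks$y[i])
}

#' Winner-take-all place cell
#'
#' Only the place cell whose landmark is closest to the agent is considered
#' active; ties break toward the lowest (alphabetically first) id.
#'
#' @param position Length-2 numeric position.
#' @param map A `cognitive_map`.
#' @return The id of the active landmark.
#' @export
active_place_cell <- function(position, map) {
  lm <- map$landmarks
  if (nrow(lm) == 0L) stop("active_place_cell: empty map")
  d <- sqrt((lm$x - position[1])^2 + (lm$y - position[2])^2)
  ord <- order(d, lm$id)
  lm$id[ord[1]]
}

#' Shortest route over the landmark graph
#'
#' Minimum-total-distance landmark sequence from `start` to `goal`
#' (Dijkstra over edge distances). Errors if the goal is unreachable so the
#' caller can fall back to non-route strategies.
#'
#' @param map A `cognitive_map`.
#' @param start,goal Landmark ids.
#' @return Character vector of landmark ids, first `start`, last `goal`.
#' @export
plan_route <- function(map, start, goal) {
  lm_ids <- map$landmarks$id
  if (!(start %in% lm_ids) || !(goal %in% lm_ids)) {
    stop("plan_route: unknown landmark id")
  }
  if (start == goal) return(start)
  sp <- suppressWarnings(
    igraph::shortest_paths(map$graph, from = start, to = goal,
                           mode = "all", output = "vpath"))
  v <- sp$vpath[[1]]
  if (length(v) == 0L) {
    stop("plan_route: no route from '", start, "' to '", goal, "'")
  }
  names(v)
}

#' Goal vector of a route
#'
#' Vector sum of the route's edge displacements, i.e. the straight-line
#' displacement from the first to the last landmark, expressed as distance
#' plus allocentric direction. A single-landmark route returns distance 0
#' with direction 0 by convention.
#'
#' @param map A `cognitive_map`.
#' @param route Character vector of landmark ids.
#' @return List with `distance` and `direction` (degrees).
#' @export
goal_vector <- function(map, route) {
  if (length(route) < 1L) stop("goal_vector: empty route")
  idx <- match(route, map$landmarks$id)
  if (anyNA(idx)) stop("goal_vector: route contains unknown landmark")
  if (length(route) == 1L) return(list(distance = 0, direction = 0))
  p1 <- c(map$landmarks$x[idx[1]], map$landmarks$y[idx[1]])
  p2 <- c(map$landmarks$x[idx[length(idx)]], map$landmarks$y[idx[length(idx)]])
  list(distance = sqrt(sum((p2 - p1)^2)), direction = bearing(p1, p2))
}

#' Allocentric goal direction population
#'
#' Encodes the allocentric goal direction in 360 AGD cells (1 degree
#' spacing, sigma = 10) and applies the noise + max-normalization stage.
#'
#' @param goal_direction Allocentric goal direction, degrees.
#' @param noise A `noise_model`.
#' @return A normalized `cell_population` of 360 units.
#' @export
agd_population <- function(goal_direction, noise = noise_model(0)) {
  add_noise_and_normalize(encode_population(goal_direction, sigma = 10,
                                            n_units = 360L), noise)
}
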