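# shared fixtures, built in code

# three landmarks on a 3-4-5 right triangle
triangle_map <- function() {
  cognitive_map(
    data.frame(id = c("A", "B", "C"), x = c(0, 3, 3), y = c(0, 0, 4)),
    data.frame(from = c("A", "B"), to = c("B", "C")))
}

# random connected landmark graph: spanning tree plus extra edges
random_map <- function(n = 8, extra = 4) {
  lm <- data.frame(id = sprintf("L%02d", seq_len(n)),
                   x = stats::runif(n, 0, 10), y = stats::runif(n, 0, 10))
  edges <- data.frame(from = lm$id[1 + floor(stats::runif(n - 1) * (seq_len(n - 1)))],
                      to = lm$id[2:n])
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2)
    edges <- rbind(edges, data.frame(from = lm$id[ij[1]], to = lm$id[ij[2]]))
  }
  cognitive_map(lm, unique(edges))
}

# exhaustive simple-path enumeration oracle for shortest routes
enumerate_shortest <- function(map, start, goal) {
  lm <- map$landmarks
  adj <- lapply(stats::setNames(lm$id, lm$id), function(id) {
    c(map$edges$to[map$edges$from == id], map$edges$from[map$edges$to == id])
  })
  pos <- function(id) c(lm$x[lm$id == id], lm$y[lm$id == id])
  best <- Inf
  walk <- function(node, visited, len) {
    if (len >= best) return()
    if (node == goal) { best <<- len; return() }
    for (nb in adj[[node]]) {
      if (!(nb %in% visited)) {
        walk(nb, c(visited, nb), len + sqrt(sum((pos(nb) - pos(node))^2)))
      }
    }
  }
  walk(start, start, 0)
  best
}

route_distance <- function(map, route) {
  if (length(route) < 2) return(0)
  idx <- match(route, map$landmarks$id)
  sum(sqrt(diff(map$landmarks$x[idx])^2 + diff(map$landmarks$y[idx])^2))
}
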