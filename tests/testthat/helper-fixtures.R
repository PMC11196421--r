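# Small fixtures built in code, shared across test files.

# 5-node toy maze on a grid: one L-shaped corridor plus a spur
#
#   D(0,4) - E(3,4)
#   |
#   A(0,0) - B(3,0) - C(6,0)
toy_maze <- function() {
  nodes <- data.frame(
    id = c("A", "B", "C", "D", "E"),
    kind = c("target_object", "hallway", "target_object", "hallway",
             "target_object"),
    object_name = c("guitar", NA, "chair", NA, "lamp post"),
    painting_adjacent = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    x = c(0, 3, 6, 0, 3), y = c(0, 0, 0, 4, 4))
  edges <- data.frame(from = c("A", "B", "A", "D"),
                      to = c("B", "C", "D", "E"),
                      length = c(3, 3, 4, 3))
  maze_graph(nodes, edges)
}

# hand-built event log: forward moves and in-place turns with physical times
toy_log <- function(events, start = "A", heading = 90, duration = 480,
                    id = "p1", block = 1) {
  event_log(id, block, events, start_location = start,
            start_heading = heading, duration_s = duration)
}

# random valid walk on a maze expressed as key events; independent of the
# simulator (used as replay oracle input)
random_walk_events <- function(maze, n_moves, start = maze$nodes$id[1],
                               seed = 1) {
  set.seed(seed)
  e <- maze$edges
  nbrs <- split(c(e$to, e$from), factor(c(e$from, e$to),
                                        levels = maze$nodes$id))
  loc <- start
  heading <- 0
  t <- 0
  rows <- list()
  for (i in seq_len(n_moves)) {
    turn <- sample(c("none", "left", "right"), 1)
    if (turn != "none") {
      heading <- (heading + if (turn == "right") 90 else -90) %% 360
      t <- t + stats::runif(1, 0.1, 0.5)
      rows[[length(rows) + 1]] <- data.frame(
        t = t, key = turn, location_after = loc, heading_after = heading)
    }
    loc <- sample(nbrs[[loc]], 1)
    t <- t + stats::runif(1, 0.1, 0.5)
    rows[[length(rows) + 1]] <- data.frame(
      t = t, key = "forward", location_after = loc, heading_after = heading)
  }
  ev <- do.call(rbind, rows)
  ev$t <- ev$t / max(ev$t) * 400  # keep within the block
  ev
}

# a visit_sequence whose collapsed counts equal `counts` (named by node id);
# greedy arrangement (largest remaining count first, never repeating the
# previous letter) -- feasible when max(counts) <= sum(others) + 1
sequence_with_counts <- function(counts) {
  counts <- counts[counts > 0]
  out <- character(sum(counts))
  prev <- ""
  for (i in seq_along(out)) {
    cand <- names(counts)[counts > 0 & names(counts) != prev]
    pick <- cand[which.max(counts[cand])]
    out[i] <- pick
    counts[pick] <- counts[pick] - 1
    prev <- pick
  }
  visit_sequence(out)
}

# tiny synthetic cohort for statistics tests (not via the simulator):
# deterministic metric columns with known group structure
stub_cohort <- function(n_per_group = 20, shift = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("young", "midlife"), each = n_per_group)
  d <- data.frame(
    participant_id = sprintf("S%02d", seq_len(n)),
    group = factor(group, levels = c("young", "midlife")),
    sex = factor(rep(c("F", "M"), n / 2), levels = c("F", "M")),
    age = ifelse(group == "young", runif(n, 18, 28), runif(n, 43, 61)))
  for (v in metric_names())
    d[[v]] <- rnorm(n) + shift * (group == "midlife")
  d$wayfinding_success <- pmin(1, pmax(0, 0.4 + rnorm(n, sd = 0.15) -
                                         0.2 * (group == "midlife")))
  d
}
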