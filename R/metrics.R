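#' @keywords internal
#' Visit counts over all maze locations (zero-count locations included)
visit_counts <- function(x, maze) {
  if (inherits(x, "pooled_blocks")) {
    letters_all <- unlist(lapply(x$blocks, function(b) b$collapsed))
  } else if (inherits(x, "visit_sequence")) {
    letters_all <- x$collapsed
  } else {
    letters_all <- collapse_repeats(x)
  }
  bad <- setdiff(unique(letters_all), maze$nodes$id)
  if (length(bad) > 0)
    stop("visited letter not in maze: ", paste(bad, collapse = ", "))
  table(factor(letters_all, levels = maze$nodes$id))
}

edge_length_map <- function(maze) {
  e <- maze$edges
  stats::setNames(e$length, paste(pmin(e$from, e$to), pmax(e$from, e$to)))
}

#' Shannon path roaming entropy of a visit distribution
#'
#' Every maze location is a bin; `P(i)` is the share of (collapsed) visits
#' falling in bin `i`, and the measure is the Shannon entropy
#' `H = -sum_i P(i) ln P(i)` in nats, with `0 ln 0 = 0`. `H` ranges from 0
#' (all visits at one location) to `ln(n)` for `n` locations visited evenly;
#' higher values mean more evenly spread exploration.
#'
#' @param x a [visit_sequence()], [concat_blocks()] result, or letter vector
#' @param maze a [maze_graph()] defining the bins
#' @return entropy in nats
#' @examples
#' m <- default_maze()
#' path_roaming_entropy(visit_sequence(m$nodes$id), m)  # ln 26
#' @export
path_roaming_entropy <- function(x, maze) {
  counts <- visit_counts(x, maze)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Clustering of exploration: spread of visit counts over one node kind
#'
#' The sample standard deviation (denominator n - 1) of visit counts across
#' all nodes of the requested kind, never-visited nodes counting as zero.
#' Higher values mean visits concentrated on few locations (more clustered
#' exploration); 0 means perfectly even coverage of that kind.
#'
#' @inheritParams path_roaming_entropy
#' @param kind `"target_object"` or `"hallway"`
#' @return standard deviation of visit counts
#' @export
clustering_sd <- function(x, maze, kind = c("target_object", "hallway")) {
  kind <- match.arg(kind)
  ids <- maze$nodes$id[maze$nodes$kind == kind]
  if (length(ids) < 2)
    stop("need at least 2 nodes of kind ", kind)
  counts <- visit_counts(x, maze)[ids]
  stats::sd(counts)
}

#' Longest hallway sequence
#'
#' The largest number of consecutive hallway-junction visits without an
#' intervening target-object visit, computed on the collapsed sequence.
#' Runs are broken by target visits and by the block boundary (participants
#' are re-placed between blocks). Returns 0 when no hallway was visited.
#'
#' @inheritParams path_roaming_entropy
#' @return maximal run length (count)
#' @export
longest_hallway_sequence <- function(x, maze) {
  blocks <- if (inherits(x, "pooled_blocks")) x$blocks else list(
    if (inherits(x, "visit_sequence")) x else visit_sequence(x))
  kind <- node_kind(maze)
  runs_max <- vapply(blocks, function(b) {
    is_hall <- kind[b$collapsed] == "hallway"
    if (!any(is_hall)) return(0L)
    r <- rle(unname(is_hall))
    max(r$lengths[r$values])
  }, numeric(1))
  max(runs_max)
}

replay_times <- function(log, maze) {
  # per-press dwell = press time minus the moment the previous action
  # finished (rotation 1 s per 90 degrees, travel edge-length seconds)
  elen <- edge_length_map(maze)
  loc <- attr(log, "start_location")
  ready <- 0
  dwell <- 0
  travel <- 0
  for (i in seq_len(nrow(log))) {
    dwell <- dwell + max(0, log$t[i] - ready)
    start_of_action <- max(ready, log$t[i])
    if (log$key[i] == "forward") {
      nxt <- log$location_after[i]
      len <- elen[[paste(min(loc, nxt), max(loc, nxt))]]
      if (is.null(len))
        stop("no maze edge between ", loc, " and ", nxt)
      travel <- travel + len
      ready <- start_of_action + len
      loc <- nxt
    } else {
      ready <- start_of_action + 1
    }
  }
  dwell <- dwell + max(0, attr(log, "duration_s") - ready)
  list(dwell = dwell, travel = travel)
}

#' Count-based exploration measures for one block or pooled blocks
#'
#' Computes the six count/time measures: `distance_traveled` (sum of edge
#' lengths over successive distinct locations, virtual units), `turns_made`
#' (left/right presses), `pause_duration` (total idle time at locations
#' between arriving / finishing a rotation and the next press, seconds),
#' `button_presses`, `target_object_visits` and `hallway_visits` (collapsed
#' visits split by node kind). Without timestamped logs, `turns_made` falls
#' back to counting string repeats and `button_presses` to the letter count;
#' `pause_duration` is then unavailable and raises an error unless
#' `require_time = FALSE`.
#'
#' @param x a [visit_sequence()] or [concat_blocks()] result
#' @param maze a [maze_graph()]
#' @param logs optional [event_log()] (or list, one per block)
#' @param require_time error (default) or return `NA` for time measures
#'   when no timestamped log is available
#' @return named numeric vector of the six measures
#' @export
count_metrics <- function(x, maze, logs = NULL, require_time = TRUE) {
  if (inherits(x, "visit_sequence")) {
    blocks <- list(x)
    if (inherits(logs, "event_log")) logs <- list(logs)
  } else if (inherits(x, "pooled_blocks")) {
    blocks <- x$blocks
    if (is.null(logs)) logs <- x$logs
  } else stop("x must be a visit_sequence or pooled blocks")
  elen <- edge_length_map(maze)
  dist_block <- vapply(blocks, function(b) {
    s <- b$collapsed
    if (length(s) < 2) return(0)
    a <- s[-length(s)]; b2 <- s[-1]
    keys <- paste(pmin(a, b2), pmax(a, b2))
    miss <- setdiff(keys, names(elen))
    if (length(miss) > 0)
      stop("sequence uses non-edges: ", paste(miss, collapse = ", "))
    sum(elen[keys])
  }, numeric(1))
  counts <- visit_counts(x, maze)
  kind <- node_kind(maze)
  have_logs <- !is.null(logs) && length(logs) == length(blocks)
  if (have_logs) {
    turns <- sum(vapply(logs, function(l)
      sum(l$key %in% c("left", "right")), numeric(1)))
    presses <- sum(vapply(logs, nrow, integer(1)))
    rep_times <- lapply(logs, replay_times, maze = maze)
    pause <- sum(vapply(rep_times, `[[`, numeric(1), "dwell"))
  } else {
    # string fallback: each consecutive repeat beyond the first is one turn,
    # each letter after the block's first is one press
    turns <- sum(vapply(blocks, function(b) {
      r <- rle(b$raw); sum(r$lengths - 1L)
    }, numeric(1)))
    presses <- sum(vapply(blocks, function(b) length(b$raw) - 1L,
                          numeric(1)))
    if (require_time)
      stop("pause_duration unavailable: no timestamped event log supplied")
    pause <- NA_real_
  }
  c(distance_traveled = sum(dist_block),
    turns_made = turns,
    pause_duration = pause,
    button_presses = presses,
    target_object_visits = sum(counts[kind[names(counts)] == "target_object"]),
    hallway_visits = sum(counts[kind[names(counts)] == "hallway"]))
}

#' All ten exploration measures for one participant
#'
#' Pools the participant's exploration blocks and returns the full measure
#' vector: the six count/time measures of [count_metrics()] plus
#' `path_roaming_entropy`, `clustering_objects`, `clustering_hallways` and
#' `longest_hallway_sequence`.
#'
#' @param pooled a [concat_blocks()] result (or single [visit_sequence()])
#' @param maze a [maze_graph()]
#' @param require_time see [count_metrics()]
#' @return named numeric vector of the ten exploration measures
#' @export
participant_metrics <- function(pooled, maze, require_time = TRUE) {
  if (inherits(pooled, "visit_sequence")) pooled <- concat_blocks(pooled)
  c(count_metrics(pooled, maze, require_time = require_time),
    path_roaming_entropy = path_roaming_entropy(pooled, maze),
    clustering_objects = clustering_sd(pooled, maze, "target_object"),
    clustering_hallways = clustering_sd(pooled, maze, "hallway"),
    longest_hallway_sequence = longest_hallway_sequence(pooled, maze))
}

#' Wayfinding success over the 24 test trials
#'
#' The test phase is a single block of 24 timed wayfinding trials (45 s
#' each); the outcome measure is the proportion of successful trials.
#' Chance level is 1/9 (0.11): one of nine target objects is correct.
#'
#' @param outcomes logical (or 0/1) vector of exactly 24 trial outcomes
#' @return list of class `test_phase_result` with `n_trials`, `n_success`,
#'   `wayfinding_success`
#' @export
wayfinding_success <- function(outcomes) {
  outcomes <- as.logical(outcomes)
  if (length(outcomes) != 24 || anyNA(outcomes))
    stop("need exactly 24 trial outcomes (got ", length(outcomes), ")")
  structure(list(n_trials = 24L, n_success = sum(outcomes),
                 wayfinding_success = mean(outcomes)),
            class = "test_phase_result")
}

#' @export
print.test_phase_result <- function(x, ...) {
  cat("Test phase: ", x$n_success, "/", x$n_trials,
      " successful trials (proportion ",
      round(x$wayfinding_success, 3), ")\n", sep = "")
  invisible(x)
}

#' Chance level of wayfinding success
#'
#' One-in-nine probability of reaching the correct target by chance,
#' rounded to two decimals as conventionally reported.
#' @return 0.11
#' @export
chance_level <- function() round(1 / 9, 2)

#' Write a per-participant metrics table as CSV
#'
#' One row per participant; columns are the ten exploration measures,
#' `wayfinding_success`, `group` and `sex`.
#'
#' @param tab cohort data.frame (see [generate_cohort()])
#' @param path CSV file path
#' @export
write_metrics_csv <- function(tab, path) {
  cols <- c("participant_id", metric_names(), "wayfinding_success",
            "group", "sex")
  utils::write.csv(tab[, intersect(cols, names(tab))], path,
                   row.names = FALSE)
  invisible(path)
}

#' Names of the ten exploration measures
#' @return character vector of length 10
#' @export
metric_names <- function() {
  c("distance_traveled", "turns_made", "pause_duration", "button_presses",
    "target_object_visits", "hallway_visits", "path_roaming_entropy",
    "clustering_objects", "clustering_hallways", "longest_hallway_sequence")
}
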