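#' Visit sequences: the letter coding of an exploration trajectory
#'
#' Exploration is coded as the temporal order of visited maze locations, one
#' letter per decision point. A turn in place at a location repeats its
#' letter ("AA" = arrive at A, then turn in place at A); because several
#' count-based measures treat a stay as a single visit, consecutive repeats
#' are collapsed ("AA" becomes "A") in the `collapsed` component.
#'
#' @param raw character vector of node letters in temporal order (repeats
#'   allowed), or a single string which is split into letters
#' @return an object of class `visit_sequence` with components `raw` and
#'   `collapsed`
#' @examples
#' visit_sequence("AGGH")$collapsed  # "A" "G" "H"
#' @export
visit_sequence <- function(raw) {
  if (length(raw) == 1 && nchar(raw) > 1) raw <- strsplit(raw, "")[[1]]
  if (length(raw) == 0) stop("empty visit sequence")
  structure(list(raw = raw, collapsed = collapse_repeats(raw)),
            class = "visit_sequence")
}

#' @export
print.visit_sequence <- function(x, ...) {
  cat("Visit sequence: ", length(x$raw), " raw / ",
      length(x$collapsed), " collapsed letters\n", sep = "")
  cat("  ", paste(x$collapsed, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Collapse consecutive repeated letters
#'
#' Maximal runs of the same letter become a single letter; the temporal
#' order is preserved. Idempotent.
#'
#' @param raw nonempty character vector of letters (or one string)
#' @return character vector without adjacent duplicates
#' @examples
#' collapse_repeats(c("A", "A", "A", "B", "B", "A"))  # "A" "B" "A"
#' @export
collapse_repeats <- function(raw) {
  if (length(raw) == 1 && is.character(raw) && nchar(raw) > 1)
    raw <- strsplit(raw, "")[[1]]
  if (length(raw) == 0) stop("cannot collapse an empty sequence")
  rle(raw)$values
}

#' Build an event log
#'
#' An event log is the timestamped key-press record of one 8-minute
#' exploration block: each row is one press of forward / left / right with
#' the resulting location and heading. The starting location (and heading)
#' are stored as attributes since they precede any press.
#'
#' @param participant_id participant identifier
#' @param block block number (1 or 2)
#' @param events data.frame with columns `t` (seconds since block start,
#'   non-decreasing), `key` (`"forward"`, `"left"` or `"right"`),
#'   `location_after` (node id) and `heading_after` (0/90/180/270)
#' @param start_location node id occupied at t = 0
#' @param start_heading heading at t = 0
#' @param duration_s block duration in seconds (default 480)
#' @param maze optional [maze_graph()]; when given, forward moves must land
#'   on an adjacent node and turns must keep the location
#' @return a data.frame of class `event_log` with attributes
#'   `participant_id`, `block`, `start_location`, `start_heading`,
#'   `duration_s`
#' @export
event_log <- function(participant_id, block, events, start_location,
                      start_heading = 0, duration_s = 480, maze = NULL) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events) > 0) {
    if (!all(c("t", "key", "location_after", "heading_after") %in%
             names(events)))
      stop("events need columns t, key, location_after, heading_after")
    if (is.unsorted(events$t)) stop("event times must be non-decreasing")
    if (any(events$t > duration_s))
      stop("event time exceeds block duration")
    bad <- !events$key %in% c("forward", "left", "right")
    if (any(bad)) stop("unknown key: ", paste(unique(events$key[bad]),
                                              collapse = ", "))
  } else {
    events <- data.frame(t = numeric(0), key = character(0),
                         location_after = character(0),
                         heading_after = numeric(0))
  }
  out <- structure(events, class = c("event_log", "data.frame"),
                   participant_id = participant_id, block = block,
                   start_location = start_location,
                   start_heading = start_heading, duration_s = duration_s)
  if (!is.null(maze)) validate_events(out, maze)
  out
}

adjacency_list <- function(maze) {
  e <- maze$edges
  adj <- split(c(e$to, e$from), factor(c(e$from, e$to),
                                       levels = maze$nodes$id))
  lapply(adj, unique)
}

validate_events <- function(log, maze) {
  loc <- attr(log, "start_location")
  if (!loc %in% maze$nodes$id)
    stop("start location not in maze: ", loc)
  nbrs <- adjacency_list(maze)
  for (i in seq_len(nrow(log))) {
    nxt <- log$location_after[i]
    if (log$key[i] == "forward") {
      if (!nxt %in% nbrs[[loc]])
        stop("event ", i, ": forward from ", loc, " to non-adjacent ", nxt)
    } else if (nxt != loc) {
      stop("event ", i, ": turn must keep location (", loc, " -> ", nxt, ")")
    }
    loc <- nxt
  }
  invisible(TRUE)
}

#' Derive the visit-letter sequence from an event log
#'
#' The raw sequence starts with the block's starting location and then
#' appends one letter per key press: a forward press appends the new
#' location, a left/right press appends the current location again (the
#' turn-in-place repeat). The collapsed form merges adjacent repeats.
#'
#' @param log an [event_log()]
#' @param maze optional [maze_graph()] used to validate adjacency
#' @return a [visit_sequence()]
#' @export
sequence_from_events <- function(log, maze = NULL) {
  if (!is.null(maze)) validate_events(log, maze)
  raw <- c(attr(log, "start_location"), log$location_after)
  visit_sequence(raw)
}

#' Pool the two exploration blocks of one participant
#'
#' Final exploration scores are computed over both 8-minute blocks put
#' together: counts, distances and durations accumulate, but the block
#' boundary is kept — participants are re-placed between blocks, so no
#' transition is created between block 1's last and block 2's first
#' location, and runs (repeat collapsing, hallway runs) never span blocks.
#'
#' @param seqs list of [visit_sequence()] objects, one per block
#' @param logs optional list of matching [event_log()] objects (checked for
#'   a common participant)
#' @return an object of class `pooled_blocks`: list with `blocks` (the
#'   sequences), `logs`, `n_blocks`, and `duration_s` (total)
#' @export
concat_blocks <- function(seqs, logs = NULL) {
  if (length(seqs) == 0) stop("no blocks given")
  if (inherits(seqs, "visit_sequence")) seqs <- list(seqs)
  stopifnot(all(vapply(seqs, inherits, logical(1), "visit_sequence")))
  duration <- NA_real_
  if (!is.null(logs)) {
    if (inherits(logs, "event_log")) logs <- list(logs)
    pid <- unique(vapply(logs, attr, FUN.VALUE = "", "participant_id"))
    if (length(pid) > 1)
      stop("blocks belong to different participants: ",
           paste(pid, collapse = ", "))
    if (length(logs) != length(seqs))
      stop("need one log per sequence")
    duration <- sum(vapply(logs, attr, numeric(1), "duration_s"))
  }
  structure(list(blocks = seqs, logs = logs, n_blocks = length(seqs),
                 duration_s = duration),
            class = "pooled_blocks")
}

#' Read and write exploration event logs as CSV
#'
#' Long-format CSV with columns `participant_id`, `block`, `t`, `key`,
#' `location_after`, `heading_after`, `start_location`, `start_heading`,
#' `duration_s` (the last three repeated per row; blocks with zero presses
#' are kept as a single row with an empty `key`).
#'
#' @param logs a list of [event_log()] objects
#' @param path CSV file path
#' @return `read_event_logs()` returns a list of [event_log()] objects.
#' @export
write_event_logs <- function(logs, path) {
  rows <- lapply(logs, function(l) {
    base <- data.frame(
      participant_id = attr(l, "participant_id"), block = attr(l, "block"),
      start_location = attr(l, "start_location"),
      start_heading = attr(l, "start_heading"),
      duration_s = attr(l, "duration_s"))
    if (nrow(l) == 0)
      return(cbind(base, t = NA_real_, key = "", location_after = "",
                   heading_after = NA_real_))
    cbind(base[rep(1, nrow(l)), , drop = FALSE], as.data.frame(l))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_logs
#' @export
read_event_logs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(d$participant_id, d$block, drop = TRUE)
  lapply(split(d, key), function(b) {
    ev <- b[!is.na(b$t) & nzchar(b$key),
            c("t", "key", "location_after", "heading_after")]
    event_log(b$participant_id[1], b$block[1], ev,
              start_location = b$start_location[1],
              start_heading = b$start_heading[1],
              duration_s = b$duration_s[1])
  })
}

#' Read bare visit sequences from CSV
#'
#' For data without timestamps: CSV with columns `participant_id`, `block`,
#' `sequence` (a letter string). Time-based measures are unavailable for
#' such data and raise an error when requested.
#'
#' @param path CSV file path
#' @return named list (by participant) of lists of [visit_sequence()]
#' @export
read_sequences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$participant_id),
         function(p) lapply(p$sequence[order(p$block)], visit_sequence))
}
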