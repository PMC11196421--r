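#' Construct and validate a maze graph
#'
#' A maze is a connected, undirected, labeled graph of decision points.
#' Each node is either a `target_object` (it holds one of the nine objects
#' participants must learn) or a `hallway` junction; edges are hallways with
#' a positive length in virtual units. Nodes may carry 2-D layout
#' coordinates, which are required for turn-aware travel-time queries
#' (rotation is 90 degrees per second, translation 1 unit per second).
#'
#' @param nodes data.frame with columns `id` (single uppercase letter),
#'   `kind` (`"target_object"` or `"hallway"`), `object_name` (character,
#'   `NA` for hallways), `painting_adjacent` (logical), and optionally
#'   numeric `x`, `y` layout coordinates.
#' @param edges data.frame with columns `from`, `to` (node ids) and `length`
#'   (virtual units, > 0).
#' @return An object of class `maze_graph`: a list with elements `nodes`,
#'   `edges` and `graph` (the underlying [igraph::graph] object).
#' @examples
#' m <- default_maze()
#' m
#' @export
maze_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("id", "kind", "object_name", "painting_adjacent")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0)
    stop("maze nodes lack column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(c("from", "to", "length") %in% names(edges)))
    stop("maze edges need columns from, to, length")
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad_id <- nodes$id[!grepl("^[A-Z]$", nodes$id)]
  if (length(bad_id) > 0)
    stop("node ids must be single uppercase letters; offending: ",
         paste(bad_id, collapse = ", "))
  bad_kind <- nodes$id[!nodes$kind %in% c("target_object", "hallway")]
  if (length(bad_kind) > 0)
    stop("unknown node kind at: ", paste(bad_kind, collapse = ", "))
  has_name <- !is.na(nodes$object_name) & nzchar(nodes$object_name)
  mism <- nodes$id[(nodes$kind == "target_object") != has_name]
  if (length(mism) > 0)
    stop("kind/object_name mismatch (targets need a name, hallways none) at: ",
         paste(mism, collapse = ", "))
  dangling <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(dangling) > 0)
    stop("edge references undeclared node: ", paste(dangling, collapse = ", "))
  if (any(edges$from == edges$to))
    stop("self-loop edge at node: ",
         paste(edges$from[edges$from == edges$to], collapse = ", "))
  bad_len <- edges$length <= 0 | !is.finite(edges$length)
  if (any(bad_len))
    stop("nonpositive edge length on edge(s): ",
         paste(paste0(edges$from[bad_len], "-", edges$to[bad_len]),
               collapse = ", "))
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key))
    stop("duplicate edge: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!"x" %in% names(nodes)) nodes$x <- NA_real_
  if (!"y" %in% names(nodes)) nodes$y <- NA_real_
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "length")], directed = FALSE,
    vertices = nodes[, c("id", "kind", "object_name", "painting_adjacent",
                         "x", "y")])
  if (!igraph::is_connected(g))
    stop("maze graph is not connected; components: ",
         igraph::count_components(g))
  out <- list(nodes = nodes, edges = edges, graph = g)
  class(out) <- "maze_graph"
  out
}

#' @export
print.maze_graph <- function(x, ...) {
  cat("Maze graph: ", nrow(x$nodes), " decision points (",
      sum(x$nodes$kind == "target_object"), " target objects, ",
      sum(x$nodes$kind == "hallway"), " hallway junctions), ",
      nrow(x$edges), " hallway edges\n", sep = "")
  cat("Edge lengths (virtual units): ",
      paste(range(x$edges$length), collapse = "-"),
      "; paintings adjacent at ",
      sum(x$nodes$painting_adjacent), " node(s)\n", sep = "")
  invisible(x)
}

#' Accessors for maze components
#'
#' @param m a [maze_graph()]
#' @return `maze_nodes()` and `maze_edges()` return the node / edge tables;
#'   `target_ids()` and `hallway_ids()` the corresponding node labels;
#'   `node_kind()` a named character vector mapping id to kind.
#' @export
maze_nodes <- function(m) m$nodes

#' @rdname maze_nodes
#' @export
maze_edges <- function(m) m$edges

#' @rdname maze_nodes
#' @export
target_ids <- function(m) m$nodes$id[m$nodes$kind == "target_object"]

#' @rdname maze_nodes
#' @export
hallway_ids <- function(m) m$nodes$id[m$nodes$kind == "hallway"]

#' @rdname maze_nodes
#' @export
node_kind <- function(m) stats::setNames(m$nodes$kind, m$nodes$id)

#' The default 26-location maze
#'
#' A deterministic hedge-maze stand-in laid out on a rectangular grid:
#' 26 decision points labeled A-Z, of which 9 hold the target objects
#' (guitar, snowman, spaceship, lamp post, chicken, trophy, chair, umbrella,
#' cuckoo clock), 4 hallway junctions adjacent to landmark paintings, axis-
#' aligned edges of 3 or 6 virtual units, and node degrees of at most 4.
#' Eight minutes of simulated exploration at 1 unit/s covers distances in
#' the low hundreds of units on this layout.
#'
#' @return a validated [maze_graph()]
#' @export
default_maze <- function() {
  # grid columns at x = 0,3,...,15; rows at y = 0,3,6,9,12; four interior
  # cells omitted so the middle rows form long corridors
  rows <- list(
    list(y = 0,  cols = 1:6,          ids = c("A", "B", "C", "D", "E", "F")),
    list(y = 3,  cols = c(1, 3, 4, 6), ids = c("G", "H", "I", "J")),
    list(y = 6,  cols = 1:6,          ids = c("K", "L", "M", "N", "O", "P")),
    list(y = 9,  cols = c(1, 3, 4, 6), ids = c("Q", "R", "S", "T")),
    list(y = 12, cols = 1:6,          ids = c("U", "V", "W", "X", "Y", "Z")))
  nodes <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r$ids, x = 3 * (r$cols - 1), y = r$y)))
  # targets mostly on low-degree nodes (dead ends, corners), as in a hedge
  # maze where objects sit in alcoves off the main corridors
  objects <- c(B = "guitar", C = "spaceship", E = "snowman", O = "chicken",
               T = "chair", U = "trophy", V = "lamp post", W = "umbrella",
               Z = "cuckoo clock")
  nodes$kind <- ifelse(nodes$id %in% names(objects), "target_object", "hallway")
  nodes$object_name <- unname(objects[nodes$id])
  nodes$painting_adjacent <- nodes$id %in% c("G", "J", "P", "S")
  edge <- function(a, b) data.frame(from = a, to = b)
  edges <- rbind(
    # corridors along rows (some grid walls: C-D, N-O, V-W are hedges)
    edge("A", "B"), edge("B", "C"), edge("D", "E"), edge("E", "F"),
    edge("G", "H"), edge("H", "I"), edge("I", "J"),
    edge("K", "L"), edge("L", "M"), edge("M", "N"), edge("O", "P"),
    edge("Q", "R"), edge("R", "S"), edge("S", "T"),
    edge("U", "V"), edge("W", "X"), edge("X", "Y"), edge("Y", "Z"),
    # cross corridors between rows
    edge("A", "G"), edge("C", "H"), edge("D", "I"), edge("F", "J"),
    edge("G", "K"), edge("H", "M"), edge("I", "N"), edge("J", "P"),
    edge("K", "Q"), edge("M", "R"), edge("N", "S"), edge("P", "T"),
    edge("Q", "U"), edge("R", "W"), edge("S", "X"), edge("T", "Z"),
    # two long corridors through the omitted interior cells
    edge("B", "L"), edge("E", "O"))
  xy <- stats::setNames(split(as.matrix(nodes[, c("x", "y")]), seq_len(26)),
                        nodes$id)
  edges$length <- vapply(seq_len(nrow(edges)), function(i) {
    a <- xy[[edges$from[i]]]; b <- xy[[edges$to[i]]]
    sum(abs(a - b))
  }, numeric(1))
  maze_graph(nodes[, c("id", "kind", "object_name", "painting_adjacent",
                       "x", "y")], edges)
}

#' Read or write a maze description file
#'
#' Two equivalent on-disk dialects are supported, chosen by file extension:
#' GraphML (`.graphml`, node attributes `kind`, `object_name`,
#' `painting_adjacent`, `x`, `y`; edge attribute `length`) and a plain JSON
#' dialect (`.json`, objects `nodes` and `edges` with the same fields).
#' `load_maze(write_maze(m, path))` round-trips exactly.
#'
#' @param path file path ending in `.graphml` or `.json`
#' @param m a [maze_graph()]
#' @return `load_maze()` returns a validated [maze_graph()]; `write_maze()`
#'   returns `path` invisibly.
#' @export
load_maze <- function(path) {
  if (!file.exists(path)) stop("maze file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(
      id = igraph::vertex_attr(g, "name"),
      kind = igraph::vertex_attr(g, "kind"),
      object_name = igraph::vertex_attr(g, "object_name"),
      painting_adjacent = as.logical(igraph::vertex_attr(g, "painting_adjacent")),
      x = as.numeric(igraph::vertex_attr(g, "x")),
      y = as.numeric(igraph::vertex_attr(g, "y")),
      stringsAsFactors = FALSE)
    nodes$object_name[!nzchar(nodes$object_name) | is.na(nodes$object_name)] <-
      NA_character_
    ee <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(from = ee$from, to = ee$to, length = ee$length,
                        stringsAsFactors = FALSE)
  } else if (ext == "json") {
    spec <- jsonlite::fromJSON(path)
    nodes <- as.data.frame(spec$nodes, stringsAsFactors = FALSE)
    if (!is.null(nodes$object_name))
      nodes$object_name[!is.na(nodes$object_name) &
                          !nzchar(nodes$object_name)] <- NA_character_
    edges <- as.data.frame(spec$edges, stringsAsFactors = FALSE)
  } else {
    stop("unsupported maze file extension: .", ext,
         " (use .graphml or .json)")
  }
  maze_graph(nodes, edges)
}

#' @rdname load_maze
#' @export
write_maze <- function(m, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    nodes <- m$nodes
    nodes$object_name[is.na(nodes$object_name)] <- ""
    g <- igraph::graph_from_data_frame(
      m$edges[, c("from", "to", "length")], directed = FALSE,
      vertices = nodes[, c("id", "kind", "object_name", "painting_adjacent",
                           "x", "y")])
    igraph::write_graph(g, path, format = "graphml")
  } else if (ext == "json") {
    jsonlite::write_json(
      list(nodes = m$nodes, edges = m$edges), path,
      dataframe = "rows", na = "null", auto_unbox = FALSE, digits = NA,
      pretty = TRUE)
  } else {
    stop("unsupported maze file extension: .", ext)
  }
  invisible(path)
}

# headings in degrees: 0 = +y, 90 = +x, 180 = -y, 270 = -x
heading_between <- function(ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  ang <- (atan2(dx, dy) * 180 / pi) %% 360
  q <- round(ang / 90) %% 4 * 90
  if (abs(((ang - q + 180) %% 360) - 180) > 1e-6)
    stop("edge is not axis-aligned; turn-aware routing needs grid layout")
  q
}

n_quarter_turns <- function(h1, h2) {
  d <- (h2 - h1) %% 360
  min(d, 360 - d) / 90
}

# directed-edge state expansion used by turn-aware shortest paths; edges is a
# data.frame(from, to, length); coords a named list of c(x, y)
expanded_state_tables <- function(edges, coords) {
  de <- rbind(edges[, c("from", "to", "length")],
              data.frame(from = edges$to, to = edges$from,
                         length = edges$length))
  de$heading <- vapply(seq_len(nrow(de)), function(i) {
    a <- coords[[de$from[i]]]; b <- coords[[de$to[i]]]
    heading_between(a[1], a[2], b[1], b[2])
  }, numeric(1))
  de
}

#' Turn-aware shortest travel time between two maze locations
#'
#' Minimal traversal time in seconds assuming translation at 1 virtual unit
#' per second and rotation at one quarter turn per `turn_cost_s` seconds:
#' the sum of edge lengths along the optimal route plus `turn_cost_s` per 90
#' degrees of heading change at intermediate junctions. The initial heading
#' is free (the traveler may face any direction at the start), which makes
#' the quantity symmetric in its endpoints.
#'
#' @param m a [maze_graph()] with node coordinates
#' @param a,b node ids
#' @param turn_cost_s seconds per 90-degree turn (default 1, the task's
#'   rotation speed)
#' @param edges optional replacement edge table (a subset of the maze edges,
#'   e.g. the part of the maze an agent knows); defaults to all edges
#' @return travel time in seconds (`Inf` if `b` is unreachable from `a`)
#' @export
shortest_path_length <- function(m, a, b, turn_cost_s = 1, edges = NULL) {
  ids <- m$nodes$id
  if (!a %in% ids) stop("unknown node id: ", a)
  if (!b %in% ids) stop("unknown node id: ", b)
  if (a == b) return(0)
  if (is.null(edges)) edges <- m$edges
  if (nrow(edges) == 0) return(Inf)
  if (turn_cost_s > 0 && anyNA(m$nodes$x))
    stop("turn-aware routing requires node coordinates")
  dmat <- state_distances(m, a, turn_cost_s, edges)
  unname(dmat[b])
}

# Dijkstra over (directed edge) states from a single start node; returns the
# named vector of minimal arrival times at every node.
state_distances <- function(m, start, turn_cost_s, edges) {
  coords <- stats::setNames(
    lapply(seq_len(nrow(m$nodes)), function(i) c(m$nodes$x[i], m$nodes$y[i])),
    m$nodes$id)
  de <- expanded_state_tables(edges, coords)
  ns <- nrow(de)
  dist <- rep(Inf, ns)
  # seed: states leaving the start node (initial heading free)
  out0 <- which(de$from == start)
  dist[out0] <- de$length[out0]
  done <- rep(FALSE, ns)
  # successor lists by origin node
  succ <- split(seq_len(ns), de$from)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (length(u) == 0 || !is.finite(dist[u])) break
    done[u] <- TRUE
    vnode <- de$to[u]
    nxt <- succ[[vnode]]
    if (!is.null(nxt)) {
      w <- dist[u] + turn_cost_s * vapply(
        de$heading[nxt], n_quarter_turns, numeric(1), h1 = de$heading[u]) +
        de$length[nxt]
      upd <- nxt[w < dist[nxt] & !done[nxt]]
      if (length(upd) > 0)
        dist[upd] <- pmin(dist[upd],
                          w[match(upd, nxt)])
    }
    if (all(done | !is.finite(dist))) break
  }
  arrive <- tapply(dist, de$to, min)
  out <- stats::setNames(rep(Inf, nrow(m$nodes)), m$nodes$id)
  out[names(arrive)] <- arrive
  out[start] <- 0
  out
}
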