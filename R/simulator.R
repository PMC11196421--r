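#' Agent movement and knowledge profile
#'
#' Parameters of the synthetic explorer. At each decision point the agent
#' dwells (exponential pause, mean `dwell_mean_s` seconds), then moves to a
#' neighboring location: neighbors are drawn with weight
#' `exp(-revisit_aversion * recency)` (recency decays geometrically with the
#' number of decisions since the last visit, so recently seen locations are
#' avoided), except that with probability `target_bias` the agent instead
#' steps along the shortest path toward the least-recently-seen target
#' object it already knows. Rotation costs 1 s per 90 degrees and travel
#' 1 s per virtual unit, inside a 480 s block budget. In the test phase the
#' agent knows each hallway edge it traversed during exploration with
#' probability `1 - knowledge_decay`.
#'
#' Between-participant heterogeneity: each simulated participant draws an
#' individual dwell mean (gamma, coefficient of variation `dwell_cv`),
#' target bias and knowledge decay (normal, truncated to their ranges, SDs
#' `bias_sd` / `decay_sd`) around the profile values.
#'
#' @param dwell_mean_s mean pause per decision, seconds (> 0)
#' @param target_bias probability in `[0, 1]` of steering toward a known
#'   but recently unvisited target object
#' @param revisit_aversion nonnegative weight penalizing recently visited
#'   neighbors
#' @param knowledge_decay probability in `[0, 1]` that a traversed edge is
#'   forgotten before the test phase
#' @param session_s block duration, seconds
#' @param dwell_cv,bias_sd,decay_sd between-participant spread
#' @return list of class `agent_profile`
#' @export
agent_profile <- function(dwell_mean_s = 1.5, target_bias = 0.15,
                          revisit_aversion = 1.5, knowledge_decay = 0.4,
                          session_s = 480, dwell_cv = 0.3, bias_sd = 0.06,
                          decay_sd = 0.1) {
  stopifnot(dwell_mean_s > 0, target_bias >= 0, target_bias <= 1,
            revisit_aversion >= 0, knowledge_decay >= 0,
            knowledge_decay <= 1, session_s > 0, dwell_cv >= 0,
            bias_sd >= 0, decay_sd >= 0)
  structure(list(dwell_mean_s = dwell_mean_s, target_bias = target_bias,
                 revisit_aversion = revisit_aversion,
                 knowledge_decay = knowledge_decay, session_s = session_s,
                 dwell_cv = dwell_cv, bias_sd = bias_sd,
                 decay_sd = decay_sd),
            class = "agent_profile")
}

#' Default group profiles of the synthetic cohort
#'
#' The midlife profile pauses longer at decision points and steers more
#' often toward already-known target objects, and retains less of the
#' traversed maze for the test phase; the young profile favors covering
#' corridors. These settings produce the qualitative young-vs-midlife
#' contrast the analysis pipeline is designed around: less distance, longer
#' pauses, fewer presses, more object visits, fewer hallway visits, shorter
#' hallway runs and lower wayfinding success in the midlife group.
#'
#' @return an [agent_profile()]
#' @export
young_profile <- function() {
  agent_profile(dwell_mean_s = 1.25, target_bias = 0.10,
                revisit_aversion = 1.5, knowledge_decay = 0.25)
}

#' @rdname young_profile
#' @export
midlife_profile <- function() {
  agent_profile(dwell_mean_s = 1.75, target_bias = 0.38,
                revisit_aversion = 1.5, knowledge_decay = 0.50)
}

#' Specification of a synthetic cohort
#'
#' Defaults mirror the study cohort: 87 midlife (64 of 87 female) and 50
#' young (26 of 50 female) participants, ages drawn uniformly in 43-61 and
#' 18-28 years respectively.
#'
#' @param n_young,n_midlife group sizes
#' @param prop_female_young,prop_female_midlife proportion female per group
#' @param young_profile,midlife_profile [agent_profile()] objects
#' @param seed integer master seed; every participant gets a reproducible
#'   substream drawn from it
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_young = 50, n_midlife = 87,
                        prop_female_young = 26 / 50,
                        prop_female_midlife = 64 / 87,
                        young_profile = mazexplore::young_profile(),
                        midlife_profile = mazexplore::midlife_profile(),
                        seed = 1L) {
  stopifnot(n_young > 0, n_midlife > 0,
            prop_female_young >= 0, prop_female_young <= 1,
            prop_female_midlife >= 0, prop_female_midlife <= 1)
  structure(list(n_young = n_young, n_midlife = n_midlife,
                 prop_female_young = prop_female_young,
                 prop_female_midlife = prop_female_midlife,
                 young_profile = young_profile,
                 midlife_profile = midlife_profile,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# per-maze lookup tables used by the walker
build_sim_tables <- function(maze) {
  ids <- maze$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  e <- maze$edges
  fr <- c(idx[e$from], idx[e$to])
  to <- c(idx[e$to], idx[e$from])
  len <- c(e$length, e$length)
  adj <- vector("list", n); lens <- vector("list", n); heads <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- fr == i
    adj[[i]] <- to[sel]
    lens[[i]] <- len[sel]
    heads[[i]] <- vapply(to[sel], function(j)
      heading_between(maze$nodes$x[i], maze$nodes$y[i],
                      maze$nodes$x[j], maze$nodes$y[j]), numeric(1))
  }
  D <- igraph::distances(maze$graph, weights = igraph::E(maze$graph)$length)
  D <- D[ids, ids]
  next_hop <- matrix(NA_integer_, n, n)
  for (u in seq_len(n)) for (tg in seq_len(n)) {
    if (u == tg) next
    nb <- adj[[u]]
    next_hop[u, tg] <- nb[which.min(lens[[u]] + D[nb, tg])]
  }
  list(n = n, ids = ids, idx = idx, adj = adj, lens = lens, heads = heads,
       is_target = maze$nodes$kind == "target_object", next_hop = next_hop)
}

# one 8-minute block; RNG state is taken as-is (caller seeds it)
sim_block <- function(tb, dwell_mean, target_bias, revisit_aversion,
                      duration = 480) {
  loc <- sample.int(tb$n, 1)
  heading <- sample(c(0, 90, 180, 270), 1)
  start_loc <- tb$ids[loc]
  start_heading <- heading
  last_seen <- rep(-Inf, tb$n)
  last_seen[loc] <- 0
  step <- 0
  t <- 0
  cap <- 1024
  ev_t <- numeric(cap); ev_key <- character(cap)
  ev_loc <- character(cap); ev_h <- numeric(cap)
  ne <- 0
  repeat {
    step <- step + 1
    dwell <- stats::rexp(1) * dwell_mean
    nb <- tb$adj[[loc]]
    rec <- 0.9^(step - last_seen[nb])
    w <- exp(-revisit_aversion * rec)
    pick <- if (length(nb) == 1) 1L else
      sample.int(length(nb), 1, prob = w)
    if (target_bias > 0 && stats::runif(1) < target_bias) {
      known <- which(is.finite(last_seen) & tb$is_target)
      known <- known[known != loc]
      if (length(known) > 0) {
        goal <- known[which.min(last_seen[known])]
        hop <- tb$next_hop[loc, goal]
        pick <- match(hop, nb)
      }
    }
    nxt <- nb[pick]
    hd <- tb$heads[[loc]][pick]
    len <- tb$lens[[loc]][pick]
    k <- n_quarter_turns(heading, hd)
    if (t + dwell + k + len > duration) break
    t <- t + dwell
    if (k > 0) {
      d <- (hd - heading) %% 360
      key <- if (d == 270) "left" else "right"
      dh <- if (d == 270) -90 else 90
      for (j in seq_len(k)) {
        ne <- ne + 1
        heading <- (heading + dh) %% 360
        ev_t[ne] <- t; ev_key[ne] <- key
        ev_loc[ne] <- tb$ids[loc]; ev_h[ne] <- heading
        t <- t + 1
      }
    }
    ne <- ne + 1
    ev_t[ne] <- t; ev_key[ne] <- "forward"
    ev_loc[ne] <- tb$ids[nxt]; ev_h[ne] <- heading
    t <- t + len
    loc <- nxt
    last_seen[loc] <- step
    if (ne > cap - 4) {
      cap <- cap * 2
      length(ev_t) <- cap; length(ev_key) <- cap
      length(ev_loc) <- cap; length(ev_h) <- cap
    }
  }
  list(events = data.frame(t = ev_t[seq_len(ne)], key = ev_key[seq_len(ne)],
                           location_after = ev_loc[seq_len(ne)],
                           heading_after = ev_h[seq_len(ne)]),
       start_location = start_loc, start_heading = start_heading)
}

#' Simulate the two-block exploration phase of one agent
#'
#' @param maze a [maze_graph()] with node coordinates
#' @param profile an [agent_profile()]
#' @param seed integer seed (the pair of blocks is reproducible)
#' @param participant_id identifier attached to the logs
#' @return list of two [event_log()] objects (blocks 1 and 2)
#' @export
simulate_exploration <- function(maze, profile, seed,
                                 participant_id = "sim") {
  tb <- build_sim_tables(maze)
  set.seed(seed)
  lapply(1:2, function(b) {
    bl <- sim_block(tb, profile$dwell_mean_s, profile$target_bias,
                    profile$revisit_aversion, profile$session_s)
    event_log(participant_id, b, bl$events, bl$start_location,
              bl$start_heading, duration_s = profile$session_s)
  })
}

edges_traversed <- function(logs, maze) {
  pairs <- do.call(rbind, lapply(logs, function(l) {
    seqc <- collapse_repeats(c(attr(l, "start_location"),
                               l$location_after))
    if (length(seqc) < 2) return(NULL)
    cbind(seqc[-length(seqc)], seqc[-1])
  }))
  if (is.null(pairs)) return(maze$edges[0, ])
  key <- unique(paste(pmin(pairs[, 1], pairs[, 2]),
                      pmax(pairs[, 1], pairs[, 2])))
  e <- maze$edges
  e[paste(pmin(e$from, e$to), pmax(e$from, e$to)) %in% key, ]
}

#' Simulate the 24-trial timed wayfinding test phase
#'
#' The agent's spatial graph knowledge is the set of hallway edges it
#' traversed during exploration, each independently retained with
#' probability `1 - knowledge_decay`. A trial places the agent at one target
#' object with the task of reaching another within 45 s; it succeeds iff a
#' route inside the known subgraph exists whose travel time (1 unit/s plus
#' 1 s per 90-degree turn) is at most 45 s. The 24 ordered target pairs are
#' sampled uniformly without replacement from all 72.
#'
#' @param maze a [maze_graph()]
#' @param logs the exploration [event_log()] pair of this agent
#' @param profile an [agent_profile()] (uses `knowledge_decay`)
#' @param seed integer seed for forgetting and trial sampling
#' @param time_limit_s per-trial budget (default 45)
#' @return a [wayfinding_success()] result
#' @export
simulate_test_phase <- function(maze, logs, profile, seed,
                                time_limit_s = 45) {
  targets <- target_ids(maze)
  if (length(targets) < 2) stop("test phase needs at least 2 targets")
  set.seed(seed)
  known <- edges_traversed(logs, maze)
  if (nrow(known) > 0 && profile$knowledge_decay > 0)
    known <- known[stats::runif(nrow(known)) >= profile$knowledge_decay, ]
  pairs <- expand.grid(start = targets, goal = targets,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$start != pairs$goal, ]
  n_trial <- min(24, nrow(pairs))
  trials <- pairs[sample.int(nrow(pairs), n_trial), ]
  ok <- logical(n_trial)
  if (nrow(known) > 0) {
    for (s in unique(trials$start)) {
      d <- state_distances(maze, s, 1, known)
      sel <- trials$start == s
      ok[sel] <- d[trials$goal[sel]] <= time_limit_s
    }
  }
  if (n_trial < 24) ok <- rep(ok, length.out = 24)  # only for toy mazes
  wayfinding_success(ok)
}

draw_individual <- function(profile) {
  shape <- if (profile$dwell_cv > 0) 1 / profile$dwell_cv^2 else Inf
  dwell <- if (is.finite(shape))
    stats::rgamma(1, shape = shape, rate = shape / profile$dwell_mean_s)
  else profile$dwell_mean_s
  bias <- min(1, max(0, stats::rnorm(1, profile$target_bias,
                                     profile$bias_sd)))
  decay <- min(1, max(0, stats::rnorm(1, profile$knowledge_decay,
                                      profile$decay_sd)))
  list(dwell = max(dwell, 1e-3), bias = bias, decay = decay)
}

#' Generate a synthetic cohort on a maze
#'
#' Simulates every participant's two exploration blocks and (optionally)
#' test phase, computes the ten exploration measures pooled across blocks,
#' and assembles the cohort table consumed by the statistical pipeline.
#' All randomness flows from `spec$seed` through per-participant
#' substreams, so any participant can be regenerated in isolation.
#'
#' @param spec a [cohort_spec()]
#' @param maze a [maze_graph()] (default [default_maze()])
#' @param test_phase simulate the wayfinding test phase (default TRUE)
#' @param per_block also compute per-block metrics (long format, attribute
#'   `"per_block"` of the result; needed for block-effect mixed models)
#' @return data.frame with columns `participant_id`, `group`, `sex`, `age`,
#'   the ten metrics, and `wayfinding_success` (NA if `test_phase = FALSE`)
#' @export
generate_cohort <- function(spec, maze = default_maze(), test_phase = TRUE,
                            per_block = FALSE) {
  tb <- build_sim_tables(maze)
  groups <- c(rep("young", spec$n_young), rep("midlife", spec$n_midlife))
  n <- length(groups)
  nf_y <- round(spec$n_young * spec$prop_female_young)
  nf_m <- round(spec$n_midlife * spec$prop_female_midlife)
  sex <- c(rep(c("F", "M"), c(nf_y, spec$n_young - nf_y)),
           rep(c("F", "M"), c(nf_m, spec$n_midlife - nf_m)))
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, n)
  ages <- ifelse(groups == "young", stats::runif(n, 18, 28),
                 stats::runif(n, 43, 61))
  rows <- vector("list", n)
  blocks_long <- if (per_block) vector("list", n) else NULL
  for (i in seq_len(n)) {
    prof <- if (groups[i] == "young") spec$young_profile else
      spec$midlife_profile
    set.seed(sub_seeds[i])
    ind <- draw_individual(prof)
    logs <- lapply(1:2, function(b) {
      bl <- sim_block(tb, ind$dwell, ind$bias, prof$revisit_aversion,
                      prof$session_s)
      event_log(sprintf("P%03d", i), b, bl$events, bl$start_location,
                bl$start_heading, duration_s = prof$session_s)
    })
    seqs <- lapply(logs, sequence_from_events)
    pooled <- concat_blocks(seqs, logs)
    met <- participant_metrics(pooled, maze)
    succ <- NA_real_
    if (test_phase) {
      prof_i <- prof
      prof_i$knowledge_decay <- ind$decay
      tp <- simulate_test_phase(maze, logs, prof_i, seed = sub_seeds[i])
      succ <- tp$wayfinding_success
    }
    rows[[i]] <- data.frame(participant_id = sprintf("P%03d", i),
                            group = groups[i], sex = sex[i], age = ages[i],
                            t(met), wayfinding_success = succ)
    if (per_block) {
      blocks_long[[i]] <- do.call(rbind, lapply(1:2, function(b) {
        mb <- participant_metrics(concat_blocks(seqs[b], logs[b]), maze)
        data.frame(participant_id = sprintf("P%03d", i),
                   group = groups[i], sex = sex[i], block = b, t(mb))
      }))
    }
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = c("young", "midlife"))
  out$sex <- factor(out$sex, levels = c("F", "M"))
  if (per_block) {
    pb <- do.call(rbind, blocks_long)
    pb$group <- factor(pb$group, levels = c("young", "midlife"))
    pb$sex <- factor(pb$sex, levels = c("F", "M"))
    attr(out, "per_block") <- pb
  }
  out
}
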