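test_that("roaming entropy hits its degenerate and uniform extremes", {
  m <- default_maze()
  expect_equal(path_roaming_entropy(visit_sequence("A"), m), 0)
  one_each <- visit_sequence(m$nodes$id)
  expect_equal(path_roaming_entropy(one_each, m), log(26), tolerance = 1e-12)
})

test_that("roaming entropy equals direct formula summation", {
  m <- default_maze()
  set.seed(21)
  for (i in 1:60) {
    raw <- sample(m$nodes$id, sample(5:200, 1), replace = TRUE)
    s <- visit_sequence(raw)
    p <- table(s$collapsed) / length(s$collapsed)
    expect_equal(path_roaming_entropy(s, m), -sum(p * log(p)),
                 tolerance = 1e-12)
  }
})

test_that("entropy depends only on counts; clustering scales linearly", {
  m <- default_maze()
  counts <- c(A = 4, G = 3, M = 2, B = 2, K = 1)
  s <- sequence_with_counts(counts)
  set.seed(3)
  s_perm <- sequence_with_counts(counts[sample(names(counts))])
  expect_equal(path_roaming_entropy(s, m), path_roaming_entropy(s_perm, m))
  s2 <- sequence_with_counts(counts * 2)
  expect_equal(path_roaming_entropy(s2, m), path_roaming_entropy(s, m),
               tolerance = 1e-12)
  expect_equal(clustering_sd(s2, m, "hallway"),
               2 * clustering_sd(s, m, "hallway"), tolerance = 1e-12)
})

test_that("moving a visit from the fullest bin to an empty one raises H", {
  m <- default_maze()
  before <- sequence_with_counts(c(A = 5, G = 3, M = 2))
  after <- sequence_with_counts(c(A = 4, G = 3, M = 2, K = 1))
  expect_gt(path_roaming_entropy(after, m), path_roaming_entropy(before, m))
})

test_that("clustering SD: even coverage gives 0, the worked case gives 3", {
  m <- default_maze()
  tg <- target_ids(m)
  even <- sequence_with_counts(stats::setNames(rep(2, 9), tg))
  expect_equal(clustering_sd(even, m, "target_object"), 0)
  # all 9 visits on one object: mean 1, sum((x-1)^2) = 72, sd = sqrt(72/8)
  skewed <- sequence_with_counts(stats::setNames(c(9, rep(3, 3)),
                                                 c(tg[1], hallway_ids(m)[1:3])))
  expect_equal(clustering_sd(skewed, m, "target_object"), 3)
  set.seed(9)
  raw <- sample(m$nodes$id, 150, replace = TRUE)
  s <- visit_sequence(raw)
  counts <- table(factor(s$collapsed, levels = m$nodes$id))
  expect_equal(clustering_sd(s, m, "hallway"),
               stats::sd(counts[hallway_ids(m)]))
  expect_equal(clustering_sd(s, m, "target_object"),
               stats::sd(counts[target_ids(m)]))
})

test_that("longest hallway sequence scans runs and respects block breaks", {
  m <- default_maze()
  tg <- target_ids(m)[1:3]
  hw <- hallway_ids(m)
  expect_equal(longest_hallway_sequence(sequence_with_counts(
    stats::setNames(c(1, 1, 1), tg)), m), 0)
  s <- visit_sequence(c(tg[1], hw[1], hw[2], hw[3], tg[2], hw[4]))
  expect_equal(longest_hallway_sequence(s, m), 3)
  # runs do not bridge the block boundary
  b1 <- visit_sequence(c(tg[1], hw[1], hw[2]))
  b2 <- visit_sequence(c(hw[3], hw[4], tg[1]))
  expect_equal(longest_hallway_sequence(concat_blocks(list(b1, b2)), m), 2)
})

test_that("longest hallway sequence equals a brute-force scan", {
  m <- default_maze()
  kind <- node_kind(m)
  set.seed(31)
  for (i in 1:40) {
    s <- visit_sequence(sample(m$nodes$id, 200, replace = TRUE))
    col <- s$collapsed
    hall <- kind[col] == "hallway"
    n <- length(col)
    best <- 0  # O(n^2): scan forward from every start position
    for (a in seq_len(n)) {
      stopper <- which(!hall[a:n])
      best <- max(best, if (length(stopper) == 0) n - a + 1 else
        stopper[1] - 1)
    }
    expect_equal(longest_hallway_sequence(s, m), best)
  }
})

test_that("count metrics: distance additivity and the degenerate case", {
  tm <- toy_maze()
  s <- visit_sequence(c("A", "B", "C"))
  cm <- count_metrics(s, tm, require_time = FALSE)
  expect_equal(unname(cm["distance_traveled"]), 6)
  expect_equal(unname(cm["target_object_visits"]), 2)  # A and C
  expect_equal(unname(cm["hallway_visits"]), 1)        # B
  cm0 <- count_metrics(visit_sequence("A"), tm, require_time = FALSE)
  expect_equal(unname(cm0["distance_traveled"]), 0)
  expect_equal(unname(cm0["button_presses"]), 0)
  expect_equal(unname(cm0["target_object_visits"]), 1)
  expect_error(count_metrics(s, tm), "pause_duration unavailable")
  expect_error(count_metrics(visit_sequence(c("A", "E")), tm,
                             require_time = FALSE), "non-edges")
})

test_that("replay accounting: dwell + travel + rotation partitions time", {
  tm <- toy_maze()
  # A(facing east) forward@4 -> B, right@10 (south), forward@12 illegal ->
  # use: left@10 back to east? keep: turn then forward B->C
  ev <- data.frame(t = c(4, 10, 12),
                   key = c("forward", "left", "forward"),
                   location_after = c("B", "B", "C"),
                   heading_after = c(90, 0, 0))
  log <- toy_log(ev, start = "A", heading = 90, duration = 20)
  s <- sequence_from_events(log, tm)
  cm <- count_metrics(s, tm, logs = log)
  # dwell: 4 (at A) + (10 - 7) at B + (12 - 11) + terminal (20 - 15)
  expect_equal(unname(cm["pause_duration"]), 4 + 3 + 1 + 5)
  expect_equal(unname(cm["pause_duration"]) +
                 unname(cm["distance_traveled"]) +
                 unname(cm["turns_made"]), 20)
  expect_equal(unname(cm["turns_made"]), 1)
  expect_equal(unname(cm["button_presses"]), 3)
})

test_that("string fallback matches the event log on simulated data", {
  m <- default_maze()
  logs <- simulate_exploration(m, young_profile(), seed = 12)
  seqs <- lapply(logs, sequence_from_events)
  pooled <- concat_blocks(seqs, logs)
  with_log <- count_metrics(pooled, m)
  bare <- count_metrics(concat_blocks(seqs), m, require_time = FALSE)
  # turn-in-place repeats are exactly the left/right presses here
  expect_equal(bare["turns_made"], with_log["turns_made"])
  expect_equal(bare["button_presses"], with_log["button_presses"])
  expect_equal(bare["distance_traveled"], with_log["distance_traveled"])
  expect_true(is.na(bare["pause_duration"]))
})

test_that("the ten pooled measures respect their joint invariants", {
  m <- default_maze()
  logs <- simulate_exploration(m, midlife_profile(), seed = 4)
  seqs <- lapply(logs, sequence_from_events)
  pm <- participant_metrics(concat_blocks(seqs, logs), m)
  expect_named(pm, metric_names())
  expect_true(all(pm >= 0))
  expect_lte(pm["path_roaming_entropy"], log(26))
  expect_lte(pm["longest_hallway_sequence"], pm["hallway_visits"])
  expect_equal(unname(pm["target_object_visits"] + pm["hallway_visits"]),
               sum(vapply(seqs, function(s) length(s$collapsed),
                          numeric(1))))
  # dwell + rotation + travel exhausts the two 480 s blocks
  expect_equal(unname(pm["pause_duration"] + pm["turns_made"] +
                        pm["distance_traveled"]), 960)
})

test_that("wayfinding success is a proportion of exactly 24 trials", {
  expect_equal(wayfinding_success(rep(FALSE, 24))$wayfinding_success, 0)
  expect_equal(wayfinding_success(rep(c(TRUE, FALSE), 12))$wayfinding_success,
               0.5)
  expect_error(wayfinding_success(rep(TRUE, 23)), "24")
  expect_equal(chance_level(), 0.11)
})
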