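test_that("merge rule is boundary-inclusive at the configured gap", {
  log <- as_event_log(data.frame(actor_i = "a", actor_j = "b",
                                 start_s = c(0, 105), end_s = c(30, 120)))
  merged <- merge_events(log, 75)  # gap of exactly 75 merges
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start_s, merged$end_s), c(0, 120))
  log76 <- as_event_log(data.frame(actor_i = "a", actor_j = "b",
                                   start_s = c(0, 106), end_s = c(30, 120)))
  expect_equal(nrow(merge_events(log76, 75)), 2L)
  expect_error(merge_events(log, -1), "nonnegative")
})

test_that("merging matches the interval-closure oracle on random logs", {
  set.seed(101)
  for (rep in 1:5) {
    log <- random_event_log(200, paste0("a", 1:8))
    merged <- merge_events(log, 75)
    got <- proxqap:::dyad_duration_totals(merged)
    want <- oracle_merge_totals(log, 75)
    key <- sub("\\|", "\r", names(want))
    expect_equal(as.numeric(got[key]), as.numeric(want))
    # idempotent, and never decreases total per-dyad duration
    expect_equal(as.data.frame(merge_events(merged, 75)),
                 as.data.frame(merged))
    # gap-tolerant merging can only add time relative to the plain union
    union_tot <- proxqap:::dyad_duration_totals(merge_events(log, 0))
    expect_true(all(as.numeric(got[key]) >=
                      as.numeric(union_tot[key]) - 1e-9))
  }
})

test_that("duration aggregation builds the symmetric matrix it claims", {
  log <- as_event_log(data.frame(actor_i = "a", actor_j = "b",
                                 start_s = 0, end_s = 90))
  m <- aggregate_durations(log, c("a", "b", "c"))
  expect_equal(m["a", "b"], 90)
  expect_equal(m["b", "a"], 90)
  expect_equal(sum(m), 180)
  expect_equal(attr(m, "units"), "seconds")
  empty <- as_event_log(data.frame(actor_i = character(),
                                   actor_j = character(),
                                   start_s = numeric(), end_s = numeric()))
  expect_equal(sum(aggregate_durations(empty, c("a", "b"))), 0)
  expect_error(aggregate_durations(log, c("a", "x")), "absent")
  # row sums are equivariant under actor relabeling
  set.seed(7)
  rl <- random_event_log(60, paste0("a", 1:6))
  m1 <- aggregate_durations(rl, paste0("a", 1:6))
  perm <- sample(paste0("a", 1:6))
  m2 <- aggregate_durations(rl, perm)
  expect_equal(rowSums(m2)[paste0("a", 1:6)], rowSums(m1)[paste0("a", 1:6)])
})

test_that("per-hour normalization rescales once and only once", {
  ids <- c("a", "b")
  m <- matrix(c(0, 3600, 3600, 0), 2, 2, dimnames = list(ids, ids))
  attr(m, "units") <- "seconds"
  nm <- normalize_per_hour(m, 36)
  expect_equal(nm["a", "b"], 100)
  expect_equal(attr(nm, "units"), "seconds_per_hour")
  expect_error(normalize_per_hour(nm, 36), "normalized")
  # windows scaled by a common factor leave normalized entries invariant
  m2 <- m * 3
  attr(m2, "units") <- "seconds"
  expect_equal(normalize_per_hour(m2, 36 * 3), nm)
})

test_that("dyadic/group decomposition handles the canonical cases", {
  lone <- as_event_log(data.frame(actor_i = "a", actor_j = "b",
                                  start_s = 0, end_s = 60))
  b <- decompose_dyadic_group_time(lone)
  expect_equal(b$dyadic_s, c(60, 60))
  expect_equal(b$group_s, c(0, 0))
  triad <- as_event_log(data.frame(actor_i = c("a", "b", "a"),
                                   actor_j = c("b", "c", "c"),
                                   start_s = 0, end_s = 60))
  b <- decompose_dyadic_group_time(triad)
  expect_equal(b$group_s, c(60, 60, 60))
  # chain a-b, b-c without a-c: components make the overlap group time
  chain <- as_event_log(data.frame(actor_i = c("a", "b"),
                                   actor_j = c("b", "c"),
                                   start_s = c(0, 30), end_s = c(60, 90)))
  b <- decompose_dyadic_group_time(chain)
  expect_equal(b[b$actor_id == "a", c("dyadic_s", "group_s")],
               data.frame(dyadic_s = 30, group_s = 30), ignore_attr = TRUE)
  # under the clique reading the same chain stays dyadic throughout
  bc <- decompose_dyadic_group_time(chain, mode = "clique")
  expect_equal(bc$group_s, c(0, 0, 0))
})

test_that("decomposition agrees with the per-second classifier", {
  set.seed(202)
  for (rep in 1:4) {
    log <- merge_events(random_event_log(50, paste0("a", 1:7),
                                         t_max = 400, d_max = 60), 0)
    got <- decompose_dyadic_group_time(log)
    want <- oracle_decompose(log)
    expect_equal(got$dyadic_s, want$dyadic_s)
    expect_equal(got$group_s, want$group_s)
    # each actor-second classified exactly once
    expect_equal(got$total_s, got$dyadic_s + got$group_s)
  }
})

test_that("actor summaries match direct recomputation from the matrices", {
  set.seed(11)
  actors <- fixture_actors()
  sub <- actors[actors$sample_id == "1", ]
  noms <- as_nominations(data.frame(from_id = c("a1", "a2", "a3"),
                                    to_id = c("a2", "a1", "a1")), actors)
  fr <- friendship_matrices(noms, sub$actor_id)
  ids <- sub$actor_id
  m <- matrix(0, 3, 3, dimnames = list(ids, ids))
  m[upper.tri(m)] <- c(120, 30, 10)
  m <- m + t(m)
  out <- actor_summaries(m, friendship = fr)
  expect_equal(out$t_total, rowSums(m), ignore_attr = TRUE)
  # a1: friends a2 (mutual) and a3 (asymmetric)
  expect_equal(out$t_per_friend[1], (120 + 30) / 2)
  expect_equal(out$t_per_mutual_friend[1], 120)
  expect_equal(out$t_per_asym_friend[1], 30)
  # a2 has no asymmetric friends: field missing
  expect_true(is.na(out$t_per_asym_friend[2]))
})
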