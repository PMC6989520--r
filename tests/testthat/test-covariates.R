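test_that("mean and similarity matrices match their formulas", {
  v <- c(a = 5, b = 5, c = 20, d = NA)
  m <- mean_matrix(v)
  expect_equal(m["a", "b"], 5)
  expect_equal(m["a", "c"], 12.5)
  expect_true(is.na(m["a", "d"]))
  cm <- mean_matrix(c(a = 20, b = 24, c = 22), centered = TRUE)
  expect_equal(cm["a", "b"], 0)  # symmetric about the mean
  s <- similarity_matrix(v)
  expect_equal(s["a", "b"], 0)
  expect_equal(s["a", "c"], -15)
  expect_error(mean_matrix(c(a = NA_real_, b = NA_real_)), "missing")
  # brute-force pairwise recomputation on a random vector
  set.seed(5)
  r <- setNames(rnorm(8), paste0("x", 1:8))
  mm <- mean_matrix(r, centered = TRUE)
  ss <- similarity_matrix(r)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(mm[i, j],
                 unname(((r[i] - mean(r)) + (r[j] - mean(r))) / 2))
    expect_equal(ss[i, j], unname(-abs(r[i] - r[j])))
  }
})

test_that("category dummies realize all four truth tables", {
  g <- c(a = "female", b = "male", c = "female", d = NA)
  expect_equal(category_dummy_matrix(g, "female", "at_least_one")["a", "b"], 1)
  expect_equal(category_dummy_matrix(g, "female", "both")["a", "b"], 0)
  expect_equal(category_dummy_matrix(g, "female", "both")["a", "c"], 1)
  expect_equal(category_dummy_matrix(g, "female", "exactly_one")["a", "c"], 0)
  expect_equal(category_dummy_matrix(g, "female", "same")["a", "c"], 1)
  expect_true(is.na(category_dummy_matrix(g, "female", "both")["a", "d"]))
  # brute-force truth tables on random assignments
  set.seed(9)
  vals <- setNames(sample(c("m", "f"), 10, replace = TRUE), paste0("v", 1:10))
  for (mode in c("at_least_one", "both", "exactly_one", "same")) {
    m <- category_dummy_matrix(vals, "f", mode)
    for (i in 1:9) for (j in (i + 1):10) {
      a <- vals[i] == "f"; b <- vals[j] == "f"
      want <- switch(mode, at_least_one = a | b, both = a & b,
                     exactly_one = xor(a, b), same = a == b)
      expect_equal(m[i, j], as.numeric(want))
    }
  }
})

test_that("friendship matrices split ties into mutual and asymmetric", {
  actors <- fixture_actors()
  noms <- as_nominations(data.frame(from_id = c("a1", "a2", "a3"),
                                    to_id = c("a2", "a1", "a1")), actors)
  fr <- friendship_matrices(noms, paste0("a", 1:3))
  expect_equal(fr$any["a1", "a2"], 1)
  expect_equal(fr$mutual["a1", "a2"], 1)
  expect_equal(fr$asymmetric["a1", "a2"], 0)
  expect_equal(fr$mutual["a1", "a3"], 0)
  expect_equal(fr$asymmetric["a1", "a3"], 1)
})

test_that("a 48-nomination fixture reproduces both tie-count conventions", {
  # 10 mutual dyads (20 nominations) + 28 singleton nominations = 48 edges
  ids <- sprintf("p%02d", 1:73)
  from <- c(ids[seq(1, 19, 2)], ids[seq(2, 20, 2)], ids[21:48])
  to <- c(ids[seq(2, 20, 2)], ids[seq(1, 19, 2)], ids[22:49])
  noms <- data.frame(from_id = from, to_id = to, stringsAsFactors = FALSE)
  actors <- data.frame(actor_id = ids, stringsAsFactors = FALSE)
  fr <- friendship_matrices(noms, ids)
  cnt <- attr(fr, "counts")
  expect_equal(nrow(noms), 48L)
  expect_equal(unname(cnt$dyads["mutual"]), 10)
  expect_equal(unname(cnt$dyads["asymmetric"]), 28)
  expect_equal(unname(cnt$dyads["any"]), 38)
  expect_equal(unname(cnt$nominations["mutual"]), 20)
  expect_equal(unname(cnt$nominations["total"]), 48)
  # brute-force cross-check of the any matrix tie count
  A <- matrix(0, 73, 73, dimnames = list(ids, ids))
  A[cbind(match(from, ids), match(to, ids))] <- 1
  expect_equal(sum((A + t(A)) > 0) / 2, 38)
})

test_that("any = mutual + asymmetric on randomized nomination sets", {
  set.seed(31)
  ids <- paste0("q", 1:20)
  actors <- data.frame(actor_id = ids, stringsAsFactors = FALSE)
  for (rep in 1:5) {
    pairs <- t(combn(ids, 2))
    pick <- runif(nrow(pairs)) < 0.2
    dirflip <- runif(nrow(pairs)) < 0.5
    recip <- runif(nrow(pairs)) < 0.4
    from <- ifelse(dirflip, pairs[, 1], pairs[, 2])[pick]
    to <- ifelse(dirflip, pairs[, 2], pairs[, 1])[pick]
    from2 <- c(from, to[recip[pick]])
    to2 <- c(to, from[recip[pick]])
    fr <- friendship_matrices(
      data.frame(from_id = from2, to_id = to2, stringsAsFactors = FALSE),
      ids)
    expect_equal(fr$any, fr$mutual + fr$asymmetric, ignore_attr = TRUE)
  }
})

test_that("interaction products follow hand arithmetic", {
  dep <- c(a = 5, b = 20, c = 0)
  pm <- product_matrix(mean_matrix(dep), similarity_matrix(dep))
  expect_equal(pm["a", "b"], 12.5 * (-15))
  ones <- mean_matrix(c(a = 1, b = 1, c = 1))
  expect_equal(product_matrix(similarity_matrix(dep), ones),
               similarity_matrix(dep), ignore_attr = TRUE)
  other <- mean_matrix(c(x = 1, y = 2, z = 3))
  expect_error(product_matrix(pm, other), "different actors")
})

test_that("design stacking counts dyads and applies listwise deletion", {
  actors <- fixture_actors()
  mk_y <- function(ids) {
    m <- matrix(10, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 0
    attr(m, "units") <- "seconds_per_hour"
    m
  }
  covs <- function(sub) {
    dep <- setNames(sub$depression_score, sub$actor_id)
    list(dep_mean = mean_matrix(dep), dep_sim = similarity_matrix(dep))
  }
  s1 <- actors[actors$sample_id == "1", ]
  s2 <- actors[actors$sample_id == "2", ]
  d <- build_design(list(`1` = mk_y(s1$actor_id), `2` = mk_y(s2$actor_id)),
                    list(`1` = covs(s1), `2` = covs(s2)))
  expect_equal(d$n_pre, 3 + 3)
  # a5 (sample 2) has a missing item: its 2 dyads are deleted
  expect_equal(d$n_post, 4)
  expect_true("sample_2" %in% d$predictors)
  expect_equal(d$data$y, rep(log(11), 6))
  # un-normalized y is refused
  raw <- mk_y(s1$actor_id)
  attr(raw, "units") <- "seconds"
  expect_error(build_design(list(`1` = raw), list(`1` = covs(s1))),
               "normalized")
  # offset 1 with y = 0 gives an identically zero response
  z <- mk_y(s1$actor_id) * 0
  attr(z, "units") <- "seconds_per_hour"
  dz <- build_design(list(`1` = z), list(`1` = covs(s1)), log_offset = 1)
  expect_equal(dz$data$y, rep(0, 3))
})

test_that("covariate builders are permutation-equivariant", {
  set.seed(41)
  v <- setNames(rnorm(7), paste0("a", 1:7))
  perm <- sample(names(v))
  for (f in list(function(x) mean_matrix(x, centered = TRUE),
                 similarity_matrix)) {
    m <- f(v)
    mp <- f(v[perm])
    expect_equal(mp[names(v), names(v)], m, ignore_attr = TRUE)
  }
})
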