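small_cfg <- function(seed = 42L, ...) {
  simulation_config(n_actors = c(20L, 15L), window_hours = c(8, 6),
                    n_org = c(4L, 3L), seed = seed, ...)
}

test_that("the generator is a deterministic function of its config", {
  a <- simulate_study(small_cfg())
  b <- simulate_study(small_cfg())
  expect_identical(a$actors, b$actors)
  expect_identical(a$friendships, b$friendships)
  expect_identical(lapply(a$events, as.data.frame),
                   lapply(b$events, as.data.frame))
  c2 <- simulate_study(small_cfg(seed = 43L))
  expect_false(identical(as.data.frame(a$events[["1"]]),
                         as.data.frame(c2$events[["1"]])))
})

test_that("generated actors respect counts, ranges and missingness", {
  st <- simulate_study(simulation_config(n_actors = c(73L, 50L),
                                         missing_rate = 0, seed = 5L))
  expect_equal(nrow(st$actors), 123L)
  expect_true(all(st$actors$depression_score >= 0 &
                    st$actors$depression_score <= 60))
  expect_equal(sum(st$actors$sample_id == "1"), 73L)
  expect_equal(sum(st$actors$org_member[st$actors$sample_id == "1"]), 14L)
  # non-response blanks whole survey rows
  st2 <- simulate_study(small_cfg(missing_rate = c(0.5, 0)))
  nonresp <- !st2$actors$responded
  expect_true(any(nonresp))
  expect_true(all(is.na(st2$actors$depression_score[nonresp])))
  expect_true(all(is.na(st2$actors$age[nonresp])))
  expect_false(anyNA(attr(st2$actors, "latent")$depression_score))
})

test_that("CES-D item model hits its configured mean", {
  # Binomial(3, p) items: a target mean of 10 needs p = 10/60
  set.seed(8)
  cfg <- simulation_config(n_actors = c(500L, 2L), n_org = c(0L, 0L),
                           cesd_item_prob = 10 / 60, missing_rate = 0,
                           seed = 8L)
  actors <- generate_actors(cfg)
  sc <- actors$depression_score[actors$sample_id == "1"]
  se <- sd(sc) / sqrt(length(sc))
  expect_lt(abs(mean(sc) - 10), 3 * se)
})

test_that("friendship generation obeys density and reciprocity", {
  cfg0 <- small_cfg(friend_density = 0, missing_rate = 0)
  expect_equal(nrow(simulate_study(cfg0)$friendships), 0L)
  cfg1 <- small_cfg(friend_density = 0.3, reciprocity = 1, missing_rate = 0)
  st <- simulate_study(cfg1)
  fr <- friendship_matrices(st$friendships, st$actors$actor_id)
  expect_equal(sum(fr$asymmetric, na.rm = TRUE), 0)
  expect_gt(sum(fr$mutual, na.rm = TRUE), 0)
  # mutual dyad count is Binomial(ties, reciprocity): check the exact
  # central 95% band at rho = 0.5
  set.seed(9)
  cfg2 <- simulation_config(n_actors = c(73L, 2L), n_org = c(0L, 0L),
                            friend_density = c(0.1, 0), reciprocity = 0.5,
                            missing_rate = 0, seed = 9L)
  st2 <- simulate_study(cfg2)
  fr2 <- friendship_matrices(st2$friendships, st2$actors$actor_id)
  cnt <- attr(fr2, "counts")$dyads
  ties <- cnt["mutual"] + cnt["asymmetric"]
  band <- qbinom(c(0.025, 0.975), ties, 0.5)
  expect_gte(cnt[["mutual"]], band[1])
  expect_lte(cnt[["mutual"]], band[2])
})

test_that("zero coefficients and zero noise give unit per-hour durations", {
  cfg <- small_cfg(gamma = c(intercept = 0), noise_sd = 0, missing_rate = 0)
  st <- simulate_study(cfg)
  latent <- st$actors_latent
  sub <- latent[latent$sample_id == "1", ]
  class(sub) <- class(latent)
  noms <- st$friendships[st$friendships$from_id %in% sub$actor_id, ]
  class(noms) <- class(st$friendships)
  y <- generate_dyadic_durations(sub, noms, cfg, 1L)
  expect_equal(unname(y[upper.tri(y)]), rep(1, sum(upper.tri(y))))
})

test_that("event fragmentation preserves per-dyad totals through merging", {
  cfg <- small_cfg(triad_rate = 0, missing_rate = 0)
  st <- simulate_study(cfg)
  for (s in names(st$events)) {
    log <- st$events[[s]]
    book <- attr(log, "durations_s")
    merged <- merge_events(log, cfg$gap_split_s)
    m <- aggregate_durations(merged, rownames(book))
    expect_equal(m, book, tolerance = 1e-9)
    # fragmentation makes raw totals strictly smaller than merged ones
    raw <- aggregate_durations(log, rownames(book))
    expect_true(all(raw <= m + 1e-9))
    expect_gt(nrow(log), nrow(merged))
  }
})

test_that("a degenerate fragmentation law makes merging the identity", {
  cfg <- small_cfg(frag_prob = 0, mean_blocks = 1, triad_rate = 0,
                   missing_rate = 0)
  st <- simulate_study(cfg)
  log <- st$events[["1"]]
  merged <- merge_events(log, cfg$gap_split_s)
  ord <- order(paste(log$actor_i, log$actor_j), log$start_s)
  expect_equal(as.data.frame(merged), as.data.frame(log)[ord, ],
               ignore_attr = TRUE)
})

test_that("injected triads create group interaction time", {
  cfg <- small_cfg(triad_rate = 5, missing_rate = 0)
  st <- simulate_study(cfg)
  budget <- decompose_dyadic_group_time(
    merge_events(st$events[["1"]], cfg$gap_split_s))
  expect_gt(sum(budget$group_s), 0)
  expect_equal(budget$total_s, budget$dyadic_s + budget$group_s)
})

test_that("depression-mean contrast matches the generating coefficient", {
  # with gamma_mean = -0.059 and everything else 0, dyads at depression
  # mean 20 vs 5 differ by -0.885 in expected log duration
  set.seed(10)
  n <- 2000
  noise <- 0.5
  d5 <- rnorm(n, -0.059 * 5, noise)
  d20 <- rnorm(n, -0.059 * 20, noise)
  diff <- mean(d20) - mean(d5)
  se <- sqrt(var(d5) / n + var(d20) / n)
  expect_lt(abs(diff - (-0.885)), 3 * se)
  # and the generator realizes the same contrast through its event stream
  cfg <- small_cfg(gamma = c(intercept = 2, dep_mean = -0.059),
                   noise_sd = 0, missing_rate = 0, triad_rate = 0)
  st <- simulate_study(cfg)
  d <- pipeline_design(st, log_offset = 0)
  rows <- d$data[d$data$complete, ]
  fit <- lm(y ~ dep_mean, data = rows)
  expect_equal(unname(coef(fit)["dep_mean"]), -0.059, tolerance = 1e-8)
})

test_that("the full pipeline inverts the generator exactly at zero noise", {
  cfg <- small_cfg(noise_sd = 0, triad_rate = 0, missing_rate = 0)
  st <- simulate_study(cfg)
  d <- pipeline_design(st, log_offset = 0)
  fit <- ols_fit(d)
  truth <- reference_coefficients()
  est <- fit$coefficients
  expect_equal(unname(est["(Intercept)"]), truth[["intercept"]],
               tolerance = 1e-8)
  expect_equal(unname(est["sample_2"]), truth[["sample_two"]],
               tolerance = 1e-8)
  for (nm in setdiff(names(truth), c("intercept", "sample_two"))) {
    expect_equal(unname(est[nm]), truth[[nm]], tolerance = 1e-8)
  }
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
})

test_that("infeasible windows are refused", {
  cfg <- small_cfg()
  set.seed(1)
  expect_error(proxqap:::place_dyad_events(380, 400, "a", "b", cfg),
               "window too short")
})
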