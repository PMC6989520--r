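#' Configuration of the synthetic study generator
#'
#' Bundles the generative parameters of a synthetic two-cohort proximity
#' study. The defaults emulate the field conditions the package's analysis
#' targets: two samples of 73 and 50 actors observed for 37 and 32 hours,
#' survey response rates of roughly 73\% and 96\% (whole-survey
#' non-response), CES-D item distributions matching cohort means of about
#' 10.3 and 12.0 scale points, sparse directed friendship nominations with a
#' reciprocity tendency, dyadic interaction durations drawn from the
#' log-linear duration model with the \code{\link{reference_coefficients}}
#' as generative truth, sensor-style fragmentation of each contact into
#' several signals, and occasional synchronous triadic contacts so group
#' interaction time is nonzero.
#'
#' @param n_actors Integer vector, actors per sample.
#' @param window_hours Observation window per sample, hours.
#' @param gamma Named generative coefficient vector on the log scale (names
#'   as in \code{\link{reference_coefficients}}; missing names mean 0).
#' @param cesd_item_prob Per-sample success probability of the
#'   Binomial(3, p) CES-D item model; the implied mean score is \code{60 p}.
#' @param female_prop,age_mean,age_sd,n_org Per-sample demographics.
#' @param missing_rate Per-sample probability that an actor's whole survey
#'   row (age, gender, CES-D, BFI) is missing.
#' @param friend_density Per-sample probability that an unordered dyad
#'   carries at least one nomination seed.
#' @param reciprocity Per-sample probability that a seeded nomination is
#'   reciprocated (the tie becomes mutual).
#' @param noise_sd SD of the Gaussian noise added to log per-hour durations
#'   (durations are therefore log-normal, a heavy-tailed law).
#' @param mean_blocks Mean number of separate contact episodes (merged
#'   blocks, separated by gaps > \code{gap_split_s}) per interacting dyad.
#' @param events_per_block Mean number of sensor signals per episode;
#'   fragments within an episode are separated by short gaps (at most
#'   \code{gap_split_s} seconds) so the merge rule reassembles the episode
#'   exactly.
#' @param frag_prob Probability that an episode is fragmented at all.
#' @param gap_split_s Boundary between short (mergeable) and long gaps;
#'   should equal the analysis \code{max_gap_s}. Default 75.
#' @param triad_rate Expected synchronous triadic contacts per hour per
#'   sample (three pairwise events with an identical span).
#' @param triad_duration_s Mean duration (seconds, exponential) of a triadic
#'   contact.
#' @param seed Integer RNG seed; the full dataset is a deterministic
#'   function of the configuration.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_actors = c(73L, 50L),
                              window_hours = c(37, 32),
                              gamma = reference_coefficients(),
                              cesd_item_prob = c(10.28, 11.98) / 60,
                              female_prop = c(0.37, 0.60),
                              age_mean = c(20.75, 21.73),
                              age_sd = c(2.09, 3.24),
                              n_org = c(14L, 14L),
                              missing_rate = c(20 / 73, 2 / 50),
                              friend_density = c(38 / 2628, 68 / 1225),
                              reciprocity = c(10 / 38, 39 / 68),
                              noise_sd = 1.5,
                              mean_blocks = 2,
                              events_per_block = 2.5,
                              frag_prob = 0.6,
                              gap_split_s = 75,
                              triad_rate = 2,
                              triad_duration_s = 180,
                              seed = 1L) {
  S <- length(n_actors)
  rep_s <- function(x) if (length(x) == 1L) rep(x, S) else x
  cfg <- list(n_actors = as.integer(n_actors),
              window_hours = rep_s(window_hours),
              gamma = gamma,
              cesd_item_prob = rep_s(cesd_item_prob),
              female_prop = rep_s(female_prop),
              age_mean = rep_s(age_mean), age_sd = rep_s(age_sd),
              n_org = as.integer(rep_s(n_org)),
              missing_rate = rep_s(missing_rate),
              friend_density = rep_s(friend_density),
              reciprocity = rep_s(reciprocity),
              noise_sd = noise_sd, mean_blocks = mean_blocks,
              events_per_block = events_per_block, frag_prob = frag_prob,
              gap_split_s = gap_split_s, triad_rate = rep_s(triad_rate),
              triad_duration_s = triad_duration_s,
              seed = as.integer(seed))
  with(cfg, stopifnot(
    all(n_actors >= 2L), all(window_hours > 0),
    all(cesd_item_prob >= 0 & cesd_item_prob <= 1),
    all(female_prop >= 0 & female_prop <= 1),
    all(missing_rate >= 0 & missing_rate <= 1),
    all(friend_density >= 0 & friend_density <= 1),
    all(reciprocity >= 0 & reciprocity <= 1),
    noise_sd >= 0, mean_blocks >= 1, events_per_block >= 1,
    frag_prob >= 0 && frag_prob <= 1, gap_split_s >= 0,
    all(triad_rate >= 0), triad_duration_s > 0,
    all(n_org <= n_actors)))
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic actor attribute table
#'
#' Draws demographics and survey items per sample: ages (rounded normal),
#' genders, organization membership, CES-D items as Binomial(3, p) draws
#' (so every sum score lies in [0, 60]) and BFI items as discretized
#' normals. Whole survey rows are then blanked at the configured
#' non-response rate. The complete (pre-missingness) table is attached as
#' attribute \code{"latent"}; the generator uses it to produce behavior,
#' while the analysis only ever sees the observed table.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return An \code{actor_table} with a \code{responded} column and
#'   attribute \code{latent}.
#' @export
generate_actors <- function(config) {
  rows <- list()
  for (s in seq_along(config$n_actors)) {
    n <- config$n_actors[s]
    ids <- sprintf("s%d_%03d", s, seq_len(n))
    age <- round(stats::rnorm(n, config$age_mean[s], config$age_sd[s]))
    gender <- ifelse(stats::runif(n) < config$female_prop[s],
                     "female", "male")
    org <- rep(FALSE, n)
    if (config$n_org[s] > 0L)
      org[sample.int(n, config$n_org[s])] <- TRUE
    cesd <- matrix(stats::rbinom(n * 20L, 3L, config$cesd_item_prob[s]),
                   nrow = n)
    bfi <- matrix(pmin(5L, pmax(1L, round(stats::rnorm(n * 10L, 3.2, 1)))),
                  nrow = n)
    responded <- stats::runif(n) >= config$missing_rate[s]
    df <- data.frame(actor_id = ids, sample_id = as.character(s),
                     age = age, gender = gender, org_member = org,
                     responded = responded, stringsAsFactors = FALSE)
    colnames(cesd) <- cesd_cols()
    colnames(bfi) <- bfi_cols()
    rows[[s]] <- cbind(df, cesd, bfi)
  }
  full <- do.call(rbind, rows)
  rownames(full) <- NULL
  latent <- as_actor_table(full)
  obs <- full
  blank <- !obs$responded
  obs[blank, c("age", "gender", cesd_cols(), bfi_cols())] <- NA
  observed <- as_actor_table(obs)
  attr(observed, "latent") <- latent
  observed
}

#' Generate directed friendship nominations
#'
#' Each unordered dyad independently carries a nomination seed with the
#' configured per-sample density; the seed's direction is uniform and it is
#' reciprocated with the configured reciprocity probability, producing the
#' mix of mutual and asymmetric ties seen in sparse early-acquaintance
#' networks. Nominations whose sender did not respond to the survey are
#' dropped, since non-respondents cannot nominate.
#'
#' @param actors Actor table from \code{\link{generate_actors}} (needs the
#'   \code{responded} column).
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{nominations} data frame.
#' @export
generate_friendships <- function(actors, config) {
  stopifnot(nrow(actors) > 0L)
  out <- list()
  for (s in seq_along(config$n_actors)) {
    sub <- actors[actors$sample_id == as.character(s), ]
    ids <- sub$actor_id
    n <- length(ids)
    if (n < 2L) next
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    seed_on <- stats::runif(nrow(pairs)) < config$friend_density[s]
    if (!any(seed_on)) next
    pr <- pairs[seed_on, , drop = FALSE]
    flip <- stats::runif(nrow(pr)) < 0.5
    from <- ifelse(flip, ids[pr[, 1L]], ids[pr[, 2L]])
    to <- ifelse(flip, ids[pr[, 2L]], ids[pr[, 1L]])
    recip <- stats::runif(nrow(pr)) < config$reciprocity[s]
    edges <- data.frame(from_id = c(from, to[recip]),
                        to_id = c(to, from[recip]),
                        stringsAsFactors = FALSE)
    keep <- sub$responded[match(edges$from_id, ids)]
    out[[s]] <- edges[keep, , drop = FALSE]
  }
  edges <- if (length(out)) do.call(rbind, out)
  else data.frame(from_id = character(), to_id = character(),
                  stringsAsFactors = FALSE)
  as_nominations(edges, actors)
}

#' Draw model-implied per-hour dyadic durations for one sample
#'
#' The generative core: for every unordered dyad the per-hour interaction
#' duration is \eqn{y_{ij} = \exp(\gamma^\top x_{ij} + \varepsilon)} with
#' \eqn{x_{ij}} built by exactly the same covariate constructors the
#' analysis uses (on the latent, complete attributes) and
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. Durations are capped at 80\% of
#' the hour, since a dyad cannot interact longer than the window and event
#' placement needs slack for inter-episode gaps.
#'
#' @param actors Actor table (latent/complete rows of one sample).
#' @param noms Nominations within that sample.
#' @param config A \code{\link{simulation_config}}.
#' @param sample_index Which sample (1-based); applies the sample dummy
#'   coefficient for indices > 1.
#' @return Symmetric matrix of per-hour durations (seconds/hour) with
#'   \code{units = "seconds_per_hour"}.
#' @export
generate_dyadic_durations <- function(actors, noms, config, sample_index) {
  covs <- default_covariates(actors, noms)
  g <- config$gamma
  gam <- function(nm) if (nm %in% names(g)) g[[nm]] else 0
  n <- nrow(actors)
  eta <- matrix(gam("intercept"), n, n)
  for (nm in names(covs)) eta <- eta + gam(nm) * covs[[nm]]
  if (sample_index > 1L) eta <- eta + gam("sample_two")
  if (config$noise_sd > 0) {
    eps <- matrix(0, n, n)
    ut <- upper.tri(eps)
    eps[ut] <- stats::rnorm(sum(ut), 0, config$noise_sd)
    eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
    eta <- eta + eps
  }
  y <- pmin(exp(eta), 0.8 * 3600)
  diag(y) <- 0
  dimnames(y) <- list(actors$actor_id, actors$actor_id)
  attr(y, "units") <- "seconds_per_hour"
  y
}

# place one dyad's total seconds into the window as merged-block episodes,
# optionally fragmenting each episode into signals with short internal gaps
place_dyad_events <- function(total_s, window_s, a, b, config) {
  gap_big <- config$gap_split_s + 1
  if (total_s >= 0.9 * window_s)
    stop("window too short to place a requested total duration (",
         round(total_s), " s in ", window_s, " s)")
  n_blocks <- 1L + stats::rpois(1L, max(0, config$mean_blocks - 1))
  # shrink block count until blocks plus minimal separating gaps fit
  while (n_blocks > 1L &&
         total_s + gap_big * (n_blocks - 1L) > 0.95 * window_s)
    n_blocks <- n_blocks - 1L
  w <- stats::rgamma(n_blocks, 1)
  block_len <- total_s * w / sum(w)
  gaps <- if (n_blocks > 1L)
    gap_big + stats::rexp(n_blocks - 1L, 1 / 300) else numeric(0)
  while (sum(block_len) + sum(gaps) > 0.95 * window_s)
    gaps <- pmax(gap_big, gaps / 2)
  span <- sum(block_len) + sum(gaps)
  t0 <- stats::runif(1L, 0, window_s - span)
  starts <- t0 + cumsum(c(0, block_len[-n_blocks] + gaps))
  ev <- list()
  for (k in seq_len(n_blocks)) {
    s0 <- starts[k]; L <- block_len[k]
    nf <- if (stats::runif(1L) < config$frag_prob)
      1L + stats::rpois(1L, max(0, config$events_per_block - 1)) else 1L
    if (nf > 1L) {
      g <- stats::runif(nf - 1L, 0, config$gap_split_s)
      if (sum(g) >= 0.5 * L) g <- g * (0.5 * L / sum(g)) * 0.99
      wf <- stats::rgamma(nf, 1)
      frag <- (L - sum(g)) * wf / sum(wf)
      st <- s0 + cumsum(c(0, frag[-nf] + g))
      ev[[k]] <- data.frame(actor_i = a, actor_j = b,
                            start_s = st, end_s = st + frag,
                            stringsAsFactors = FALSE)
    } else {
      ev[[k]] <- data.frame(actor_i = a, actor_j = b,
                            start_s = s0, end_s = s0 + L,
                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, ev)
}

#' Generate a timestamped interaction event log for one sample
#'
#' Converts model-implied per-hour dyadic durations into a sensor-style
#' event stream: each dyad's total seconds are split into contact episodes
#' separated by gaps longer than the merge threshold, episodes are
#' fragmented into signals with short internal gaps (so the 75-second merge
#' rule is exercised and, applied with the matching threshold, recovers the
#' episode totals exactly), and synchronous triadic contacts are injected at
#' the configured rate so group interaction time is nonzero.
#'
#' The exact per-dyad totals implied by the drawn durations (including the
#' injected triads) are attached as attribute \code{"durations_s"} for
#' bookkeeping.
#'
#' @param actors Latent/complete actor rows of one sample.
#' @param noms Nominations within that sample.
#' @param config A \code{\link{simulation_config}}.
#' @param sample_index Which sample (1-based).
#' @return An \code{event_log} with \code{window_hours} set.
#' @export
generate_interaction_events <- function(actors, noms, config, sample_index) {
  y <- generate_dyadic_durations(actors, noms, config, sample_index)
  wh <- config$window_hours[sample_index]
  window_s <- wh * 3600
  ids <- rownames(y)
  total <- y * wh  # seconds over the window
  ut <- which(upper.tri(total), arr.ind = TRUE)
  ev <- vector("list", nrow(ut))
  for (r in seq_len(nrow(ut))) {
    tt <- total[ut[r, 1L], ut[r, 2L]]
    if (tt <= 0) next
    ev[[r]] <- place_dyad_events(tt, window_s,
                                 ids[ut[r, 1L]], ids[ut[r, 2L]], config)
  }
  ev <- ev[!vapply(ev, is.null, TRUE)]
  n_triads <- stats::rpois(1L, config$triad_rate[sample_index] * wh)
  if (n_triads > 0L && length(ids) >= 3L) {
    tri <- vector("list", n_triads)
    for (k in seq_len(n_triads)) {
      trio <- sample(ids, 3L)
      L <- min(stats::rexp(1L, 1 / config$triad_duration_s), window_s / 4)
      t0 <- stats::runif(1L, 0, window_s - L)
      tri[[k]] <- data.frame(
        actor_i = trio[c(1L, 1L, 2L)], actor_j = trio[c(2L, 3L, 3L)],
        start_s = t0, end_s = t0 + L, stringsAsFactors = FALSE)
    }
    ev <- c(ev, tri)
  }
  df <- if (length(ev)) do.call(rbind, ev)
  else data.frame(actor_i = character(), actor_j = character(),
                  start_s = numeric(), end_s = numeric(),
                  stringsAsFactors = FALSE)
  log <- as_event_log(df, window_hours = wh)
  book <- aggregate_durations(merge_events(log, config$gap_split_s), ids)
  attr(log, "durations_s") <- book
  log
}

#' Generate a complete synthetic proximity study
#'
#' Runs the full generator under one seed: actors (with survey
#' non-response), friendship nominations, and one event log per sample, all
#' deterministic functions of the configuration. The generative coefficient
#' vector is returned alongside the data so parameter-recovery checks can
#' compare against the truth.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List of class \code{synthetic_study}: \code{actors} (observed),
#'   \code{actors_latent}, \code{friendships}, \code{events} (named list per
#'   sample), \code{gamma}, \code{config}.
#' @export
simulate_study <- function(config = simulation_config()) {
  set.seed(config$seed)
  actors <- generate_actors(config)
  latent <- attr(actors, "latent")
  friendships <- generate_friendships(actors, config)
  events <- list()
  for (s in seq_along(config$n_actors)) {
    sub_l <- latent[latent$sample_id == as.character(s), ]
    sub_n <- friendships[friendships$from_id %in% sub_l$actor_id, ]
    class(sub_n) <- class(friendships)
    events[[as.character(s)]] <-
      generate_interaction_events(sub_l, sub_n, config, s)
  }
  structure(list(actors = actors, actors_latent = latent,
                 friendships = friendships, events = events,
                 gamma = config$gamma, config = config),
            class = "synthetic_study")
}

#' Run the preprocessing pipeline and build the regression design
#'
#' Convenience wrapper from raw study inputs to the fitted design: merges
#' each sample's events, aggregates to interaction matrices, normalizes per
#' hour, builds the default covariate set from the observed (survey)
#' attributes, and stacks the samples.
#'
#' @param study A \code{synthetic_study}, or a list with elements
#'   \code{actors}, \code{friendships}, \code{events} in the same shapes.
#' @param log_offset Offset for the log transform (see
#'   \code{\link{build_design}}).
#' @param max_gap_s Merge threshold in seconds.
#' @param split_friendship Use mutual/asymmetric friendship matrices instead
#'   of the symmetrized tie.
#' @return A \code{dyad_design}.
#' @export
pipeline_design <- function(study, log_offset = 1, max_gap_s = 75,
                            split_friendship = FALSE) {
  actors <- study$actors
  samples <- unique(actors$sample_id)
  y <- list()
  covs <- list()
  for (s in samples) {
    sub <- actors[actors$sample_id == s, ]
    class(sub) <- class(actors)
    log <- study$events[[s]]
    merged <- merge_events(log, max_gap_s)
    m <- aggregate_durations(merged, sub$actor_id)
    y[[s]] <- normalize_per_hour(m, window_hours(merged))
    noms <- study$friendships[
      study$friendships$from_id %in% sub$actor_id, , drop = FALSE]
    class(noms) <- class(study$friendships)
    covs[[s]] <- default_covariates(sub, noms,
                                    split_friendship = split_friendship)
  }
  build_design(y, covs, log_offset = log_offset)
}
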