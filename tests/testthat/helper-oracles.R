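# Independent oracles and fixture builders used across the suite.

# Random event log over integer seconds (integer bounds keep the per-second
# brute-force classifier exact).
random_event_log <- function(n_events, actors, t_max = 600, d_max = 90) {
  pairs <- t(replicate(n_events, sort(sample(actors, 2L))))
  start <- sample.int(t_max - 1L, n_events, replace = TRUE)
  dur <- sample.int(d_max, n_events, replace = TRUE)
  as_event_log(data.frame(actor_i = pairs[, 1L], actor_j = pairs[, 2L],
                          start_s = start, end_s = start + dur,
                          stringsAsFactors = FALSE))
}

# Oracle for merge_events: per dyad, merged blocks are the connected
# components of the interval graph linking any two intervals whose gap is
# <= max_gap; each block spans min start to max end.
oracle_merge_totals <- function(log, max_gap) {
  pair <- paste(log$actor_i, log$actor_j, sep = "|")
  out <- c()
  for (p in unique(pair)) {
    iv <- log[pair == p, ]
    k <- nrow(iv)
    linked <- matrix(FALSE, k, k)
    for (a in seq_len(k)) for (b in seq_len(k)) {
      gap <- max(iv$start_s[a], iv$start_s[b]) -
        min(iv$end_s[a], iv$end_s[b])
      linked[a, b] <- gap <= max_gap
    }
    g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
    comp <- igraph::components(g)$membership
    tot <- 0
    for (cc in unique(comp)) {
      sel <- iv[comp == cc, ]
      tot <- tot + (max(sel$end_s) - min(sel$start_s))
    }
    out[p] <- tot
  }
  out
}

# Per-second brute-force dyadic/group classifier (integer-time logs).
# For every second, actors in a connected component of >= 3 co-active
# actors accrue group time, components of exactly 2 accrue dyadic time.
oracle_decompose <- function(log) {
  ids <- sort(unique(c(log$actor_i, log$actor_j)))
  dy <- gr <- setNames(numeric(length(ids)), ids)
  t_lo <- floor(min(log$start_s)); t_hi <- ceiling(max(log$end_s))
  for (t in seq(t_lo, t_hi - 1L)) {
    mid <- t + 0.5
    act <- log[log$start_s <= mid & log$end_s > mid, ]
    if (nrow(act) == 0L) next
    g <- igraph::graph_from_data_frame(act[, c("actor_i", "actor_j")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    for (v in seq_along(comp$membership)) {
      actor <- names(comp$membership)[v]
      if (comp$csize[comp$membership[v]] >= 3L)
        gr[actor] <- gr[actor] + 1
      else dy[actor] <- dy[actor] + 1
    }
  }
  data.frame(actor_id = ids, dyadic_s = unname(dy), group_s = unname(gr),
             stringsAsFactors = FALSE)
}

# All permutations of 1..n as a list, written iteratively (independent of
# the package's recursive enumerator).
oracle_perms <- function(n) {
  out <- list(1L)
  for (m in 2:n) {
    nxt <- list()
    for (p in out) for (pos in seq_len(m)) {
      nxt[[length(nxt) + 1L]] <- append(p, m, after = pos - 1L)
    }
    out <- nxt
  }
  out
}

# Normal-equations least squares, independent of qr-based ols_fit.
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X) %*% (t(X) %*% y))
}

# Mid-rank two-sided permutation p from a null set that includes the
# observed value, written from the definition (same round-off tie tolerance
# as the package so analytically tied statistics agree).
oracle_midrank_p <- function(obs, null, doubled = TRUE) {
  B <- length(null)
  eps <- 1e-8 * max(1, abs(obs))
  n_eq <- sum(abs(null - obs) <= eps)
  r_le <- (sum(null < obs - eps) + (n_eq + 1) / 2) / B
  r_ge <- (sum(null > obs + eps) + (n_eq + 1) / 2) / B
  p <- min(r_le, r_ge)
  if (doubled) min(1, 2 * p) else p
}

# Small random two-sample design built from raw matrices (bypasses the
# simulator) for regression oracle checks.
random_design <- function(n1 = 8, n2 = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- function(n, tag) {
    ids <- paste0(tag, seq_len(n))
    sym <- function(gen) {
      m <- matrix(0, n, n, dimnames = list(ids, ids))
      m[upper.tri(m)] <- gen(sum(upper.tri(m)))
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- NA
      m
    }
    y <- sym(function(k) rexp(k, 1 / 50))
    diag(y) <- 0
    attr(y, "units") <- "seconds_per_hour"
    covs <- list(a = sym(rnorm), b = sym(rnorm),
                 d = sym(function(k) rbinom(k, 1, 0.3)))
    list(y = y, covs = covs)
  }
  s1 <- mk(n1, "a"); s2 <- mk(n2, "b")
  build_design(list(`1` = s1$y, `2` = s2$y),
               list(`1` = s1$covs, `2` = s2$covs), log_offset = 1)
}

# Tiny deterministic actor table fixture (two samples, one actor with a
# missing survey).
fixture_actors <- function() {
  n <- 6L
  cesd <- matrix(1L, n, 20L, dimnames = list(NULL, paste0("cesd_", 1:20)))
  cesd[1L, ] <- 0L
  cesd[2L, ] <- 3L
  cesd[5L, 3L] <- NA
  df <- data.frame(actor_id = paste0("a", 1:n),
                   sample_id = rep(c("1", "2"), each = 3L),
                   age = c(20, 22, 21, 24, NA, 23),
                   gender = c("female", "male", "female", "male", "male",
                              "female"),
                   org_member = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  as_actor_table(cbind(df, cesd))
}
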