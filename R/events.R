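#' Merge fragmented contact events of the same dyad
#'
#' Proximity badges fragment a single continuous interaction into several
#' short signals. Following the validation literature for RFID face-to-face
#' measurement, events of the same dyad whose gap is no longer than
#' \code{max_gap_s} seconds (default 75, boundary inclusive) are coalesced
#' into one event spanning from the first start to the last end; the gap time
#' is thereby included in the merged duration. The operation is idempotent.
#'
#' @param log An \code{event_log}.
#' @param max_gap_s Maximum gap in seconds that is still merged; \code{>= 0}.
#' @return A merged \code{event_log}, sorted by dyad and then start time.
#' @export
merge_events <- function(log, max_gap_s = 75) {
  if (!is.numeric(max_gap_s) || max_gap_s < 0)
    stop("max_gap_s must be a nonnegative number")
  wh <- attr(log, "window_hours")
  if (nrow(log) == 0L) return(log)
  pair <- paste(log$actor_i, log$actor_j, sep = "\r")
  ord <- order(pair, log$start_s, log$end_s)
  df <- as.data.frame(log)[ord, ]
  pair <- pair[ord]
  # running max of end within dyad: a new merged block starts where the gap
  # to everything before it exceeds max_gap_s
  runmax_end <- stats::ave(df$end_s, pair, FUN = cummax)
  n <- nrow(df)
  new_block <- c(TRUE, pair[-1L] != pair[-n] |
                   df$start_s[-1L] - runmax_end[-n] > max_gap_s)
  block <- cumsum(new_block)
  out <- data.frame(
    actor_i = df$actor_i[new_block],
    actor_j = df$actor_j[new_block],
    start_s = as.numeric(tapply(df$start_s, block, min)),
    end_s = as.numeric(tapply(df$end_s, block, max)),
    stringsAsFactors = FALSE)
  as_event_log(out, window_hours = wh)
}

dyad_duration_totals <- function(log) {
  if (nrow(log) == 0L) return(numeric(0))
  pair <- paste(log$actor_i, log$actor_j, sep = "\r")
  tapply(log$end_s - log$start_s, pair, sum)
}

#' Aggregate event durations into a weighted interaction matrix
#'
#' Sums the duration of all (merged) contact events of each unordered dyad
#' into a symmetric, weighted adjacency matrix whose entry \eqn{(i, j)} is
#' the total time actors \eqn{i} and \eqn{j} interacted, in seconds.
#'
#' @param log An \code{event_log}.
#' @param actors Either an \code{actor_table} or a character vector of actor
#'   ids fixing the matrix index. Every event actor must appear in it.
#' @return A symmetric numeric matrix with zero diagonal and attribute
#'   \code{units = "seconds"}.
#' @export
aggregate_durations <- function(log, actors) {
  ids <- if (is.data.frame(actors)) actors$actor_id else as.character(actors)
  unknown <- setdiff(unique(c(log$actor_i, log$actor_j)), ids)
  if (length(unknown))
    stop("event log references actors absent from the actor table: ",
         paste(unknown, collapse = ", "))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(log) > 0L) {
    ia <- match(log$actor_i, ids)
    ja <- match(log$actor_j, ids)
    dur <- log$end_s - log$start_s
    # events are dyad-normalized, so each dyad accumulates on one side only
    for (k in seq_along(dur)) {
      m[ia[k], ja[k]] <- m[ia[k], ja[k]] + dur[k]
    }
    m <- m + t(m)
  }
  attr(m, "units") <- "seconds"
  m
}

#' Normalize an interaction matrix to seconds per hour
#'
#' Divides every entry by the observation window length so that samples
#' observed for different numbers of hours are on a common scale.
#'
#' @param m Interaction matrix with \code{units = "seconds"}.
#' @param observation_hours Positive window length in hours.
#' @return The matrix in \code{units = "seconds_per_hour"}.
#' @export
normalize_per_hour <- function(m, observation_hours) {
  u <- attr(m, "units")
  if (is.null(u) || u != "seconds")
    stop("matrix is not in seconds (already normalized?)")
  stopifnot(is.numeric(observation_hours), observation_hours > 0)
  out <- m / observation_hours
  attr(out, "units") <- "seconds_per_hour"
  out
}

# minimal union-find (no compression; instantaneous graphs are small)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Split each actor's interaction time into dyadic and group components
#'
#' At every instant, the co-active contact events define a graph on the
#' actors. Time an actor spends in a connected component of exactly two
#' actors counts as dyadic; time in a component of three or more actors
#' counts as group interaction ("at least three individuals present").
#' Implemented as a sweep over event start/end boundaries; within each
#' elementary interval the active component structure is constant.
#'
#' Components are the default reading of joint presence; \code{mode =
#' "clique"} instead requires the actor to sit in an active triangle before
#' its time counts as group time.
#'
#' @param log A merged \code{event_log} (see \code{\link{merge_events}}).
#' @param mode \code{"component"} (default) or \code{"clique"}.
#' @return Data frame with columns \code{actor_id}, \code{total_s},
#'   \code{dyadic_s}, \code{group_s}; \code{dyadic_s + group_s = total_s}.
#' @export
decompose_dyadic_group_time <- function(log, mode = c("component", "clique")) {
  mode <- match.arg(mode)
  ids <- sort(unique(c(log$actor_i, log$actor_j)))
  dy <- gr <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(log) > 0L) {
    ia <- match(log$actor_i, ids)
    ja <- match(log$actor_j, ids)
    bounds <- sort(unique(c(log$start_s, log$end_s)))
    # events active in elementary interval [bounds[k], bounds[k+1])
    for (k in seq_len(length(bounds) - 1L)) {
      t0 <- bounds[k]
      dt <- bounds[k + 1L] - t0
      act <- which(log$start_s <= t0 & log$end_s > t0)
      if (!length(act)) next
      ai <- ia[act]; aj <- ja[act]
      nodes <- unique(c(ai, aj))
      if (mode == "component") {
        parent <- seq_along(ids)
        for (e in seq_along(act)) {
          ra <- uf_find(parent, ai[e]); rb <- uf_find(parent, aj[e])
          if (ra != rb) parent[rb] <- ra
        }
        root <- vapply(nodes, function(v) uf_find(parent, v), 0L)
        csize <- table(root)
        grp <- nodes[csize[as.character(root)] >= 3L]
      } else {
        # clique mode: actor is in a group iff it lies on an active triangle
        adj <- matrix(FALSE, length(ids), length(ids))
        adj[cbind(ai, aj)] <- TRUE
        adj[cbind(aj, ai)] <- TRUE
        grp <- nodes[vapply(nodes, function(v) {
          nb <- which(adj[v, ])
          length(nb) >= 2L && any(adj[nb, nb, drop = FALSE])
        }, TRUE)]
      }
      dyad_nodes <- setdiff(nodes, grp)
      gr[grp] <- gr[grp] + dt
      dy[dyad_nodes] <- dy[dyad_nodes] + dt
    }
  }
  data.frame(actor_id = ids, total_s = dy + gr, dyadic_s = unname(dy),
             group_s = unname(gr), stringsAsFactors = FALSE)
}

#' Complete per-actor interaction summaries
#'
#' Builds the individual-level aggregates used in descriptive tables: total
#' interaction time (row sum of the interaction matrix), mean time per
#' friend, per mutual friend and per asymmetric friend (row sum restricted to
#' tied dyads, divided by the number of such ties; missing when the actor has
#' no ties of that kind), dyadic and group seconds, and the dyadic ratio.
#'
#' @param m Interaction matrix (any units; the summaries inherit them).
#' @param budgets Output of \code{\link{decompose_dyadic_group_time}}, or
#'   \code{NULL} to skip the dyadic/group fields.
#' @param friendship List of binary matrices \code{any}, \code{mutual},
#'   \code{asymmetric} as returned by \code{\link{friendship_matrices}}, or
#'   \code{NULL}.
#' @return Data frame with one row per actor.
#' @export
actor_summaries <- function(m, budgets = NULL, friendship = NULL) {
  ids <- rownames(m)
  out <- data.frame(actor_id = ids, t_total = rowSums(m),
                    stringsAsFactors = FALSE)
  per_tie <- function(tie) {
    stopifnot(identical(rownames(tie), ids))
    cnt <- rowSums(tie, na.rm = TRUE)  # diagonal is NA by construction
    ifelse(cnt > 0, rowSums(m * tie, na.rm = TRUE) / cnt, NA_real_)
  }
  if (!is.null(friendship)) {
    out$t_per_friend <- per_tie(friendship$any)
    out$t_per_mutual_friend <- per_tie(friendship$mutual)
    out$t_per_asym_friend <- per_tie(friendship$asymmetric)
  }
  if (!is.null(budgets)) {
    ix <- match(ids, budgets$actor_id)
    out$dyadic_s <- ifelse(is.na(ix), 0, budgets$dyadic_s[ix])
    out$group_s <- ifelse(is.na(ix), 0, budgets$group_s[ix])
    out$ratio_dyadic <- dyadic_ratio(out)
  }
  rownames(out) <- NULL
  out
}
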