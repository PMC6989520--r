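#' Read a pairwise interaction event log
#'
#' Reads a CSV of timestamped pairwise contact events, such as those produced
#' by RFID proximity badges. Each row is one recorded contact between two
#' actors over a half-open interval \code{[start_s, end_s)} in seconds since
#' the start of the observation window.
#'
#' Events are normalized so that \code{actor_i < actor_j} lexicographically;
#' normalization never alters durations and row order is preserved.
#'
#' @param path Path to a CSV file with header columns \code{actor_i},
#'   \code{actor_j}, \code{start_s}, \code{end_s} (or the names given in
#'   \code{col_map}).
#' @param col_map Optional named character vector remapping the expected
#'   column roles to the file's actual column names, e.g.
#'   \code{c(actor_i = "id1", actor_j = "id2")}. Deposited data sets rarely
#'   share one schema, so the mapping is user-supplied rather than hard-coded.
#' @param window_hours Optional length of the observation window in hours,
#'   attached to the returned log. When \code{NULL} it is left unset and
#'   downstream code defaults to the span of the data.
#' @return An \code{event_log}: a data frame with columns \code{actor_i},
#'   \code{actor_j}, \code{start_s}, \code{end_s} and attribute
#'   \code{window_hours}.
#' @export
read_event_log <- function(path, col_map = NULL, window_hours = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  roles <- c(actor_i = "actor_i", actor_j = "actor_j",
             start_s = "start_s", end_s = "end_s")
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), names(roles))
    if (length(bad))
      stop("unknown column roles in col_map: ", paste(bad, collapse = ", "))
    roles[names(col_map)] <- col_map
  }
  miss <- setdiff(unname(roles), names(df))
  if (length(miss))
    stop("event log ", path, " lacks required columns: ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    return(as_event_log(data.frame(actor_i = character(), actor_j = character(),
                                   start_s = numeric(), end_s = numeric(),
                                   stringsAsFactors = FALSE),
                        window_hours = window_hours))
  }
  start_s <- suppressWarnings(as.numeric(df[[roles["start_s"]]]))
  end_s <- suppressWarnings(as.numeric(df[[roles["end_s"]]]))
  bad <- which(is.na(start_s) | is.na(end_s))
  if (length(bad))
    stop("malformed event row at line ", bad[1L] + 1L,
         " of ", path, ": non-numeric start/end")
  out <- data.frame(actor_i = as.character(df[[roles["actor_i"]]]),
                    actor_j = as.character(df[[roles["actor_j"]]]),
                    start_s = start_s, end_s = end_s,
                    stringsAsFactors = FALSE)
  bad <- which(!(out$start_s < out$end_s))
  if (length(bad))
    stop("invalid event at line ", bad[1L] + 1L, " of ", path,
         ": end_s must be greater than start_s")
  as_event_log(out, window_hours = window_hours)
}

#' Construct an event log from a data frame
#'
#' Validates and normalizes a data frame of pairwise contact events: actor
#' pairs are reordered so \code{actor_i < actor_j}; self-contacts and
#' non-positive durations are rejected.
#'
#' @param df Data frame with columns \code{actor_i}, \code{actor_j},
#'   \code{start_s}, \code{end_s}.
#' @param window_hours Optional observation window length in hours.
#' @return An \code{event_log} data frame.
#' @export
as_event_log <- function(df, window_hours = NULL) {
  stopifnot(all(c("actor_i", "actor_j", "start_s", "end_s") %in% names(df)))
  df$actor_i <- as.character(df$actor_i)
  df$actor_j <- as.character(df$actor_j)
  if (any(df$actor_i == df$actor_j))
    stop("self-contact events (actor_i == actor_j) are not allowed")
  if (any(!(df$start_s < df$end_s)))
    stop("all events must satisfy start_s < end_s")
  swap <- df$actor_i > df$actor_j
  if (any(swap)) {
    tmp <- df$actor_i[swap]
    df$actor_i[swap] <- df$actor_j[swap]
    df$actor_j[swap] <- tmp
  }
  df <- df[, c("actor_i", "actor_j", "start_s", "end_s")]
  rownames(df) <- NULL
  if (!is.null(window_hours)) {
    stopifnot(is.numeric(window_hours), window_hours > 0)
    attr(df, "window_hours") <- as.numeric(window_hours)
  }
  class(df) <- c("event_log", "data.frame")
  df
}

#' Observation window of an event log, in hours
#'
#' Returns the window length attached to the log, or, when none was set, the
#' span from the first event start to the last event end. The denominator of
#' per-hour normalization is a study design quantity; recording it explicitly
#' is preferred to relying on the data span.
#'
#' @param log An \code{event_log}.
#' @return Window length in hours.
#' @export
window_hours <- function(log) {
  wh <- attr(log, "window_hours")
  if (!is.null(wh)) return(wh)
  if (nrow(log) == 0L) stop("empty event log with no window_hours attribute")
  (max(log$end_s) - min(log$start_s)) / 3600
}

#' Write an event log to CSV
#' @param log An \code{event_log}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_event_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

cesd_cols <- function() paste0("cesd_", 1:20)
bfi_cols <- function() paste0("bfi_", 1:10)

#' Read an actor attribute table
#'
#' Reads a CSV of per-actor survey attributes: sample membership, age, gender,
#' student-organization membership, the 20 CES-D depression items (each scored
#' 0--3), and the 10 BFI personality items (each scored 1--5). Missing values
#' are empty cells; whole-survey non-response leaves all survey fields blank.
#' The CES-D sum score and the five BFI trait means are derived on read and
#' are missing whenever any contributing item is missing (no imputation).
#'
#' @param path CSV path. Required columns: \code{actor_id}, \code{sample_id},
#'   \code{age}, \code{gender}, \code{org_member}, \code{cesd_1..cesd_20};
#'   optional \code{bfi_1..bfi_10}.
#' @param col_map Optional named character vector remapping role names to the
#'   file's column names.
#' @return An \code{actor_table} data frame with derived columns
#'   \code{depression_score} and the five traits \code{openness},
#'   \code{conscientiousness}, \code{extraversion}, \code{agreeableness},
#'   \code{neuroticism} (when BFI items are present).
#' @export
read_actor_table <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!is.null(col_map)) {
    idx <- match(unname(col_map), names(df))
    if (anyNA(idx))
      stop("col_map names columns absent from ", path)
    names(df)[idx] <- names(col_map)
  }
  as_actor_table(df)
}

#' Validate and derive an actor attribute table
#'
#' @param df Data frame with the columns documented in
#'   \code{\link{read_actor_table}}.
#' @return An \code{actor_table}.
#' @export
as_actor_table <- function(df) {
  need <- c("actor_id", "sample_id", "age", "gender", "org_member")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("actor table lacks columns: ", paste(miss, collapse = ", "))
  df$actor_id <- as.character(df$actor_id)
  if (anyDuplicated(df$actor_id))
    stop("actor_id values must be unique")
  df$sample_id <- as.character(df$sample_id)
  bad_g <- !is.na(df$gender) & !df$gender %in% c("female", "male")
  if (any(bad_g))
    stop("gender must be 'female', 'male' or missing")
  df$org_member <- as.logical(df$org_member)
  has_cesd <- all(cesd_cols() %in% names(df))
  if (has_cesd) {
    items <- as.matrix(df[, cesd_cols()])
    storage.mode(items) <- "numeric"
    vals <- items[!is.na(items)]
    if (any(vals != round(vals) | vals < 0 | vals > 3))
      stop("CES-D items must be integers in [0, 3]")
    df$depression_score <- score_cesd(items)
  }
  has_bfi <- all(bfi_cols() %in% names(df))
  if (has_bfi) {
    bfi <- as.matrix(df[, bfi_cols()])
    storage.mode(bfi) <- "numeric"
    vals <- bfi[!is.na(bfi)]
    if (any(vals != round(vals) | vals < 1 | vals > 5))
      stop("BFI items must be integers in [1, 5]")
    tr <- t(apply(bfi, 1L, bfi_traits))
    df[, colnames(tr)] <- tr
  }
  rownames(df) <- NULL
  class(df) <- c("actor_table", "data.frame")
  df
}

#' Write an actor table to CSV
#' @param actors An \code{actor_table}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_actor_table <- function(actors, path) {
  drop <- intersect(c("depression_score", "openness", "conscientiousness",
                      "extraversion", "agreeableness", "neuroticism"),
                    names(actors))
  out <- as.data.frame(actors)[, setdiff(names(actors), drop)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read directed friendship nominations
#'
#' Reads a CSV edge list of directed friendship nominations
#' (\code{from_id, to_id}). Every endpoint must exist in the supplied actor
#' table; self-nominations and duplicate edges are rejected.
#'
#' @param path CSV path with columns \code{from_id} and \code{to_id}.
#' @param actors The \code{actor_table} whose ids the edges must reference.
#' @return A \code{nominations} data frame with columns \code{from_id},
#'   \code{to_id}.
#' @export
read_nominations <- function(path, actors) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(c("from_id", "to_id"), names(df))
  if (length(miss))
    stop("nomination file lacks columns: ", paste(miss, collapse = ", "))
  as_nominations(df, actors)
}

#' Validate a directed nomination edge list
#' @param df Data frame with columns \code{from_id}, \code{to_id}.
#' @param actors Actor table the endpoints must belong to.
#' @return A \code{nominations} data frame.
#' @export
as_nominations <- function(df, actors) {
  df$from_id <- as.character(df$from_id)
  df$to_id <- as.character(df$to_id)
  if (any(df$from_id == df$to_id))
    stop("self-nominations are not allowed")
  key <- paste(df$from_id, df$to_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate nomination edges")
  unknown <- setdiff(c(df$from_id, df$to_id), actors$actor_id)
  if (length(unknown))
    stop("nominations reference unknown actor ids: ",
         paste(unknown, collapse = ", "))
  df <- df[, c("from_id", "to_id")]
  rownames(df) <- NULL
  class(df) <- c("nominations", "data.frame")
  df
}

#' Write nominations to CSV
#' @param noms A \code{nominations} data frame.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_nominations <- function(noms, path) {
  utils::write.csv(as.data.frame(noms), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a labelled matrix as TSV
#'
#' Matrices (interaction matrices, dyadic covariates, selection grids) are
#' exported as tab-separated tables with actor ids as row and column labels,
#' so they stay human-inspectable and diff-able.
#'
#' @param m A matrix with dimnames.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  out <- m
  storage.mode(out) <- "character"
  out[] <- formatC(m, digits = 17, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a labelled TSV matrix written by \code{write_matrix}
#' @param path Input file path.
#' @param units Optional units flag to attach (\code{"seconds"} or
#'   \code{"seconds_per_hour"}).
#' @return A numeric matrix with dimnames.
#' @export
read_matrix <- function(path, units = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.null(units)) attr(m, "units") <- units
  m
}

#' Run configuration for the analysis pipeline
#'
#' Bundles the tunable processing and inference parameters: the maximum
#' signal gap merged into one contact (seconds), the per-sample observation
#' window (hours), the offset added before log-transforming per-hour
#' durations, the number of permutations, the seed, the p-value convention,
#' and the depression-score range of the selection grid.
#'
#' @param max_gap_s Maximum gap (seconds) between two signals of the same
#'   dyad that is still merged into one interaction. Default 75.
#' @param observation_hours Numeric vector of window lengths per sample, or
#'   \code{NULL} to default to each log's span.
#' @param log_offset Nonnegative constant added to per-hour durations before
#'   the log transform. Default 1.
#' @param n_permutations Number of Y-permutations. Default 5000.
#' @param rng_seed Integer seed or \code{NULL}.
#' @param p_value_convention \code{"two_sided_doubled"} or
#'   \code{"percent_rank"}; see \code{\link{mrqap}}.
#' @param grid_range Integer depression-score range of the selection grid.
#' @return A \code{run_config} list.
#' @export
run_config <- function(max_gap_s = 75, observation_hours = NULL,
                       log_offset = 1, n_permutations = 5000,
                       rng_seed = NULL,
                       p_value_convention = c("two_sided_doubled",
                                              "percent_rank"),
                       grid_range = 0:36) {
  p_value_convention <- match.arg(p_value_convention)
  stopifnot(max_gap_s >= 0, log_offset >= 0, n_permutations >= 1,
            length(grid_range) >= 1)
  if (!is.null(observation_hours)) stopifnot(all(observation_hours > 0))
  structure(list(max_gap_s = max_gap_s,
                 observation_hours = observation_hours,
                 log_offset = log_offset,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = rng_seed,
                 p_value_convention = p_value_convention,
                 grid_range = grid_range),
            class = "run_config")
}

#' Read a plain-text run configuration
#'
#' Parses a \code{key: value} text file into a \code{\link{run_config}}.
#' Vector values are comma-separated. Unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([a-z_]+)\\s*:\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L))
    stop("malformed config line: ", lines[which(lengths(kv) != 3L)[1L]])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  known <- names(formals(run_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",")[[1L]]
    v <- trimws(v)
    if (keys[i] == "p_value_convention") args[[keys[i]]] <- v
    else args[[keys[i]]] <- as.numeric(v)
  }
  do.call(run_config, args)
}
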