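#' Dyadic mean covariate matrix
#'
#' For a numeric actor attribute \eqn{v}, builds the symmetric matrix with
#' entries \eqn{x_{ij} = (v_i + v_j)/2}, or, when \code{centered = TRUE},
#' \eqn{x_{ij} = ((v_i - \bar v) + (v_j - \bar v))/2} with \eqn{\bar v} the
#' mean over actors with non-missing values. An entry is missing when either
#' actor's value is missing.
#'
#' @param values Named numeric vector of attribute values (names = actor
#'   ids), missing allowed.
#' @param centered Subtract the attribute mean before averaging.
#' @return Symmetric matrix with \code{NA} diagonal and attribute
#'   \code{kind}.
#' @export
mean_matrix <- function(values, centered = FALSE) {
  v <- as.numeric(values)
  if (all(is.na(v))) stop("attribute is missing for every actor")
  if (centered) v <- v - mean(v, na.rm = TRUE)
  m <- outer(v, v, function(a, b) (a + b) / 2)
  dimnames(m) <- list(names(values), names(values))
  diag(m) <- NA_real_
  attr(m, "kind") <- if (centered) "centered_mean" else "mean"
  m
}

#' Dyadic similarity covariate matrix
#'
#' Negative absolute difference \eqn{x_{ij} = -|v_i - v_j|}: the entry is 0
#' (maximal similarity, the reference category) when the two actors have
#' identical values and grows more negative with dissimilarity.
#'
#' @inheritParams mean_matrix
#' @return Symmetric nonpositive matrix with attribute
#'   \code{kind = "similarity"}.
#' @export
similarity_matrix <- function(values) {
  v <- as.numeric(values)
  if (all(is.na(v))) stop("attribute is missing for every actor")
  m <- -abs(outer(v, v, "-"))
  dimnames(m) <- list(names(values), names(values))
  diag(m) <- NA_real_
  attr(m, "kind") <- "similarity"
  m
}

#' Dyadic category dummy matrix
#'
#' Builds a binary dyad-level indicator from a categorical actor attribute
#' and a designated level: \code{at_least_one} (either actor has the level),
#' \code{both}, \code{exactly_one}, or \code{same} (both actors on the same
#' side of the level, i.e. both have it or neither does). Missing attribute
#' values propagate.
#'
#' @param values Named vector of a categorical attribute.
#' @param level The level the dyad is tested against.
#' @param mode One of \code{"at_least_one"}, \code{"both"},
#'   \code{"exactly_one"}, \code{"same"}.
#' @return Symmetric 0/1 matrix with attribute \code{kind = "dummy"}.
#' @export
category_dummy_matrix <- function(values, level,
                                  mode = c("at_least_one", "both",
                                           "exactly_one", "same")) {
  mode <- match.arg(mode)
  is_lvl <- as.numeric(values == level)  # NA propagates
  f <- switch(mode,
              at_least_one = function(a, b) pmax(a, b),
              both = function(a, b) pmin(a, b),
              exactly_one = function(a, b) as.numeric(xor(a > 0, b > 0)),
              same = function(a, b) as.numeric(a == b))
  m <- outer(is_lvl, is_lvl, f)
  dimnames(m) <- list(names(values), names(values))
  diag(m) <- NA_real_
  attr(m, "kind") <- "dummy"
  m
}

#' Friendship covariate matrices
#'
#' From directed friendship nominations, builds three symmetric binary
#' matrices: \code{any} (at least one nomination in either direction, the
#' symmetrized friendship matrix), \code{mutual} (both directions present, a
#' strong tie), and \code{asymmetric} (exactly one direction, a weak tie).
#' Elementwise, \code{any = mutual + asymmetric}.
#'
#' Tie counts are attached in both field conventions: per dyad, and per
#' nomination (a mutual dyad contributes two nominations).
#'
#' @param noms A \code{nominations} data frame (see
#'   \code{\link{read_nominations}}).
#' @param actor_ids Character vector fixing the matrix index.
#' @return List with elements \code{any}, \code{mutual}, \code{asymmetric}
#'   and attribute \code{counts}.
#' @export
friendship_matrices <- function(noms, actor_ids) {
  ids <- as.character(actor_ids)
  unknown <- setdiff(unique(c(noms$from_id, noms$to_id)), ids)
  if (length(unknown))
    stop("nominations reference actors outside the index: ",
         paste(unknown, collapse = ", "))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(noms) > 0L)
    A[cbind(match(noms$from_id, ids), match(noms$to_id, ids))] <- 1
  any_m <- pmax(A, t(A))
  mutual <- pmin(A, t(A))
  asym <- any_m - mutual
  diag(any_m) <- diag(mutual) <- diag(asym) <- NA_real_
  attr(any_m, "kind") <- attr(mutual, "kind") <- attr(asym, "kind") <- "dummy"
  ut <- upper.tri(any_m)
  counts <- list(
    dyads = c(any = sum(any_m[ut], na.rm = TRUE),
              mutual = sum(mutual[ut], na.rm = TRUE),
              asymmetric = sum(asym[ut], na.rm = TRUE)),
    nominations = c(total = nrow(noms),
                    mutual = 2 * sum(mutual[ut], na.rm = TRUE),
                    asymmetric = sum(asym[ut], na.rm = TRUE)))
  structure(list(any = any_m, mutual = mutual, asymmetric = asym),
            counts = counts)
}

#' Elementwise product of two dyadic covariates
#'
#' Interaction term between two dyad-level predictors (e.g. depression mean
#' with depression similarity, or depression mean with the friendship tie).
#' Missing entries propagate.
#'
#' @param a,b Dyadic covariate matrices over the same actor index.
#' @return Symmetric matrix with attribute \code{kind = "product"}.
#' @export
product_matrix <- function(a, b) {
  if (!identical(dimnames(a), dimnames(b)))
    stop("covariates are indexed by different actors")
  m <- a * b
  attr(m, "kind") <- "product"
  attr(m, "units") <- NULL
  m
}

#' Stack samples into a dyadic regression design
#'
#' Builds the pooled dyad-level design of the multi-group regression: one row
#' per unordered dyad (\eqn{i < j}) of each sample, response
#' \eqn{\log(y_{ij} + \mathrm{offset})} with \eqn{y_{ij}} the per-hour
#' interaction duration, the supplied dyadic covariates as predictor columns,
#' and a dummy for each sample beyond the first. Dyads with any missing
#' predictor are flagged for listwise deletion; both pre- and post-deletion
#' counts are recorded.
#'
#' @param y Named list of interaction matrices, one per sample, each with
#'   \code{units = "seconds_per_hour"}.
#' @param covariates Named list (same sample names) of named lists of dyadic
#'   covariate matrices; covariate names must agree across samples.
#' @param log_offset Nonnegative constant added before the log transform.
#'   The default 1 second/hour keeps zero dyads finite; 0 is exact when every
#'   dyad has positive duration.
#' @return A \code{dyad_design}: list with \code{data} (row per dyad, with
#'   \code{complete} mask), \code{ylog} (per-sample log-response matrices,
#'   kept for Y-permutation), \code{predictors}, \code{samples},
#'   \code{offset}, \code{n_pre}, \code{n_post}.
#' @export
build_design <- function(y, covariates, log_offset = 1) {
  stopifnot(is.list(y), is.list(covariates), log_offset >= 0)
  samples <- names(y)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("y must be a named list of per-sample matrices")
  if (!identical(sort(samples), sort(names(covariates))))
    stop("y and covariates must cover the same samples")
  prednames <- names(covariates[[1L]])
  rows <- list()
  ylog <- list()
  for (s in samples) {
    m <- y[[s]]
    u <- attr(m, "units")
    if (is.null(u) || u != "seconds_per_hour")
      stop("dependent matrix for sample ", s,
           " is not per-hour normalized; call normalize_per_hour() first")
    ids <- rownames(m)
    covs <- covariates[[s]]
    if (!identical(names(covs), prednames))
      stop("covariate names differ between samples")
    for (k in prednames) {
      if (!identical(rownames(covs[[k]]), ids))
        stop("covariate ", k, " of sample ", s,
             " is indexed by different actors than y")
    }
    yl <- log(m + log_offset)
    attr(yl, "units") <- NULL
    ylog[[s]] <- yl
    ut <- which(upper.tri(m), arr.ind = TRUE)
    df <- data.frame(sample = s,
                     actor_i = ids[ut[, 1L]], actor_j = ids[ut[, 2L]],
                     ia = ut[, 1L], ja = ut[, 2L],
                     y = yl[ut],
                     stringsAsFactors = FALSE)
    for (k in prednames) df[[k]] <- covs[[k]][ut]
    rows[[s]] <- df
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  dummy_names <- character(0)
  if (length(samples) > 1L) {
    for (s in samples[-1L]) {
      nm <- paste0("sample_", s)
      data[[nm]] <- as.numeric(data$sample == s)
      dummy_names <- c(dummy_names, nm)
    }
  }
  predictors <- c(dummy_names, prednames)
  pred_mat <- as.matrix(data[, predictors, drop = FALSE])
  data$complete <- stats::complete.cases(pred_mat) & !is.na(data$y)
  structure(list(data = data, ylog = ylog, predictors = predictors,
                 samples = samples, offset = log_offset,
                 n_pre = nrow(data), n_post = sum(data$complete)),
            class = "dyad_design")
}

#' @export
print.dyad_design <- function(x, ...) {
  cat("Dyadic design:", x$n_pre, "dyads over",
      length(x$samples), "sample(s);", x$n_post,
      "remain after listwise deletion\n")
  cat("Response: log(y +", x$offset, "), y in seconds/hour\n")
  cat("Predictors:", paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Export a dyadic design as TSV
#'
#' Writes one row per dyad with a provenance header recording the log
#' offset and the deletion counts.
#'
#' @param design A \code{dyad_design}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_design <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# log_offset: %g", design$offset),
               sprintf("# dyads_before_deletion: %d", design$n_pre),
               sprintf("# dyads_after_deletion: %d", design$n_post)), con)
  utils::write.table(design$data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default dyadic covariate set
#'
#' Builds the covariate matrices of the standard interaction-duration model
#' for one sample: gender dummies (at least one female, both female),
#' centered age mean, age similarity, student-organization dummies (at least
#' one member, and same membership status; with an intercept this pair is
#' the only non-collinear coding of the three dyad categories), the
#' symmetrized friendship tie,
#' depression mean (uncentered), depression similarity, and the interactions
#' depression mean x similarity and depression mean x friendship.
#'
#' @param actors \code{actor_table} rows of one sample (needs
#'   \code{depression_score}).
#' @param noms \code{nominations} within that sample.
#' @param split_friendship Replace the symmetrized friendship tie and its
#'   depression interaction with separate mutual and asymmetric versions.
#' @return Named list of covariate matrices, ordered as in the standard
#'   model.
#' @export
default_covariates <- function(actors, noms, split_friendship = FALSE) {
  ids <- actors$actor_id
  gender <- stats::setNames(actors$gender, ids)
  age <- stats::setNames(actors$age, ids)
  org <- stats::setNames(ifelse(actors$org_member, "member", "nonmember"), ids)
  dep <- stats::setNames(actors$depression_score, ids)
  fr <- friendship_matrices(noms, ids)
  dep_mean <- mean_matrix(dep, centered = FALSE)
  dep_sim <- similarity_matrix(dep)
  out <- list(
    female_any = category_dummy_matrix(gender, "female", "at_least_one"),
    female_both = category_dummy_matrix(gender, "female", "both"),
    age_mean_c = mean_matrix(age, centered = TRUE),
    age_sim = similarity_matrix(age),
    org_one = category_dummy_matrix(org, "member", "at_least_one"),
    org_same = category_dummy_matrix(org, "member", "same"),
    friend_any = fr$any,
    dep_mean = dep_mean,
    dep_sim = dep_sim,
    dep_mean_x_sim = product_matrix(dep_mean, dep_sim),
    dep_mean_x_friend = product_matrix(dep_mean, fr$any))
  if (split_friendship) {
    out$friend_any <- NULL
    out$dep_mean_x_friend <- NULL
    out$friend_mutual <- fr$mutual
    out$friend_asym <- fr$asymmetric
    out$dep_mean_x_mutual <- product_matrix(dep_mean, fr$mutual)
    out$dep_mean_x_asym <- product_matrix(dep_mean, fr$asymmetric)
  }
  out
}
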