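#' CES-D sum score
#'
#' Scores the 20-item Center for Epidemiologic Studies Depression scale by
#' summing the items, each rated 0 (never or rarely) to 3 (most of the time).
#' The score ranges 0--60; if any item is missing, the score is missing
#' (no prorating or imputation).
#'
#' @param items Numeric vector of 20 item responses in \code{[0, 3]};
#'   \code{NA} allowed.
#' @return The sum score, or \code{NA} under any item missingness.
#' @seealso \code{\link{cesd_band}} for the conventional screening bands.
#' @export
cesd_score <- function(items) {
  if (length(items) != 20L)
    stop("CES-D requires exactly 20 items, got ", length(items))
  ok <- items[!is.na(items)]
  if (any(ok != round(ok) | ok < 0 | ok > 3))
    stop("CES-D items must be integers in [0, 3]")
  if (anyNA(items)) return(NA_real_)
  sum(items)
}

#' Row-wise CES-D scoring of an item matrix
#' @param item_matrix Numeric matrix, one row per actor, 20 columns.
#' @return Numeric vector of sum scores (\code{NA} where any item missing).
#' @export
score_cesd <- function(item_matrix) {
  stopifnot(ncol(item_matrix) == 20L)
  apply(item_matrix, 1L, function(r) {
    if (anyNA(r)) NA_real_ else cesd_score(r)
  })
}

#' Screening band of a CES-D score
#'
#' Conventional screening bands: scores above 16 flag clinically relevant
#' depressive symptoms, scores between 9 and 16 sub-clinical symptoms.
#'
#' @param score Numeric vector of CES-D sum scores.
#' @return Factor with levels \code{none}, \code{subclinical},
#'   \code{clinical}.
#' @export
cesd_band <- function(score) {
  out <- ifelse(is.na(score), NA_character_,
                ifelse(score > 16, "clinical",
                       ifelse(score >= 9, "subclinical", "none")))
  factor(out, levels = c("none", "subclinical", "clinical"))
}

#' BFI-10 trait scores
#'
#' Scores the 10-item Big Five Inventory: each trait is the mean of two items
#' on a 1--5 scale, with items 1, 3, 4, 5 and 7 reverse-keyed. A trait is
#' missing if either of its items is missing.
#'
#' @param items Numeric vector of 10 item responses in \code{[1, 5]}.
#' @return Named numeric vector with elements \code{extraversion},
#'   \code{agreeableness}, \code{conscientiousness}, \code{neuroticism},
#'   \code{openness}.
#' @export
bfi_traits <- function(items) {
  if (length(items) != 10L)
    stop("BFI-10 requires exactly 10 items, got ", length(items))
  rev_idx <- c(1L, 3L, 4L, 5L, 7L)
  r <- items
  r[rev_idx] <- 6 - r[rev_idx]
  c(extraversion = mean(r[c(1L, 6L)]),
    agreeableness = mean(r[c(2L, 7L)]),
    conscientiousness = mean(r[c(3L, 8L)]),
    neuroticism = mean(r[c(4L, 9L)]),
    openness = mean(r[c(5L, 10L)]))
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1) \, (1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2} are
#' the item variances and \eqn{s_T^2} the variance of the item sum. Rows with
#' any missing item are dropped.
#'
#' @param items Numeric matrix, one row per respondent, \eqn{k \ge 2}
#'   columns.
#' @return Alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("Cronbach's alpha needs at least 2 items")
  items <- items[stats::complete.cases(items), , drop = FALSE]
  if (nrow(items) < 2L) stop("need at least 2 complete rows")
  k <- ncol(items)
  vt <- stats::var(rowSums(items))
  if (vt == 0) stop("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2L, stats::var)) / vt)
}

star_code <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Pairwise correlation panel of individual-level aggregates
#'
#' Computes the matrix of pairwise correlations among node-level variables
#' (depression score, age, gender, interaction-time aggregates), using
#' Pearson correlations except for pairs involving a variable named in
#' \code{spearman_vars} (e.g. gender), which use Spearman rank correlations.
#' Each cell uses pairwise-complete observations; cells with fewer than 3
#' complete pairs are missing. Classical two-sided p-values are attached for
#' display stars.
#'
#' @param data Data frame of numeric node-level variables.
#' @param spearman_vars Character vector of variable names for which Spearman
#'   correlations are used.
#' @return A list of class \code{correlation_panel} with elements \code{r},
#'   \code{p}, \code{n} (matrices) and \code{stars}.
#' @export
correlation_panel <- function(data, spearman_vars = "gender") {
  vars <- names(data)
  k <- length(vars)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      x <- as.numeric(data[[a]]); y <- as.numeric(data[[b]])
      ok <- stats::complete.cases(x, y)
      n[a, b] <- sum(ok)
      if (sum(ok) < 3L) next
      if (a == b) { r[a, b] <- 1; p[a, b] <- 0; next }
      method <- if (vars[a] %in% spearman_vars || vars[b] %in% spearman_vars)
        "spearman" else "pearson"
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
      r[a, b] <- unname(ct$estimate)
      p[a, b] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n, stars = star_code(p)),
            class = "correlation_panel")
}

#' @export
print.correlation_panel <- function(x, digits = 2, ...) {
  show <- matrix(paste0(formatC(x$r, digits = digits, format = "f"),
                        x$stars),
                 nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  show[is.na(x$r)] <- "."
  show[upper.tri(show, diag = TRUE)] <- ""
  print(as.data.frame(show), right = TRUE)
  cat("Stars: * p<0.05, ** p<0.01, *** p<0.001 (two-sided)\n")
  invisible(x)
}

#' Export a correlation panel as TSV
#' @param panel A \code{correlation_panel}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_correlation_panel <- function(panel, path) {
  show <- matrix(paste0(formatC(panel$r, digits = 2, format = "f"),
                        panel$stars),
                 nrow(panel$r), ncol(panel$r), dimnames = dimnames(panel$r))
  show[is.na(panel$r)] <- ""
  utils::write.table(show, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Permutation correlation test
#'
#' Tests the correlation between two node-level variables by permuting the
#' second variable (the dependent one, following the logic of a bivariate
#' QAP) and comparing the observed correlation to the permutation null
#' distribution. When group labels are given, permutations are confined
#' within groups, consistent with multi-group network inference; with
#' \code{groups = NULL} the pooled vector is permuted freely.
#'
#' @param x,y Numeric vectors of equal length. \code{y} is permuted.
#' @param groups Optional vector of group labels (e.g. sample ids) defining
#'   permutation blocks.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param n_permutations Number of random permutations (ignored when
#'   \code{exhaustive = TRUE}).
#' @param convention P-value convention, as in \code{\link{mrqap}}.
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all within-group permutations (feasible only
#'   for tiny n); the p-value is then exact.
#' @return A list of class \code{correlation_result}: \code{r}, \code{p},
#'   \code{n}, \code{n_permutations}, \code{method}, \code{convention},
#'   \code{null} (the null correlations).
#' @export
permutation_correlation_test <- function(x, y, groups = NULL,
                                         method = c("pearson", "spearman"),
                                         n_permutations = 5000,
                                         convention = c("two_sided_doubled",
                                                        "percent_rank"),
                                         seed = NULL, exhaustive = FALSE) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  stopifnot(length(x) == length(y))
  if (is.null(groups)) groups <- rep(1L, length(x))
  stopifnot(length(groups) == length(x))
  ok <- stats::complete.cases(x, y, groups)
  x <- x[ok]; y <- y[ok]; groups <- groups[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r_obs <- stats::cor(x, y, method = method)
  if (!is.null(seed)) set.seed(seed)
  blocks <- split(seq_along(y), groups)
  if (exhaustive) {
    perms_per_block <- lapply(blocks, function(ix) all_permutations(length(ix)))
    combo <- Reduce(function(a, b) {
      out <- vector("list", length(a) * length(b))
      k <- 0L
      for (pa in a) for (pb in b) { k <- k + 1L; out[[k]] <- c(pa, pb) }
      out
    }, lapply(seq_along(blocks), function(bi) {
      lapply(seq_len(nrow(perms_per_block[[bi]])), function(r)
        blocks[[bi]][perms_per_block[[bi]][r, ]])
    }))
    null <- vapply(combo, function(ix) {
      yp <- y
      yp[unlist(blocks)] <- y[ix]
      stats::cor(x, yp, method = method)
    }, 0)
    null_with_obs <- null  # identity relabeling is part of the enumeration
    B <- length(null)
  } else {
    B <- n_permutations
    null <- vapply(seq_len(B), function(b) {
      yp <- y
      for (ix in blocks) yp[ix] <- y[sample(ix)]
      stats::cor(x, yp, method = method)
    }, 0)
    null_with_obs <- c(null, r_obs)
  }
  structure(list(r = r_obs,
                 p = perm_pvalue(r_obs, null_with_obs, convention),
                 n = length(x), n_permutations = B, method = method,
                 convention = convention, null = null),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation r(%d) = %.3f, p = %.4g (%d permutations, %s)\n",
              x$method, x$n - 2L, x$r, x$p, x$n_permutations, x$convention))
  invisible(x)
}

#' Ratio of dyadic interaction time
#'
#' Fraction of each actor's interaction time spent in two-person
#' interactions: \code{dyadic / (dyadic + group)}. Missing for actors with no
#' interaction time.
#'
#' @param budget An actor time budget as returned by
#'   \code{\link{decompose_dyadic_group_time}} or
#'   \code{\link{actor_summaries}} (needs columns \code{dyadic_s},
#'   \code{group_s}).
#' @return Named numeric vector of ratios in \code{[0, 1]}.
#' @export
dyadic_ratio <- function(budget) {
  tot <- budget$dyadic_s + budget$group_s
  out <- ifelse(tot > 0, budget$dyadic_s / tot, NA_real_)
  names(out) <- budget$actor_id
  out
}
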