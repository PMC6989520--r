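# All n! permutations of 1..n, one per row. For exhaustive-inference toys.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (k in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- integer(n)
      row[pos] <- n
      row[-pos] <- sub[k, ]
      out[r, ] <- row
    }
  }
  out
}

# Mid-rank permutation p-value. `null` must already contain the observed
# statistic (the identity relabeling), which bounds p away from 0. Values
# within a small relative tolerance of the observed statistic count as ties,
# so analytically equal permutation statistics are not split by round-off.
perm_pvalue <- function(obs, null,
                        convention = c("two_sided_doubled", "percent_rank")) {
  convention <- match.arg(convention)
  B1 <- length(null)
  eps <- 1e-8 * max(1, abs(obs))
  n_lt <- sum(null < obs - eps)
  n_gt <- sum(null > obs + eps)
  n_eq <- B1 - n_lt - n_gt
  r_le <- (n_lt + (n_eq + 1) / 2) / B1  # mid-rank fraction <= obs
  r_ge <- (n_gt + (n_eq + 1) / 2) / B1  # mid-rank fraction >= obs
  p1 <- min(r_le, r_ge)
  switch(convention,
         two_sided_doubled = min(1, 2 * p1),
         percent_rank = p1)
}

design_matrix <- function(design, complete_only = TRUE) {
  d <- design$data
  if (complete_only) d <- d[d$complete, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(d[, design$predictors, drop = FALSE]))
  X
}

#' Ordinary least squares fit of a dyadic design
#'
#' Fits the pooled dyad-level regression
#' \eqn{y_{ij} = \beta_0 + \sum_k \beta_k x^k_{ij} + e_{ij}} by OLS on the
#' rows surviving listwise deletion. Point estimates are meaningful as in an
#' ordinary linear model; their parametric standard errors are not, because
#' dyads sharing an actor are dependent — use \code{\link{mrqap}} for
#' inference.
#'
#' @param design A \code{dyad_design} from \code{\link{build_design}}.
#' @return List of class \code{ols_fit}: \code{coefficients},
#'   \code{r.squared}, \code{adj.r.squared}, \code{residuals},
#'   \code{skewness} (of the residuals), \code{n}.
#' @export
ols_fit <- function(design) {
  X <- design_matrix(design)
  yv <- design$data$y[design$data$complete]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, yv)
  res <- yv - drop(X %*% beta)
  n <- length(yv)
  p <- ncol(X)
  tss <- sum((yv - mean(yv))^2)
  r2 <- 1 - sum(res^2) / tss
  structure(list(coefficients = beta, r.squared = r2,
                 adj.r.squared = 1 - (1 - r2) * (n - 1) / (n - p),
                 residuals = res,
                 skewness = e1071::skewness(res),
                 n = n),
            class = "ols_fit")
}

#' Y-permute the dependent dyadic values of a design
#'
#' Applies one actor relabeling per sample simultaneously to the rows and
#' columns of that sample's dependent matrix, leaving every predictor (and
#' hence the listwise-deletion mask, which is defined by the predictors)
#' untouched. Returns the permuted response aligned with the design rows.
#'
#' @param design A \code{dyad_design}.
#' @param perms Named list (one element per sample) of integer permutation
#'   vectors over that sample's actor indices.
#' @return Numeric vector of permuted responses, one per design row
#'   (pre-deletion order).
#' @export
y_permute <- function(design, perms) {
  d <- design$data
  out <- numeric(nrow(d))
  for (s in design$samples) {
    yl <- design$ylog[[s]]
    pm <- perms[[s]]
    stopifnot(length(pm) == nrow(yl))
    rows <- which(d$sample == s)
    ylp <- yl[pm, pm, drop = FALSE]
    out[rows] <- ylp[cbind(d$ia[rows], d$ja[rows])]
  }
  out
}

#' Multi-group MRQAP with Y-permutation inference
#'
#' Fits the dyadic regression by OLS and obtains permutation-based inference
#' by repeatedly relabeling the actors of each sample's dependent matrix
#' (rows and columns swapped together, independent matrices fixed) and
#' refitting. With several samples, relabelings are confined within each
#' sample — the multi-group scheme. For every coefficient the permutation
#' null sample yields its expectation \eqn{E(\beta)}, 2.5th/97.5th
#' percentiles (nearest order statistic), and a percent-rank p-value.
#'
#' Two p-value conventions are available. \code{"two_sided_doubled"}
#' (default) doubles the smaller tail of the mid-rank, capped at 1 — the
#' standard two-sided permutation p. \code{"percent_rank"} reports the
#' smaller tail itself (a percent rank of 0.99 gives p = 0.01), the
#' convention used in some MRQAP software. The observed statistic is always
#' counted in the null set, so p is bounded below by the permutation
#' resolution.
#'
#' @param design A \code{dyad_design}.
#' @param n_permutations Number of random Y-permutations (default 5000).
#' @param seed Optional integer seed for reproducible inference.
#' @param convention P-value convention, see above.
#' @param exhaustive Enumerate every within-sample relabeling instead of
#'   sampling; only feasible for toy designs (the product of factorials must
#'   not exceed \code{max_exhaustive}).
#' @param max_exhaustive Guard for \code{exhaustive = TRUE}.
#' @return Object of class \code{mrqap}: a coefficient table
#'   (\code{estimate}, \code{p}, \code{e_null}, \code{q025}, \code{q975}),
#'   fit statistics, the null coefficient samples, and the settings used.
#' @export
mrqap <- function(design, n_permutations = 5000, seed = NULL,
                  convention = c("two_sided_doubled", "percent_rank"),
                  exhaustive = FALSE, max_exhaustive = 50000) {
  convention <- match.arg(convention)
  fit <- ols_fit(design)
  mask <- design$data$complete
  X <- design_matrix(design)
  V <- chol2inv(chol(crossprod(X)))
  P <- V %*% t(X)  # coefficient operator: beta = P %*% y
  ns <- vapply(design$ylog, nrow, 0L)
  if (exhaustive) {
    n_comb <- prod(factorial(ns))
    if (n_comb > max_exhaustive)
      stop("exhaustive enumeration infeasible: ", n_comb, " relabelings")
    perm_sets <- lapply(ns, all_permutations)
    grid <- do.call(expand.grid,
                    lapply(perm_sets, function(m) seq_len(nrow(m))))
    B <- nrow(grid)
    beta_star <- matrix(0, ncol(X), B,
                        dimnames = list(colnames(X), NULL))
    for (b in seq_len(B)) {
      perms <- lapply(seq_along(design$samples), function(si)
        perm_sets[[si]][grid[b, si], ])
      names(perms) <- design$samples
      beta_star[, b] <- P %*% y_permute(design, perms)[mask]
    }
    null_incl <- beta_star  # identity relabeling is one of the B columns
  } else {
    if (!is.null(seed)) set.seed(seed)
    B <- as.integer(n_permutations)
    beta_star <- matrix(0, ncol(X), B,
                        dimnames = list(colnames(X), NULL))
    chunk <- 500L
    done <- 0L
    while (done < B) {
      nb <- min(chunk, B - done)
      Y <- matrix(0, sum(mask), nb)
      for (b in seq_len(nb)) {
        perms <- lapply(ns, sample)
        Y[, b] <- y_permute(design, perms)[mask]
      }
      beta_star[, done + seq_len(nb)] <- P %*% Y
      done <- done + nb
    }
    null_incl <- cbind(beta_star, fit$coefficients)
  }
  terms <- names(fit$coefficients)
  tab <- data.frame(
    term = terms,
    estimate = unname(fit$coefficients),
    p = vapply(seq_along(terms), function(k)
      perm_pvalue(fit$coefficients[k], null_incl[k, ], convention), 0),
    e_null = rowMeans(beta_star),
    q025 = apply(beta_star, 1L, stats::quantile, probs = 0.025, type = 1),
    q975 = apply(beta_star, 1L, stats::quantile, probs = 0.975, type = 1),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(coefficients = tab, r.squared = fit$r.squared,
                 adj.r.squared = fit$adj.r.squared,
                 skewness = fit$skewness, n = fit$n,
                 n_permutations = B, convention = convention,
                 exhaustive = exhaustive, seed = seed,
                 null = beta_star),
            class = "mrqap")
}

#' @export
print.mrqap <- function(x, digits = 3, ...) {
  cat("Multi-group MRQAP on", x$n, "dyads,",
      x$n_permutations,
      if (x$exhaustive) "exhaustive Y-relabelings\n" else "Y-permutations\n")
  tab <- x$coefficients
  out <- data.frame(
    Estimate = formatC(tab$estimate, digits = digits, format = "f"),
    p = formatC(tab$p, digits = digits, format = "f"),
    `E(Est.)` = formatC(tab$e_null, digits = digits, format = "f"),
    `2.5th` = formatC(tab$q025, digits = digits, format = "f"),
    `97.5th` = formatC(tab$q975, digits = digits, format = "f"),
    row.names = tab$term, check.names = FALSE)
  print(out)
  cat(sprintf("R-squared %.3f, adj. %.3f, residual skewness %.2f\n",
              x$r.squared, x$adj.r.squared, x$skewness))
  cat("p-value convention:", x$convention, "\n")
  invisible(x)
}

#' Export MRQAP results as TSV
#'
#' Writes the coefficient table (estimate, p, null expectation, 2.5th and
#' 97.5th null percentiles) with a header recording fit statistics, the
#' permutation count, seed and p-value convention.
#'
#' @param result An \code{mrqap} object.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_mrqap_results <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# r_squared: %.6g", result$r.squared),
               sprintf("# adj_r_squared: %.6g", result$adj.r.squared),
               sprintf("# residual_skewness: %.6g", result$skewness),
               sprintf("# n_dyads: %d", result$n),
               sprintf("# n_permutations: %d", result$n_permutations),
               sprintf("# convention: %s", result$convention),
               sprintf("# seed: %s",
                       if (is.null(result$seed)) "NA" else result$seed)),
             con)
  utils::write.table(result$coefficients, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
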