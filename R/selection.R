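#' Reference coefficient set of the standard interaction-duration model
#'
#' Named coefficient vector for the log-linear dyadic interaction-duration
#' model, as published for a two-cohort weekend field study of first-year
#' students wearing RFID badges (response: log-transformed interaction
#' seconds per hour). Used as the package's worked-example coefficients and
#' as the default generative parameters of \code{\link{simulation_config}}.
#'
#' @return Named numeric vector with elements \code{intercept},
#'   \code{sample_two}, \code{female_any}, \code{female_both},
#'   \code{age_mean_c}, \code{age_sim}, \code{org_one}, \code{org_same},
#'   \code{friend_any}, \code{dep_mean}, \code{dep_sim},
#'   \code{dep_mean_x_sim}, \code{dep_mean_x_friend}.
#' @export
reference_coefficients <- function() {
  c(intercept = 2.504, sample_two = 0.806,
    female_any = -0.095, female_both = -0.148,
    age_mean_c = 0.065, age_sim = 0.042,
    org_one = -0.028, org_same = 0.269,
    friend_any = 2.128,
    dep_mean = -0.059, dep_sim = 0.047,
    dep_mean_x_sim = -0.004, dep_mean_x_friend = -0.012)
}

#' Model-implied interaction duration for a depression-score pair
#'
#' Evaluates the fitted log-linear model at depression scores
#' \eqn{(d_i, d_j)} with every other predictor at its reference value (same
#' age, no friendship tie, two males, first sample, no organization
#' membership): the linear predictor is
#' \deqn{\eta = \beta_0 + \beta_m \bar d + \beta_s (-|d_i - d_j|)
#'   + \beta_{ms} \, \bar d \, (-|d_i - d_j|)}
#' with \eqn{\bar d = (d_i + d_j)/2}, and the prediction is
#' \eqn{\hat y = e^\eta} seconds per hour. The back-transform deliberately
#' ignores the log offset and any smearing correction (the convention used
#' when such models are reported); \code{smearing} multiplies by a supplied
#' factor instead.
#'
#' @param coeffs Named coefficient vector containing \code{intercept} and
#'   \code{dep_mean}; \code{dep_sim} and \code{dep_mean_x_sim} default to 0
#'   when absent.
#' @param d_i,d_j Depression scores (vectors recycle).
#' @param smearing Optional multiplicative back-transform correction
#'   (default 1, i.e. none).
#' @return Predicted interaction duration in seconds per hour.
#' @export
predict_duration <- function(coeffs, d_i, d_j, smearing = 1) {
  need <- c("intercept", "dep_mean")
  miss <- setdiff(need, names(coeffs))
  if (length(miss))
    stop("missing required coefficients: ", paste(miss, collapse = ", "))
  get0c <- function(nm) if (nm %in% names(coeffs)) coeffs[[nm]] else 0
  dbar <- (d_i + d_j) / 2
  sim <- -abs(d_i - d_j)
  eta <- coeffs[["intercept"]] + coeffs[["dep_mean"]] * dbar +
    get0c("dep_sim") * sim + get0c("dep_mean_x_sim") * dbar * sim
  unname(exp(eta) * smearing)
}

#' Selection table of model-implied durations over a depression grid
#'
#' Evaluates \code{\link{predict_duration}} on the full grid of
#' depression-score pairs, producing the heat-map table that shows which
#' score combinations the fitted model makes most and least likely to
#' interact.
#'
#' @param coeffs Coefficient vector as in \code{\link{predict_duration}}.
#' @param range Integer vector of depression scores (default \code{0:36},
#'   the observed range; the \code{1:36} figure convention is a flag away).
#' @param smearing Passed to \code{\link{predict_duration}}.
#' @return A symmetric matrix of class \code{selection_grid} with the scores
#'   as dimnames and attribute \code{coefficients}.
#' @export
selection_grid <- function(coeffs, range = 0:36, smearing = 1) {
  if (length(range) == 0L) stop("empty depression-score range")
  m <- outer(range, range,
             function(a, b) predict_duration(coeffs, a, b, smearing))
  dimnames(m) <- list(range, range)
  attr(m, "coefficients") <- coeffs
  class(m) <- c("selection_grid", class(m))
  m
}

#' @export
print.selection_grid <- function(x, ...) {
  cat("Selection table: model-implied interaction duration (sec/h)\n")
  y <- x
  attr(y, "coefficients") <- NULL
  print(unclass(round(y, 2)))
  invisible(x)
}
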