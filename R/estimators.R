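#' Treatment hazard ratio on the matched subsample
#'
#' Performs greedy nearest-neighbour matching on the propensity score and
#' fits a univariate Cox model of the treatment on the matched population
#' (robust variance).
#'
#' @param fit a `propensity_fit`.
#' @param y survival days.
#' @param event 0/1 death indicator.
#' @param covariate_set label for the adjustment set used by the fit.
#' @return An `hr_estimate`.
#' @export
hr_matching <- function(fit, y, event, covariate_set = "covariates") {
  m <- nnm_match(fit)
  idx <- m$matched
  assert_that(sum(event[idx]) >= 1, "no events in the matched subsample")
  model <- fit_cox(fit$W[idx], y[idx], event[idx])
  new_hr_estimate("matching", covariate_set, model, length(idx))
}

#' Treatment hazard ratio under stabilized IPTW
#'
#' Fits a univariate Cox model of the treatment weighted by the stabilized
#' inverse-probability-of-treatment weights (treated weight 1, controls
#' their propensity odds), with robust variance.
#'
#' @inheritParams hr_matching
#' @return An `hr_estimate`.
#' @export
hr_iptw <- function(fit, y, event, covariate_set = "covariates") {
  w <- stabilized_weights(fit)
  model <- fit_cox(fit$W, y, event, weights = w)
  new_hr_estimate("IPTW", covariate_set, model, length(y))
}

#' Doubly robust weighted multivariate Cox hazard ratio
#'
#' Fits a multivariate Cox model of the treatment and the adjustment
#' covariates, weighted by the stabilized inverse propensity weights, so
#' the estimate is consistent if either the propensity model or the outcome
#' adjustment is correctly specified.
#'
#' @inheritParams hr_matching
#' @param X a [covariate_matrix()] containing the adjustment covariates.
#' @param columns covariate columns to adjust for (default: all columns of
#'   `X`).
#' @return An `hr_estimate`; the full covariate table is attached as
#'   attribute `"covariate_table"`.
#' @export
hr_multicoxph <- function(fit, y, event, X, columns = NULL,
                          covariate_set = "covariates") {
  xm <- as.matrix(X)
  if (!is.null(columns)) {
    missing <- setdiff(columns, colnames(xm))
    assert_that(length(missing) == 0,
                paste("covariate_set columns not present:",
                      paste(missing, collapse = ", ")))
    xm <- xm[, columns, drop = FALSE]
  }
  if (sum(event) < ncol(xm) / 10) {
    warning(sprintf("only %d events for %d covariates (1-in-10 rule)",
                    sum(event), ncol(xm)))
  }
  w <- stabilized_weights(fit)
  model <- if (ncol(xm) == 0) {
    fit_cox(fit$W, y, event, weights = w)
  } else {
    fit_cox(fit$W, y, event, X = xm, weights = w)
  }
  est <- new_hr_estimate("multi.coxph", covariate_set, model, length(y))
  attr(est, "covariate_table") <- model$table
  est
}
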