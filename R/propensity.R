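#' Estimate propensity scores with a chosen learner
#'
#' Estimates `e(X) = P(W = 1 | X)` with logistic regression, gradient
#' boosting or a (probability) random forest. Scores are cross-fitted
#' (2-fold, seeded) by default so that balance diagnostics are not
#' flattered by in-sample overfitting, then clipped to `[0.01, 0.99]` for
#' positivity. Covariate balance is summarized as the standardized mean
#' difference (SMD) per covariate before and after stabilized weighting.
#'
#' @param X a [covariate_matrix()] (or matrix) of the adjustment covariates.
#' @param W 0/1 treatment indicator; both arms must be present.
#' @param learner `"logistic"`, `"gradient_boosting"` or `"random_forest"`.
#' @param seed integer seed (fold split and stochastic learners).
#' @param cross_fit set `FALSE` for in-sample fitting.
#' @param clip clipping bounds for the scores.
#' @return An object of class `propensity_fit` with elements `scores`,
#'   `learner`, `W`, `balance` (per-covariate SMD before/after), `overlap`
#'   (per-arm clipped fractions and score quantiles).
#' @export
estimate_propensity <- function(X, W,
                                learner = c("logistic", "gradient_boosting",
                                            "random_forest"),
                                seed = 1, cross_fit = TRUE,
                                clip = c(0.01, 0.99)) {
  learner <- match.arg(learner)
  x <- as.matrix(X)
  assert_that(length(W) == nrow(x), "W must align with rows of X")
  assert_that(all(W %in% c(0, 1)) && length(unique(W)) == 2,
              "both treatment arms must be present")
  raw <- rep(NA_real_, nrow(x))
  if (cross_fit && nrow(x) >= 20) {
    foldid <- balanced_folds(W, 2, seed)
    for (f in 1:2) {
      tr <- foldid != f
      raw[!tr] <- fit_propensity_learner(x[tr, , drop = FALSE], W[tr],
                                         x[!tr, , drop = FALSE], learner,
                                         derive_seed(seed, paste0("fold", f)))
    }
  } else {
    raw <- fit_propensity_learner(x, W, x, learner, seed)
  }
  clipped_lo <- raw < clip[1]
  clipped_hi <- raw > clip[2]
  scores <- pmin(pmax(raw, clip[1]), clip[2])
  wts <- W + (1 - W) * scores / (1 - scores)
  balance <- data.frame(
    covariate = colnames(x),
    smd_before = vapply(seq_len(ncol(x)), function(j)
      weighted_smd(x[, j], W, rep(1, length(W))), numeric(1)),
    smd_after = vapply(seq_len(ncol(x)), function(j)
      weighted_smd(x[, j], W, wts), numeric(1)),
    stringsAsFactors = FALSE)
  clip_frac <- c(treated = mean(clipped_lo[W == 1] | clipped_hi[W == 1]),
                 control = mean(clipped_lo[W == 0] | clipped_hi[W == 0]))
  overlap <- list(clip_frac = clip_frac,
                  quantiles_treated = quantile(scores[W == 1], c(.05, .5, .95)),
                  quantiles_control = quantile(scores[W == 0], c(.05, .5, .95)))
  structure(list(scores = scores, learner = learner, W = W,
                 balance = balance, overlap = overlap, clip = clip,
                 cross_fit = cross_fit, seed = seed,
                 columns = colnames(x)),
            class = "propensity_fit")
}

fit_propensity_learner <- function(xtr, wtr, xte, learner, seed) {
  if (learner == "logistic") {
    df <- as.data.frame(xtr)
    names(df) <- paste0("V", seq_len(ncol(xtr)))
    fit <- suppressWarnings(glm(wtr ~ ., data = cbind(wtr = wtr, df),
                                family = binomial()))
    nd <- as.data.frame(xte)
    names(nd) <- names(df)
    as.numeric(suppressWarnings(predict(fit, newdata = nd, type = "response")))
  } else if (learner == "gradient_boosting") {
    dtr <- xgboost::xgb.DMatrix(xtr, label = wtr, nthread = 1)
    fit <- with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 2,
                    eta = 0.3, nthread = 1),
      data = dtr, nrounds = 60, verbose = 0))
    as.numeric(predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1)))
  } else if (learner == "random_forest") {
    fit <- with_seed(seed, randomForest::randomForest(
      x = as.data.frame(xtr), y = factor(wtr, levels = c(0, 1)),
      ntree = 300))
    as.numeric(predict(fit, as.data.frame(xte), type = "prob")[, "1"])
  } else {
    stop("unknown learner: ", learner, call. = FALSE)
  }
}

# Weighted standardized mean difference in pooled-SD units.
weighted_smd <- function(x, W, w) {
  m1 <- weighted.mean(x[W == 1], w[W == 1])
  m0 <- weighted.mean(x[W == 0], w[W == 0])
  v1 <- weighted.mean((x[W == 1] - m1)^2, w[W == 1])
  v0 <- weighted.mean((x[W == 0] - m0)^2, w[W == 0])
  sp <- sqrt((v1 + v0) / 2)
  if (sp == 0) return(0)
  (m1 - m0) / sp
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("<propensity_fit> learner %s (%s); mean |SMD| %.3f -> %.3f; clipped T %.1f%% / C %.1f%%\n",
              x$learner, if (x$cross_fit) "cross-fitted" else "in-sample",
              mean(abs(x$balance$smd_before)), mean(abs(x$balance$smd_after)),
              100 * x$overlap$clip_frac["treated"],
              100 * x$overlap$clip_frac["control"]))
  invisible(x)
}

#' Pick the propensity model with the best overlap and balance
#'
#' Discards candidates whose clipping exceeds 5% of either arm's scores
#' (poor overlap), then returns the candidate minimizing the mean absolute
#' post-weighting SMD. Exact ties are broken by the deterministic learner
#' preference logistic > gradient_boosting > random_forest.
#'
#' @param fits list of `propensity_fit` candidates.
#' @return The selected `propensity_fit`, with the selection criterion in
#'   attribute `"selection"`.
#' @export
select_propensity_model <- function(fits) {
  assert_that(length(fits) >= 1, "need at least one candidate fit")
  ok <- vapply(fits, function(f) all(f$overlap$clip_frac <= 0.05), logical(1))
  if (!any(ok)) {
    stop("all propensity candidates fail the overlap check (> 5% clipped scores in an arm); revise the covariate set",
         call. = FALSE)
  }
  fits <- fits[ok]
  crit <- vapply(fits, function(f) mean(abs(f$balance$smd_after)), numeric(1))
  pref <- match(vapply(fits, `[[`, character(1), "learner"),
                c("logistic", "gradient_boosting", "random_forest"))
  best <- order(crit, pref)[1]
  out <- fits[[best]]
  attr(out, "selection") <- data.frame(
    learner = vapply(fits, `[[`, character(1), "learner"),
    mean_abs_smd_after = crit)
  out
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Treated patients receive weight 1; controls receive their propensity
#' odds `e / (1 - e)`, re-weighting the control arm to the treated
#' population.
#'
#' @param fit a `propensity_fit`, or a numeric vector of scores in (0, 1).
#' @param W 0/1 treatment indicator (taken from `fit` when omitted).
#' @return Numeric vector of weights.
#' @export
stabilized_weights <- function(fit, W = NULL) {
  if (inherits(fit, "propensity_fit")) {
    e <- fit$scores
    if (is.null(W)) W <- fit$W
  } else {
    e <- as.numeric(fit)
  }
  assert_that(!is.null(W), "W is required when passing raw scores")
  assert_that(all(e > 0 & e < 1), "propensity scores must lie strictly in (0, 1)")
  W + (1 - W) * e / (1 - e)
}

#' Greedy 1:1 nearest-neighbour matching on the propensity score
#'
#' Matches each treated unit to the nearest unmatched control on the score,
#' without replacement, processing treated units in descending score order.
#' Unmatched units are dropped (their count is reported in the result).
#'
#' @param fit a `propensity_fit` (or numeric score vector).
#' @param W 0/1 treatment indicator (taken from `fit` when omitted).
#' @return A list with `pairs` (data frame `treated`, `control`,
#'   `distance`), `matched` (sorted row indices of the matched subsample)
#'   and `n_unmatched`.
#' @export
nnm_match <- function(fit, W = NULL) {
  if (inherits(fit, "propensity_fit")) {
    scores <- fit$scores
    if (is.null(W)) W <- fit$W
  } else {
    scores <- as.numeric(fit)
  }
  treated <- which(W == 1)
  control <- which(W == 0)
  assert_that(length(treated) > 0 && length(control) > 0,
              "both arms must be non-empty")
  treated <- treated[order(-scores[treated], treated)]
  available <- rep(TRUE, length(control))
  pairs <- matrix(NA_integer_, nrow = min(length(treated), length(control)),
                  ncol = 2)
  dist <- numeric(nrow(pairs))
  k <- 0
  for (t in treated) {
    if (!any(available)) break
    cand <- control[available]
    d <- abs(scores[cand] - scores[t])
    j <- cand[which.min(d)]
    available[match(j, control)] <- FALSE
    k <- k + 1
    pairs[k, ] <- c(t, j)
    dist[k] <- min(d)
  }
  pairs <- pairs[seq_len(k), , drop = FALSE]
  matched <- sort(c(pairs))
  list(pairs = data.frame(treated = pairs[, 1], control = pairs[, 2],
                          distance = dist[seq_len(k)]),
       matched = matched,
       n_unmatched = length(W) - length(matched))
}
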