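#' L1-penalized treatment model with cross-validated penalty path
#'
#' Fits a cross-validated L1-penalized logistic regression of the treatment
#' indicator on the covariates (deviance loss), returning the penalty path,
#' the `lambda.min` / `lambda.1se` choices, the non-zero supports at both,
#' and an unpenalized refit of the model on the `lambda.1se` support.
#'
#' @param X a [covariate_matrix()] (standardized).
#' @param W 0/1 treatment indicator aligned with the rows of `X`.
#' @param folds number of cross-validation folds (>= 3).
#' @param seed integer seed controlling fold assignment.
#' @return An object of class `lasso_path`.
#' @export
fit_treatment_lasso <- function(X, W, folds = 10, seed = 1) {
  x <- as.matrix(X)
  assert_that(length(W) == nrow(x), "W must align with rows of X")
  assert_that(all(W %in% c(0, 1)), "W must be 0/1")
  assert_that(length(unique(W)) == 2 && min(table(W)) >= 2,
              "need at least 2 patients per arm")
  assert_that(folds >= 3, "folds must be >= 3")
  foldid <- balanced_folds(W, folds, seed)
  cvfit <- glmnet::cv.glmnet(x, W, family = "binomial",
                             type.measure = "deviance", foldid = foldid,
                             nlambda = 100,
                             lambda.min.ratio = path_min_ratio(x))
  new_lasso_path(cvfit, x, model = "treatment",
                 refit_fun = function(cols) refit_logistic(x, W, cols))
}

#' L1-penalized Cox outcome model with cross-validated penalty path
#'
#' Fits a cross-validated L1-penalized Cox partial-likelihood path of the
#' survival outcome on the covariates (Breslow tie handling inside the
#' penalized fit). The treatment indicator is not part of the design: the
#' path is used for variable selection over candidate confounders.
#'
#' @param X a [covariate_matrix()] (standardized).
#' @param y survival days.
#' @param event 0/1 death indicator; at least one event required.
#' @inheritParams fit_treatment_lasso
#' @return An object of class `lasso_path`.
#' @export
fit_outcome_lasso_cox <- function(X, y, event, folds = 10, seed = 1) {
  x <- as.matrix(X)
  assert_that(length(y) == nrow(x) && length(event) == nrow(x),
              "outcome must align with rows of X")
  assert_that(sum(event) >= 1, "need at least one event")
  assert_that(folds >= 3, "folds must be >= 3")
  foldid <- balanced_folds(event, folds, seed)
  surv <- survival::Surv(y, event)
  cvfit <- glmnet::cv.glmnet(x, surv, family = "cox",
                             type.measure = "deviance", foldid = foldid,
                             nlambda = 100,
                             lambda.min.ratio = path_min_ratio(x))
  path <- new_lasso_path(cvfit, x, model = "outcome",
                         refit_fun = function(cols) refit_cox(x, y, event, cols))
  path$n_events <- sum(event)
  path
}

path_min_ratio <- function(x) if (nrow(x) > ncol(x)) 1e-3 else 1e-2

# Stratified fold assignment: each stratum of `strata` is spread evenly
# over folds, deterministically given the seed.
balanced_folds <- function(strata, folds, seed) {
  with_seed(seed, {
    foldid <- integer(length(strata))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    foldid
  })
}

new_lasso_path <- function(cvfit, x, model, refit_fun) {
  support_at <- function(s) {
    cf <- as.matrix(coef(cvfit, s = s))
    rn <- rownames(cf)
    rn[cf[, 1] != 0 & rn != "(Intercept)"]
  }
  sup_1se <- support_at("lambda.1se")
  refit <- tryCatch(refit_fun(sup_1se), error = function(e) NULL)
  structure(list(cvfit = cvfit,
                 lambda = cvfit$lambda,
                 cv_error = cvfit$cvm,
                 cv_error_se = cvfit$cvsd,
                 lambda_min = cvfit$lambda.min,
                 lambda_1se = cvfit$lambda.1se,
                 support_min = support_at("lambda.min"),
                 support_1se = sup_1se,
                 columns = colnames(x),
                 refit_coefficients = refit,
                 refit_fun = refit_fun,
                 model = model),
            class = "lasso_path")
}

refit_logistic <- function(x, W, cols) {
  if (length(cols) == 0) {
    return(coef(glm(W ~ 1, family = binomial())))
  }
  df <- as.data.frame(x[, cols, drop = FALSE])
  names(df) <- make.names(cols)
  cf <- coef(glm(W ~ ., data = df, family = binomial()))
  names(cf) <- c("(Intercept)", cols)
  cf
}

refit_cox <- function(x, y, event, cols) {
  if (length(cols) == 0) return(numeric(0))
  df <- as.data.frame(x[, cols, drop = FALSE])
  names(df) <- make.names(cols)
  cf <- coef(survival::coxph(survival::Surv(y, event) ~ ., data = df,
                             ties = "efron"))
  names(cf) <- cols
  cf
}

#' Extract the non-zero support of a penalty path at a policy
#' @param path a `lasso_path`.
#' @param policy `"lambda.1se"` or `"lambda.min"`.
#' @return Character vector of covariate names with non-zero coefficients.
#' @export
path_support <- function(path, policy = c("lambda.1se", "lambda.min")) {
  policy <- match.arg(policy)
  if (policy == "lambda.1se") path$support_1se else path$support_min
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso_path:%s> %d lambdas; |support| %d at lambda.1se (%.4g), %d at lambda.min (%.4g)\n",
              x$model, length(x$lambda), length(x$support_1se), x$lambda_1se,
              length(x$support_min), x$lambda_min))
  invisible(x)
}

#' Select potential confounders by support intersection
#'
#' Potential confounders are the covariates with non-zero coefficients in
#' *both* the treatment and the survival outcome penalized models, with the
#' penalty chosen by `policy` in each. If `lambda.1se` selects no
#' text-derived covariate into the intersection, a diagnostic suggests
#' retrying with `lambda.min` (the sparser policy can shrink away all text
#' terms in smaller cohorts). A sample-size diagnostic warns when the number
#' of covariates to be estimated exceeds events/10 (the "1 in 10" rule of
#' thumb).
#'
#' @param tx_path `lasso_path` from [fit_treatment_lasso()].
#' @param out_path `lasso_path` from [fit_outcome_lasso_cox()].
#' @param policy `"lambda.1se"` or `"lambda.min"`.
#' @return An object of class `selection_result` with elements
#'   `treatment_support`, `outcome_support`, `intersection`, `policy`,
#'   `lambdas`, and `diagnostics`.
#' @export
select_confounders <- function(tx_path, out_path,
                               policy = c("lambda.1se", "lambda.min")) {
  policy <- match.arg(policy)
  assert_that(identical(tx_path$columns, out_path$columns),
              "treatment and outcome paths were fitted on different covariate columns")
  ts <- path_support(tx_path, policy)
  os <- path_support(out_path, policy)
  inter <- intersect(ts, os)
  diag <- character(0)
  if (policy == "lambda.1se" && !any(startsWith(inter, "text:"))) {
    diag <- c(diag, "lambda.1se selected no text-derived covariates; consider policy = 'lambda.min'")
    message(diag[length(diag)])
  }
  n_events <- out_path$n_events
  n_struct <- sum(startsWith(tx_path$columns, "struct:"))
  if (!is.null(n_events) && length(inter) + n_struct > n_events / 10) {
    warning(sprintf("selected %d intersection + %d structured covariates exceeds events/10 = %.1f (1-in-10 rule)",
                    length(inter), n_struct, n_events / 10))
  }
  structure(list(treatment_support = ts, outcome_support = os,
                 intersection = inter, policy = policy,
                 lambdas = c(treatment = if (policy == "lambda.1se") tx_path$lambda_1se else tx_path$lambda_min,
                             outcome = if (policy == "lambda.1se") out_path$lambda_1se else out_path$lambda_min),
                 diagnostics = diag),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> policy %s\n", x$policy))
  cat(sprintf("  treatment support (%d): %s\n", length(x$treatment_support),
              paste(x$treatment_support, collapse = ", ")))
  cat(sprintf("  outcome support   (%d): %s\n", length(x$outcome_support),
              paste(x$outcome_support, collapse = ", ")))
  cat(sprintf("  intersection      (%d): %s\n", length(x$intersection),
              paste(x$intersection, collapse = ", ")))
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}

#' Write a selection result and its coefficient table to disk
#'
#' Writes the supports and policy as JSON and a two-model coefficient table
#' (unpenalized treatment and outcome refits over the selected covariates)
#' as TSV.
#'
#' @param sel a `selection_result`.
#' @param tx_path,out_path the fitted `lasso_path` objects.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_selection <- function(sel, tx_path, out_path, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(policy = sel$policy,
                            treatment_support = sel$treatment_support,
                            outcome_support = sel$outcome_support,
                            intersection = sel$intersection,
                            lambdas = as.list(sel$lambdas)),
                       file.path(dir, "selection.json"), auto_unbox = TRUE,
                       digits = NA)
  cols <- union(sel$treatment_support, sel$outcome_support)
  tx_cf <- tryCatch(tx_path$refit_fun(cols), error = function(e) NULL)
  out_cf <- tryCatch(out_path$refit_fun(cols), error = function(e) NULL)
  tab <- data.frame(covariate = cols,
                    treatment_coef = if (is.null(tx_cf)) NA else unname(tx_cf[cols]),
                    outcome_coef = if (is.null(out_cf)) NA else unname(out_cf[cols]),
                    in_intersection = cols %in% sel$intersection)
  write.table(tab, file.path(dir, "selection_coefficients.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
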