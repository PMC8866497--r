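#' Fit a (weighted) Cox proportional-hazards model for the treatment
#'
#' Maximizes the weighted Cox partial likelihood with Efron tie handling and
#' robust (sandwich) variance via the survival package. The design is the
#' treatment indicator plus optional adjustment covariates. Point estimates
#' are invariant to a uniform rescaling of the weights.
#'
#' @param W 0/1 treatment indicator.
#' @param y survival days.
#' @param event 0/1 death indicator.
#' @param X optional [covariate_matrix()] (or plain matrix) of adjustment
#'   covariates.
#' @param weights optional non-negative observation weights.
#' @return An object of class `cox_model` with elements `table` (one row
#'   per coefficient: `coef`, `hr`, robust `se`, Wald `z`, `p`, `ci_lo`,
#'   `ci_hi`) and the underlying `fit`.
#' @export
fit_cox <- function(W, y, event, X = NULL, weights = NULL) {
  assert_that(sum(event) >= 1, "need at least one event")
  if (!is.null(weights)) {
    assert_that(all(weights >= 0), "weights must be non-negative")
  }
  df <- data.frame(W = W)
  cols <- "W"
  if (!is.null(X)) {
    xm <- as.matrix(X)
    cols <- c("W", colnames(xm))
    xdf <- as.data.frame(xm)
    names(xdf) <- make.names(colnames(xm))
    df <- cbind(df, xdf)
  }
  df$.y <- y
  df$.e <- event
  form <- stats::as.formula(paste("survival::Surv(.y, .e) ~",
                                  paste(setdiff(names(df), c(".y", ".e")),
                                        collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(form, data = df, weights = weights, robust = TRUE,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("Ran out of iterations", conditionMessage(w))) {
        stop("Cox model did not converge: ", conditionMessage(w),
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- cols[is.na(cf)]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  z <- cf / se
  tab <- data.frame(term = cols, coef = unname(cf), hr = unname(exp(cf)),
                    se = unname(se), z = unname(z),
                    p = unname(2 * pnorm(-abs(z))),
                    ci_lo = unname(exp(cf - qnorm(0.975) * se)),
                    ci_hi = unname(exp(cf + qnorm(0.975) * se)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit, n = nrow(df),
                 n_events = sum(event)), class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("<cox_model> n = %d, events = %d\n", x$n, x$n_events))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cox_model <- function(object, ...) {
  stats::setNames(object$table$coef, object$table$term)
}

new_hr_estimate <- function(estimator, covariate_set, model, n_used) {
  row <- model$table[model$table$term == "W", ]
  structure(list(estimator = estimator, covariate_set = covariate_set,
                 hr = row$hr, ci95 = c(row$ci_lo, row$ci_hi),
                 p_value = row$p, loghr = row$coef, se = row$se,
                 n_used = n_used),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("<hr_estimate> %s / %s: HR %.2f [%.2f, %.2f]; p = %.3f; n = %d\n",
              x$estimator, x$covariate_set, x$hr, x$ci95[1], x$ci95[2],
              x$p_value, x$n_used))
  invisible(x)
}

#' Proportional-hazards diagnostic
#'
#' Schoenfeld-residual test of the proportional-hazards assumption for a
#' fitted model; emits a warning for each coefficient whose test rejects at
#' the given level.
#'
#' @param model a `cox_model` from [fit_cox()].
#' @param alpha rejection level for the per-coefficient warning.
#' @return The `cox.zph` table, invisibly.
#' @export
check_proportionality <- function(model, alpha = 0.05) {
  zph <- survival::cox.zph(model$fit)
  tab <- zph$table
  bad <- rownames(tab)[tab[, "p"] < alpha & rownames(tab) != "GLOBAL"]
  if (length(bad) > 0) {
    warning("proportional-hazards assumption questionable for: ",
            paste(bad, collapse = ", "))
  }
  invisible(tab)
}

#' Univariate and multivariate covariate-specific hazard ratios
#'
#' For every covariate in the adjustment set, fits an unweighted univariate
#' Cox model, and fits one unweighted multivariate Cox model on the
#' treatment plus all covariates, reporting HR, 95% CI and Wald P value for
#' each — the layout of the covariate HR tables, with the treatment in the
#' first row.
#'
#' @param X a [covariate_matrix()] of the adjustment covariates.
#' @param W,y,event treatment indicator and survival outcome.
#' @param intersection optional character vector marking the covariates
#'   selected as intersection terms.
#' @return Data frame with one row per covariate plus the treatment row.
#' @export
covariate_hr_table <- function(X, W, y, event, intersection = character()) {
  xm <- as.matrix(X)
  cols <- colnames(xm)
  uni <- vector("list", length(cols) + 1)
  m <- fit_cox(W, y, event)$table[1, ]
  uni[[1]] <- data.frame(covariate = "W", uni_hr = m$hr, uni_lo = m$ci_lo,
                         uni_hi = m$ci_hi, uni_p = m$p)
  for (j in seq_along(cols)) {
    fitj <- fit_cox(xm[, j], y, event)$table[1, ]
    uni[[j + 1]] <- data.frame(covariate = cols[j], uni_hr = fitj$hr,
                               uni_lo = fitj$ci_lo, uni_hi = fitj$ci_hi,
                               uni_p = fitj$p)
  }
  uni <- do.call(rbind, uni)
  multi <- fit_cox(W, y, event, X = xm)$table
  multi$covariate <- ifelse(multi$term == "W", "W", multi$term)
  out <- merge(uni, data.frame(covariate = multi$covariate,
                               multi_hr = multi$hr, multi_lo = multi$ci_lo,
                               multi_hi = multi$ci_hi, multi_p = multi$p),
               by = "covariate", sort = FALSE)
  out <- out[match(c("W", cols), out$covariate), ]
  out$intersection_term <- out$covariate %in% intersection
  rownames(out) <- NULL
  out
}
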