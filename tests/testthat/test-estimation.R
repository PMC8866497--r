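test_that("fit_cox matches brute-force partial-likelihood maximization on tie-free toys", {
  toys <- list(
    list(x = c(1, 0, 1, 0), y = c(2, 5, 7, 11), e = c(1, 1, 1, 1)),
    list(x = c(0, 0, 1, 1), y = c(3, 9, 4, 13), e = c(1, 0, 1, 1)),
    list(x = c(1, 0, 1, 0, 0, 1), y = c(1, 2, 4, 8, 16, 32),
         e = c(1, 1, 0, 1, 1, 1)))
  for (toy in toys) {
    fit <- fit_cox(toy$x, toy$y, toy$e)
    b_oracle <- oracle_cox_mle(toy$x, toy$y, toy$e)
    expect_equal(fit$table$coef[1], b_oracle, tolerance = 1e-6)
  }
  # HR = exp(coef); null coefficient gives HR 1
  expect_equal(exp(fit_cox(c(1, 0, 1, 0), c(2, 5, 7, 11),
                           c(1, 1, 1, 1))$table$coef[1]),
               fit_cox(c(1, 0, 1, 0), c(2, 5, 7, 11),
                       c(1, 1, 1, 1))$table$hr[1])
  expect_error(fit_cox(c(1, 0), c(3, 4), c(0, 0)), "event")
})

test_that("Wald p-values equal the closed-form normal tail probability", {
  set.seed(7)
  n <- 120
  W <- rbinom(n, 1, 0.5)
  y <- rexp(n, 0.01 * exp(0.5 * W))
  fit <- fit_cox(W, y, rep(1, n))
  z <- fit$table$coef / fit$table$se
  expect_equal(fit$table$p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  # and against the survival package's own robust summary
  sfit <- summary(survival::coxph(survival::Surv(y, rep(1, n)) ~ W,
                                  robust = TRUE, ties = "efron"))
  expect_equal(fit$table$p[1], sfit$coefficients["W", "Pr(>|z|)"],
               tolerance = 1e-10)
})

test_that("uniformly rescaled weights leave the estimate and robust SE unchanged", {
  set.seed(9)
  n <- 150
  W <- rbinom(n, 1, 0.4)
  y <- rexp(n, 0.01 * exp(0.3 * W))
  w <- runif(n, 0.5, 2)
  f1 <- fit_cox(W, y, rep(1, n), weights = w)
  f2 <- fit_cox(W, y, rep(1, n), weights = 2 * w)
  expect_equal(f1$table$coef, f2$table$coef, tolerance = 1e-8)
  expect_equal(f1$table$se, f2$table$se, tolerance = 1e-8)
  expect_error(fit_cox(W, y, rep(1, n), weights = -w), "non-negative")
})

test_that("stabilized weights follow the treated-1 / control-odds rule", {
  grid <- expand.grid(W = c(0, 1), e = c(0.1, 0.3, 0.5, 0.8, 0.95))
  w <- stabilized_weights(grid$e, grid$W)
  expect_equal(w, grid$W + (1 - grid$W) * grid$e / (1 - grid$e))
  expect_true(all(w[grid$W == 1] == 1))
  expect_equal(stabilized_weights(0.5, 0), 1)
  expect_equal(stabilized_weights(0.8, 0), 4)
  expect_error(stabilized_weights(c(0, 0.5), c(0, 0)), "strictly")
})

test_that("propensity estimation is calibrated, accurate and deterministic", {
  sim <- generate_cohort(sim_config(n_patients = 2000,
                                    confounder_terms = list(),
                                    structured_effects = list(),
                                    treatment_intercept = -0.5, seed = 12))
  xs <- scale_covariates(encode_structured(sim$cohort$patients, "prostate"))
  W <- sim$manifest$W
  fit <- estimate_propensity(xs, W, "logistic", seed = 1)
  # under the null, scores concentrate at the treated fraction
  se <- sd(fit$scores) / sqrt(length(W))
  expect_lt(abs(mean(fit$scores) - mean(W)), max(3 * se, 0.02))
  expect_identical(estimate_propensity(xs, W, "logistic", seed = 1)$scores,
                   fit$scores)
  expect_error(estimate_propensity(xs, W, "mystery"), "arg")
})

test_that("the logistic learner recovers a logistic truth to RMSE < 0.05", {
  cfg <- sim_config(n_patients = 5000, seed = 13,
                    confounder_terms = list(bladder = c(treat = 1, hazard = 1)))
  sim <- generate_cohort(cfg)
  # adjust on the true generative covariates: latent term + structured
  terms <- sim$manifest$terms
  x <- covariate_matrix(
    cbind("text:bladder" = terms[, "bladder"],
          "struct:age" = (sim$cohort$patients$age - 65) / 10,
          "struct:stage" = stage_to_int(sim$cohort$patients$clinical_stage) - 2),
    sim$manifest$patient_ids)
  fit <- estimate_propensity(x, sim$manifest$W, "logistic", seed = 2)
  rmse <- sqrt(mean((fit$scores - sim$manifest$true_propensity)^2))
  expect_lt(rmse, 0.05)
})

test_that("gradient boosting and random forest learners produce sane, seeded scores", {
  sim <- generate_cohort(confounded_config(n = 400, seed = 14))
  xs <- scale_covariates(encode_structured(sim$cohort$patients, "prostate"))
  W <- sim$manifest$W
  for (learner in c("gradient_boosting", "random_forest")) {
    f1 <- estimate_propensity(xs, W, learner, seed = 5)
    f2 <- estimate_propensity(xs, W, learner, seed = 5)
    expect_identical(f1$scores, f2$scores)
    expect_true(all(f1$scores >= 0.01 & f1$scores <= 0.99))
    expect_equal(nrow(f1$balance), ncol(xs$values))
  }
})

test_that("propensity model selection prefers balance, then the deterministic learner order", {
  mk <- function(learner, smds, clip = c(treated = 0, control = 0)) {
    structure(list(learner = learner,
                   balance = data.frame(covariate = seq_along(smds),
                                        smd_before = smds * 2,
                                        smd_after = smds),
                   overlap = list(clip_frac = clip)),
              class = "propensity_fit")
  }
  a <- mk("random_forest", c(0.02, 0.04))
  b <- mk("gradient_boosting", c(0.10, 0.12))
  expect_equal(select_propensity_model(list(b, a))$learner, "random_forest")
  expect_equal(select_propensity_model(list(a))$learner, "random_forest")
  # exact tie broken toward logistic
  tie1 <- mk("random_forest", c(0.05, 0.05))
  tie2 <- mk("logistic", c(0.05, 0.05))
  expect_equal(select_propensity_model(list(tie1, tie2))$learner, "logistic")
  # overlap failure discards a candidate; all failing is an error
  bad <- mk("logistic", c(0.001, 0.001), clip = c(treated = 0.2, control = 0))
  expect_equal(select_propensity_model(list(bad, a))$learner, "random_forest")
  expect_error(select_propensity_model(list(bad)), "overlap")
})

test_that("greedy matching matches the brute-force oracle and never reuses a control", {
  expect_equal(nnm_match(c(0.8, 0.7, 0.2), W = c(1, 0, 0))$pairs$control, 2)
  m32 <- nnm_match(c(0.9, 0.6, 0.3, 0.5, 0.45), W = c(1, 1, 1, 0, 0))
  expect_equal(nrow(m32$pairs), 2)  # without replacement: min(3, 2) pairs
  set.seed(15)
  for (rep in 1:25) {
    scores <- round(runif(8), 3)
    W <- sample(rep(c(1, 0), each = 4))
    got <- nnm_match(scores, W = W)
    want <- oracle_greedy_match(scores, W)
    expect_equal(as.matrix(got$pairs[, c("treated", "control")]),
                 want, ignore_attr = TRUE)
    expect_false(anyDuplicated(got$pairs$control) > 0)
  }
  # relabeling invariance: permuting patients permutes the pairing
  scores <- c(0.9, 0.2, 0.8, 0.3, 0.7, 0.4)
  W <- c(1, 0, 1, 0, 1, 0)
  perm <- c(6, 5, 4, 3, 2, 1)
  base <- nnm_match(scores, W = W)$pairs
  permd <- nnm_match(scores[perm], W = W[perm])$pairs
  expect_setequal(paste(perm[permd$treated], perm[permd$control]),
                  paste(base$treated, base$control))
})

test_that("estimator reductions: unit weights and degenerate scores recover the univariate Cox", {
  sim <- generate_cohort(sim_config(n_patients = 300, seed = 16,
                                    confounder_terms = list(),
                                    structured_effects = list()))
  W <- sim$manifest$W; y <- sim$manifest$Y; e <- sim$manifest$E
  ps <- structure(list(scores = rep(0.5, 300), W = W,
                       learner = "logistic"), class = "propensity_fit")
  unadj <- fit_cox(W, y, e)
  iptw <- hr_iptw(ps, y, e)
  expect_equal(iptw$hr, unadj$table$hr[1], tolerance = 1e-10)
  xs <- scale_covariates(encode_structured(sim$cohort$patients, "prostate"))
  multi0 <- hr_multicoxph(ps, y, e, X = xs, columns = character(0))
  expect_equal(multi0$hr, unadj$table$hr[1], tolerance = 1e-10)
  expect_error(hr_multicoxph(ps, y, e, X = xs, columns = "struct:missing"),
               "not present")
  # cloned arms: HR is 1 up to solver tolerance under matching
  y2 <- c(y, y); e2 <- c(e, e); W2 <- rep(c(1, 0), each = 300)
  ps2 <- structure(list(scores = rep(c(0.6, 0.6), each = 300), W = W2,
                        learner = "logistic"), class = "propensity_fit")
  match_est <- hr_matching(ps2, y2, e2)
  expect_equal(match_est$hr, 1, tolerance = 1e-6)
  expect_equal(match_est$n_used, 600)
})

test_that("matched-sample confidence intervals cover a null treatment effect", {
  # moderate confounding: greedy 1:1 matching without a caliper is known to
  # retain residual bias when a strong confounder thins the control reservoir,
  # so the calibration claim is made in the regime the estimator targets
  cover <- logical(200)
  for (s in seq_len(200)) {
    cfg <- sim_config(n_patients = 400,
                      confounder_terms = list(bladder = c(treat = 0.5,
                                                          hazard = 0.5)),
                      true_treatment_loghr = 0, seed = 7000 + s)
    sim <- generate_cohort(cfg)
    x <- covariate_matrix(
      cbind("text:bladder" = sim$manifest$terms[, "bladder"],
            "struct:age" = (sim$cohort$patients$age - 65) / 10,
            "struct:stage" = stage_to_int(sim$cohort$patients$clinical_stage) - 2),
      sim$manifest$patient_ids)
    ps <- estimate_propensity(scale_covariates(x), sim$manifest$W,
                              "logistic", seed = s)
    est <- hr_matching(ps, sim$manifest$Y, sim$manifest$E)
    cover[s] <- est$ci95[1] <= 1 && 1 <= est$ci95[2]
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("the proportionality diagnostic is quiet on proportional data", {
  sim <- generate_cohort(sim_config(n_patients = 500, seed = 33,
                                    confounder_terms = list(),
                                    structured_effects = list()))
  fit <- fit_cox(sim$manifest$W, sim$manifest$Y, sim$manifest$E)
  expect_no_warning(tab <- check_proportionality(fit))
  expect_true("W" %in% rownames(tab))
})

test_that("the covariate HR table mirrors the univariate/multivariate layout", {
  sim <- generate_cohort(confounded_config(n = 500, seed = 17))
  xs <- scale_covariates(encode_structured(sim$cohort$patients, "prostate"))
  W <- sim$manifest$W; y <- sim$manifest$Y; e <- sim$manifest$E
  tab <- covariate_hr_table(xs, W, y, e,
                            intersection = "struct:patient_age")
  expect_equal(nrow(tab), ncol(xs$values) + 1)
  expect_equal(tab$covariate[1], "W")
  expect_true(tab$intersection_term[tab$covariate == "struct:patient_age"])
  # univariate rows agree with directly fitted single-covariate models
  j <- which(xs$column_names == "struct:clinical_stage")
  single <- fit_cox(xs$values[, j], y, e)$table
  row <- tab[tab$covariate == "struct:clinical_stage", ]
  expect_equal(row$uni_hr, single$hr[1], tolerance = 1e-12)
  expect_equal(row$uni_p, single$p[1], tolerance = 1e-12)
})
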