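# Shared fixtures for the test suite. Everything is generated in code;
# small sizes keep individual tests fast while the acceptance suite uses
# the full study conditions.

# A compact confounded configuration: one planted term affecting both
# treatment (log-odds +1) and hazard (log-hazard +1).
confounded_config <- function(n = 1000, seed = 1, b_w = 0) {
  sim_config(n_patients = n,
             confounder_terms = list(bladder = c(treat = 1, hazard = 1)),
             true_treatment_loghr = b_w,
             seed = seed)
}

# All-noise configuration: no planted confounders, no treatment effect.
null_config <- function(n = 1000, seed = 1) {
  sim_config(n_patients = n, confounder_terms = list(),
             structured_effects = list(),
             true_treatment_loghr = 0, seed = seed)
}

# Small text config so small synthetic corpora do not warn about top_k.
small_text_config <- function(...) text_config(top_k = 20, ...)

# Independent two-pass TF-IDF oracle (count pass + weighting pass),
# written directly from the formula: idf = ln((1+N)/(1+df)) + 1, cell =
# tf * idf, then L2 row normalization. Used to cross-check build_tfidf.
oracle_tfidf <- function(term_docs) {
  vocab <- sort(unique(unlist(term_docs)))
  N <- length(term_docs)
  tf <- matrix(0, N, length(vocab), dimnames = list(names(term_docs), vocab))
  for (i in seq_len(N)) {
    for (t in term_docs[[i]]) tf[i, t] <- tf[i, t] + 1
  }
  df <- colSums(tf > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  x <- tf
  for (j in seq_along(vocab)) x[, j] <- tf[, j] * idf[j]
  for (i in seq_len(N)) {
    nrm <- sqrt(sum(x[i, ]^2))
    if (nrm > 0) x[i, ] <- x[i, ] / nrm
  }
  x
}

# Hand-written Cox partial log-likelihood for a single covariate with no
# ties (Breslow = Efron in that case); independent of the survival package.
oracle_cox_loglik <- function(b, x, y, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(y >= y[i])
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}

# Brute-force maximizer of the hand-written partial likelihood over a grid
# refined by golden-section search.
oracle_cox_mle <- function(x, y, event, lower = -5, upper = 5) {
  grid <- seq(lower, upper, length.out = 2001)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), x = x, y = y,
               event = event)
  b0 <- grid[which.max(ll)]
  stats::optimize(oracle_cox_loglik, c(b0 - 0.02, b0 + 0.02), x = x, y = y,
                  event = event, maximum = TRUE, tol = 1e-10)$maximum
}

# Independent greedy nearest-neighbour matcher working on an explicit
# distance matrix with masking; treated processed in descending score
# order, ties to the lower index.
oracle_greedy_match <- function(scores, W) {
  treated <- which(W == 1)
  control <- which(W == 0)
  treated <- treated[order(-scores[treated], treated)]
  used <- logical(length(scores))
  pairs <- NULL
  for (t in treated) {
    cand <- control[!used[control]]
    if (length(cand) == 0) break
    d <- abs(scores[cand] - scores[t])
    j <- cand[which.min(d)]
    used[j] <- TRUE
    pairs <- rbind(pairs, c(t, j))
  }
  pairs
}
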