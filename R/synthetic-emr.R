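#' Configuration for the synthetic EMR cohort generator
#'
#' Describes a generative model for an EMR-like two-arm cohort with known
#' ground truth. Treatment assignment follows a logistic model over
#' structured covariates and latent note terms; survival follows an
#' exponential (constant baseline) proportional-hazards model, so the
#' proportional-hazards assumption of the downstream estimators holds by
#' construction. Censoring is independent exponential with its rate solved
#' numerically to hit `censoring_rate`.
#'
#' @param n_patients number of patients to simulate.
#' @param vocab character vector of latent clinical terms a patient may carry.
#' @param confounder_terms named list, one entry per planted confounder term
#'   (must be in `vocab`), each a numeric vector `c(treat =, hazard =)`
#'   giving the term's treatment log-odds and log-hazard effects.
#' @param structured_effects named list with optional entries `age`, `stage`,
#'   `grade`, each `c(treat =, hazard =)`; effects apply to the standardized
#'   covariate (age centred at 65 per 10 years, stage/grade centred at 2).
#' @param treatment_intercept intercept of the treatment logit.
#' @param baseline_hazard_rate baseline event rate, events per day.
#' @param true_treatment_loghr ground-truth treatment log hazard ratio.
#' @param censoring_rate target fraction of patients censored before the
#'   event, in `[0, 1]`.
#' @param term_prevalence marginal probability that a vocabulary term is
#'   active for a patient (scalar or per-term vector).
#' @param noise_term_rate mean number of irrelevant filler terms per note.
#' @param noise_vocab filler terms used for noise mentions; not part of the
#'   latent term model.
#' @param negated_mention_rate probability that a note carries a short
#'   negated mention of an inactive term (e.g. "No history of smoking.").
#' @param notes_per_patient number of notes rendered per patient.
#' @param treatment_start_range integer range (days since diagnosis) from
#'   which the treatment start day is drawn uniformly; note dates are drawn
#'   uniformly in the pre-treatment window `[0, start]`.
#' @param seed integer seed; a fixed seed reproduces the cohort byte for
#'   byte.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       vocab = c("bladder", "urothelial", "carcinoma",
                                 "obstruction", "smoking", "copd",
                                 "diabetes", "hypertension", "anemia",
                                 "fatigue", "carotid", "lesion"),
                       confounder_terms = list(bladder = c(treat = 1, hazard = 1)),
                       structured_effects = list(age = c(treat = 0.5, hazard = 0.4),
                                                 stage = c(treat = 0.3, hazard = 0.3)),
                       treatment_intercept = -1,
                       baseline_hazard_rate = 1e-4,
                       true_treatment_loghr = 0,
                       censoring_rate = 0.3,
                       term_prevalence = 0.4,
                       noise_term_rate = 2,
                       noise_vocab = c("ambulatory", "stable", "review",
                                       "benign", "routine", "hydration",
                                       "appetite", "mobility"),
                       negated_mention_rate = 0.3,
                       notes_per_patient = 3,
                       treatment_start_range = c(120, 240),
                       seed = 1) {
  cfg <- structure(list(n_patients = n_patients, vocab = vocab,
                        confounder_terms = confounder_terms,
                        structured_effects = structured_effects,
                        treatment_intercept = treatment_intercept,
                        baseline_hazard_rate = baseline_hazard_rate,
                        true_treatment_loghr = true_treatment_loghr,
                        censoring_rate = censoring_rate,
                        term_prevalence = term_prevalence,
                        noise_term_rate = noise_term_rate,
                        noise_vocab = noise_vocab,
                        negated_mention_rate = negated_mention_rate,
                        notes_per_patient = notes_per_patient,
                        treatment_start_range = treatment_start_range,
                        seed = seed),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(is.numeric(cfg$n_patients) && cfg$n_patients >= 1,
              "n_patients must be >= 1")
  assert_that(all(names(cfg$confounder_terms) %in% cfg$vocab),
              "confounder_terms must be a subset of vocab")
  assert_that(is.numeric(cfg$censoring_rate) &&
                cfg$censoring_rate >= 0 && cfg$censoring_rate <= 1,
              "censoring_rate must be in [0, 1]")
  assert_that(is.numeric(cfg$baseline_hazard_rate) && cfg$baseline_hazard_rate > 0,
              "baseline_hazard_rate must be > 0")
  assert_that(is.numeric(cfg$negated_mention_rate) &&
                cfg$negated_mention_rate >= 0 && cfg$negated_mention_rate <= 1,
              "negated_mention_rate must be in [0, 1]")
  assert_that(all(cfg$term_prevalence > 0 & cfg$term_prevalence < 1),
              "term_prevalence must be in (0, 1)")
  assert_that(cfg$notes_per_patient >= 1, "notes_per_patient must be >= 1")
  invisible(cfg)
}

affirm_templates <- c(
  "Patient has a documented history of %s.",
  "Assessment today is notable for %s.",
  "Findings remain consistent with %s on physical exam.",
  "Ongoing %s was discussed with the patient in clinic today."
)
negated_templates <- c("No history of %s.", "Patient denies %s.")
boilerplate_header <- c("Example Medical Center, Palo Alto.",
                        "Attending physician: John Smith, M.D.")
boilerplate_footer <- c("Return visit scheduled at Example Medical Center.",
                        "Dictated by Jane Doe, M.D.")

#' Render one synthetic clinical note
#'
#' Produces a sentence-templated note containing an affirmative sentence for
#' every active term, optional filler-term sentences, with probability
#' `negated_mention_rate` a short negated mention of an inactive term, and
#' boilerplate header/footer sentences (clinic name, physician name) so that
#' boilerplate stripping downstream has work to do. Consumes the current RNG
#' stream; call inside a seeded context for reproducibility.
#'
#' @param active_terms character vector of the patient's active terms.
#' @param inactive_terms character vector of inactive vocabulary terms
#'   eligible for a negated mention.
#' @param config a [sim_config()].
#' @return A single string, sentences separated by spaces.
#' @export
render_note <- function(active_terms, inactive_terms = character(),
                        config = sim_config()) {
  body <- character(0)
  for (term in active_terms) {
    tpl <- affirm_templates[sample.int(length(affirm_templates), 1)]
    body <- c(body, sprintf(tpl, term))
  }
  n_noise <- rpois(1, config$noise_term_rate)
  if (n_noise > 0 && length(config$noise_vocab) > 0) {
    filler <- sample(config$noise_vocab, n_noise, replace = TRUE)
    body <- c(body, sprintf("Patient reports %s at this visit.", filler))
  }
  if (length(inactive_terms) > 0 && config$negated_mention_rate > 0 &&
      runif(1) < config$negated_mention_rate) {
    term <- inactive_terms[sample.int(length(inactive_terms), 1)]
    tpl <- negated_templates[sample.int(length(negated_templates), 1)]
    body <- c(body, sprintf(tpl, term))
  }
  if (length(body) == 0) body <- "Routine follow up visit today."
  paste(c(boilerplate_header, body, boilerplate_footer), collapse = " ")
}

# Solve the exponential censoring rate so that P(C < T) averaged over the
# cohort's patient-specific hazards equals the target censoring rate.
solve_censoring_rate <- function(hazards, target) {
  if (target <= 0) return(0)
  f <- function(rc) mean(rc / (rc + hazards)) - target
  upper <- max(hazards) * 1e6
  uniroot(f, lower = 1e-12, upper = upper, tol = 1e-12)$root
}

#' Generate a synthetic EMR cohort with known ground truth
#'
#' Draws structured covariates, latent note-term indicators, treatment via a
#' logistic model, and survival from an exponential proportional-hazards
#' model, then renders per-patient clinical notes. Returns the cohort
#' together with a ground-truth manifest (latent indicators, true propensity
#' scores, true treatment log hazard ratio) used as the oracle in
#' parameter-recovery checks.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cohort` (class `emr_cohort`: `$patients`
#'   data frame and `$notes` data frame) and `manifest` (class
#'   `ground_truth_manifest`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- as.integer(config$n_patients)
    pid <- sprintf("P%05d", seq_len(n))
    age <- pmin(90, pmax(40, round(rnorm(n, 67, 8))))
    gender <- sample(c("male", "female"), n, replace = TRUE)
    race <- sample(c("white", "api", "black", "unknown"), n, replace = TRUE,
                   prob = c(0.62, 0.12, 0.03, 0.23))
    ethnicity <- sample(c("hispanic", "non-hispanic", "unknown"), n,
                        replace = TRUE, prob = c(0.06, 0.88, 0.06))
    clinical_stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                             prob = c(0.30, 0.50, 0.15, 0.05))
    upstage <- rbinom(n, 1, 0.3)
    path_int <- pmin(4L, stage_to_int(clinical_stage) + upstage)
    pathological_stage <- c("I", "II", "III", "IV")[path_int]
    pathological_stage[rbinom(n, 1, 0.2) == 1] <- NA
    tumor_grade <- sample(1:4, n, replace = TRUE, prob = c(0.3, 0.4, 0.25, 0.05))
    tumor_grade[rbinom(n, 1, 0.05) == 1] <- NA
    diagnosis_year <- sample(2008:2017, n, replace = TRUE)

    vocab <- config$vocab
    prev <- rep_len(config$term_prevalence, length(vocab))
    terms <- matrix(rbinom(n * length(vocab), 1, rep(prev, each = n)),
                    nrow = n, dimnames = list(pid, vocab))

    age_z <- (age - 65) / 10
    stage_z <- stage_to_int(clinical_stage) - 2
    grade_z <- ifelse(is.na(tumor_grade), 0, tumor_grade - 2)
    struct_z <- list(age = age_z, stage = stage_z, grade = grade_z)

    lp_t <- rep(config$treatment_intercept, n)
    lp_y <- rep(0, n)
    for (nm in names(config$structured_effects)) {
      eff <- config$structured_effects[[nm]]
      lp_t <- lp_t + eff[["treat"]] * struct_z[[nm]]
      lp_y <- lp_y + eff[["hazard"]] * struct_z[[nm]]
    }
    for (nm in names(config$confounder_terms)) {
      eff <- config$confounder_terms[[nm]]
      lp_t <- lp_t + eff[["treat"]] * terms[, nm]
      lp_y <- lp_y + eff[["hazard"]] * terms[, nm]
    }
    e_true <- plogis(lp_t)
    W <- rbinom(n, 1, e_true)
    hazard <- config$baseline_hazard_rate *
      exp(lp_y + config$true_treatment_loghr * W)
    t_event <- rexp(n, hazard)
    if (config$censoring_rate > 0) {
      rc <- solve_censoring_rate(hazard, config$censoring_rate)
      t_cens <- rexp(n, rc)
    } else {
      t_cens <- rep(Inf, n)
    }
    survival_days <- pmax(1, ceiling(pmin(t_event, t_cens)))
    event <- as.integer(t_event <= t_cens)

    treatment <- ifelse(W == 1, "surgery", "radiation")
    treatment_start_day <- sample(config$treatment_start_range[1]:config$treatment_start_range[2],
                                  n, replace = TRUE)

    notes <- vector("list", n)
    for (i in seq_len(n)) {
      k <- config$notes_per_patient
      dates <- sort(sample.int(treatment_start_day[i] + 1L, k, replace = TRUE) - 1L)
      active <- vocab[terms[i, ] == 1]
      inactive <- vocab[terms[i, ] == 0]
      txt <- vapply(seq_len(k), function(j) render_note(active, inactive, config),
                    character(1))
      notes[[i]] <- data.frame(patient_id = pid[i], date = dates, text = txt,
                               stringsAsFactors = FALSE)
    }
    notes <- do.call(rbind, notes)
    rownames(notes) <- NULL

    patients <- data.frame(
      patient_id = pid, age = age, gender = gender, race = race,
      ethnicity = ethnicity, clinical_stage = clinical_stage,
      pathological_stage = pathological_stage, tumor_grade = tumor_grade,
      diagnosis_year = diagnosis_year, treatment = treatment,
      treatment_start_day = treatment_start_day,
      survival_days = survival_days, event = event,
      stringsAsFactors = FALSE)

    cohort <- structure(list(patients = patients, notes = notes),
                        class = "emr_cohort")
    manifest <- structure(list(
      patient_ids = pid, terms = terms, W = W, Y = survival_days,
      E = event, true_propensity = e_true,
      true_treatment_loghr = config$true_treatment_loghr,
      confounders = names(config$confounder_terms),
      hazard = hazard, config = config),
      class = "ground_truth_manifest")
    list(cohort = cohort, manifest = manifest)
  })
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat(sprintf("<emr_cohort> %d patients, %d notes, %d events\n",
              nrow(x$patients), nrow(x$notes), sum(x$patients$event)))
  invisible(x)
}

#' Ground-truth marginal hazard ratio under a chosen adjustment set
#'
#' Fits a Cox model for the treatment on the *latent* term indicators in
#' `adjustment_set` (not the text-derived covariates), giving the best
#' achievable adjusted estimate for bias-reduction comparisons.
#'
#' @param manifest a `ground_truth_manifest` from [generate_cohort()].
#' @param adjustment_set character vector of vocabulary terms to adjust for
#'   (possibly empty for the unadjusted estimate).
#' @return The hazard ratio for the treatment (a single number).
#' @export
oracle_marginal_hr <- function(manifest, adjustment_set = character()) {
  assert_that(inherits(manifest, "ground_truth_manifest"),
              "manifest must come from generate_cohort")
  assert_that(length(manifest$W) > 0, "empty cohort")
  missing <- setdiff(adjustment_set, colnames(manifest$terms))
  assert_that(length(missing) == 0,
              paste("unknown terms in adjustment_set:", paste(missing, collapse = ", ")))
  df <- data.frame(W = manifest$W)
  if (length(adjustment_set) > 0) {
    df <- cbind(df, as.data.frame(manifest$terms[, adjustment_set, drop = FALSE]))
  }
  fit <- survival::coxph(survival::Surv(manifest$Y, manifest$E) ~ .,
                         data = df, ties = "efron")
  unname(exp(coef(fit)["W"]))
}

#' Write a cohort (and optional manifest) to disk as plain text
#'
#' Writes the patient table as TSV, one UTF-8 text file per note plus a
#' note manifest TSV (`patient_id`, `date`, `path`), and the ground-truth
#' manifest as JSON.
#'
#' @param cohort an `emr_cohort`.
#' @param dir output directory (created if needed).
#' @param manifest optional `ground_truth_manifest`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, manifest = NULL) {
  dir.create(file.path(dir, "notes"), recursive = TRUE, showWarnings = FALSE)
  write.table(cohort$patients, file.path(dir, "patients.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- sprintf("notes/%s_%03d.txt", cohort$notes$patient_id,
                   stats::ave(seq_len(nrow(cohort$notes)), cohort$notes$patient_id,
                              FUN = seq_along))
  for (i in seq_len(nrow(cohort$notes))) {
    writeLines(cohort$notes$text[i], file.path(dir, paths[i]), useBytes = TRUE)
  }
  write.table(data.frame(patient_id = cohort$notes$patient_id,
                         date = cohort$notes$date, path = paths),
              file.path(dir, "notes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(manifest)) {
    m <- list(patient_ids = manifest$patient_ids,
              terms = as.data.frame(manifest$terms),
              W = manifest$W, Y = manifest$Y, E = manifest$E,
              true_propensity = manifest$true_propensity,
              true_treatment_loghr = manifest$true_treatment_loghr,
              confounders = manifest$confounders)
    jsonlite::write_json(m, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `patients.tsv`, `notes.tsv` and note files.
#' @return An `emr_cohort`.
#' @export
read_cohort <- function(dir) {
  patients <- read.delim(file.path(dir, "patients.tsv"),
                         stringsAsFactors = FALSE)
  nm <- read.delim(file.path(dir, "notes.tsv"), stringsAsFactors = FALSE)
  text <- vapply(nm$path, function(p) {
    paste(readLines(file.path(dir, p), warn = FALSE), collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
  notes <- data.frame(patient_id = nm$patient_id, date = nm$date,
                      text = text, stringsAsFactors = FALSE)
  structure(list(patients = patients, notes = notes), class = "emr_cohort")
}
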