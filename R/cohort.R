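#' Convert a clinical stage label to an ordinal integer
#'
#' Accepts roman numerals (optionally with substage suffixes, e.g. "IIA"),
#' arabic numerals, or "Stage X" labels; returns 1-4 (NA passes through).
#' @param stage character or numeric vector of stage labels.
#' @return Integer vector.
#' @export
stage_to_int <- function(stage) {
  if (is.numeric(stage)) return(as.integer(stage))
  s <- toupper(trimws(sub("(?i)^stage\\s*", "", stage, perl = TRUE)))
  out <- rep(NA_integer_, length(s))
  out[grepl("^IV", s)] <- 4L
  out[grepl("^III", s)] <- 3L
  out[grepl("^II($|[AB])", s)] <- 2L
  out[grepl("^I($|[AB])", s)] <- 1L
  out[grepl("^[1-4]$", s)] <- as.integer(s[grepl("^[1-4]$", s)])
  out
}

#' Assign a patient to a treatment group
#'
#' Patients with only surgery records go to the surgery group, only
#' radiation to the radiation group; with both, the group of the earlier
#' start day wins. Patients with no recorded treatment are assigned to
#' active monitoring for prostate cancer and excluded (NA) for NSCLC.
#' A tie in start days is an error: no deterministic rule exists for it.
#'
#' @param modalities character vector of treatment modalities
#'   (`"surgery"`/`"radiation"`), possibly empty.
#' @param start_days numeric vector of start days aligned with `modalities`.
#' @param disease `"prostate"` or `"nsclc"`.
#' @param patient_id optional id used in error messages.
#' @return One of `"surgery"`, `"radiation"`, `"monitoring"`, or `NA`
#'   (excluded).
#' @export
assign_treatment_group <- function(modalities, start_days,
                                   disease = c("prostate", "nsclc"),
                                   patient_id = "?") {
  disease <- match.arg(disease)
  assert_that(length(modalities) == length(start_days),
              "modalities and start_days must align")
  assert_that(all(start_days >= 0), "treatment start_day must be >= 0")
  mods <- unique(modalities)
  if (length(modalities) == 0) {
    return(if (disease == "prostate") "monitoring" else NA_character_)
  }
  if (identical(mods, "surgery")) return("surgery")
  if (identical(mods, "radiation")) return("radiation")
  s_first <- min(start_days[modalities == "surgery"])
  r_first <- min(start_days[modalities == "radiation"])
  if (s_first == r_first) {
    stop(sprintf("patient %s: surgery and radiation start on the same day; no tie rule",
                 patient_id), call. = FALSE)
  }
  if (s_first < r_first) "surgery" else "radiation"
}

#' Apply the cohort inclusion filters
#'
#' Keeps patients who survived at least `min_survival_days` past diagnosis
#' (the landmark filter against immortal-time bias; boundary inclusive) and,
#' optionally, who retain at least one note in the pre-treatment window.
#' Order is preserved; the filter is monotone (adding a patient never
#' removes another).
#'
#' @param cohort an `emr_cohort`.
#' @param min_survival_days landmark threshold in days (183 = 6 months).
#' @param require_note drop patients without a retained pre-treatment note.
#' @param window_days pre-treatment note exclusion window in days.
#' @return The filtered `emr_cohort`.
#' @export
filter_cohort <- function(cohort, min_survival_days = 183,
                          require_note = TRUE, window_days = 60) {
  assert_that(min_survival_days > 0, "min_survival_days must be > 0")
  p <- cohort$patients
  keep <- p$survival_days >= min_survival_days
  if (require_note) {
    note_split <- split(cohort$notes, cohort$notes$patient_id)
    has_note <- vapply(seq_len(nrow(p)), function(i) {
      nd <- note_split[[p$patient_id[i]]]
      if (is.null(nd) || nrow(nd) == 0) return(FALSE)
      start <- p$treatment_start_day[i]
      if (is.na(start)) return(TRUE)
      nrow(window_notes(nd, start, window_days)) > 0
    }, logical(1))
    keep <- keep & has_note
  }
  p <- p[keep, , drop = FALSE]
  notes <- cohort$notes[cohort$notes$patient_id %in% p$patient_id, , drop = FALSE]
  structure(list(patients = p, notes = notes), class = "emr_cohort")
}

age_bucket_labels <- c("<=49", paste(seq(50, 80, 5), seq(54, 84, 5), sep = "-"),
                       ">=85")

#' Bucket an age into the analysis age categories
#'
#' Categories: 49 and younger, 5-year buckets from 50 to 84, and 85 and
#' older. The bucket index (1-9) is used as a single ordinal covariate.
#'
#' @param age age in years (vectorized).
#' @return Character vector of bucket labels; see [age_bucket_index()] for
#'   the ordinal encoding.
#' @export
bucket_age <- function(age) {
  assert_that(all(age >= 0), "age must be non-negative")
  age_bucket_labels[age_bucket_index(age)]
}

#' @rdname bucket_age
#' @export
age_bucket_index <- function(age) {
  assert_that(all(age >= 0), "age must be non-negative")
  idx <- ifelse(age <= 49, 1L,
                ifelse(age >= 85, 9L, 2L + (pmin(age, 84) - 50) %/% 5))
  as.integer(idx)
}

#' Build the structured covariate block
#'
#' Encodes the structured record into the `struct:` covariate block:
#' bucketed ordinal age, one-hot race (white/api/black; unknown race is all
#' zeros and carries no column), a Hispanic indicator and diagnosis year,
#' plus, for prostate, ordinal clinical stage and ordinal tumor grade with
#' a grade-unknown indicator (unknown grade imputed with the median
#' observed grade), or, for NSCLC (a stage-I-only cohort), a male
#' indicator. Yields 9 columns for prostate and 7 for NSCLC.
#'
#' @param patients patient data frame (see [generate_cohort()] for schema).
#' @param disease `"prostate"` or `"nsclc"`.
#' @return A [covariate_matrix()] of `struct:` columns.
#' @export
encode_structured <- function(patients, disease = c("prostate", "nsclc")) {
  disease <- match.arg(disease)
  assert_that(nrow(patients) > 0, "records must be non-empty")
  p <- patients
  race <- tolower(p$race)
  cols <- list(
    "struct:patient_age" = age_bucket_index(p$age),
    "struct:race_white" = as.numeric(race == "white"),
    "struct:race_api" = as.numeric(race %in% c("api", "asian", "pacific")),
    "struct:race_black" = as.numeric(race == "black"),
    "struct:hispanic" = as.numeric(tolower(p$ethnicity) == "hispanic"),
    "struct:diagnosis_year" = as.numeric(p$diagnosis_year))
  if (disease == "prostate") {
    # clinical stage varies for prostate; the NSCLC cohort is stage I only
    cols[["struct:clinical_stage"]] <- as.numeric(stage_to_int(p$clinical_stage))
    grade <- as.numeric(p$tumor_grade)
    assert_that(any(!is.na(grade)), "all tumor grades missing; median undefined")
    med <- median(grade, na.rm = TRUE)
    unknown <- as.numeric(is.na(grade))
    grade[is.na(grade)] <- med
    cols[["struct:tumor_grade"]] <- grade
    cols[["struct:grade_unknown"]] <- unknown
  } else {
    cols[["struct:male"]] <- as.numeric(tolower(p$gender) == "male")
  }
  m <- do.call(cbind, cols)
  assert_that(all(is.finite(m)),
              "structured covariates contain missing values; impute stages first")
  covariate_matrix(m, p$patient_id, names(cols))
}

#' Impute missing clinical stage from pathological stage
#'
#' Trains a seeded random-forest classifier on patients with both stages
#' observed, using age bucket, pathological stage, diagnosis year and tumor
#' grade, and predicts the clinical stage of patients missing it but having
#' a pathological stage. Patients missing both stages are left missing and
#' flagged in the returned attribute `"stage_unresolved"`.
#'
#' @param patients patient data frame.
#' @param seed integer seed for the forest.
#' @param ntree number of trees.
#' @return The patient data frame with `clinical_stage` filled in where
#'   possible.
#' @export
impute_clinical_stage <- function(patients, seed = 1, ntree = 200) {
  p <- patients
  cs <- stage_to_int(p$clinical_stage)
  ps <- stage_to_int(p$pathological_stage)
  grade <- as.numeric(p$tumor_grade)
  grade[is.na(grade)] <- median(grade, na.rm = TRUE)
  feats <- data.frame(age = age_bucket_index(p$age),
                      path_stage = ps,
                      year = as.numeric(p$diagnosis_year),
                      grade = grade)
  train <- !is.na(cs) & !is.na(ps)
  target <- is.na(cs) & !is.na(ps)
  assert_that(any(train), "no patients with both stages observed; cannot train")
  if (any(target)) {
    observed_classes <- unique(cs[train])
    if (length(observed_classes) == 1) {
      cs[target] <- observed_classes
    } else {
      fit <- with_seed(seed, randomForest::randomForest(
        x = feats[train, , drop = FALSE],
        y = factor(cs[train], levels = 1:4), ntree = ntree))
      pred <- predict(fit, feats[target, , drop = FALSE])
      cs[target] <- as.integer(as.character(pred))
    }
    p$clinical_stage <- c("I", "II", "III", "IV")[cs]
  }
  attr(p, "stage_unresolved") <- p$patient_id[is.na(cs)]
  p
}

#' Standardize covariate columns
#'
#' Z-scores every column (mean 0, sample SD 1). Constant columns cannot be
#' scaled; they are set to zero with a warning.
#'
#' @param x a [covariate_matrix()] with at least 2 rows.
#' @return The standardized `covariate_matrix`.
#' @export
scale_covariates <- function(x) {
  m <- x$values
  assert_that(nrow(m) >= 2, "need at least 2 rows to scale")
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning(sprintf("constant columns set to 0: %s",
                    paste(x$column_names[const], collapse = ", ")))
    sdv[const] <- 1
  }
  z <- sweep(sweep(m, 2, mu, `-`), 2, sdv, `/`)
  z[, const] <- 0
  covariate_matrix(z, x$patient_ids, x$column_names)
}

#' Build treatment indicators for a two-group comparison
#'
#' Assigns each patient a group via [assign_treatment_group()] and returns,
#' for patients inside the comparison, `W = 1` for the first-named group.
#'
#' @param cohort an `emr_cohort`.
#' @param comparison character vector of two group names; the first is the
#'   treatment of interest (`W = 1`).
#' @param disease `"prostate"` or `"nsclc"`.
#' @return Data frame `patient_id`, `group`, `W`, restricted to the two
#'   groups.
#' @export
make_assignments <- function(cohort, comparison = c("surgery", "radiation"),
                             disease = "prostate") {
  p <- cohort$patients
  group <- vapply(seq_len(nrow(p)), function(i) {
    if (!is.null(p$treatment) && !is.na(p$treatment[i]) &&
        nzchar(p$treatment[i]) && p$treatment[i] != "none") {
      assign_treatment_group(p$treatment[i], p$treatment_start_day[i],
                             disease, p$patient_id[i])
    } else {
      assign_treatment_group(character(0), numeric(0), disease,
                             p$patient_id[i])
    }
  }, character(1))
  keep <- !is.na(group) & group %in% comparison
  data.frame(patient_id = p$patient_id[keep], group = group[keep],
             W = as.integer(group[keep] == comparison[1]),
             stringsAsFactors = FALSE)
}
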