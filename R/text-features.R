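#' Configuration for the clinical-text featurization pipeline
#'
#' Bundles the knobs of the note-to-covariate pipeline: negation filtering,
#' boilerplate stripping, dictionary-based entity extraction with
#' lemmatization and synonym folding, and bag-of-words TF-IDF weighting.
#'
#' @param negation_terms negation tokens/phrases; a sentence shorter than
#'   `negation_word_cap` words containing one of these is dropped.
#' @param negation_word_cap word-count threshold for the negation rule.
#' @param boilerplate_trim number of sentences trimmed from each end of a
#'   document.
#' @param boilerplate_patterns regexes (case-insensitive) for location /
#'   physician-name boilerplate sentences to drop.
#' @param entity_dictionary character vector of normalized terms retained as
#'   biomedical entities; defaults to the dictionary shipped with the
#'   package (see `system.file("extdata", "entity_dictionary.txt")`).
#' @param synonym_map named character vector mapping lexical variants and
#'   abbreviations to canonical terms (e.g. `c(hx = "history")`).
#' @param stopwords stopword tokens removed before dictionary lookup.
#' @param ngram_max 1 for unigrams only, 2 to add bigrams.
#' @param top_k number of most frequent features retained.
#' @param max_document_frequency features occurring in at least this
#'   fraction of documents are excluded (e.g. 0.7 keeps features with
#'   document frequency strictly below 0.7); 1 disables the cut.
#' @return An object of class `text_config`.
#' @export
text_config <- function(negation_terms = c("no", "denies", "does not", "none"),
                        negation_word_cap = 15,
                        boilerplate_trim = 2,
                        boilerplate_patterns = c("medical center", "palo alto",
                                                 "m\\.d\\."),
                        entity_dictionary = default_entity_dictionary(),
                        synonym_map = default_synonym_map(),
                        stopwords = default_stopwords(),
                        ngram_max = 1,
                        top_k = 500,
                        max_document_frequency = 1) {
  assert_that(top_k >= 1, "top_k must be >= 1")
  assert_that(ngram_max %in% c(1, 2), "ngram_max must be 1 or 2")
  assert_that(max_document_frequency > 0 && max_document_frequency <= 1,
              "max_document_frequency must be in (0, 1]")
  assert_that(boilerplate_trim >= 0, "boilerplate_trim must be >= 0")
  structure(list(negation_terms = tolower(negation_terms),
                 negation_word_cap = negation_word_cap,
                 boilerplate_trim = boilerplate_trim,
                 boilerplate_patterns = boilerplate_patterns,
                 entity_dictionary = entity_dictionary,
                 synonym_map = synonym_map,
                 stopwords = stopwords,
                 ngram_max = ngram_max,
                 top_k = top_k,
                 max_document_frequency = max_document_frequency),
            class = "text_config")
}

#' Default entity dictionary shipped with the package
#'
#' A user-replaceable list of normalized clinical terms; only tokens present
#' here survive [extract_terms()].
#' @return Character vector of terms.
#' @export
default_entity_dictionary <- function() {
  path <- system.file("extdata", "entity_dictionary.txt",
                      package = "textconfound")
  if (nzchar(path)) readLines(path, warn = FALSE) else character(0)
}

#' Default synonym map (lexical variants, abbreviations, common synonyms)
#' @return Named character vector mapping variant to canonical term.
#' @export
default_synonym_map <- function() {
  c(hx = "history", fu = "followup", abnormality = "abnormal",
    consult = "consultation", assistance = "service", action = "movement")
}

#' Default stopword list
#'
#' English function words plus data-specific stopwords: medical units,
#' time terms, and clinic-generic words that are common but uninformative.
#' @return Character vector of stopword tokens.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "of", "in", "on", "at", "to",
    "for", "with", "by", "from", "as", "is", "are", "was", "were", "be",
    "been", "being", "has", "have", "had", "this", "that", "these",
    "those", "it", "its", "he", "she", "his", "her", "they", "their",
    "we", "our", "you", "your", "i", "me", "my", "up", "out", "about",
    "into", "over", "after", "before", "today", "not",
    # units
    "lb", "lbs", "oz", "kg", "mg", "ml", "mmhg", "cm", "mm",
    # time terms
    "day", "days", "week", "weeks", "month", "months", "year", "years",
    # clinic-generic
    "patient", "doctor", "clinic", "visit", "exam", "physical",
    "assessment", "findings", "documented", "ongoing", "discussed",
    "reports", "remain", "consistent", "notable")
}

#' Segment a note into sentences
#'
#' Splits on clinical field labels (an ALL-CAPS token run followed by a
#' colon, e.g. `"IMPRESSION:"`), tab runs and newlines, then on sentence
#' punctuation. Field labels are removed from the output.
#'
#' @param text a note document (single string).
#' @return Character vector of trimmed, non-empty sentences.
#' @export
segment_sentences <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(character(0))
  # field labels become segment boundaries and are dropped
  text <- gsub("(^|[\\t\\n ])[A-Z][A-Z]+(?: [A-Z][A-Z]+)*:", "\n", text,
               perl = TRUE)
  chunks <- unlist(strsplit(text, "[\t\n]+"))
  sentences <- unlist(lapply(chunks, function(ch) {
    strsplit(ch, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  }))
  sentences <- trimws(sentences)
  sentences[nzchar(sentences)]
}

#' Trim document-edge and pattern-matched boilerplate sentences
#'
#' Removes `boilerplate_trim` sentences from each end of the document, then
#' any remaining sentence matching a configured location or physician-name
#' pattern. Trimming may exhaust short documents.
#'
#' @param sentences character vector from [segment_sentences()].
#' @param config a [text_config()].
#' @return Character vector of retained sentences.
#' @export
strip_boilerplate <- function(sentences, config = text_config()) {
  k <- config$boilerplate_trim
  n <- length(sentences)
  if (n <= 2 * k) return(character(0))
  if (k > 0) sentences <- sentences[(k + 1):(n - k)]
  if (length(config$boilerplate_patterns) > 0) {
    hit <- Reduce(`|`, lapply(config$boilerplate_patterns, function(p) {
      grepl(p, sentences, ignore.case = TRUE, perl = TRUE)
    }))
    sentences <- sentences[!hit]
  }
  sentences
}

note_tokens <- function(sentence) {
  s <- tolower(sentence)
  s <- gsub("[^a-z0-9 ]", " ", s)
  tok <- strsplit(trimws(s), "\\s+")[[1]]
  tok[nzchar(tok)]
}

# Vectorized tokenizer: one token list per sentence.
note_tokens_list <- function(sentences) {
  s <- gsub("[^a-z0-9 ]", " ", tolower(sentences))
  lapply(strsplit(trimws(s), "\\s+"), function(tok) tok[nzchar(tok)])
}

#' Drop short negated sentences
#'
#' A sentence is dropped iff it has fewer than `negation_word_cap` words
#' (whitespace tokens after punctuation stripping) and contains at least one
#' negation term as a case-insensitive token or phrase match. This keeps
#' long sentences where a negation is likely incidental while removing
#' statements such as "No history of smoking.".
#'
#' @param sentences character vector of sentences.
#' @param config a [text_config()].
#' @return The retained sentences, order preserved. Idempotent.
#' @export
filter_negated <- function(sentences, config = text_config()) {
  if (length(sentences) == 0) return(sentences)
  toks <- note_tokens_list(sentences)
  short <- lengths(toks) < config$negation_word_cap
  joined <- vapply(toks, paste, character(1), collapse = " ")
  neg <- rep(FALSE, length(sentences))
  for (term in config$negation_terms) {
    neg <- neg | grepl(paste0("(^| )", term, "( |$)"), joined)
  }
  sentences[!(short & neg)]
}

lemma_exceptions <- c(men = "man", women = "woman", teeth = "tooth",
                      feet = "foot", biopsies = "biopsy", mice = "mouse")

# Suffix-rule + exception-lookup lemmatizer. `known` is the set of
# acceptable lemmas (dictionary plus synonym keys); suffix stripping is only
# applied when the stripped form is known, so ordinary words pass through.
lemmatize_token <- function(token, known) {
  if (token %in% names(lemma_exceptions)) return(unname(lemma_exceptions[[token]]))
  if (token %in% known) return(token)
  cands <- character(0)
  if (grepl("ies$", token)) cands <- c(cands, sub("ies$", "y", token))
  if (grepl("(s|x|z|ch|sh)es$", token)) cands <- c(cands, sub("es$", "", token))
  if (grepl("[a-z]s$", token) && !grepl("ss$", token)) {
    cands <- c(cands, sub("s$", "", token))
  }
  if (grepl("ing$", token)) {
    stem <- sub("ing$", "", token)
    cands <- c(cands, stem, paste0(stem, "e"))
  }
  if (grepl("ed$", token)) {
    stem <- sub("ed$", "", token)
    cands <- c(cands, stem, paste0(stem, "e"))
  }
  hit <- cands[cands %in% known]
  if (length(hit) > 0) hit[1] else token
}

#' Extract normalized dictionary terms from sentences
#'
#' Lowercases, strips punctuation, lemmatizes each token with a
#' suffix-rule/exception lemmatizer, folds lexical variants through the
#' synonym map, removes stopwords, and keeps only tokens present in the
#' entity dictionary. Output preserves text order and repeats.
#'
#' @param sentences character vector of (preprocessed) sentences.
#' @param config a [text_config()].
#' @return Character vector of normalized terms.
#' @export
extract_terms <- function(sentences, config = text_config()) {
  assert_that(length(config$entity_dictionary) > 0,
              "entity_dictionary must be non-empty")
  known <- unique(c(config$entity_dictionary, names(config$synonym_map)))
  tok <- unlist(note_tokens_list(sentences), use.names = FALSE)
  if (length(tok) == 0) return(character(0))
  # lemmatize each distinct surface form once
  uniq <- unique(tok)
  lem <- vapply(uniq, lemmatize_token, character(1), known = known,
                USE.NAMES = FALSE)
  tok <- lem[match(tok, uniq)]
  if (length(config$synonym_map) > 0) {
    mapped <- config$synonym_map[tok]
    tok <- ifelse(is.na(mapped), tok, mapped)
  }
  tok <- tok[!(tok %in% config$stopwords)]
  tok <- tok[tok %in% config$entity_dictionary]
  unname(tok)
}

#' Restrict notes to the pre-treatment window
#'
#' Keeps documents dated at least `window_days` before the treatment start
#' (boundary inclusive), so that features never encode the treatment
#' decision itself.
#'
#' @param docs data frame with columns `patient_id`, `date`, `text`.
#' @param treatment_start treatment start day (days since diagnosis).
#' @param window_days length of the exclusion window before treatment.
#' @return The retained rows of `docs`.
#' @export
window_notes <- function(docs, treatment_start, window_days) {
  assert_that(window_days >= 0, "window_days must be >= 0")
  docs[docs$date <= treatment_start - window_days, , drop = FALSE]
}

make_ngrams <- function(terms, ngram_max) {
  if (ngram_max < 2 || length(terms) < 2) return(terms)
  bigrams <- paste(terms[-length(terms)], terms[-1], sep = "_")
  c(terms, bigrams)
}

#' Build the TF-IDF text covariate block
#'
#' Takes one term document per patient (all extracted terms from that
#' patient's retained notes), forms unigram (and optionally bigram)
#' candidates, drops candidates whose document frequency reaches
#' `max_document_frequency`, keeps the `top_k` most frequent, and weights
#' counts by smoothed inverse document frequency
#' `idf = ln((1 + N) / (1 + df)) + 1` with L2 normalization of each
#' patient's feature vector.
#'
#' @param term_docs named list, one character vector of terms per patient
#'   (names are patient ids).
#' @param config a [text_config()].
#' @return A [covariate_matrix()] with `text:`-prefixed columns.
#' @export
build_tfidf <- function(term_docs, config = text_config()) {
  assert_that(length(term_docs) > 0, "zero documents")
  assert_that(length(term_docs) >= 2, "need at least 2 patients")
  ids <- names(term_docs)
  assert_that(!is.null(ids) && all(nzchar(ids)), "term_docs must be named by patient id")
  docs <- lapply(term_docs, make_ngrams, ngram_max = config$ngram_max)
  n_docs <- length(docs)
  counts <- lapply(docs, function(d) table(d))
  vocab_tf <- tapply(unlist(lapply(counts, as.numeric)),
                     unlist(lapply(counts, names)), sum)
  df <- table(unlist(lapply(counts, names)))
  terms <- names(vocab_tf)
  if (config$max_document_frequency < 1) {
    keep <- as.numeric(df[terms]) / n_docs < config$max_document_frequency
    terms <- terms[keep]
  }
  if (length(terms) == 0) {
    return(covariate_matrix(matrix(0, n_docs, 0), ids, character(0)))
  }
  ord <- order(-as.numeric(vocab_tf[terms]), terms)
  terms <- terms[ord]
  if (length(terms) < config$top_k) {
    warning(sprintf("only %d candidate terms for top_k = %d; keeping all",
                    length(terms), config$top_k))
  }
  terms <- head(terms, config$top_k)
  tf <- matrix(0, n_docs, length(terms), dimnames = list(ids, terms))
  for (i in seq_len(n_docs)) {
    ct <- counts[[i]]
    hit <- intersect(names(ct), terms)
    tf[i, hit] <- as.numeric(ct[hit])
  }
  idf <- log((1 + n_docs) / (1 + as.numeric(df[terms]))) + 1
  x <- sweep(tf, 2, idf, `*`)
  norms <- sqrt(rowSums(x^2))
  norms[norms == 0] <- 1
  x <- x / norms
  covariate_matrix(x, ids, paste0("text:", terms))
}

#' Run the full note-to-terms pipeline for one cohort
#'
#' Applies, per patient: pre-treatment windowing, sentence segmentation,
#' boilerplate stripping, negation filtering, and entity extraction, then
#' concatenates each patient's terms into a single document.
#'
#' @param notes data frame (`patient_id`, `date`, `text`).
#' @param patients data frame with `patient_id` and `treatment_start_day`
#'   (NA start day keeps all notes).
#' @param window_days pre-treatment exclusion window in days.
#' @param config a [text_config()].
#' @return Named list of term vectors, one entry per patient in
#'   `patients$patient_id` order (patients without retained notes get an
#'   empty vector).
#' @export
featurize_notes <- function(notes, patients, window_days = 60,
                            config = text_config()) {
  docs <- vector("list", nrow(patients))
  names(docs) <- patients$patient_id
  note_split <- split(notes, notes$patient_id)
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    nd <- note_split[[pid]]
    if (is.null(nd) || nrow(nd) == 0) { docs[[i]] <- character(0); next }
    start <- patients$treatment_start_day[i]
    if (!is.na(start)) nd <- window_notes(nd, start, window_days)
    terms <- character(0)
    for (txt in nd$text) {
      sent <- segment_sentences(txt)
      sent <- strip_boilerplate(sent, config)
      sent <- filter_negated(sent, config)
      terms <- c(terms, extract_terms(sent, config))
    }
    docs[[i]] <- terms
  }
  docs
}
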