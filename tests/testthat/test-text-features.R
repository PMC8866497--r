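test_that("sentence segmentation splits on field labels, tabs and sentence punctuation", {
  expect_equal(segment_sentences("IMPRESSION: Tumor stable. Follow up in 3 months."),
               c("Tumor stable.", "Follow up in 3 months."))
  expect_equal(segment_sentences("HISTORY:\tSevere COPD noted."),
               "Severe COPD noted.")
  expect_equal(segment_sentences("   "), character(0))
  expect_equal(segment_sentences(""), character(0))
})

test_that("boilerplate stripping trims document edges and pattern sentences", {
  cfg <- text_config(boilerplate_trim = 2,
                     boilerplate_patterns = c("example medical center"))
  s6 <- sprintf("Sentence %d.", 1:6)
  expect_equal(strip_boilerplate(s6, cfg), c("Sentence 3.", "Sentence 4."))
  expect_equal(strip_boilerplate(sprintf("Sentence %d.", 1:3), cfg),
               character(0))
  mid <- c("A.", "B.", "Seen at Example Medical Center.", "Tumor stable.",
           "C.", "D.")
  expect_equal(strip_boilerplate(mid, cfg), "Tumor stable.")
})

test_that("the negation filter drops short negated sentences and keeps long ones", {
  cfg <- text_config()
  expect_equal(filter_negated("No history of smoking.", cfg), character(0))
  expect_equal(filter_negated("Patient denies chest pain.", cfg), character(0))
  long <- paste("The patient reports that there has been no recurrence of",
                "the severe chest pain that was described at the previous",
                "two clinic visits.")
  expect_equal(filter_negated(long, cfg), long)
  # word count uses whitespace tokens after punctuation stripping
  expect_equal(filter_negated("Does not tolerate statins.", cfg), character(0))
  # idempotence
  mixed <- c("No history of smoking.", "Tumor stable.", long)
  once <- filter_negated(mixed, cfg)
  expect_identical(filter_negated(once, cfg), once)
})

test_that("term extraction lowercases, lemmatizes, maps synonyms and filters by dictionary", {
  cfg <- text_config(entity_dictionary = c("bladder", "obstruction"),
                     synonym_map = character(0))
  expect_equal(extract_terms("evidence of chronic bladder outlet obstruction", cfg),
               c("bladder", "obstruction"))
  cfg2 <- text_config(entity_dictionary = c("history", "urothelial", "carcinoma"),
                      synonym_map = c(hx = "history"))
  expect_equal(extract_terms("hx of urothelial carcinoma", cfg2),
               c("history", "urothelial", "carcinoma"))
  # plural and participle forms are lemmatized into dictionary terms
  cfg3 <- text_config(entity_dictionary = c("lesion", "smoking", "biopsy"))
  expect_equal(extract_terms("Multiple lesions and biopsies; smoking.", cfg3),
               c("lesion", "biopsy", "smoking"))
  # all-stopword input
  expect_equal(extract_terms("the and of was", cfg),
               character(0))
  expect_error(extract_terms("x", text_config(entity_dictionary = character(0))),
               "entity_dictionary")
})

test_that("TF-IDF matches the hand-computed example and the independent two-pass oracle", {
  docs <- list(p1 = c("a", "a", "b"), p2 = c("a", "c"))
  cfg <- text_config(top_k = 3)
  m <- build_tfidf(docs, cfg)
  expect_equal(m$column_names, c("text:a", "text:b", "text:c"))
  # hand computation: idf_a = ln(3/3)+1 = 1, idf_b = idf_c = ln(3/2)+1
  idf_bc <- log(3 / 2) + 1
  r1 <- c(2 * 1, idf_bc, 0); r1 <- r1 / sqrt(sum(r1^2))
  r2 <- c(1, 0, idf_bc); r2 <- r2 / sqrt(sum(r2^2))
  expect_equal(unname(m$values[1, ]), r1, tolerance = 1e-12)
  expect_equal(unname(m$values[2, ]), r2, tolerance = 1e-12)

  # oracle equivalence on a slightly larger corpus (<= 5 docs)
  docs5 <- list(p1 = c("a", "b", "b"), p2 = c("c"), p3 = c("a", "c", "d"),
                p4 = c("d", "d", "e"), p5 = c("b", "e", "a", "a"))
  got <- suppressWarnings(build_tfidf(docs5, text_config(top_k = 10)))
  want <- oracle_tfidf(docs5)
  for (term in colnames(want)) {
    expect_equal(unname(got$values[, paste0("text:", term)]),
                 unname(want[, term]), tolerance = 1e-12)
  }
})

test_that("document-frequency threshold and top_k bound the vocabulary", {
  docs <- list(p1 = c("a", "b"), p2 = c("a", "c"), p3 = c("a", "b"),
               p4 = c("a", "d"))
  # "a" occurs in every document: df = 1 >= 0.7 -> excluded
  m <- suppressWarnings(
    build_tfidf(docs, text_config(top_k = 10, max_document_frequency = 0.7)))
  expect_false("text:a" %in% m$column_names)
  expect_true(all(c("text:b", "text:c", "text:d") %in% m$column_names))
  # top_k bounds the number of text columns
  m2 <- build_tfidf(docs, text_config(top_k = 2, max_document_frequency = 1))
  expect_lte(ncol(m2$values), 2)
  expect_warning(build_tfidf(docs, text_config(top_k = 50)), "top_k")
  expect_error(build_tfidf(list(), text_config(top_k = 2)), "documents")
})

test_that("bigram features are formed from adjacent terms when requested", {
  docs <- list(p1 = c("squamous", "cell", "lung"), p2 = c("squamous", "cell"))
  m <- suppressWarnings(build_tfidf(docs, text_config(top_k = 10, ngram_max = 2)))
  expect_true("text:squamous_cell" %in% m$column_names)
  m1 <- suppressWarnings(build_tfidf(docs, text_config(top_k = 10, ngram_max = 1)))
  expect_false(any(grepl("_", m1$column_names)))
})

test_that("patient order permutations permute rows but not columns", {
  docs <- list(p1 = c("a", "b"), p2 = c("c", "a"), p3 = c("b", "b"))
  m <- suppressWarnings(build_tfidf(docs, text_config(top_k = 5)))
  m_perm <- suppressWarnings(build_tfidf(docs[c(3, 1, 2)], text_config(top_k = 5)))
  expect_equal(m_perm$column_names, m$column_names)
  expect_equal(m_perm$values[c("p1", "p2", "p3"), ], m$values)
})

test_that("the note window keeps only notes sufficiently before treatment", {
  docs <- data.frame(patient_id = "P1", date = c(100, 140, 150),
                     text = c("a", "b", "c"))
  kept <- window_notes(docs, treatment_start = 200, window_days = 60)
  expect_equal(kept$date, c(100, 140))  # boundary day 140 inclusive
  expect_error(window_notes(docs, 200, -1), "window_days")
})

test_that("planted terms survive the pipeline and negated-only mentions contribute nothing", {
  sim <- generate_cohort(sim_config(n_patients = 60, seed = 21,
                                    negated_mention_rate = 1))
  cfg <- small_text_config()
  docs <- featurize_notes(sim$cohort$notes, sim$cohort$patients, 0, cfg)
  m <- build_tfidf(docs, cfg)
  expect_true("text:bladder" %in% m$column_names)
  # a patient with the term inactive only ever sees negated mentions,
  # which the filter removes: the count must be zero
  inactive <- rownames(sim$manifest$terms)[sim$manifest$terms[, "bladder"] == 0]
  expect_true(all(m$values[inactive, "text:bladder"] == 0))
  active <- rownames(sim$manifest$terms)[sim$manifest$terms[, "bladder"] == 1]
  expect_true(all(m$values[active, "text:bladder"] > 0))
  expect_lte(sum(startsWith(m$column_names, "text:")), cfg$top_k)
})
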