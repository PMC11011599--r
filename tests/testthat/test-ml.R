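test_that("preprocessing lowercases, tokenizes, strips non-alphanumerics", {
  expect_equal(preprocess_text("Opioid abuse (ICD-9 304.00)")[[1]],
               c("opioid", "abuse", "icd9", "30400"))
  expect_equal(preprocess_text("")[[1]], character())
  expect_equal(preprocess_text("mg/dL")[[1]], "mgdl")
  # tokens emptied by stripping are dropped
  expect_equal(preprocess_text("a -- b")[[1]], c("a", "b"))
})

test_that("vocabulary obeys the lexical filters", {
  # one snippet: unigrams letters-only, bigram second word may be numeric
  spec <- build_feature_spec("opioid abuse 30400", min_document_frequency = 1)
  expect_equal(spec$unigram_vocab, c("abuse", "opioid"))
  expect_equal(spec$bigram_vocab, c("abuse 30400", "opioid abuse"))

  # duplicated snippet does not change a min_df = 1 vocabulary
  spec2 <- build_feature_spec(rep("opioid abuse 30400", 2),
                              min_document_frequency = 1)
  expect_equal(spec2$unigram_vocab, spec$unigram_vocab)
  expect_equal(spec2$bigram_vocab, spec$bigram_vocab)

  expect_error(build_feature_spec(character()), "empty corpus")
  expect_error(build_feature_spec(c("aa bb", "cc dd"),
                                  min_document_frequency = 5),
               "empty vocabulary")

  # filter invariants on a larger built spec
  gold <- shared_corpus()$gold
  sp <- build_feature_spec(gold$text, min_document_frequency = 2)
  expect_true(all(grepl("^[a-z]+$", sp$unigram_vocab)))
  first <- sub(" .*", "", sp$bigram_vocab)
  second <- sub(".* ", "", sp$bigram_vocab)
  expect_true(all(grepl("^[a-z]+$", first)))
  expect_true(all(grepl("^[a-z0-9]+$", second)))
})

test_that("featurization counts n-grams and appends the position scalar", {
  spec <- build_feature_spec(c("opioid abuse opioid", "abuse opioid abuse"),
                             min_document_frequency = 1)
  s <- make_snippet("opioid abuse opioid", "opioid", n_before = 0L)
  x <- featurize(s, spec)
  expect_equal(unname(x[1, "opioid"]), 2)
  expect_equal(unname(x[1, "abuse"]), 1)
  expect_equal(unname(x[1, "bi:opioid abuse"]), 1)
  expect_equal(unname(x[1, "bi:abuse opioid"]), 1)
  expect_equal(unname(x[1, "key_phrase_position"]), 0)

  # position is recomputed on the preprocessed token stream: a token
  # emptied by stripping does not count
  s2 <- make_snippet("-- pt opioid abuse", "opioid", n_before = 2L)
  x2 <- featurize(s2, spec)
  expect_equal(unname(x2[1, "key_phrase_position"]), 1)

  # no vocabulary n-gram present -> all-zero n-gram block
  s3 <- make_snippet("nothing relevant here", "opioid", n_before = 0L)
  x3 <- featurize(s3, spec)
  expect_equal(sum(x3[1, colnames(x3) != "key_phrase_position"]), 0)
})

test_that("training is stratified, reproducible, and separable by design", {
  gold <- shared_corpus()$gold
  model <- shared_model()
  # split is a partition
  expect_setequal(c(model$train_idx, model$test_idx), seq_len(nrow(gold)))
  expect_length(intersect(model$train_idx, model$test_idx), 0L)
  # held-out precision and recall on the separable corpus
  expect_gte(model$metrics[["ppv"]], 0.95)
  expect_gte(model$metrics[["sensitivity"]], 0.95)
  # same corpus, same seed -> identical metrics and predictions
  model2 <- train_text_model(gold, gold$label, seed = 99L)
  expect_identical(model$metrics, model2$metrics)
  expect_identical(model$train_idx, model2$train_idx)
})

test_that("suspected labels are merged into positive before splitting", {
  gold <- shared_corpus()$gold
  lab <- gold$label
  pos <- which(lab == "positive")
  lab[pos[seq_len(30)]] <- "suspected"
  m <- train_text_model(gold, lab, seed = 99L)
  # merge happens pre-split, so the fit equals the all-positive labelling
  expect_identical(m$train_idx, shared_model()$train_idx)
  expect_identical(m$metrics, shared_model()$metrics)
})

test_that("degenerate corpora are rejected", {
  s <- do.call(rbind, lapply(1:6, function(i)
    make_snippet(paste("text number", i), "opioid")))
  expect_error(train_text_model(s, rep("positive", 6)), "single class")
  expect_error(train_text_model(s, c("positive", rep("suspected", 5))),
               "single class")
  expect_error(train_text_model(s, rep(c("positive", "maybe"), 3)),
               "unknown label")
})

test_that("prediction is deterministic, batch-consistent, and total", {
  model <- shared_model()
  gold <- shared_corpus()$gold
  sub <- gold[model$test_idx[1:20], ]
  batch <- predict(model, sub)
  single <- vapply(seq_len(nrow(sub)), function(i)
    as.character(predict(model, sub[i, , drop = FALSE])), character(1))
  expect_equal(as.character(batch), single)
  # empty-text snippet gets a valid label, no crash
  p <- predict(model, make_snippet("", "opioid"))
  expect_true(as.character(p) %in% c("positive", "negative"))
  # a strongly positive training exemplar predicts positive
  exemplar <- gold[model$train_idx, ][match(
    "positive", gold$label[model$train_idx]), ]
  expect_equal(as.character(predict(model, exemplar)), "positive")
})

test_that("model persistence round-trips with a JSON sidecar", {
  model <- shared_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_text_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$seed, model$seed)
  expect_equal(side$n_test, length(model$test_idx))
  back <- load_text_model(path)
  gold <- shared_corpus()$gold
  expect_equal(predict(back, gold[1:5, ]), predict(model, gold[1:5, ]))
})
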