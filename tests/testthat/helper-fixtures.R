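# Shared fixtures and independent oracles.

# Minimal lexicon used where the full 36-phrase default is overkill.
tiny_lexicon <- function() {
  key_phrase_lexicon(c("oxycodone", "morphine", "opioid",
                       "opioid dependence", "withdrawal"),
                     c("drug_name", "drug_name", "other", "other", "other"))
}

# Build a snippet data.frame row directly from text, bypassing extraction
# (the key phrase is taken to start at raw-token index `n_before`).
make_snippet <- function(text, key_phrase = "opioid", n_before = 0L,
                         note_id = "n1", patient_id = "p1") {
  ntok <- length(strsplit(trimws(text), "\\s+")[[1]])
  nkey <- length(strsplit(key_phrase, " ", fixed = TRUE)[[1]])
  data.frame(note_id = note_id, patient_id = patient_id,
             key_phrase = key_phrase,
             key_phrase_token_index = n_before, n_before = n_before,
             n_after = max(0L, ntok - n_before - nkey),
             text = text, stringsAsFactors = FALSE)
}

# Brute-force key-phrase match count oracle: tries every phrase at every
# token position under the same greedy longest-match semantics, written
# independently of the extractor (direct position-by-position scan on a
# normalized token vector).
oracle_match_count <- function(text, lexicon) {
  tok <- strsplit(trimws(text), "\\s+")[[1]]
  tok <- tok[nzchar(tok)]
  norm <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", tolower(tok))
  phrases <- strsplit(lexicon$phrase, " ", fixed = TRUE)
  count <- 0L
  i <- 1L
  while (i <= length(norm)) {
    best <- 0L
    for (p in phrases) {
      if (length(p) > best && i + length(p) - 1L <= length(norm) &&
          all(norm[i:(i + length(p) - 1L)] == p))
        best <- length(p)
    }
    if (best > 0L) { count <- count + 1L; i <- i + best } else i <- i + 1L
  }
  count
}

# Brute-force Pearson chi-square oracle from first principles.
oracle_chisq <- function(counts) {
  counts <- as.matrix(counts)
  total <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / total
  sum((counts - expected)^2 / expected)
}

# A small classified-snippet table with chosen per-patient positivity.
make_classified <- function(patient_ids, labels) {
  data.frame(note_id = paste0("n", seq_along(patient_ids)),
             patient_id = patient_ids, key_phrase = "oxycodone",
             key_phrase_token_index = 0L, n_before = 0L, n_after = 0L,
             text = "x", label = labels, method = "rule",
             tier = "general_positive", matched_pattern = "",
             stringsAsFactors = FALSE)
}

# Shared trained model on a moderate synthetic corpus (built once per test
# run; several test files use it).
shared_corpus <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      plan <- corpus_plan(n_patients = 600L, notes_per_patient = 1L,
                          implant_rate = 1, positive_rate = 0.5, seed = 99L)
      val <<- generate_corpus(plan)
    }
    val
  }
})

shared_model <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      gold <- shared_corpus()$gold
      val <<- train_text_model(gold, gold$label, seed = 99L)
    }
    val
  }
})
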