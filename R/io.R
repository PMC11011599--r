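# File formats: note corpora as JSONL (one object per line: note_id,
# patient_id, note_date, note_type, text) or CSV with the same columns;
# annotated snippets, patient tables, ICD tables and all outputs as
# RFC-4180 CSV (UTF-8, header row, ISO-8601 dates). Run configuration as
# YAML or JSON.

.require_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  df
}

NOTE_COLUMNS <- c("note_id", "patient_id", "note_date", "note_type", "text")

#' Read a note corpus (JSONL or CSV)
#'
#' JSONL files (`.jsonl`/`.ndjson`) carry one JSON object per line; a
#' malformed line is reported by its line number. CSV files need the same
#' columns.
#'
#' @param path corpus file path.
#' @return data.frame with columns `note_id`, `patient_id`, `note_date`,
#'   `note_type`, `text`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    recs <- lapply(keep, function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        stop("malformed JSON on line ", i, " of ", path, ": ",
                             conditionMessage(e), call. = FALSE))
      as.data.frame(rec[NOTE_COLUMNS[NOTE_COLUMNS %in% names(rec)]],
                    stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    if (is.null(out)) stop("corpus file is empty: ", path)
  } else {
    out <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  }
  .require_columns(out, NOTE_COLUMNS, "note corpus")
}

#' Write a note corpus as JSONL
#'
#' @param notes note data.frame (see [read_corpus()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(notes, path) {
  .require_columns(notes, NOTE_COLUMNS, "note corpus")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes)))
    writeLines(jsonlite::toJSON(as.list(notes[i, NOTE_COLUMNS]),
                                auto_unbox = TRUE), con)
  invisible(path)
}

#' Read annotated snippets (CSV: snippet_id, key_phrase, text, label)
#'
#' @param path CSV path.
#' @return data.frame with the annotation columns; labels must be
#'   `positive`, `suspected` or `negative`.
#' @export
read_annotated_snippets <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("snippet_id", "key_phrase", "text", "label"),
                   "annotated snippet file")
  bad <- !df$label %in% c("positive", "suspected", "negative")
  if (any(bad))
    stop("invalid label(s) in ", path, ": ",
         paste(unique(df$label[bad]), collapse = ", "))
  df
}

#' Read a patient covariate table (CSV)
#' @param path CSV path.
#' @return data.frame; must contain `patient_id`.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("patient table not found: ", path)
  .require_columns(utils::read.csv(path, stringsAsFactors = FALSE),
                   "patient_id", "patient table")
}

#' Read an ICD code table (CSV: patient_id, code, date)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_icd <- function(path) {
  if (!file.exists(path)) stop("ICD table not found: ", path)
  .require_columns(utils::read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = "character"),
                   c("patient_id", "code", "date"), "ICD table")
}

#' Write a table as RFC-4180 CSV
#' @param rows data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognized fields: `lexicon`, `patterns`, `corpus`, `annotations`,
#' `patients`, `icd`, `model`, `output_dir`, `seed`,
#' `min_document_frequency`, `split_fraction`, `threshold`. Missing fields
#' take the defaults below.
#'
#' @param path config file (`.yml`/`.yaml`/`.json`).
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  run_config(cfg)
}

#' @rdname read_run_config
#' @param config named list of configuration fields.
#' @export
run_config <- function(config = list()) {
  defaults <- list(lexicon = NULL, patterns = NULL, corpus = NULL,
                   annotations = NULL, patients = NULL, icd = NULL,
                   model = NULL, output_dir = ".", seed = 1L,
                   min_document_frequency = 2L, split_fraction = 0.8,
                   threshold = 0.85)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$split_fraction > 0, cfg$split_fraction < 1,
            cfg$threshold > 0, cfg$threshold <= 1)
  class(cfg) <- "run_config"
  cfg
}

.cfg_lexicon <- function(cfg)
  if (is.null(cfg$lexicon)) default_lexicon() else read_lexicon(cfg$lexicon)
.cfg_patterns <- function(cfg) {
  if (is.null(cfg$patterns)) default_pattern_library()
  else read_pattern_library(cfg$patterns)
}

.log <- function(...) message("[opioidphen] ", ...)

#' Run a pipeline subcommand
#'
#' Dispatcher behind the command-line interface. Subcommands:
#' \describe{
#'   \item{simulate}{generate a synthetic corpus (notes JSONL + gold CSV)
#'     and cohort (patients CSV + ICD CSV) under `seed`.}
#'   \item{extract}{extract snippets from `corpus` and write
#'     `snippets.csv` + `key_phrase_counts.csv`.}
#'   \item{train}{train the SVM on `annotations` and write the model
#'     artifact + sidecar.}
#'   \item{classify}{cascade-classify `corpus` snippets with patterns +
#'     `model`; writes `classified.csv` + `classification_summary.csv`.}
#'   \item{evaluate}{score `classified.csv`-style predictions in
#'     `annotations` against gold labels; writes `metrics.json`.}
#'   \item{group}{assign patients to groups from classified snippets +
#'     ICD table; writes `groups.csv`.}
#'   \item{tally}{positive-snippet tallies by key-phrase category; writes
#'     `tally.csv`.}
#'   \item{compare}{two-group covariate comparison table; writes
#'     `comparison.csv`.}
#' }
#' Each subcommand logs its input/output record counts.
#'
#' @param config a `run_config` (or named list coerced through
#'   [run_config()]).
#' @param subcommand one of the names above.
#' @return 0 invisibly on success (errors propagate).
#' @export
opioid_run <- function(config, subcommand) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  switch(
    subcommand,
    simulate = {
      corp <- generate_corpus(corpus_plan(seed = config$seed,
                                          lexicon = .cfg_lexicon(config)))
      write_corpus(corp$notes, out("notes.jsonl"))
      write_table(corp$gold, out("gold_snippets.csv"))
      coh <- generate_cohort(cohort_plan(seed = config$seed))
      write_table(coh$patients, out("patients.csv"))
      write_table(coh$icd, out("icd.csv"))
      .log("simulated ", nrow(corp$notes), " notes (",
           nrow(corp$gold), " gold snippets), ",
           nrow(coh$patients), " patients, ", nrow(coh$icd), " ICD rows")
    },
    extract = {
      notes <- read_corpus(config$corpus)
      sn <- extract_corpus_snippets(notes, .cfg_lexicon(config))
      write_table(sn, out("snippets.csv"))
      write_table(count_key_phrases(sn), out("key_phrase_counts.csv"))
      .log(nrow(notes), " notes -> ", nrow(sn), " snippets")
    },
    train = {
      ann <- read_annotated_snippets(config$annotations)
      sn <- data.frame(note_id = ann$snippet_id, patient_id = NA_character_,
                       key_phrase = ann$key_phrase,
                       key_phrase_token_index = 0L, n_before = 0L,
                       n_after = 0L, text = ann$text,
                       stringsAsFactors = FALSE)
      model <- train_text_model(
        sn, ann$label, split_fraction = config$split_fraction,
        seed = config$seed,
        min_document_frequency = config$min_document_frequency)
      save_text_model(model, out("text_model.rds"))
      .log("trained on ", length(model$train_idx), ", held out ",
           length(model$test_idx), "; metrics: ",
           paste(sprintf("%s=%.3f", names(model$metrics), model$metrics),
                 collapse = " "))
    },
    classify = {
      notes <- read_corpus(config$corpus)
      sn <- extract_corpus_snippets(notes, .cfg_lexicon(config))
      model <- if (is.null(config$model)) NULL else load_text_model(config$model)
      cl <- classify_snippets(sn, .cfg_patterns(config), model)
      write_table(cl, out("classified.csv"))
      write_table(classification_summary(cl), out("classification_summary.csv"))
      .log(nrow(sn), " snippets classified (",
           sum(cl$method == "rule"), " by rule, ",
           sum(cl$method == "svm"), " by SVM)")
    },
    evaluate = {
      ann <- utils::read.csv(config$annotations, stringsAsFactors = FALSE)
      .require_columns(ann, c("label", "prediction"), "evaluation file")
      m <- classification_metrics(confusion_counts(ann$label, ann$prediction))
      gate <- performance_gate(m, config$threshold)
      jsonlite::write_json(
        c(as.list(m), list(threshold = config$threshold,
                           gate_passed = isTRUE(gate),
                           gate_reason = attr(gate, "reason"))),
        out("metrics.json"), auto_unbox = TRUE, digits = NA, null = "null")
      .log(nrow(ann), " labels scored; gate ",
           if (isTRUE(gate)) "passed" else "FAILED")
    },
    group = {
      patients <- read_patients(config$patients)
      icd <- if (is.null(config$icd)) NULL else read_icd(config$icd)
      cl <- utils::read.csv(file.path(config$output_dir, "classified.csv"),
                            stringsAsFactors = FALSE)
      ga <- assign_groups(patients, cl, icd)
      write_table(ga, out("groups.csv"))
      .log(paste(sprintf("%s=%d", names(group_counts(ga)), group_counts(ga)),
                 collapse = " "))
    },
    tally = {
      cl <- utils::read.csv(file.path(config$output_dir, "classified.csv"),
                            stringsAsFactors = FALSE)
      ga <- utils::read.csv(file.path(config$output_dir, "groups.csv"),
                            stringsAsFactors = FALSE)
      tl <- tally_positive_patterns(cl, .cfg_lexicon(config), ga)
      write_table(tl, out("tally.csv"))
      .log(nrow(tl), " tally rows written")
    },
    compare = {
      patients <- read_patients(config$patients)
      tab <- build_comparison_table(patients)
      write_table(tab, out("comparison.csv"))
      .log(nrow(tab), " comparison rows written")
    },
    stop("unknown subcommand: ", subcommand))
  invisible(0L)
}
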