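# The cascade: every snippet first goes through the tiered rules; snippets
# the rules abstain on are classified by the SVM, so coverage is always
# 100%.

#' Classify snippets with the rule/SVM cascade
#'
#' @param snippets snippet data.frame ([extract_snippets()] columns).
#' @param library a [pattern_library()] (default: the shipped seed library).
#' @param model an [train_text_model()] result, used for snippets the rules
#'   abstain on. May be `NULL` only if the rules decide every snippet.
#' @return The snippet data.frame with added columns `label`
#'   (`"positive"`/`"negative"`), `method` (`"rule"`/`"svm"`), `tier`
#'   (deciding tier or `""`), and `matched_pattern`.
#' @export
classify_snippets <- function(snippets, library = default_pattern_library(),
                              model = NULL) {
  if (nrow(snippets) == 0L) {
    out <- snippets
    out$label <- character(0); out$method <- character(0)
    out$tier <- character(0); out$matched_pattern <- character(0)
    return(out)
  }
  rd <- rule_classify(snippets$text, library)
  out <- snippets
  out$label <- rd$label
  out$method <- ifelse(rd$label == "abstain", "svm", "rule")
  out$tier <- ifelse(rd$tier == "none", "", rd$tier)
  out$matched_pattern <- rd$matched_pattern
  abst <- which(rd$label == "abstain")
  if (length(abst)) {
    if (is.null(model))
      stop(length(abst), " snippet(s) not decided by the rules and no text ",
           "model supplied")
    out$label[abst] <- as.character(
      predict(model, snippets[abst, , drop = FALSE]))
  }
  out
}

#' Summarize cascade output on a document basis
#'
#' A note is counted positive when it contains at least one positive
#' snippet.
#'
#' @param classified output of [classify_snippets()].
#' @return One-row data.frame: total notes, total snippets,
#'   positive/negative snippet counts, positive note count, and mean
#'   snippets per note.
#' @export
classification_summary <- function(classified) {
  n_notes <- length(unique(classified$note_id))
  pos_notes <- length(unique(classified$note_id[classified$label == "positive"]))
  data.frame(
    n_notes = n_notes,
    n_snippets = nrow(classified),
    n_positive_snippets = sum(classified$label == "positive"),
    n_negative_snippets = sum(classified$label == "negative"),
    n_positive_notes = pos_notes,
    mean_snippets_per_note = if (n_notes) nrow(classified) / n_notes else NA_real_)
}
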