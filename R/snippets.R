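# Snippet extraction: the unit of classification is a key-phrase occurrence
# plus up to `window` (default 50) whitespace tokens of context on each side.
# Tokenization for windowing splits on runs of whitespace and keeps
# punctuation attached to tokens, so the snippet text stays raw for the rule
# classifier. Matching compares phrase tokens against tokens lowercased and
# stripped of leading/trailing non-alphanumerics, so "Oxycodone," matches
# "oxycodone". Matching is greedy left-to-right: at a given position the
# longest phrase wins and its span is consumed; occurrences starting at other
# positions each yield their own snippet.

.tokenize_raw <- function(text) {
  tok <- strsplit(text, "\\s+")[[1]]
  tok[nzchar(tok)]
}

.norm_token <- function(tokens) {
  tok <- tolower(tokens)
  gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", tok)
}

#' Extract key-phrase snippets from one note
#'
#' Scans the note for occurrences of lexicon phrases and returns one snippet
#' per match: the key phrase plus up to `window` tokens before and after,
#' truncated (never padded) at the note boundaries.
#'
#' @param text note text (a single string; may be empty).
#' @param lexicon a [key_phrase_lexicon()].
#' @param note_id,patient_id identifiers carried into the result.
#' @param window maximum context tokens on each side (default 50).
#' @return A data.frame with one row per match and columns `note_id`,
#'   `patient_id`, `key_phrase`, `key_phrase_token_index` (0-based index of
#'   the key phrase's first token within the snippet token sequence, equal to
#'   the number of context tokens before it), `n_before`, `n_after`, and
#'   `text` (the snippet window, raw tokens joined by single spaces).
#' @examples
#' lex <- default_lexicon()
#' extract_snippets("pt requested methadone", lex, note_id = "n1")
#' @export
extract_snippets <- function(text, lexicon, note_id = NA_character_,
                             patient_id = NA_character_, window = 50L) {
  stopifnot(inherits(lexicon, "key_phrase_lexicon"), length(text) == 1L)
  empty <- data.frame(note_id = character(), patient_id = character(),
                      key_phrase = character(),
                      key_phrase_token_index = integer(),
                      n_before = integer(), n_after = integer(),
                      text = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  raw <- .tokenize_raw(text)
  if (length(raw) == 0L) return(empty)
  norm <- .norm_token(raw)

  phr_tok <- strsplit(lexicon$phrase, " ", fixed = TRUE)
  # index phrases by first token; try longer phrases first at each position
  first <- vapply(phr_tok, `[[`, character(1), 1L)
  ord <- order(lengths(phr_tok), decreasing = TRUE)

  hits_pos <- integer(); hits_phr <- integer()
  i <- 1L
  n <- length(raw)
  while (i <= n) {
    matched <- 0L
    for (j in ord[first[ord] == norm[i]]) {
      len <- length(phr_tok[[j]])
      if (i + len - 1L <= n &&
          identical(norm[i:(i + len - 1L)], phr_tok[[j]])) {
        matched <- j
        break
      }
    }
    if (matched > 0L) {
      hits_pos <- c(hits_pos, i)
      hits_phr <- c(hits_phr, matched)
      i <- i + length(phr_tok[[matched]])
    } else {
      i <- i + 1L
    }
  }
  if (length(hits_pos) == 0L) return(empty)

  rows <- lapply(seq_along(hits_pos), function(k) {
    i <- hits_pos[k]
    len <- length(phr_tok[[hits_phr[k]]])
    lo <- max(1L, i - window)
    hi <- min(n, i + len - 1L + window)
    data.frame(note_id = note_id, patient_id = patient_id,
               key_phrase = lexicon$phrase[hits_phr[k]],
               key_phrase_token_index = i - lo,
               n_before = i - lo,
               n_after = hi - (i + len - 1L),
               text = paste(raw[lo:hi], collapse = " "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract snippets from a note corpus
#'
#' @param notes data.frame with columns `note_id`, `patient_id`, `text`
#'   (additional columns such as `note_date`, `note_type` are ignored here
#'   but used by [compute_index_dates()]).
#' @param lexicon a [key_phrase_lexicon()].
#' @param window context size per side, see [extract_snippets()].
#' @return Row-bound snippet data.frame across all notes.
#' @export
extract_corpus_snippets <- function(notes, lexicon, window = 50L) {
  need <- c("note_id", "patient_id", "text")
  miss <- setdiff(need, names(notes))
  if (length(miss))
    stop("notes table is missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(notes)), function(i)
    extract_snippets(notes$text[i], lexicon,
                     note_id = as.character(notes$note_id[i]),
                     patient_id = as.character(notes$patient_id[i]),
                     window = window))
  do.call(rbind, out)
}

#' Tabulate key-phrase occurrences in snippets
#'
#' One row per key phrase present, with the number of snippets and the
#' number of distinct patients having at least one snippet for the phrase.
#' Snippet counts sum to `nrow(snippets)`.
#'
#' @param snippets snippet data.frame from [extract_snippets()] or
#'   [extract_corpus_snippets()].
#' @return data.frame with columns `key_phrase`, `n_snippets`, `n_patients`.
#' @export
count_key_phrases <- function(snippets) {
  if (is.null(snippets) || nrow(snippets) == 0L)
    return(data.frame(key_phrase = character(), n_snippets = integer(),
                      n_patients = integer(), stringsAsFactors = FALSE))
  sp <- split(snippets, snippets$key_phrase)
  out <- data.frame(
    key_phrase = names(sp),
    n_snippets = vapply(sp, nrow, integer(1)),
    n_patients = vapply(sp, function(d) length(unique(d$patient_id)),
                        integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_snippets, out$key_phrase), , drop = FALSE]
}
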