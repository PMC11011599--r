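# Text preprocessing and featurization for the machine-learning fallback.
# Preprocessing: lowercase -> whitespace tokenization -> strip
# non-alphanumeric characters from tokens -> drop tokens emptied by
# stripping. Features: counts of vocabulary unigrams (letters only) and
# bigrams (first word letters only; second word letters and/or digits),
# plus the 0-based position of the key phrase's first word in the
# preprocessed token sequence.

#' Preprocess text for the SVM
#'
#' Lowercases, tokenizes on whitespace, removes non-alphanumeric characters
#' from each token, and drops tokens emptied by the stripping.
#'
#' @param text character vector.
#' @return A list of character vectors (one token vector per input string).
#' @examples
#' preprocess_text("Opioid abuse (ICD-9 304.00)")
#' # [["opioid", "abuse", "icd9", "30400"]]
#' @export
preprocess_text <- function(text) {
  lapply(strsplit(tolower(text), "\\s+"), function(tok) {
    tok <- gsub("[^a-z0-9]", "", tok)
    tok[nzchar(tok)]
  })
}

.lexical_unigrams <- function(tokens) {
  unique(tokens[grepl("^[a-z]+$", tokens)])
}

.lexical_bigrams <- function(tokens) {
  if (length(tokens) < 2L) return(character())
  a <- tokens[-length(tokens)]
  b <- tokens[-1L]
  keep <- grepl("^[a-z]+$", a) & grepl("^[a-z0-9]+$", b)
  unique(paste(a[keep], b[keep]))
}

#' Build the lexically filtered n-gram feature specification
#'
#' Collects, over the preprocessed snippet texts, all unigrams consisting
#' entirely of letters and all bigrams whose first word is letters-only and
#' whose second word is letters, digits, or both; keeps those whose document
#' frequency reaches `min_document_frequency`; and orders each vocabulary
#' lexicographically so featurization is deterministic. The resulting
#' vocabulary sizes are corpus outcomes, not parameters.
#'
#' @param text character vector of snippet texts (the training corpus).
#' @param min_document_frequency minimum number of snippets an n-gram must
#'   appear in (default 2).
#' @param include_position whether to append the key-phrase position scalar
#'   at featurization time (default TRUE).
#' @return An object of class `feature_spec` with elements `unigram_vocab`,
#'   `bigram_vocab`, `include_position`, `min_document_frequency`.
#' @export
build_feature_spec <- function(text, min_document_frequency = 2L,
                               include_position = TRUE) {
  if (length(text) == 0L) stop("cannot build a feature spec from an empty corpus")
  stopifnot(min_document_frequency >= 1L)
  toks <- preprocess_text(text)
  uni_df <- table(unlist(lapply(toks, .lexical_unigrams)))
  big_df <- table(unlist(lapply(toks, .lexical_bigrams)))
  uni <- sort(names(uni_df[uni_df >= min_document_frequency]))
  big <- sort(names(big_df[big_df >= min_document_frequency]))
  if (length(uni) == 0L && length(big) == 0L)
    stop("empty vocabulary: no n-gram reaches document frequency ",
         min_document_frequency)
  spec <- list(unigram_vocab = uni, bigram_vocab = big,
               include_position = isTRUE(include_position),
               min_document_frequency = as.integer(min_document_frequency))
  class(spec) <- "feature_spec"
  spec
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("Feature spec: ", length(x$unigram_vocab), " unigrams, ",
      length(x$bigram_vocab), " bigrams",
      if (x$include_position) ", + key-phrase position" else "",
      " (min document frequency ", x$min_document_frequency, ")\n", sep = "")
  invisible(x)
}

# 0-based index of the key phrase's first word in the preprocessed token
# sequence: the number of pre-key-phrase raw tokens that survive
# preprocessing.
.position_feature <- function(snippets) {
  vapply(seq_len(nrow(snippets)), function(i) {
    nb <- snippets$n_before[i]
    if (nb == 0L) return(0L)
    before <- .tokenize_raw(snippets$text[i])[seq_len(nb)]
    length(preprocess_text(paste(before, collapse = " "))[[1]])
  }, integer(1))
}

#' Featurize snippets against a feature spec
#'
#' @param snippets snippet data.frame (see [extract_snippets()]).
#' @param spec a [build_feature_spec()] result.
#' @return Numeric matrix, one row per snippet: n-gram counts in vocabulary
#'   order, then (if `spec$include_position`) the `key_phrase_position`
#'   column.
#' @export
featurize <- function(snippets, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  toks <- preprocess_text(snippets$text)
  uni <- spec$unigram_vocab
  big <- spec$bigram_vocab
  m <- matrix(0, nrow = nrow(snippets), ncol = length(uni) + length(big),
              dimnames = list(NULL, c(uni, if (length(big)) paste0("bi:", big))))
  for (i in seq_len(nrow(snippets))) {
    tk <- toks[[i]]
    if (length(uni)) {
      tb <- table(tk[tk %in% uni])
      m[i, names(tb)] <- as.numeric(tb)
    }
    if (length(big) && length(tk) >= 2L) {
      bg <- paste(tk[-length(tk)], tk[-1L])
      tb <- table(bg[bg %in% big])
      if (length(tb)) m[i, paste0("bi:", names(tb))] <- as.numeric(tb)
    }
  }
  if (spec$include_position)
    m <- cbind(m, key_phrase_position = as.numeric(.position_feature(snippets)))
  m
}
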