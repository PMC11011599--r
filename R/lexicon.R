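#' Key-phrase lexicon
#'
#' A `key_phrase_lexicon` holds the phrases (one or two words each) that
#' trigger snippet extraction, together with a category per phrase:
#' `"drug_name"` for generic and trade opioid names (fentanyl, percocet,
#' ...), `"other"` for concept phrases such as "withdrawal" or
#' "opioid dependence". The category only matters for downstream tallies;
#' extraction treats all phrases alike.
#'
#' Phrases are stored lowercase with internal whitespace collapsed to a
#' single space. Every phrase must survive the machine-learning
#' preprocessing ([preprocess_text()]) unchanged except for case, so that a
#' phrase found in raw text is still locatable in the preprocessed token
#' stream.
#'
#' @param phrases character vector of key phrases (1-2 words each).
#' @param category character vector, same length, each `"drug_name"` or
#'   `"other"`.
#' @return An object of class `key_phrase_lexicon`: a data.frame with
#'   columns `phrase` and `category`.
#' @examples
#' lex <- key_phrase_lexicon(c("oxycodone", "opioid dependence"),
#'                           c("drug_name", "other"))
#' @export
key_phrase_lexicon <- function(phrases, category) {
  if (length(phrases) == 0L) stop("lexicon must contain at least one phrase")
  phrases <- tolower(trimws(phrases))
  phrases <- gsub("\\s+", " ", phrases)
  if (anyDuplicated(phrases))
    stop("duplicate key phrase(s): ",
         paste(unique(phrases[duplicated(phrases)]), collapse = ", "))
  if (length(category) != length(phrases))
    stop("'category' must have one entry per phrase")
  bad <- !category %in% c("drug_name", "other")
  if (any(bad))
    stop("invalid category value(s): ", paste(unique(category[bad]), collapse = ", "),
         " (must be 'drug_name' or 'other')")
  # phrases must round-trip through ML preprocessing (case aside)
  surv <- vapply(preprocess_text(phrases),
                 function(tok) paste(tok, collapse = " "), character(1))
  if (any(surv != phrases))
    stop("phrase(s) altered by preprocessing (only letters/digits and single ",
         "spaces are allowed): ",
         paste(phrases[surv != phrases], collapse = ", "))
  out <- data.frame(phrase = phrases, category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("key_phrase_lexicon", "data.frame")
  out
}

#' Default key-phrase lexicon
#'
#' The 36 key phrases used for snippet extraction: 27 generic/trade opioid
#' drug names and 9 concept phrases (withdrawal, dependence terms, abuse
#' terms). Shipped as a plain-text file in `inst/extdata/key_phrases.txt`;
#' this accessor reads and validates it.
#'
#' @return A [key_phrase_lexicon()] with 36 phrases.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "key_phrases.txt",
                           package = "opioidphen", mustWork = TRUE))
}

#' Read a key-phrase lexicon file
#'
#' One phrase per line, UTF-8, with an optional tab-separated category tag
#' (`drug_name` or `other`). Lines without a tag default to `"other"`.
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path path to the lexicon file.
#' @return A [key_phrase_lexicon()].
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) stop("lexicon file is empty: ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  phrase <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  category <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 2L || !nzchar(trimws(p[[2]]))) return("other")
    cat <- trimws(p[[2]])
    if (!cat %in% c("drug_name", "other"))
      stop("malformed category '", cat, "' on line ", keep[i], " of ", path)
    cat
  }, character(1))
  key_phrase_lexicon(phrase, category)
}

#' Write a key-phrase lexicon file
#'
#' @param lexicon a [key_phrase_lexicon()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "key_phrase_lexicon"))
  writeLines(paste(lexicon$phrase, lexicon$category, sep = "\t"), path)
  invisible(path)
}

#' @export
print.key_phrase_lexicon <- function(x, ...) {
  cat("Key-phrase lexicon: ", nrow(x), " phrases (",
      sum(x$category == "drug_name"), " drug names, ",
      sum(x$category == "other"), " other)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}
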