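# Four-tier sequential rule voting. Tiers are tested strictly in order:
#   1. absolute_positive  -> positive (current problematic use stated in
#                            template/standardized language; overrides
#                            everything else in the window)
#   2. canceling          -> negative (positive-sounding language negated:
#                            "former ...", denial, remission)
#   3. general_positive   -> positive (plain positive concept language)
#   4. neutral            -> negative (not about the patient's current use:
#                            family members, allergies, medication
#                            directions)
# The first tier with any matching pattern decides; no match -> abstain.
# Matching runs on the lowercased raw snippet window (preprocessing is
# reserved for the machine-learning fallback).

RULE_TIERS <- c("absolute_positive", "canceling", "general_positive", "neutral")

.check_patterns <- function(patterns, tier) {
  for (i in seq_along(patterns)) {
    ok <- tryCatch({grepl(patterns[i], "", perl = TRUE); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok)
      stop("invalid regular expression in tier '", tier, "', pattern ", i,
           ": ", patterns[i])
  }
  as.character(patterns)
}

#' Build a tiered pattern library
#'
#' @param absolute_positive,canceling,general_positive,neutral character
#'   vectors of Perl-compatible regular expressions; individual tiers may be
#'   empty but the library as a whole must not be.
#' @return An object of class `pattern_library`: a named list of the four
#'   tiers, in precedence order.
#' @export
pattern_library <- function(absolute_positive = character(),
                            canceling = character(),
                            general_positive = character(),
                            neutral = character()) {
  lib <- list(absolute_positive = absolute_positive, canceling = canceling,
              general_positive = general_positive, neutral = neutral)
  if (sum(lengths(lib)) == 0L)
    stop("pattern library must contain at least one pattern")
  lib <- mapply(.check_patterns, lib, names(lib), SIMPLIFY = FALSE)
  class(lib) <- "pattern_library"
  lib
}

#' Default (seed) pattern library
#'
#' A starter library covering the pattern families that recur in opioid
#' documentation: enumerated problem-list and ICD/SNOMED-coded diagnoses and
#' checked questionnaire boxes (absolute positive); "former ...", denial and
#' remission language (canceling); plain opioid abuse/dependence phrases
#' (general positive); family-member mentions, allergy lists and medication
#' directions (neutral). Users are expected to extend it for their own
#' corpus via [read_pattern_library()].
#'
#' @return A [pattern_library()].
#' @export
default_pattern_library <- function() {
  read_pattern_library(system.file("extdata", "patterns.yml",
                                   package = "opioidphen", mustWork = TRUE))
}

#' Read a pattern library from YAML
#'
#' The file has one mapping per tier (`absolute_positive`, `canceling`,
#' `general_positive`, `neutral`), each a sequence of regex strings.
#'
#' @param path YAML file path.
#' @return A [pattern_library()].
#' @export
read_pattern_library <- function(path) {
  if (!file.exists(path)) stop("pattern library file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), RULE_TIERS)
  if (length(unknown))
    stop("unknown tier(s) in ", path, ": ", paste(unknown, collapse = ", "))
  args <- lapply(RULE_TIERS, function(t) as.character(raw[[t]]))
  names(args) <- RULE_TIERS
  do.call(pattern_library, args)
}

#' Write a pattern library to YAML
#'
#' @param library a [pattern_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pattern_library <- function(library, path) {
  stopifnot(inherits(library, "pattern_library"))
  yaml::write_yaml(lapply(unclass(library), as.list), path)
  invisible(path)
}

#' Classify snippet text by the tiered rules
#'
#' Applies the four tiers in precedence order to each text and returns the
#' decision of the first tier with any match, or an abstention.
#'
#' @param text character vector of snippet window texts (matched after
#'   lowercasing; no other normalization).
#' @param library a [pattern_library()].
#' @return data.frame with columns `label` (`"positive"`, `"negative"`, or
#'   `"abstain"`), `tier` (tier name or `"none"`), and `matched_pattern`
#'   (first matching pattern within the deciding tier, or `""`).
#' @examples
#' lib <- default_pattern_library()
#' rule_classify("former opioid dependence", lib)
#' @export
rule_classify <- function(text, library) {
  stopifnot(inherits(library, "pattern_library"))
  low <- tolower(text)
  n <- length(low)
  label <- rep("abstain", n)
  tier <- rep("none", n)
  matched <- rep("", n)
  undecided <- rep(TRUE, n)
  tier_label <- c(absolute_positive = "positive", canceling = "negative",
                  general_positive = "positive", neutral = "negative")
  for (t in RULE_TIERS) {
    if (!any(undecided)) break
    for (p in library[[t]]) {
      if (!any(undecided)) break
      hit <- undecided & grepl(p, low, perl = TRUE)
      if (any(hit)) {
        label[hit] <- tier_label[[t]]
        tier[hit] <- t
        matched[hit] <- p
      }
      undecided <- undecided & !hit
    }
    # a later pattern in the same tier cannot override an earlier one, and a
    # later tier cannot override this one: all matches above are final
  }
  data.frame(label = label, tier = tier, matched_pattern = matched,
             stringsAsFactors = FALSE)
}
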