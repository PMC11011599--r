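# Patient grouping by identification method. Opioid use disorder ICD codes:
# ICD-9-CM 304.00, 304.70, 305.50 (exact) and the ICD-10-CM F11 family (any
# F11.x, since F11 alone is the category header). Groups partition the
# cohort:
#   ALL_ICD             any qualifying code (may also be NLP positive)
#   NLP_ONLY            >= 1 positive snippet, no qualifying code
#   NO_PROBLEMATIC_USE  neither
# The NLP/ICD overlap subgroup is ALL_ICD patients who are also NLP
# positive.

OUD_ICD9 <- c("304.00", "304.70", "305.50")

.code_qualifies <- function(codes) {
  codes <- toupper(trimws(as.character(codes)))
  codes %in% OUD_ICD9 | startsWith(codes, "F11")
}

#' Does a patient's code list indicate opioid use disorder?
#'
#' @param codes character vector of ICD codes (dots preserved).
#' @return TRUE iff any code is exactly 304.00, 304.70 or 305.50, or begins
#'   with "F11".
#' @examples
#' is_icd_positive(c("F11.20"))       # TRUE
#' is_icd_positive(c("F10.20", "305.1")) # FALSE
#' @export
is_icd_positive <- function(codes) {
  any(.code_qualifies(codes))
}

#' Assign patients to identification-method groups
#'
#' @param patients data.frame with a `patient_id` column (one row per
#'   patient).
#' @param classified classified snippets ([classify_snippets()] output), or
#'   `NULL` for none.
#' @param icd data.frame of codes with columns `patient_id`, `code`
#'   (optionally `date`), or `NULL` for none.
#' @return data.frame with columns `patient_id`, `nlp_positive`,
#'   `icd_positive`, `group` (factor: `ALL_ICD`, `NLP_ONLY`,
#'   `NO_PROBLEMATIC_USE`). Snippets for patients absent from `patients` are
#'   an error.
#' @export
assign_groups <- function(patients, classified = NULL, icd = NULL) {
  ids <- as.character(patients$patient_id)
  if (anyDuplicated(ids)) stop("duplicate patient_id in patients table")
  nlp_ids <- character()
  if (!is.null(classified) && nrow(classified)) {
    orphan <- setdiff(unique(as.character(classified$patient_id)), ids)
    if (length(orphan))
      stop("classified snippets reference unknown patient id(s): ",
           paste(utils::head(orphan, 10), collapse = ", "))
    nlp_ids <- unique(as.character(
      classified$patient_id[classified$label == "positive"]))
  }
  icd_ids <- character()
  if (!is.null(icd) && nrow(icd)) {
    qual <- .code_qualifies(icd$code)
    icd_ids <- unique(as.character(icd$patient_id[qual]))
    icd_ids <- intersect(icd_ids, ids)
  }
  nlp_positive <- ids %in% nlp_ids
  icd_positive <- ids %in% icd_ids
  group <- ifelse(icd_positive, "ALL_ICD",
                  ifelse(nlp_positive, "NLP_ONLY", "NO_PROBLEMATIC_USE"))
  data.frame(
    patient_id = ids,
    nlp_positive = nlp_positive,
    icd_positive = icd_positive,
    group = factor(group, levels = c("ALL_ICD", "NLP_ONLY",
                                     "NO_PROBLEMATIC_USE")),
    stringsAsFactors = FALSE)
}

#' Group sizes and the NLP/ICD overlap
#'
#' @param assignments output of [assign_groups()].
#' @return Named integer vector: cohort size `n`, `nlp_positive`, `all_icd`,
#'   `nlp_only`, `no_problematic_use`, and `overlap` (ALL_ICD patients who
#'   are also NLP positive). By construction
#'   `overlap == nlp_positive - nlp_only`.
#' @export
group_counts <- function(assignments) {
  c(n = nrow(assignments),
    nlp_positive = sum(assignments$nlp_positive),
    all_icd = sum(assignments$group == "ALL_ICD"),
    nlp_only = sum(assignments$group == "NLP_ONLY"),
    no_problematic_use = sum(assignments$group == "NO_PROBLEMATIC_USE"),
    overlap = sum(assignments$icd_positive & assignments$nlp_positive))
}

#' Index dates: first documentation of problematic opioid use
#'
#' The index date is the earliest of the first qualifying ICD code date and
#' the first positive-snippet note date; same-day ties resolve to the ICD
#' date.
#'
#' @param icd code table with `patient_id`, `code`, `date`.
#' @param classified classified snippets with `note_id`, `patient_id`,
#'   `label`.
#' @param notes note table with `note_id`, `note_date`, used to date
#'   positive snippets.
#' @return data.frame `patient_id`, `index_date` (Date), `source`
#'   (`"icd"`/`"nlp"`).
#' @export
compute_index_dates <- function(icd, classified, notes) {
  first_by <- function(ids, dates) {
    d <- as.Date(dates)
    keep <- !is.na(d)
    if (!any(keep)) return(data.frame(patient_id = character(),
                                      date = as.Date(character())))
    agg <- tapply(d[keep], as.character(ids[keep]), min)
    data.frame(patient_id = names(agg), date = as.Date(agg, origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  }
  icd_first <- if (!is.null(icd) && nrow(icd)) {
    qual <- .code_qualifies(icd$code)
    first_by(icd$patient_id[qual], icd$date[qual])
  } else data.frame(patient_id = character(), date = as.Date(character()))
  nlp_first <- if (!is.null(classified) && nrow(classified)) {
    pos <- classified[classified$label == "positive", , drop = FALSE]
    dates <- notes$note_date[match(pos$note_id, notes$note_id)]
    first_by(pos$patient_id, dates)
  } else data.frame(patient_id = character(), date = as.Date(character()))

  ids <- union(icd_first$patient_id, nlp_first$patient_id)
  di <- icd_first$date[match(ids, icd_first$patient_id)]
  dn <- nlp_first$date[match(ids, nlp_first$patient_id)]
  use_icd <- !is.na(di) & (is.na(dn) | di <= dn)
  data.frame(patient_id = ids,
             index_date = as.Date(ifelse(use_icd, di, dn),
                                  origin = "1970-01-01"),
             source = ifelse(use_icd, "icd", "nlp"),
             stringsAsFactors = FALSE)
}

#' Tally positive snippets by key-phrase category and patient group
#'
#' For each requested group, counts patients having at least one positive
#' snippet whose key phrase is a specific drug name, patients having at
#' least one positive snippet with another (concept) key phrase, and the
#' mean and SD of positive snippet counts among the group's NLP-positive
#' patients. A patient can appear in both count columns.
#'
#' @param classified classified snippets ([classify_snippets()] output).
#' @param lexicon a [key_phrase_lexicon()] supplying the category of each
#'   key phrase.
#' @param assignments [assign_groups()] output.
#' @param groups which groups to report; `"NLP_ICD"` denotes the overlap
#'   subgroup (ALL_ICD patients who are also NLP positive).
#' @return data.frame: `group`, `n_drug_name_patients`, `n_other_patients`,
#'   `mean_positive_snippets`, `sd_positive_snippets`.
#' @export
tally_positive_patterns <- function(classified, lexicon, assignments,
                                    groups = c("NLP_ONLY", "NLP_ICD")) {
  stopifnot(inherits(lexicon, "key_phrase_lexicon"))
  pos <- classified[classified$label == "positive", , drop = FALSE]
  cat_of <- lexicon$category[match(pos$key_phrase, lexicon$phrase)]
  pid <- as.character(pos$patient_id)
  rows <- lapply(groups, function(g) {
    members <- switch(g,
      NLP_ICD = assignments$patient_id[assignments$icd_positive &
                                       assignments$nlp_positive],
      ALL = assignments$patient_id,
      assignments$patient_id[assignments$group == g])
    in_g <- pid %in% as.character(members)
    per_patient <- table(pid[in_g])
    data.frame(
      group = g,
      n_drug_name_patients = length(unique(pid[in_g & cat_of == "drug_name"])),
      n_other_patients = length(unique(pid[in_g & cat_of == "other"])),
      mean_positive_snippets = if (length(per_patient))
        mean(as.numeric(per_patient)) else 0,
      sd_positive_snippets = if (length(per_patient) > 1L)
        stats::sd(as.numeric(per_patient)) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
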