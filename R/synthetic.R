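# Synthetic note corpora and patient cohorts with recorded ground truth.
# The corpus generator implants one templated key-phrase context per chosen
# note among neutral filler sentences; gold labels are produced by running
# the package's own extractor on each generated note and labelling every
# extracted snippet with the implanted context's polarity (filler contains
# no key phrases, so all snippets arise from the template). Negative-context
# templates are filled only with drug-name key phrases: a bare concept
# phrase such as "opioid abuse" is itself positive documentation, so
# implanting it in a negative context would make the gold label wrong.

#' Default positive/negative context template banks
#'
#' Each template contains a `{KEY}` placeholder for the implanted key
#' phrase. Positive templates describe current problematic use (some in
#' standardized/template language the rule tiers recognize, some in free
#' prose left to the SVM); negative templates mention an opioid without any
#' indication of problematic use.
#'
#' @return Character vector of templates.
#' @export
default_positive_templates <- function() c(
  "patient continues to struggle with substance abuse involving {KEY} and requests early refills",
  "admitted to abuse of prescription pain killers in particular {KEY}",
  "attends substance abuse treatment program heroin last used yesterday also misusing {KEY}",
  "alludes to self medicating on the street with {KEY} and appears to be in acute withdrawal",
  "taking additional doses of {KEY} beyond prescribed was a patient safety issue and would not be tolerated",
  "urine screen positive and concern for overuse of pain medication specifically {KEY}",
  "escalating use of {KEY} obtained from multiple providers raising concern for misuse")

#' @rdname default_positive_templates
#' @export
default_negative_templates <- function() c(
  "pt has pain mostly at night was on {KEY} and tried to change but she developed a rash",
  "patient requested no {KEY} at this visit",
  "continue tylenol and {KEY} as needed per home regimen",
  "{KEY} 4 mg tab take one tablet every four hours when needed for pain",
  "family hx of substance abuse patient currently prescribed {KEY} appropriately",
  "denies any substance misuse and takes {KEY} exactly as prescribed",
  "home medication list includes {KEY} prn for chronic knee pain")

# filler sentences: no key phrases, no rule-pattern triggers
.filler_sentences <- c(
  "vital signs stable and patient resting comfortably in the exam room",
  "reviewed laboratory results with the patient and discussed the follow up plan",
  "patient ambulating without assistance and tolerating a regular diet",
  "blood pressure well controlled on current antihypertensive therapy",
  "no acute distress noted on physical examination today",
  "follow up appointment scheduled with primary care in three months",
  "patient reports sleeping better since the last clinic visit",
  "immunizations reviewed and updated according to the schedule",
  "discussed diet and exercise recommendations at length with the patient",
  "wound healing well with no signs of infection at the incision site")

#' Plan a synthetic note corpus
#'
#' @param n_patients number of patients.
#' @param notes_per_patient notes per patient (a fixed integer).
#' @param implant_rate probability that a note carries an implanted
#'   key-phrase context (default 0.5).
#' @param positive_rate probability that an implanted context is positive
#'   (default 0.5, a balanced annotated-set condition).
#' @param positive_templates,negative_templates template banks with a
#'   `{KEY}` placeholder.
#' @param lexicon a [key_phrase_lexicon()]; negative templates draw only
#'   drug-name phrases.
#' @param seed integer seed; generation is fully reproducible under it.
#' @return A `corpus_plan` list.
#' @export
corpus_plan <- function(n_patients = 500L, notes_per_patient = 2L,
                        implant_rate = 0.5, positive_rate = 0.5,
                        positive_templates = default_positive_templates(),
                        negative_templates = default_negative_templates(),
                        lexicon = default_lexicon(), seed = 1L) {
  stopifnot(n_patients >= 1L, notes_per_patient >= 1L,
            implant_rate >= 0, implant_rate <= 1,
            positive_rate >= 0, positive_rate <= 1)
  if (length(positive_templates) == 0L || length(negative_templates) == 0L)
    stop("template banks must be non-empty")
  if (!all(grepl("{KEY}", c(positive_templates, negative_templates),
                 fixed = TRUE)))
    stop("every template must contain the {KEY} placeholder")
  structure(list(n_patients = as.integer(n_patients),
                 notes_per_patient = as.integer(notes_per_patient),
                 implant_rate = implant_rate, positive_rate = positive_rate,
                 positive_templates = positive_templates,
                 negative_templates = negative_templates,
                 lexicon = lexicon, seed = as.integer(seed)),
            class = "corpus_plan")
}

#' Generate a synthetic note corpus with gold snippet labels
#'
#' @param plan a [corpus_plan()].
#' @return list with `notes` (note_id, patient_id, note_date, note_type,
#'   text) and `gold`: the extracted snippets of every implanted note with
#'   a `label` column (`"positive"`/`"negative"`, the implanted context's
#'   polarity) and the originating `template`.
#' @export
generate_corpus <- function(plan) {
  stopifnot(inherits(plan, "corpus_plan"))
  set.seed(plan$seed)
  lex <- plan$lexicon
  drug <- lex$phrase[lex$category == "drug_name"]
  if (length(drug) == 0L)
    stop("lexicon has no drug_name phrases for negative contexts")
  note_types <- c("primary care note", "emergency dept note",
                  "mental health note", "pain clinic note",
                  "discharge summary")
  dates <- seq(as.Date("2012-01-01"), as.Date("2019-12-31"), by = "day")

  n_notes <- plan$n_patients * plan$notes_per_patient
  pid <- rep(sprintf("P%05d", seq_len(plan$n_patients)),
             each = plan$notes_per_patient)
  nid <- sprintf("N%06d", seq_len(n_notes))
  notes <- vector("list", n_notes)
  gold <- vector("list", n_notes)
  for (i in seq_len(n_notes)) {
    sent <- sample(.filler_sentences, sample(2:5, 1))
    implanted <- stats::runif(1) < plan$implant_rate
    label <- NA_character_; tmpl <- NA_character_
    if (implanted) {
      positive <- stats::runif(1) < plan$positive_rate
      label <- if (positive) "positive" else "negative"
      tmpl <- if (positive) sample(plan$positive_templates, 1)
              else sample(plan$negative_templates, 1)
      key <- if (positive) sample(lex$phrase, 1) else sample(drug, 1)
      filled <- gsub("{KEY}", key, tmpl, fixed = TRUE)
      pos <- sample(length(sent) + 1L, 1) - 1L
      sent <- append(sent, filled, after = pos)
    }
    notes[[i]] <- data.frame(
      note_id = nid[i], patient_id = pid[i],
      note_date = as.character(sample(dates, 1)),
      note_type = sample(note_types, 1),
      text = paste(sent, collapse = ". "),
      stringsAsFactors = FALSE)
    if (implanted) {
      sn <- extract_snippets(notes[[i]]$text, lex, note_id = nid[i],
                             patient_id = pid[i])
      if (nrow(sn)) {
        sn$label <- label
        sn$template <- tmpl
        gold[[i]] <- sn
      }
    }
  }
  list(notes = do.call(rbind, notes),
       gold = do.call(rbind, gold[!vapply(gold, is.null, logical(1))]))
}

#' A per-group covariate profile for cohort generation
#'
#' @param size number of patients in the group.
#' @param male proportion male.
#' @param age_mean,age_sd age at cohort entry (years), drawn
#'   Normal(mean, sd) truncated at 0.
#' @param marital,race,ethnicity named probability vectors over levels
#'   (normalized at sampling).
#' @param comorbidities named vector of Bernoulli prevalences for the 12
#'   comorbidity flags.
#' @param prior_opioid_rx,concurrent_benzodiazepine_rx prescription-flag
#'   prevalences.
#' @param enc_mean,enc_sd outpatient encounter count, Normal truncated at 0
#'   and rounded to an integer.
#' @param icd_positive probability the patient receives at least one
#'   qualifying opioid-use-disorder ICD code.
#' @return A `group_profile` list.
#' @export
group_profile <- function(size, male, age_mean, age_sd, marital, race,
                          ethnicity, comorbidities, prior_opioid_rx,
                          concurrent_benzodiazepine_rx, enc_mean, enc_sd,
                          icd_positive = 0) {
  probs <- c(male, prior_opioid_rx, concurrent_benzodiazepine_rx,
             icd_positive, comorbidities)
  if (any(probs < 0 | probs > 1))
    stop("prevalences must lie in [0, 1]")
  stopifnot(age_sd >= 0, enc_sd >= 0, size >= 1)
  structure(list(size = as.integer(size), male = male, age_mean = age_mean,
                 age_sd = age_sd, marital = marital, race = race,
                 ethnicity = ethnicity, comorbidities = comorbidities,
                 prior_opioid_rx = prior_opioid_rx,
                 concurrent_benzodiazepine_rx = concurrent_benzodiazepine_rx,
                 enc_mean = enc_mean, enc_sd = enc_sd,
                 icd_positive = icd_positive),
            class = "group_profile")
}

#' Default group profiles for the three analysis groups
#'
#' Prevalences, means and SDs for the ALL_ICD, NLP_ONLY and
#' NO_PROBLEMATIC_USE groups at their reported relative sizes; these are
#' the package's reference cohort-composition defaults. Override `sizes`
#' to rescale.
#'
#' @param sizes named or positional integer vector of group sizes (default
#'   6997, 57331, 158043).
#' @return Named list of three [group_profile()]s.
#' @export
default_group_profiles <- function(sizes = c(ALL_ICD = 6997L,
                                             NLP_ONLY = 57331L,
                                             NO_PROBLEMATIC_USE = 158043L)) {
  comorb <- function(...) {
    v <- c(...)
    names(v) <- c("hypertension", "diabetes", "depression", "ptsd", "cancer",
                  "tobacco", "alcohol", "other_drug_addictions", "tbi",
                  "anxiety", "neck_pain", "back_pain")
    v
  }
  mar <- function(...) {
    v <- c(...)
    names(v) <- c("married", "divorced", "never_married", "widowed",
                  "separated", "other")
    v
  }
  rac <- function(...) {
    v <- c(...)
    names(v) <- c("black", "white", "asian", "nhpi", "aian", "unknown")
    v
  }
  eth <- function(...) {
    v <- c(...)
    names(v) <- c("not_hispanic", "hispanic", "unknown")
    v
  }
  list(
    ALL_ICD = group_profile(
      size = sizes[[1]], male = 0.93, age_mean = 53.3, age_sd = 12.2,
      marital = mar(0.257, 0.316, 0.265, 0.045, 0.113, 0.004),
      race = rac(0.597, 0.357, 0.001, 0.004, 0.005, 0.036),
      ethnicity = eth(0.965, 0.015, 0.020),
      comorbidities = comorb(0.571, 0.221, 0.618, 0.396, 0.090, 0.620,
                             0.609, 0.666, 0.115, 0.397, 0.394, 0.570),
      prior_opioid_rx = 0.715, concurrent_benzodiazepine_rx = 0.194,
      enc_mean = 50.9, enc_sd = 49.8, icd_positive = 1),
    NLP_ONLY = group_profile(
      size = sizes[[2]], male = 0.82, age_mean = 55.4, age_sd = 16.1,
      marital = mar(0.385, 0.258, 0.228, 0.051, 0.065, 0.013),
      race = rac(0.540, 0.366, 0.010, 0.005, 0.005, 0.074),
      ethnicity = eth(0.923, 0.029, 0.048),
      comorbidities = comorb(0.535, 0.250, 0.411, 0.251, 0.121, 0.311,
                             0.238, 0.186, 0.070, 0.276, 0.313, 0.472),
      prior_opioid_rx = 0.516, concurrent_benzodiazepine_rx = 0.101,
      enc_mean = 33.4, enc_sd = 31.3, icd_positive = 0),
    NO_PROBLEMATIC_USE = group_profile(
      size = sizes[[3]], male = 0.849, age_mean = 58.8, age_sd = 18.7,
      marital = mar(0.502, 0.171, 0.156, 0.069, 0.032, 0.070),
      race = rac(0.282, 0.514, 0.012, 0.005, 0.005, 0.182),
      ethnicity = eth(0.806, 0.029, 0.165),
      comorbidities = comorb(0.458, 0.204, 0.196, 0.108, 0.129, 0.154,
                             0.092, 0.042, 0.036, 0.141, 0.182, 0.307),
      prior_opioid_rx = 0.321, concurrent_benzodiazepine_rx = 0.039,
      enc_mean = 16.2, enc_sd = 23.2, icd_positive = 0))
}

#' Plan a synthetic patient cohort
#'
#' @param groups named list of [group_profile()]s (default: the three
#'   reference groups, see [default_group_profiles()]). A single-profile
#'   list with `icd_positive` between 0 and 1 models a plain cohort in
#'   which a fraction carries qualifying codes.
#' @param seed integer seed.
#' @return A `cohort_plan` list.
#' @export
cohort_plan <- function(groups = default_group_profiles(), seed = 1L) {
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "group_profile")))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_plan")
}

# Normal truncated at zero (rejection sampling; configured moments are the
# parent-normal's, so realized moments shift upward when sd is large
# relative to mean)
.rtruncnorm0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

QUALIFYING_CODES <- c("304.00", "304.70", "305.50", "F11.10", "F11.20",
                      "F11.90")
NOISE_CODES <- c("I10", "E11.9", "F32.9", "M54.5", "F10.20", "305.1",
                 "J45.909", "K21.9")

#' Generate a synthetic patient cohort with an ICD code table
#'
#' Covariates are drawn independently per patient: Bernoulli for flags,
#' categorical draws for demographics, truncated Normal for age and
#' encounter counts. Every patient receives 0-2 non-qualifying noise codes;
#' patients selected by their group's `icd_positive` probability receive
#' 1-2 qualifying opioid-use-disorder codes.
#'
#' @param plan a [cohort_plan()].
#' @return list with `patients` (one row per patient, including the true
#'   `group`) and `icd` (`patient_id`, `code`, `date`).
#' @export
generate_cohort <- function(plan) {
  stopifnot(inherits(plan, "cohort_plan"))
  set.seed(plan$seed)
  dates <- seq(as.Date("2012-01-01"), as.Date("2019-12-31"), by = "day")
  offset <- 0L
  pats <- vector("list", length(plan$groups))
  icds <- list()
  for (gi in seq_along(plan$groups)) {
    pr <- plan$groups[[gi]]
    n <- pr$size
    id <- sprintf("C%06d", offset + seq_len(n))
    offset <- offset + n
    flags <- vapply(pr$comorbidities,
                    function(p) stats::runif(n) < p,
                    logical(n))
    if (n == 1L) flags <- matrix(flags, nrow = 1L,
                                 dimnames = list(NULL, names(pr$comorbidities)))
    df <- data.frame(
      patient_id = id,
      group = names(plan$groups)[gi],
      gender = ifelse(stats::runif(n) < pr$male, "M", "F"),
      age = .rtruncnorm0(n, pr$age_mean, pr$age_sd),
      marital_status = sample(names(pr$marital), n, replace = TRUE,
                              prob = pr$marital),
      race = sample(names(pr$race), n, replace = TRUE, prob = pr$race),
      ethnicity = sample(names(pr$ethnicity), n, replace = TRUE,
                         prob = pr$ethnicity),
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(flags))
    df$prior_opioid_rx <- stats::runif(n) < pr$prior_opioid_rx
    df$concurrent_benzodiazepine_rx <-
      stats::runif(n) < pr$concurrent_benzodiazepine_rx
    df$outpatient_encounters <- pmax(0L, as.integer(round(
      .rtruncnorm0(n, pr$enc_mean, pr$enc_sd))))
    pats[[gi]] <- df

    n_noise <- sample(0:2, n, replace = TRUE)
    noise <- data.frame(
      patient_id = rep(id, n_noise),
      code = sample(NOISE_CODES, sum(n_noise), replace = TRUE),
      date = as.character(sample(dates, sum(n_noise), replace = TRUE)),
      stringsAsFactors = FALSE)
    qual_who <- id[stats::runif(n) < pr$icd_positive]
    n_qual <- sample(1:2, length(qual_who), replace = TRUE)
    qual <- data.frame(
      patient_id = rep(qual_who, n_qual),
      code = sample(QUALIFYING_CODES, sum(n_qual), replace = TRUE),
      date = as.character(sample(dates, sum(n_qual), replace = TRUE)),
      stringsAsFactors = FALSE)
    icds[[length(icds) + 1L]] <- rbind(noise, qual)
  }
  list(patients = do.call(rbind, pats), icd = do.call(rbind, icds))
}
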