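---
title: "Phenotyping problematic opioid use from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping problematic opioid use from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opioidphen)
```

## The problem

Opioid use disorder is under-coded: many patients whose clinicians document
abuse, overuse, or addiction to prescribed or illicit opioids in free-text
notes never receive an OUD diagnostic code (ICD-9-CM 304.00, 304.70, 305.50
or the ICD-10-CM F11 family). A surveillance pipeline that reads the notes
can therefore find a substantially larger — and demographically different —
population than the coded one. `opioidphen` implements such a pipeline at
the *snippet* level: the unit of classification is a key-phrase occurrence
with up to 50 words of context on each side, not a whole document, because
opioid mentions are sparse and a local window is what a chart reviewer
actually judges.

## The classification cascade

Snippets flow through two stages.

**Stage 1 — tiered rule voting.** A library of regular expressions is
organized into four ordered tiers, applied strictly in sequence to the
lowercased raw snippet window:

1. *absolute positive* → positive. Standardized, high-precision statements
   of current problematic use: enumerated problem-list entries
   ("5. opioid dependence"), diagnoses with inline ICD/SNOMED codes,
   checked questionnaire boxes ("[x] substance abuse and/or dependence").
   Because this tier fires first, a snippet that also contains, say, an
   opioid allergy list is still classified positive.
2. *canceling* → negative. Positive-sounding language that is negated or
   not current: "former opioid dependence", denial, remission.
3. *general positive* → positive. Plain concept language such as
   "opioid abuse". This tier deliberately excludes the unqualified phrase
   "substance abuse": that phrase occurs routinely in family-history and
   program-name contexts, which tier 4 must be allowed to catch.
4. *neutral* → negative. Mentions not about the patient's current use:
   family members ("sister abuses hydrocodone"), allergy lists, medication
   directions ("take one tablet ... when needed for pain", "q2h prn").

The first tier containing any match decides the label; the order of
patterns *within* a tier can only change which pattern is reported, never
the label. If no tier matches, the rules abstain.

The shipped seed library (`inst/extdata/patterns.yml`) covers these pattern
families; it is a starting point, stored as editable YAML, because any real
deployment tunes its expression library to its own note ecology. Rule
matching operates on the raw (lowercased) window text — preprocessing is
reserved for the SVM — since the templates the rules target (numbering,
brackets, doses) live precisely in the characters preprocessing removes.

**Stage 2 — linear SVM fallback.** Snippets the rules abstain on are
preprocessed (lowercase; whitespace tokenization; non-alphanumeric
characters stripped from tokens; emptied tokens dropped — so
"ICD-9 304.00" becomes `icd9 30400`) and classified by a support vector
machine. Features are:

* counts of vocabulary *unigrams consisting entirely of letters* and
  *bigrams whose first word is letters-only and whose second word is
  letters, digits, or both* — the lexical filters discard pure numbers
  (doses, dates) as unigrams while keeping clinically meaningful
  letter–number bigrams such as `icd9 30400`;
* the 0-based position of the key phrase's first word in the preprocessed
  token stream (a key phrase at the window edge behaves differently from
  one mid-context).

Every snippet receives a label, so cascade coverage is 100% by
construction.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| window (tokens/side) | 50 | the annotation unit: key phrase ± 50 words |
| `min_document_frequency` | 2 | vocabulary sizes are corpus outcomes, not parameters; a floor of 2 removes hapax noise at desk scale |
| SVM kernel / cost | linear / 1 | the standard, reproducible choice for sparse n-gram text; no class weighting |
| `split_fraction` | 0.8 | stratified 80/20 train/held-out split under the caller's seed |
| gate `threshold` | 0.85 | minimum for each of sensitivity, specificity, PPV, accuracy (inclusive at the boundary) before a model is applied at scale |

Three-class annotations (`positive`, `suspected`, `negative`) are accepted;
`suspected` is merged into `positive` *before* the split, so training is
binary and the merge cannot leak across the partition.

## Grouping and cohort comparison

A patient is NLP-positive with ≥ 1 positive snippet and ICD-positive with
any qualifying code; `F11` is treated as a prefix family because bare F11
is a category header in ICD-10-CM. The three groups — `ALL_ICD` (any
qualifying code, possibly also NLP-positive), `NLP_ONLY`, and
`NO_PROBLEMATIC_USE` — partition the cohort, and the NLP/ICD overlap obeys
`overlap = NLP-positive − NLP_ONLY` as an arithmetic identity. Index dates
take the earliest of the first qualifying code date and the first
positive-note date; same-day ties resolve to the ICD side (an arbitrary
but recorded convention).

Group comparisons use Pearson chi-square without continuity correction
(large-sample practice; no Yates), a two-sided Welch *t* test from summary
statistics (robust to the unequal SDs these groups display), and the
absolute standardized difference:

$$\mathrm{ASD}_{bin} = \frac{|p_1-p_2|}{\sqrt{(p_1(1-p_1)+p_2(1-p_2))/2}},
\qquad
\mathrm{ASD}_{cont} = \frac{|m_1-m_2|}{\sqrt{(s_1^2+s_2^2)/2}},$$

reported as percentages. ASD > 10% flags meaningful imbalance — with
cohorts of tens of thousands, p-values alone flag trivial differences.
Raw ASDs are kept internally; display rounding is half-away-from-zero
(`round_half_up()`), since R's banker's rounding disagrees with
conventional table rounding at `.5`. Categorical variables are reported
per level as binary contrasts with one overall chi-square p-value, and no
multiple-testing correction is applied.

## What the synthetic generators emulate — and what they do not

`generate_corpus()` builds notes from neutral filler sentences plus (at
`implant_rate`) one templated key-phrase context per note, positive with
probability `positive_rate`. Defaults (500 patients × 2 notes,
`implant_rate = 0.5`, `positive_rate = 0.5`) model a balanced annotated
snippet set, the regime in which the classifier is trained; corpus-scale
prevalences (a few percent of notes carrying a key phrase, ~20% of
snippets positive) are reachable through the plan but are not the training
condition. Gold labels are produced by running the package's own extractor
on each generated note and labelling every extracted snippet with the
implanted context's polarity; filler text contains no key phrases and no
rule triggers, so ground truth covers every snippet exactly. Negative
templates are filled only with drug-name key phrases, because a concept
phrase such as "opioid abuse" *is* positive documentation and would
falsify the gold label.

Consequences to keep in mind: the synthetic corpus is linearly separable
by template vocabulary, so near-perfect held-out metrics there demonstrate
the machinery (features, split hygiene, determinism), **not** expected
performance on real notes, whose misspellings, copy-forward templates and
ambiguous prose are absent. One implant per note also understates real
snippet-per-document multiplicity.

`generate_cohort()` draws covariates independently per patient — Bernoulli
flags, categorical demographics, Normal(mean, SD) truncated at zero for
age and encounter counts — from per-group profiles whose defaults are the
package's reference composition for the three groups (group sizes
6997 / 57,331 / 158,043, rescalable). Independence is sufficient because
the comparison consumes only marginal summaries; correlated comorbidity
structure is out of scope. Note one deliberate artefact: for encounter
counts the configured SD exceeds the mean, so zero-truncation shifts the
realized moments well above the configured ones (closed-form
truncated-normal moments, asserted in the tests). Parameter-recovery
checks therefore target the prevalence covariates and age, where
truncation is negligible.

## Numerical and degenerate-input choices

* Snippet matching compares phrase tokens against tokens lowercased and
  stripped of leading/trailing punctuation, so "Oxycodone," matches; the
  window keeps the raw tokens. Greedy left-to-right longest match: at one
  position the longest phrase wins and its span is consumed ("opioid
  dependence" yields one snippet, not an extra "dependence" inside it);
  occurrences at other positions fire independently. Short notes truncate
  windows — padding would inject artificial tokens into features.
* ASD edge cases: equal inputs give 0 even when the denominator is 0;
  a zero denominator with unequal inputs is flagged `NA` with a warning.
  Undefined classifier metrics (zero denominators) are `NA`, and the gate
  fails with a reason rather than crashing.
* Determinism: extraction, rules, featurization and libsvm fitting are
  deterministic given data; all sampling (splits, generators) flows from
  explicit integer seeds.

## Problem sizes used in the shipped checks

The test suite trains on a 2,000-note separable corpus (~2,500 snippets)
for the cascade/gate checks and a 600-note corpus for unit-level model
tests; cohort parameter recovery uses 50,000 patients per compared group,
where the Monte-Carlo error of an estimated ASD is ~0.6 points,
comfortably inside the 2-point recovery bound. These sizes were chosen as
the smallest that make the binomial/Monte-Carlo error negligible relative
to the assertions.

## Known limitations

* The seed rule library is a starting point, not the production library of
  a deployed system; precision on real notes depends on local tuning.
* The SVM is a bag-of-n-grams model: no negation scope, no section logic,
  no semantic normalization (deliberate non-goals at this layer, partly
  covered by the canceling/neutral tiers).
* Document-level positivity is "≥ 1 positive snippet", which is sensitive
  to a single false-positive snippet in long notes.
* Inter-rater agreement is reported as simple percent agreement (with
  Cohen's kappa available) — adequate for two raters on a three-class
  scheme, but not chance-corrected by default.
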