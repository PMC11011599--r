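# Two-group covariate comparison: absolute standardized differences (ASD)
# with the >10% imbalance flag, Pearson chi-square for categorical
# variables, and two-sided Welch t tests for continuous variables. ASD
# follows the standard two-group standardized-difference convention:
#   binary      |p1 - p2| / sqrt[(p1(1-p1) + p2(1-p2)) / 2] * 100
#   continuous  |m1 - m2| / sqrt[(s1^2 + s2^2) / 2] * 100
# Raw (unrounded) values are carried internally; table display rounds half
# away from zero to integer percent.

#' Round half away from zero
#'
#' Display rounding for ASD percent columns (R's `round()` rounds half to
#' even, which does not match conventional table rounding).
#'
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Absolute standardized difference between two proportions
#'
#' @param p1,p2 group proportions in `[0, 1]`.
#' @return ASD as an unrounded percentage (use [round_half_up()] for table
#'   display). `NA` with a warning when the denominator is zero with
#'   `p1 != p2` (both proportions degenerate); 0 when `p1 == p2`.
#' @examples
#' round_half_up(asd_binary(0.93, 0.82))   # 34
#' round_half_up(asd_binary(0.666, 0.186)) # 111
#' @export
asd_binary <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  if (p1 == p2) return(0)
  denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  if (denom == 0) {
    warning("ASD undefined: both proportions are degenerate (0 or 1)")
    return(NA_real_)
  }
  100 * abs(p1 - p2) / denom
}

#' Absolute standardized difference between two continuous summaries
#'
#' @param m1,s1,m2,s2 group means and standard deviations.
#' @return ASD as an unrounded percentage; 0 when means are equal, `NA` with
#'   a warning when both SDs are zero with unequal means.
#' @examples
#' round_half_up(asd_continuous(53.3, 12.2, 55.4, 16.1)) # 15
#' @export
asd_continuous <- function(m1, s1, m2, s2) {
  stopifnot(s1 >= 0, s2 >= 0)
  if (m1 == m2) return(0)
  denom <- sqrt((s1^2 + s2^2) / 2)
  if (denom == 0) {
    warning("ASD undefined: zero variance in both groups with unequal means")
    return(NA_real_)
  }
  100 * abs(m1 - m2) / denom
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' No continuity correction (matching large-sample cohort comparison
#' practice); degrees of freedom k - 1.
#'
#' @param counts numeric matrix with 2 rows (groups) and k columns (levels).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("expected a 2 x k table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter))
}

#' Two-sided Welch t test from summary statistics
#'
#' @param m1,s1,n1,m2,s2,n2 means, SDs and sizes of the two groups
#'   (`n >= 2` each).
#' @return list with `statistic`, `p_value`, `df`
#'   (Welch-Satterthwaite).
#' @export
welch_t_test <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0)
    return(list(statistic = 0, p_value = 1, df = n1 + n2 - 2))
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = stat, p_value = 2 * stats::pt(-abs(stat), df), df = df)
}

#' Default covariate specification for generated cohorts
#'
#' Maps the columns produced by [generate_cohort()] to comparison types:
#' categorical (per-level binary ASDs), binary flags, and continuous
#' summaries.
#'
#' @return data.frame with columns `variable`, `column`, `type`.
#' @export
default_covariate_spec <- function() {
  rbind(
    data.frame(variable = "gender", column = "gender", type = "categorical"),
    data.frame(variable = "age", column = "age", type = "continuous"),
    data.frame(variable = "marital_status", column = "marital_status",
               type = "categorical"),
    data.frame(variable = "race", column = "race", type = "categorical"),
    data.frame(variable = "ethnicity", column = "ethnicity",
               type = "categorical"),
    data.frame(
      variable = c("hypertension", "diabetes", "depression", "ptsd",
                   "cancer", "tobacco", "alcohol", "other_drug_addictions",
                   "tbi", "anxiety", "neck_pain", "back_pain",
                   "prior_opioid_rx", "concurrent_benzodiazepine_rx"),
      column = c("hypertension", "diabetes", "depression", "ptsd",
                 "cancer", "tobacco", "alcohol", "other_drug_addictions",
                 "tbi", "anxiety", "neck_pain", "back_pain",
                 "prior_opioid_rx", "concurrent_benzodiazepine_rx"),
      type = "binary"),
    data.frame(variable = "outpatient_encounters",
               column = "outpatient_encounters", type = "continuous"))
}

.binary_row <- function(variable, level, x1, x2) {
  p1 <- mean(x1); p2 <- mean(x2)
  asd <- asd_binary(p1, p2)
  counts <- rbind(c(sum(x1), sum(!x1)), c(sum(x2), sum(!x2)))
  p <- tryCatch(chi_square_test(counts)$p_value, error = function(e) NA_real_)
  data.frame(variable = variable, level = level,
             stat1 = p1, sd1 = NA_real_, stat2 = p2, sd2 = NA_real_,
             n1 = length(x1), n2 = length(x2),
             p_value = p, asd_percent = asd,
             asd_rounded = round_half_up(asd),
             imbalanced = !is.na(asd) & asd > 10,
             stringsAsFactors = FALSE)
}

#' Build a two-group covariate comparison table
#'
#' One row per binary or continuous variable and per categorical level,
#' with group summaries, a test p-value (Pearson chi-square over the
#' variable's levels for binary/categorical, two-sided Welch t for
#' continuous), the raw and integer-rounded ASD, and the `imbalanced` flag
#' (raw ASD strictly greater than 10). Categorical variables additionally
#' report each level as a binary contrast, mirroring per-level table
#' reporting; the overall chi-square p-value is repeated on every level row.
#'
#' @param patients patient covariate table (e.g. from [generate_cohort()]).
#' @param groups length-2 character vector naming the groups to compare.
#' @param group_col column of `patients` holding group membership (default
#'   `"group"`); alternatively pass an [assign_groups()] result via
#'   `assignments` to use its `group` column.
#' @param variables covariate specification, see [default_covariate_spec()].
#' @param assignments optional [assign_groups()] output joined on
#'   `patient_id`.
#' @return data.frame of comparison rows.
#' @export
build_comparison_table <- function(patients,
                                   groups = c("ALL_ICD", "NLP_ONLY"),
                                   group_col = "group",
                                   variables = default_covariate_spec(),
                                   assignments = NULL) {
  stopifnot(length(groups) == 2L)
  if (!is.null(assignments)) {
    patients$group <- assignments$group[
      match(as.character(patients$patient_id),
            as.character(assignments$patient_id))]
    group_col <- "group"
  }
  if (!group_col %in% names(patients))
    stop("group column '", group_col, "' not found in patients table")
  g <- as.character(patients[[group_col]])
  miss <- setdiff(groups, unique(g))
  if (length(miss))
    stop("group(s) not present in data: ", paste(miss, collapse = ", "))
  d1 <- patients[g == groups[1], , drop = FALSE]
  d2 <- patients[g == groups[2], , drop = FALSE]

  rows <- lapply(seq_len(nrow(variables)), function(i) {
    v <- variables$variable[i]
    col <- variables$column[i]
    if (!col %in% names(patients)) stop("unknown variable column: ", col)
    type <- variables$type[i]
    if (type == "binary") {
      .binary_row(v, "", as.logical(d1[[col]]), as.logical(d2[[col]]))
    } else if (type == "continuous") {
      m1 <- mean(d1[[col]]); s1 <- stats::sd(d1[[col]])
      m2 <- mean(d2[[col]]); s2 <- stats::sd(d2[[col]])
      asd <- asd_continuous(m1, s1, m2, s2)
      tt <- welch_t_test(m1, s1, nrow(d1), m2, s2, nrow(d2))
      data.frame(variable = v, level = "",
                 stat1 = m1, sd1 = s1, stat2 = m2, sd2 = s2,
                 n1 = nrow(d1), n2 = nrow(d2),
                 p_value = tt$p_value, asd_percent = asd,
                 asd_rounded = round_half_up(asd),
                 imbalanced = !is.na(asd) & asd > 10,
                 stringsAsFactors = FALSE)
    } else if (type == "categorical") {
      levs <- sort(unique(as.character(patients[[col]])))
      counts <- rbind(table(factor(as.character(d1[[col]]), levels = levs)),
                      table(factor(as.character(d2[[col]]), levels = levs)))
      keep <- colSums(counts) > 0
      p <- tryCatch(chi_square_test(counts[, keep, drop = FALSE])$p_value,
                    error = function(e) NA_real_)
      out <- do.call(rbind, lapply(levs, function(l)
        .binary_row(v, l, as.character(d1[[col]]) == l,
                    as.character(d2[[col]]) == l)))
      out$p_value <- p
      out
    } else stop("unknown variable type: ", type)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  out
}
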