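# Sex-bias summaries: sample/study sex breakdowns, cell-line donor-vs-
# inferred concordance (sex "switching", e.g. through Y chromosome loss),
# score-vs-copy-number rank correlation, ATC drug-class enrichment, and
# per-drug sex profiles.

#' Enrichment configuration
#'
#' @param min_class_count classes with any tested cell below this are
#'   removed (default 5).
#' @param n_tests Bonferroni denominator; `NULL` (default) uses the number
#'   of tests actually run, or fix it (e.g. 48) for fidelity with a
#'   pre-registered test count.
#' @param alpha family-wise significance level (default 0.05).
#' @return list of class `enrichment_config`.
#' @export
enrichment_config <- function(min_class_count = 5L, n_tests = NULL,
                              alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  check_count(min_class_count, "min_class_count")
  structure(list(min_class_count = as.integer(min_class_count),
                 n_tests = n_tests, alpha = alpha),
            class = "enrichment_config")
}

#' Per-stratum sex proportions
#'
#' @param labels data.frame with a `label` column ("female"/"male"/
#'   "unlabeled") and optional stratum columns.
#' @param strata character vector of stratum column names (may be empty).
#' @return data.frame of per-stratum proportions (rows normalize to 1).
#' @export
sex_breakdown <- function(labels, strata = character()) {
  key <- if (length(strata)) {
    interaction(labels[, strata, drop = FALSE], drop = TRUE, sep = " / ")
  } else {
    factor(rep("all", nrow(labels)))
  }
  parts <- split(labels, key)
  out <- do.call(rbind, lapply(names(parts), function(s) {
    df <- parts[[s]]
    n <- nrow(df)
    data.frame(stratum = s, n = n,
               prop_female = sum(df$label == "female") / n,
               prop_male = sum(df$label == "male") / n,
               prop_unlabeled = sum(!df$label %in%
                                      c("female", "male")) / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cell-line donor-sex vs inferred-sex concordance
#'
#' @param cellmap data.frame sample_id, accession.
#' @param reference data.frame accession, donor_sex.
#' @param inferred data.frame sample_id, label, score.
#' @param min_studies,min_samples_per_study thresholds for the per-line
#'   profile table (defaults 5 and 3); pass a `study_id` column in
#'   `cellmap` to enable the study filter, else only a total-sample
#'   threshold applies.
#' @return list `switch_rates` (per donor-sex direction), `profiles`
#'   (per-line), `unknown` (samples with unknown donor sex, reported
#'   separately).
#' @export
cell_line_concordance <- function(cellmap, reference, inferred,
                                  min_studies = 5L,
                                  min_samples_per_study = 3L) {
  df <- merge(cellmap, reference, by = "accession")
  df <- merge(df, inferred, by = "sample_id")
  if (!nrow(df)) {
    return(list(switch_rates = data.frame(), profiles = data.frame(),
                unknown = data.frame()))
  }
  known <- df[df$donor_sex %in% c("female", "male") &
                df$label %in% c("female", "male"), ]
  switch_rates <- do.call(rbind, lapply(split(known, known$donor_sex),
    function(d) {
      opp <- if (d$donor_sex[1] == "male") "female" else "male"
      data.frame(donor_sex = d$donor_sex[1], n = nrow(d),
                 n_switched = sum(d$label == opp),
                 switch_rate = mean(d$label == opp))
    }))
  rownames(switch_rates) <- NULL

  prof <- do.call(rbind, lapply(split(df, df$accession), function(d) {
    n_st <- if ("study_id" %in% names(d)) {
      st <- table(d$study_id)
      sum(st >= min_samples_per_study)
    } else NA_integer_
    data.frame(accession = d$accession[1], donor_sex = d$donor_sex[1],
               n_samples = nrow(d), n_studies = n_st,
               frac_male = mean(d$label == "male"),
               frac_female = mean(d$label == "female"),
               frac_unlabeled = mean(!d$label %in% c("female", "male")),
               median_score = stats::median(d$score),
               stringsAsFactors = FALSE)
  }))
  rownames(prof) <- NULL
  if ("study_id" %in% names(df)) {
    prof <- prof[prof$n_studies >= min_studies, ]
  }
  list(switch_rates = switch_rates, profiles = prof,
       unknown = df[!df$donor_sex %in% c("female", "male"), ])
}

#' Spearman correlation of per-line median score vs chromosome copy number
#'
#' @param medians data.frame with `accession`, `median_score`,
#'   `cn_median`.
#' @return list rho, p_value, n.
#' @export
score_cnv_correlation <- function(medians) {
  ok <- stats::complete.cases(medians[, c("median_score", "cn_median")])
  d <- medians[ok, ]
  if (nrow(d) < 3) stop("need at least 3 lines with both values",
                        call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(d$median_score, d$cn_median,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}

#' ATC-class enrichment of study sex categories
#'
#' For each ATC class, two 2x2 chi-squared tests against all other classes:
#' male-only vs female-only studies, and single-sex vs mixed studies
#' (single = male-only/female-only; mixed = any category containing both
#' sexes). Classes with any tested cell below `min_class_count` are removed
#' from that test. Significance at `alpha / n_tests` (Bonferroni).
#'
#' @param study_classes data.frame study_id, atc_class (one row per pair).
#' @param categories data.frame study_id, category.
#' @param config an [enrichment_config()].
#' @return data.frame class, test, statistic, p, significant (possibly
#'   empty, with a warning when nothing survives filtering).
#' @export
atc_enrichment <- function(study_classes, categories,
                           config = enrichment_config()) {
  df <- merge(study_classes, categories, by = "study_id")
  df$mo <- df$category == "male-only"
  df$fo <- df$category == "female-only"
  df$single <- df$mo | df$fo
  df$mixedish <- df$category %in% c("mixed", "mostly-male", "mostly-female")
  classes <- sort(unique(df$atc_class))
  rows <- list()
  for (cl in classes) {
    inc <- df$atc_class == cl
    for (test in c("male_vs_female_only", "single_vs_mixed")) {
      if (test == "male_vs_female_only") {
        tab <- rbind(c(sum(inc & df$mo), sum(inc & df$fo)),
                     c(sum(!inc & df$mo), sum(!inc & df$fo)))
      } else {
        tab <- rbind(c(sum(inc & df$single), sum(inc & df$mixedish)),
                     c(sum(!inc & df$single), sum(!inc & df$mixedish)))
      }
      if (any(tab[1, ] < config$min_class_count)) next
      ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, test = test, statistic = unname(ch$statistic),
        p = ch$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no ATC classes survive the count filter")
    return(data.frame(class = character(), test = character(),
                      statistic = numeric(), p = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows)
  n_tests <- config$n_tests %||% nrow(out)
  out$significant <- out$p < config$alpha / n_tests
  rownames(out) <- NULL
  out
}

#' Per-drug sex profiles with a sex-bias flag
#'
#' Fractions of female-only / male-only / other-category studies per drug;
#' a drug is flagged biased when it has at least `min_studies` categorized
#' studies and one single-sex fraction exceeds 2/3 while the other is below
#' 1/3.
#'
#' @param pairs data.frame study_id, drug_id.
#' @param categories data.frame study_id, category.
#' @param min_studies default 3.
#' @return data.frame drug_id, n_studies, frac_female_only, frac_male_only,
#'   frac_other, biased, bias_direction.
#' @export
drug_sex_profiles <- function(pairs, categories, min_studies = 3L) {
  df <- merge(unique(pairs), categories, by = "study_id")
  out <- do.call(rbind, lapply(split(df, df$drug_id), function(d) {
    n <- nrow(d)
    ff <- mean(d$category == "female-only")
    fm <- mean(d$category == "male-only")
    biased_f <- n >= min_studies && ff > 2 / 3 && fm < 1 / 3
    biased_m <- n >= min_studies && fm > 2 / 3 && ff < 1 / 3
    data.frame(drug_id = d$drug_id[1], n_studies = n,
               frac_female_only = ff, frac_male_only = fm,
               frac_other = 1 - ff - fm,
               biased = biased_f || biased_m,
               bias_direction = if (biased_f) "female"
                                else if (biased_m) "male"
                                else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
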