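# Metadata sex-label extraction and study sex categorization.
#
# Sample sex labels are pulled from attribute key/value pairs (keys containing
# "sex"/"gender", or values with whole-word "male"/"female" matches) and
# harmonized to a closed vocabulary {female, male, mixed, unlabeled}, where
# "mixed" means a single pooled sample containing both sexes. Studies are then
# assigned one of six categories from their label composition.

#' Study categorization configuration
#'
#' @param majority_cutoff strict proportion above which a study is
#'   "mostly-male"/"mostly-female" (default 0.8).
#' @param small_study_max largest study size to which the "less than half
#'   labeled" unlabeled rule applies (default 60).
#' @param min_labeled_large minimum labeled samples for studies larger than
#'   `small_study_max` (default 30; strictly fewer means unlabeled).
#' @return list of class `category_config`.
#' @export
category_config <- function(majority_cutoff = 0.8, small_study_max = 60L,
                            min_labeled_large = 30L) {
  stopifnot(majority_cutoff > 0.5, majority_cutoff < 1)
  check_count(small_study_max, "small_study_max")
  check_count(min_labeled_large, "min_labeled_large")
  structure(list(majority_cutoff = majority_cutoff,
                 small_study_max = as.integer(small_study_max),
                 min_labeled_large = as.integer(min_labeled_large)),
            class = "category_config")
}

#' Extract candidate sex strings from attribute key/value pairs
#'
#' Returns values whose key contains "sex" or "gender" (case-insensitive),
#' plus values from any other key containing a whole-word match to "male" or
#' "female".
#'
#' @param attributes named character vector or list (names = keys) or a
#'   data.frame with columns `key`, `value`.
#' @return character vector of candidate raw values (may be empty).
#' @export
extract_sex_attributes <- function(attributes) {
  if (is.data.frame(attributes)) {
    keys <- as.character(attributes$key)
    vals <- as.character(attributes$value)
  } else {
    keys <- names(attributes) %||% rep("", length(attributes))
    vals <- as.character(unlist(attributes, use.names = FALSE))
  }
  if (!length(vals)) return(character())
  key_hit <- grepl("sex|gender", keys, ignore.case = TRUE)
  val_hit <- grepl("\\b(male|female)\\b", vals, ignore.case = TRUE)
  unique(vals[key_hit | val_hit])
}

# value -> label dictionary beyond whole-word male/female matches; the paper
# does not enumerate its table, so a small configurable set of common variants
# is shipped.
default_sex_dictionary <- function() {
  list(female = c("f", "female", "woman", "women", "girl", "xx", "fem"),
       male = c("m", "male", "man", "men", "boy", "xy"))
}

#' Normalize a raw metadata string to a canonical sex label
#'
#' Whole-word matching ensures "female" is never consumed by the substring
#' "male"; a value containing whole-word matches to both sexes (e.g. a pooled
#' sample description) maps to "mixed".
#'
#' @param raw character vector of raw values.
#' @param dictionary optional list with `female` and `male` term vectors.
#' @return character vector in \{"female", "male", "mixed", "unlabeled"\}.
#' @export
normalize_sex_value <- function(raw, dictionary = default_sex_dictionary()) {
  vapply(as.character(raw), function(v) {
    v <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "",
              norm_string(v))
    if (!nzchar(v) || is.na(v)) return("unlabeled")
    has_f <- grepl("\\bfemale\\b", v)
    has_m <- grepl("\\bmale\\b", v)
    if (has_f && has_m) return("mixed")
    if (has_f) return("female")
    if (has_m) return("male")
    dict <- dictionary
    if (v %in% dict$female) return("female")
    if (v %in% dict$male) return("male")
    if (grepl("\\b(mixed|pooled|both)\\b", v) &&
        grepl("\\bsex", v)) return("mixed")
    "unlabeled"
  }, character(1), USE.NAMES = FALSE)
}

#' Assign a study to one of six sex categories
#'
#' Rules, applied in order: (1) *unlabeled* — strictly less than half of the
#' samples labeled for studies of up to `small_study_max` samples, or strictly
#' fewer than `min_labeled_large` labeled for larger studies; (2)
#' *female-only* / *male-only* — all labeled male/female samples of one sex;
#' (3) *mostly-female* / *mostly-male* — the majority sex exceeds
#' `majority_cutoff` (strict) among male+female labels; (4) *mixed*
#' otherwise. Pooled ("mixed") sample labels count as labeled for rule (1) but
#' are excluded from the sex proportion; a labeled study with no male/female
#' labels at all is categorized "mixed".
#'
#' @param labels character vector of per-sample labels from
#'   [normalize_sex_value()]; "unlabeled" entries may be included or omitted.
#' @param n_samples total number of samples in the study (>= labeled count).
#' @param config a [category_config()].
#' @return single character category.
#' @export
categorize_study <- function(labels, n_samples = length(labels),
                             config = category_config()) {
  if (n_samples < 1) stop("study has zero samples", call. = FALSE)
  labels <- labels[!is.na(labels)]
  if (!all(labels %in% c("female", "male", "mixed", "unlabeled"))) {
    stop("labels must come from normalize_sex_value()", call. = FALSE)
  }
  n_labeled <- sum(labels != "unlabeled")
  if (n_samples <= config$small_study_max) {
    if (n_labeled < n_samples / 2) return("unlabeled")
  } else {
    if (n_labeled < config$min_labeled_large) return("unlabeled")
  }
  nf <- sum(labels == "female")
  nm <- sum(labels == "male")
  if (nf + nm == 0) return("mixed")
  if (nm == 0) return("female-only")
  if (nf == 0) return("male-only")
  pf <- nf / (nf + nm)
  if (pf > config$majority_cutoff) return("mostly-female")
  if (1 - pf > config$majority_cutoff) return("mostly-male")
  "mixed"
}

#' Label samples and categorize studies from a long metadata table
#'
#' @param meta data.frame with columns `sample_id`, `study_id`, `key`,
#'   `value` (long format; multiple rows per sample allowed).
#' @param config a [category_config()].
#' @return list with `samples` (sample_id, study_id, metadata_sex) and
#'   `studies` (study_id, n_samples, n_labeled, category).
#' @export
label_metadata_sex <- function(meta, config = category_config()) {
  stopifnot(all(c("sample_id", "study_id", "key", "value") %in% names(meta)))
  per_sample <- lapply(split(meta, meta$sample_id), function(df) {
    cand <- extract_sex_attributes(df[, c("key", "value")])
    labs <- normalize_sex_value(cand)
    labs <- labs[labs != "unlabeled"]
    lab <- if (!length(labs)) "unlabeled"
           else if (length(unique(labs)) > 1L) "unlabeled"  # conflicting
           else labs[1]
    data.frame(sample_id = df$sample_id[1], study_id = df$study_id[1],
               metadata_sex = lab, stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, per_sample)
  rownames(samples) <- NULL
  studies <- do.call(rbind, lapply(split(samples, samples$study_id),
    function(df) {
      data.frame(study_id = df$study_id[1], n_samples = nrow(df),
                 n_labeled = sum(df$metadata_sex != "unlabeled"),
                 category = categorize_study(df$metadata_sex, nrow(df),
                                             config),
                 stringsAsFactors = FALSE)
    }))
  rownames(studies) <- NULL
  list(samples = samples, studies = studies)
}
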