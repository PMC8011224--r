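# Shared fixtures. Heavy objects (corpora, fitted models) are memoized per
# test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Small swap-free corpus + fast-grid model for unit tests (seconds, not
# minutes); clean labels so the separable-by-construction CV-error bound
# applies.
small_corpus <- function() {
  cached("small_corpus", function()
    generate_corpus(sim_config(n_studies = 40, swap_rate = 0, seed = 101)))
}

small_model_fit <- function() {
  cached("small_model", function() {
    co <- small_corpus()
    fs <- feature_set(co$expr, co$genes)
    groups <- build_study_groups(co$meta[, c("sample_id", "study_id")])
    ml <- label_metadata_sex(co$meta)
    lab <- merge(ml$samples, co$samples[, c("sample_id", "platform")],
                 by = "sample_id")
    sp <- construct_train_test(lab, groups, seed = 7)
    model <- nested_cv_fit(fs$x[sp$train$sample_id, , drop = FALSE],
                           sp$train$metadata_sex, sp$train$group_id,
                           alpha_grid = c(0.5, 1), seed = 5)
    list(corpus = co, features = fs, groups = groups, labels = ml,
         split = sp, model = model)
  })
}

# Default-scale corpus and full-grid nested-CV model shared by the
# acceptance criteria (the stated world: ~200 studies, ~3000 samples).
acceptance_fit <- function() {
  cached("acceptance_fit", function() {
    co <- generate_corpus(sim_config(seed = 2024))
    fs <- feature_set(co$expr, co$genes)
    groups <- build_study_groups(co$meta[, c("sample_id", "study_id")])
    ml <- label_metadata_sex(co$meta)
    lab <- merge(ml$samples, co$samples[, c("sample_id", "platform")],
                 by = "sample_id")
    sp <- construct_train_test(lab, groups, seed = 11)
    model <- nested_cv_fit(fs$x[sp$train$sample_id, , drop = FALSE],
                           sp$train$metadata_sex, sp$train$group_id,
                           seed = 13)
    list(corpus = co, features = fs, groups = groups, labels = ml,
         split = sp, model = model)
  })
}

fixture_lexicons <- function() {
  cached("lexicons", function() {
    fx <- generate_lexicon_fixtures(1)
    list(fx = fx,
         cells = build_cell_line_lexicon(fx$cell_lines),
         drugs = build_drug_lexicon(fx$drugs, fx$control_terms))
  })
}

# Independent re-implementation of the study-category prose rules, used as
# the enumeration oracle. Deliberately written as literal case analysis.
oracle_categorize <- function(nf, nm, nmix, n_samples,
                              cutoff = 0.8, small_max = 60,
                              min_large = 30) {
  n_labeled <- nf + nm + nmix
  if (n_samples <= small_max) {
    if (n_labeled < n_samples / 2) return("unlabeled")
  } else if (n_labeled < min_large) {
    return("unlabeled")
  }
  if (nf + nm == 0) return("mixed")
  if (nf > 0 && nm == 0) return("female-only")
  if (nm > 0 && nf == 0) return("male-only")
  if (nf / (nf + nm) > cutoff) return("mostly-female")
  if (nm / (nf + nm) > cutoff) return("mostly-male")
  "mixed"
}
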