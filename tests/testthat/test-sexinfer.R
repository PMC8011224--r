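# Study groups, split construction, nested-CV model, scoring, thresholds,
# and platform QC.

test_that("study groups merge on shared samples and drop promiscuous studies", {
  mem <- data.frame(sample_id = c("s1", "s1", "s2", "s3"),
                    study_id = c("A", "B", "B", "C"))
  g <- build_study_groups(mem)
  gr <- setNames(g$groups$group_id, g$groups$study_id)
  expect_identical(unname(gr["A"]), unname(gr["B"]))
  expect_false(gr["C"] %in% gr[c("A", "B")])
  expect_length(g$removed_studies, 0)

  # a study sharing samples with 6 others is removed first
  mem2 <- data.frame(
    sample_id = c(paste0("x", 1:6), paste0("x", 1:6), "y1"),
    study_id = c(rep("HUB", 6), paste0("S", 1:6), "Z"))
  g2 <- build_study_groups(mem2)
  expect_identical(g2$removed_studies, "HUB")
  expect_true(all(paste0("S", 1:6) %in% g2$groups$study_id))

  # no sharing: every study its own group
  mem3 <- data.frame(sample_id = paste0("s", 1:4),
                     study_id = paste0("S", 1:4))
  g3 <- build_study_groups(mem3)
  expect_length(unique(g3$groups$group_id), 4L)
})

test_that("train/test split has no group leakage, caps per study, is seeded", {
  fit <- small_model_fit()
  sp <- fit$split
  expect_length(intersect(unique(sp$train$group_id),
                          unique(sp$test$group_id)), 0)
  per_study <- table(rbind(sp$train, sp$test)$study_id)
  expect_true(all(per_study <= 5))
  for (part in list(sp$train, sp$test)) {
    pm <- mean(part$metadata_sex == "male")
    expect_gte(pm, 0.45); expect_lte(pm, 0.55)
  }
  # determinism
  ml <- fit$labels
  lab <- merge(ml$samples, fit$corpus$samples[, c("sample_id", "platform")],
               by = "sample_id")
  sp2 <- construct_train_test(lab, fit$groups, seed = 7)
  expect_identical(sp$train$sample_id, sp2$train$sample_id)
  expect_identical(sp$test$sample_id, sp2$test$sample_id)
})

test_that("feature set excludes autosomes and fit rejects degenerate input", {
  fit <- small_model_fit()
  expect_false(any(grepl("^AUT", fit$features$annotation$gene_id)))
  expect_true(all(fit$features$annotation$chromosome %in% c("X", "Y")))
  x <- fit$features$x[1:20, ]
  expect_error(nested_cv_fit(x, rep("male", 20), rep("G1", 20)),
               "single class")
  x2 <- x; x2[1, 1] <- NA
  expect_error(nested_cv_fit(x2, rep(c("male", "female"), 10),
                             rep(paste0("G", 1:10), 2)), "non-finite")
})

test_that("model separates the synthetic sexes and orients coefficients", {
  fit <- small_model_fit()
  m <- fit$model
  expect_lte(min(m$median_errors), 0.02)
  ann <- fit$features$annotation
  co <- m$coefficients
  y_nz <- co[ann$gene_id[ann$chromosome == "Y"]]
  xe_nz <- co[ann$gene_id[ann$xi_status == "escape"]]
  expect_true(all(y_nz[y_nz != 0] > 0))
  expect_true(all(xe_nz[xe_nz != 0] < 0))
})

test_that("predict_scores is the logistic formula, handles missing genes", {
  fit <- small_model_fit()
  m <- fit$model
  # a sample sitting at the training feature means scores logistic(intercept)
  x0 <- matrix(m$feature_means, 1, dimnames = list("mid", m$genes))
  expect_equal(predict_scores(m, x0)$score, 1 / (1 + exp(-m$intercept)),
               tolerance = 1e-12)
  # duplicated rows give identical scores
  xx <- fit$features$x[c(1, 1, 2), ]
  rownames(xx) <- c("r1", "r2", "r3")
  sc <- predict_scores(m, xx)
  expect_identical(sc$score[1], sc$score[2])
  # dropping a model gene imputes its mean; still one score per sample
  xd <- fit$features$x[1:3, setdiff(m$genes, m$genes[1])]
  expect_equal(nrow(predict_scores(m, xd)), 3L)
  # zero overlap errors
  xz <- matrix(0, 2, 2, dimnames = list(NULL, c("no1", "no2")))
  expect_error(predict_scores(m, xz), "overlap")
})

test_that("assign_labels uses closed boundaries around the open band", {
  sc <- data.frame(sample_id = 1:5,
                   score = c(0.85, 0.50, 0.30, 0.70, 0.29))
  lab <- assign_labels(sc)$label
  expect_identical(lab, c("male", "unlabeled", "female", "male", "female"))
  expect_error(assign_labels(data.frame(score = 1.2)))
})

test_that("threshold_sweep arithmetic and trivial cases", {
  sc <- data.frame(score = c(rep(0.01, 10), rep(0.99, 10)),
                   metadata_sex = rep(c("female", "male"), each = 10))
  sw <- threshold_sweep(sc)
  expect_true(all(sw$concordance == 1))
  expect_equal(sw$fraction_labeled[sw$threshold == 0.5],
               max(sw$fraction_labeled))
  expect_error(threshold_sweep(data.frame(score = 0.5,
                                          metadata_sex = "unlabeled")),
               "metadata")
})

test_that("model JSON serialization round-trips scoring", {
  fit <- small_model_fit()
  path <- tempfile(fileext = ".json")
  write_sex_model(fit$model, path)
  m2 <- read_sex_model(path)
  x <- fit$features$x[1:10, ]
  expect_equal(predict_scores(m2, x)$score,
               predict_scores(fit$model, x)$score, tolerance = 1e-12)
  unlink(path)
})

test_that("platform QC excludes low-concordance platforms only with enough n", {
  sc <- data.frame(
    score = c(rep(c(0.99, 0.01), 50), rep(0.99, 30)),
    metadata_sex = c(rep("female", 100), rep("male", 30)),
    platform = c(rep("BAD", 100), rep("OK", 30)))
  # BAD: 50 labeled male vs metadata female + 50 correct female -> 50%
  qc <- platform_qc(sc)
  tab <- qc$table
  expect_identical(qc$excluded, "BAD")
  expect_equal(tab$concordance[tab$platform == "BAD"], 0.5)
  expect_equal(tab$status[tab$platform == "OK"], "ok")
  # platform with no labeled metadata -> insufficient, not excluded
  sc2 <- data.frame(score = rep(0.99, 5), metadata_sex = "unlabeled",
                    platform = "EMPTY")
  qc2 <- platform_qc(sc2)
  expect_identical(qc2$table$status, "insufficient")
  expect_length(qc2$excluded, 0)
})

test_that("a zero-effect platform is excluded end to end", {
  co <- generate_corpus(sim_config(n_studies = 60, n_platforms = 3,
                                   zero_effect_platforms = 3,
                                   missing_rate = 0.1, seed = 55))
  fs <- feature_set(co$expr, co$genes)
  groups <- build_study_groups(co$meta[, c("sample_id", "study_id")])
  ml <- label_metadata_sex(co$meta)
  lab <- merge(ml$samples, co$samples[, c("sample_id", "platform")],
               by = "sample_id")
  # train on informative platforms only, then QC across all
  informative <- lab[lab$platform != "P3", ]
  sp <- construct_train_test(informative, groups, seed = 19)
  m <- nested_cv_fit(fs$x[sp$train$sample_id, , drop = FALSE],
                     sp$train$metadata_sex, sp$train$group_id,
                     alpha_grid = c(0.5, 1), seed = 23)
  sc <- predict_scores(m, fs$x)
  sc <- merge(sc, lab, by = "sample_id")
  qc <- platform_qc(sc)
  expect_true("P3" %in% qc$excluded)
  expect_false(any(c("P1", "P2") %in% qc$excluded))
})

test_that("pooled samples land in the unlabeled band more often", {
  co <- generate_corpus(sim_config(n_studies = 40, frac_pooled = 0.15,
                                   seed = 61))
  fit <- small_model_fit()  # model from a corpus with the same effects
  sc <- assign_labels(predict_scores(fit$model,
                                     feature_set(co$expr, co$genes)$x))
  tr <- co$truth[match(sc$sample_id, co$truth$sample_id), ]
  rate_pooled <- mean(sc$label[tr$true_sex == "pooled"] == "unlabeled")
  rate_sexed <- mean(sc$label[tr$true_sex != "pooled"] == "unlabeled")
  expect_gt(rate_pooled, rate_sexed)
})
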