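# Sex-bias summaries and their statistics.

chisq_oracle <- function(tab) {
  # textbook formula, no continuity correction
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

test_that("sex_breakdown arithmetic and normalization", {
  lab <- data.frame(label = c(rep("female", 48), rep("male", 52)))
  bd <- sex_breakdown(lab)
  expect_equal(bd$prop_male, 0.52)
  expect_equal(bd$prop_female, 0.48)
  # strata: proportions row-normalize to 1
  lab2 <- data.frame(
    label = sample(c("female", "male", "unlabeled"), 200, replace = TRUE),
    organism = sample(c("human", "mouse"), 200, replace = TRUE))
  bd2 <- sex_breakdown(lab2, "organism")
  expect_true(all(abs(bd2$prop_female + bd2$prop_male +
                        bd2$prop_unlabeled - 1) < 1e-12))
})

test_that("configured sex ratio is recovered within binomial error", {
  co <- generate_corpus(sim_config(frac_single_sex = 0, frac_pooled = 0,
                                   frac_cellline_studies = 0,
                                   swap_rate = 0, missing_rate = 0,
                                   seed = 19))
  bd <- sex_breakdown(data.frame(label = co$truth$true_sex))
  se <- sqrt(0.25 / nrow(co$truth))
  expect_lt(abs(bd$prop_male - 0.5), 4 * se)
})

test_that("cell-line switch rates are arithmetic on mapped samples", {
  cellmap <- data.frame(sample_id = sprintf("s%02d", 1:12),
                        accession = c(rep("CL1", 10), "CL2", "CL3"))
  ref <- data.frame(accession = c("CL1", "CL2", "CL3"),
                    donor_sex = c("male", "female", "unknown"))
  inf <- data.frame(sample_id = sprintf("s%02d", 1:12),
                    label = c(rep("female", 4), rep("male", 6), "male",
                              "female"),
                    score = c(rep(0.1, 4), rep(0.9, 6), 0.9, 0.2))
  res <- cell_line_concordance(cellmap, ref, inf)
  sr <- res$switch_rates
  expect_equal(sr$switch_rate[sr$donor_sex == "male"], 0.4)     # 4/10
  expect_equal(sr$switch_rate[sr$donor_sex == "female"], 1.0)   # 1/1
  expect_identical(res$unknown$accession, "CL3")                # reported
  prof <- res$profiles
  expect_equal(prof$median_score[prof$accession == "CL1"], 0.9)
})

test_that("synthetic Y-loss lines switch male->female at the silencing rate", {
  co <- generate_corpus(sim_config(n_studies = 120,
                                   frac_cellline_studies = 0.5,
                                   cellline_yloss_rate = 0.5,
                                   frac_yloss_lines = 1, seed = 99))
  tr <- co$truth[!is.na(co$truth$cell_line), ]
  # expression-faithful labels: silenced Y reads as female
  inf <- data.frame(sample_id = tr$sample_id,
                    label = ifelse(tr$y_silenced, "female", tr$true_sex),
                    score = ifelse(tr$y_silenced, 0.02,
                                   ifelse(tr$true_sex == "male", 0.98,
                                          0.02)))
  cellmap <- data.frame(sample_id = tr$sample_id,
                        accession = tr$cell_line,
                        study_id = tr$study_id)
  res <- cell_line_concordance(cellmap, co$cell_lines, inf)
  sr <- res$switch_rates
  m <- sr[sr$donor_sex == "male", ]
  expect_gt(m$n, 100)
  expect_lt(abs(m$switch_rate - 0.5), 3 * sqrt(0.25 / m$n))
  expect_equal(sr$switch_rate[sr$donor_sex == "female"], 0)
})

test_that("Spearman of medians: monotone fixtures and the permutation null", {
  d <- data.frame(accession = letters[1:10],
                  median_score = seq(0.1, 1, by = 0.1),
                  cn_median = 1:10)
  expect_equal(score_cnv_correlation(d)$rho, 1)
  d$cn_median <- 10:1
  expect_equal(score_cnv_correlation(d)$rho, -1)
  expect_error(score_cnv_correlation(d[1:2, ]), "at least 3")
  # random permutation fixture lands inside the permutation 95% band
  withr::with_seed(45, {
    dd <- data.frame(accession = as.character(1:45),
                     median_score = runif(45),
                     cn_median = sample(45))
    obs <- score_cnv_correlation(dd)$rho
    null <- replicate(2000, cor(rank(dd$median_score),
                                rank(sample(dd$cn_median))))
    band <- quantile(null, c(0.025, 0.975))
    expect_gt(obs, band[1]); expect_lt(obs, band[2])
  })
})

test_that("ATC enrichment filters small classes and flags by Bonferroni", {
  # "rest" is the other classified study-class pairs
  cats <- data.frame(
    study_id = sprintf("st%03d", 1:160),
    category = c(rep("male-only", 80), rep("female-only", 80)))
  # class A heavily male-only; B and D balanced; C too small
  pairs <- rbind(
    data.frame(study_id = sprintf("st%03d", c(1:35, 81:85)),
               atc_class = "A"),
    data.frame(study_id = sprintf("st%03d", c(36:65, 86:115)),
               atc_class = "B"),
    data.frame(study_id = sprintf("st%03d", c(66, 116, 117)),
               atc_class = "C"),
    data.frame(study_id = sprintf("st%03d", c(41:80, 121:160)),
               atc_class = "D"))
  res <- atc_enrichment(pairs, cats, enrichment_config(n_tests = 48))
  expect_false("C" %in% res$class)  # any tested cell < 5 -> removed
  a <- res[res$class == "A" & res$test == "male_vs_female_only", ]
  expect_lt(a$p, 0.05 / 48)
  expect_true(a$significant)
  # statistic agrees with the textbook formula: A is 35 male-only / 5
  # female-only, the remaining classified pairs are 71 / 72
  tab <- rbind(c(35, 5), c(71, 72))
  expect_equal(a$statistic, chisq_oracle(tab), tolerance = 1e-8)
  b <- res[res$class == "B" & res$test == "male_vs_female_only", ]
  expect_false(b$significant)
  # identical proportions across two classes: statistic 0, p = 1
  cats2 <- data.frame(study_id = sprintf("q%02d", 1:40),
                      category = rep(c("male-only", "female-only"), 20))
  pairs2 <- rbind(
    data.frame(study_id = sprintf("q%02d", 1:20), atc_class = "X"),
    data.frame(study_id = sprintf("q%02d", 21:40), atc_class = "Y"))
  res2 <- atc_enrichment(pairs2, cats2, enrichment_config(n_tests = 48))
  mvf <- res2[res2$class == "X" & res2$test == "male_vs_female_only", ]
  expect_equal(mvf$statistic, 0)
  expect_equal(mvf$p, 1)
  expect_false(mvf$significant)
  # nothing survives -> empty table with warning
  expect_warning(
    res3 <- atc_enrichment(pairs2[1:3, ], cats2,
                           enrichment_config(min_class_count = 50)),
    "survive")
  expect_equal(nrow(res3), 0L)
})

test_that("enrichment is invariant to row order", {
  cats <- data.frame(study_id = sprintf("s%03d", 1:100),
                     category = rep(c("male-only", "female-only", "mixed",
                                      "mixed"), 25))
  pairs <- data.frame(study_id = sprintf("s%03d", c(1:30, 51:70)),
                      atc_class = rep(c("L", "N"), 25))
  r1 <- atc_enrichment(pairs, cats)
  perm <- withr::with_seed(3, sample(nrow(pairs)))
  r2 <- atc_enrichment(pairs[perm, ], cats[sample(nrow(cats)), ])
  expect_equal(r1[order(r1$class, r1$test), ],
               r2[order(r2$class, r2$test), ], ignore_attr = TRUE)
})

test_that("drug sex profiles implement the 2/3 - 1/3 bias rule", {
  cats <- data.frame(study_id = paste0("d", 1:9),
                     category = c("male-only", "male-only", "male-only",
                                  "female-only", "male-only", "mixed",
                                  "female-only", "female-only", "mixed"))
  pairs <- data.frame(study_id = paste0("d", c(1:3, 4:6, 7:8, 9)),
                      drug_id = c("MALE3", "MALE3", "MALE3",
                                  "EVEN", "EVEN", "EVEN",
                                  "TWOF", "TWOF", "LONE"))
  prof <- drug_sex_profiles(pairs, cats)
  p <- function(id) prof[prof$drug_id == id, ]
  expect_true(p("MALE3")$biased)
  expect_identical(p("MALE3")$bias_direction, "male")
  expect_false(p("EVEN")$biased)     # 1/3 each way
  expect_false(p("TWOF")$biased)     # only 2 studies
  expect_true(all(abs(prof$frac_female_only + prof$frac_male_only +
                        prof$frac_other - 1) < 1e-12))
})
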