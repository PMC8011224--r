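# Mixture clustering, swap flags, mismatch rates, consensus, baseline
# labeler.

mk_scores <- function(x, study = "S") {
  data.frame(sample_id = sprintf("s%03d", seq_along(x)), score = x,
             study_id = study, stringsAsFactors = FALSE)
}

# direct density recomputation from fitted parameters (independent of the
# EM code path)
mixture_loglik <- function(fit, x) {
  G <- fit$n_components
  dens <- sapply(seq_len(G), function(k)
    fit$weights[k] * stats::dnorm(x, fit$means[k], sqrt(fit$variances[k])))
  dens <- matrix(dens, length(x), G)
  if (fit$noise) dens <- cbind(dens, fit$weights[G + 1])
  sum(log(rowSums(dens)))
}

test_that("point-like two-group study is a clean two-component fit", {
  sc <- mk_scores(c(rep(0.02, 10), rep(0.98, 10)))
  fit <- fit_study_mixture(sc, seed = 1)
  expect_equal(fit$n_components, 2L)
  expect_false(fit$discarded)
  expect_equal(sort(fit$means), c(0.02, 0.98), tolerance = 0.01)
  expect_false(fit$noise)  # nothing in the unclassified band
})

test_that("a single tight cluster is selected as one component by BIC", {
  sc <- mk_scores(0.9 + seq(-0.03, 0.03, length.out = 12))
  fit <- fit_study_mixture(sc, seed = 1)
  expect_equal(fit$n_components, 1L)
  expect_identical(fit$reason, "single_component")
  # direct check: the 2-component BIC really is worse
  expect_gt(fit$bic_by_g[2], fit$bic_by_g[1])
})

test_that("two tight clusters closer than 0.3 are discarded", {
  x <- c(rep(0.10, 50) + seq(-0.005, 0.005, length.out = 50),
         rep(0.35, 50) + seq(-0.005, 0.005, length.out = 50))
  fit <- fit_study_mixture(mk_scores(x), seed = 1)
  expect_equal(fit$n_components, 2L)
  expect_lt(abs(diff(fit$means)), 0.3)
  expect_true(fit$discarded)
  expect_identical(fit$reason, "low_separation")
})

test_that("BIC equals k ln n - 2 lnL recomputed from the parameters", {
  sc <- mk_scores(c(0.04, 0.05, 0.06, 0.07, 0.93, 0.94, 0.95, 0.96))
  fit <- fit_study_mixture(sc, seed = 1)
  ll <- mixture_loglik(fit, sc$score)
  expect_equal(fit$loglik, ll, tolerance = 1e-9)
  expect_equal(fit$bic, fit$n_params * log(8) - 2 * ll, tolerance = 1e-9)
})

test_that("EM objective is non-decreasing on every fixture", {
  fixtures <- list(
    c(rep(0.02, 10), rep(0.98, 10)),
    0.9 + seq(-0.03, 0.03, length.out = 12),
    c(0.05, 0.1, 0.2, 0.4, 0.5, 0.6, 0.85, 0.9, 0.95, 0.99),
    withr::with_seed(3, pmin(pmax(c(rnorm(15, 0.1, 0.05),
                                    rnorm(15, 0.9, 0.05)), 0), 1)))
  for (x in fixtures) {
    fit <- fit_study_mixture(mk_scores(x), seed = 1)
    for (trace in fit$objective_traces) {
      expect_true(all(diff(trace) >= -1e-8))
    }
  }
})

test_that("noise term follows the unclassified-band rules", {
  # some in-band samples, fraction <= 1/3: noise on
  x <- c(rep(0.02, 8), rep(0.98, 8), 0.45, 0.5)
  fit <- fit_study_mixture(mk_scores(x), seed = 1)
  expect_true(fit$noise)
  # more than 1/3 in band: noise off
  x2 <- c(rep(0.02, 4), rep(0.98, 4), seq(0.35, 0.65, length.out = 5))
  fit2 <- fit_study_mixture(mk_scores(x2), seed = 1)
  expect_false(fit2$noise)
  # no in-band samples: noise off
  expect_false(fit_study_mixture(mk_scores(c(rep(0.1, 5), rep(0.9, 5))),
                                 seed = 1)$noise)
  expect_error(fit_study_mixture(mk_scores(c(0.1, 0.9, 0.5))), "at least 4")
})

test_that("flag_swaps implements the posterior rules", {
  x <- c(rep(0.02, 14), 0.03, rep(0.98, 14), 0.97, 0.5)
  sc <- mk_scores(x)
  fit <- fit_study_mixture(sc, seed = 1)
  meta <- c(rep("female", 14), "male",     # s015 is a swapped male label
            rep("male", 14), "female",     # s030 is a swapped female label
            "female")                      # in-band sample
  fl <- flag_swaps(fit, meta)
  expect_identical(fl$flag[15], "mismatch")
  expect_identical(fl$flag[30], "mismatch")
  expect_true(all(fl$flag[c(1:14, 16:29)] == "match"))
  expect_identical(fl$flag[31], "unclassified")  # captured by noise
  # metadata-free samples get NA
  meta2 <- meta; meta2[1] <- "unlabeled"
  expect_true(is.na(flag_swaps(fit, meta2)$flag[1]))
  # discarded fits refuse to flag
  bad <- fit_study_mixture(mk_scores(0.9 + seq(-0.02, 0.02,
                                               length.out = 10)), seed = 1)
  expect_error(flag_swaps(bad, rep("male", 10)), "discarded")
})

test_that("flags are invariant to sample order and restarts are stable", {
  x <- withr::with_seed(8, pmin(pmax(c(rnorm(12, 0.08, 0.04),
                                       rnorm(8, 0.93, 0.04)), 0), 1))
  sc <- mk_scores(x)
  meta <- c(rep("female", 12), rep("male", 8))
  f1 <- flag_swaps(fit_study_mixture(sc, seed = 1), meta)
  perm <- withr::with_seed(10, sample(nrow(sc)))
  f2 <- flag_swaps(fit_study_mixture(sc[perm, ], seed = 1), meta[perm])
  expect_identical(f1$flag[match(f2$sample_id, f1$sample_id)], f2$flag)
  # different seed, same deterministic restarts -> same selected model
  f3 <- fit_study_mixture(sc, seed = 99)
  expect_equal(sort(f3$means), sort(fit_study_mixture(sc, seed = 1)$means),
               tolerance = 1e-8)
})

test_that("simple mismatch rates and chi-squared stratification", {
  labels <- data.frame(
    sample_id = sprintf("s%02d", 1:20),
    study_id = rep(c("MIX", "SGL"), each = 10),
    metadata_sex = c(rep(c("female", "male"), 5), rep("male", 10)),
    expr_label = c(rep(c("female", "male"), 4), "male", "male",
                   rep("male", 10)),
    stringsAsFactors = FALSE)
  cats <- data.frame(study_id = c("MIX", "SGL"),
                     category = c("mixed", "male-only"),
                     n_samples = c(10, 10))
  res <- simple_mismatch_rates(labels, cats)
  sr <- res$sample_rates
  expect_equal(sr$rate[sr$stratum == "mixed"], 0.1)
  expect_equal(sr$rate[sr$stratum == "single"], 0)
  expect_equal(res$study_rates$rate[res$study_rates$stratum == "mixed"], 1)
  expect_s3_class(res$chisq, "htest")
  # no mismatches anywhere: rates 0, p = 1
  labels2 <- labels; labels2$expr_label <- labels2$metadata_sex
  res2 <- simple_mismatch_rates(labels2, cats)
  expect_true(all(res2$sample_rates$rate == 0))
  expect_equal(res2$chisq$p.value, 1)
})

test_that("consensus mismatch is conservative", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:10), study_id = "A",
                     metadata_sex = rep(c("female", "male"), each = 5))
  lab <- function(v) data.frame(sample_id = meta$sample_id, label = v)
  all_m <- lab(rep("male", 10))
  mixed <- lab(c("male", "female", rep("female", 3), rep("male", 5)))
  abst <- lab(rep("unlabeled", 10))
  res <- consensus_mismatch(meta, list(all_m, all_m, all_m))
  expect_identical(res$flag[1], "mismatch")      # F meta, all vote M
  res2 <- consensus_mismatch(meta, list(all_m, mixed, all_m))
  expect_identical(res2$flag[2], "match")        # one method agrees
  res3 <- consensus_mismatch(meta, list(abst, abst))
  expect_true(all(res3$flag == "insufficient"))
  # ineligible study (fewer than 5 per sex) yields no rows
  meta2 <- meta[1:8, ]
  expect_equal(nrow(consensus_mismatch(meta2, list(all_m, all_m))), 0L)
})

test_that("baseline cluster labeler splits on mean Y expression", {
  co <- generate_corpus(sim_config(n_studies = 6, frac_single_sex = 0,
                                   frac_pooled = 0, swap_rate = 0,
                                   frac_cellline_studies = 0, seed = 71))
  y <- co$expr[, co$genes$gene_id[co$genes$chromosome == "Y"]]
  one <- co$truth$study_id == co$truth$study_id[1]
  lab <- baseline_cluster_labeler(y[one, ])
  expect_identical(lab$label, co$truth$true_sex[one])
  # constant matrix and tiny input abstain
  expect_true(all(baseline_cluster_labeler(matrix(1, 6, 3))$label ==
                    "unlabeled"))
  expect_true(all(baseline_cluster_labeler(y[1:3, ])$label == "unlabeled"))
})
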