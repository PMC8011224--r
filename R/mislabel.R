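# Metadata misannotation estimation.
#
# Three complementary procedures: (1) mismatch rates between metadata and
# expression-based labels in large single- vs mixed-sex studies, compared by
# chi-squared; (2) a conservative consensus over several expression-based
# labelers; (3) per-study clustering of sample sex scores with a 1- or
# 2-component unequal-variance Gaussian mixture (EM with an inverse-gamma
# variance prior and an optional uniform noise component), model choice by
# BIC, a minimum between-cluster separation, and a 0.95 posterior cutoff for
# high-confidence swap flags.

#' Mixture clustering configuration
#'
#' @param prior_scale scale of the inverse-gamma variance prior (default
#'   0.15, on the variance scale of the \[0, 1\] score axis).
#' @param posterior_cutoff cluster-assignment posterior for high-confidence
#'   flags (default 0.95).
#' @param min_separation minimum |difference of cluster means| (default 0.3).
#' @param noise_band open score interval treated as unclassified
#'   (default (0.3, 0.7)).
#' @param noise_disable_frac if more than this fraction of a study's scores
#'   fall in the noise band, the noise term is dropped (default 1/3).
#' @param max_iter,tol,n_restarts EM controls.
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(prior_scale = 0.15, posterior_cutoff = 0.95,
                           min_separation = 0.3, noise_band = c(0.3, 0.7),
                           noise_disable_frac = 1 / 3, max_iter = 500L,
                           tol = 1e-8, n_restarts = 5L) {
  stopifnot(posterior_cutoff > 0, posterior_cutoff < 1,
            min_separation >= 0, min_separation <= 1,
            prior_scale > 0, length(noise_band) == 2L,
            noise_band[1] < noise_band[2])
  structure(list(prior_scale = prior_scale,
                 posterior_cutoff = posterior_cutoff,
                 min_separation = min_separation, noise_band = noise_band,
                 noise_disable_frac = noise_disable_frac,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts)),
            class = "cluster_config")
}

# One EM run from given initial responsibilities. MAP EM: the variance
# M-step maximizes likelihood x inverse-gamma prior IG(shape = 1/2,
# rate = prior_scale/2), giving sigma2 = (S_k + prior_scale)/(n_k + 3); the
# monotone quantity is therefore the penalized objective (loglik + log
# prior), which is recorded per iteration alongside the raw loglik.
em_run <- function(x, resp, noise, cfg) {
  n <- length(x)
  G <- ncol(resp) - as.integer(noise)
  a <- 0.5
  b <- cfg$prior_scale / 2
  obj_trace <- numeric(0)
  ll <- -Inf
  for (it in seq_len(cfg$max_iter)) {
    ## M-step
    nk <- colSums(resp)
    w <- nk / n
    mu <- numeric(G); s2 <- numeric(G)
    for (k in seq_len(G)) {
      if (nk[k] < 1e-12) {
        mu[k] <- mean(x); s2[k] <- cfg$prior_scale / 3
      } else {
        mu[k] <- sum(resp[, k] * x) / nk[k]
        S <- sum(resp[, k] * (x - mu[k])^2)
        s2[k] <- (S + 2 * b) / (nk[k] + 2 * a + 2)
      }
    }
    ## E-step
    dens <- vapply(seq_len(G), function(k)
      w[k] * stats::dnorm(x, mu[k], sqrt(s2[k])), numeric(n))
    dens <- matrix(dens, n, G)
    if (noise) dens <- cbind(dens, w[G + 1] * 1)  # uniform on [0, 1]
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    resp <- dens / tot
    ll_new <- sum(log(tot))
    obj <- ll_new + sum(-(a + 1) * log(s2) - b / s2)
    obj_trace <- c(obj_trace, obj)
    if (it > 1 && abs(obj - obj_prev) < cfg$tol) {
      ll <- ll_new
      break
    }
    obj_prev <- obj
    ll <- ll_new
  }
  k_free <- 2 * G + (G + as.integer(noise) - 1)
  list(G = G, noise = noise, weights = w, means = mu, variances = s2,
       posteriors = resp, loglik = ll, objective_trace = obj_trace,
       bic = k_free * log(n) - 2 * ll, n_params = k_free,
       converged = length(obj_trace) < cfg$max_iter)
}

# Deterministic initial responsibilities for restart r: in-band samples start
# fully owned by the noise term (when present), the rest hard-assigned to the
# nearer of two quantile-spread initial means.
em_init_resp <- function(x, G, noise, cfg, r) {
  n <- length(x)
  probs <- list(c(0.1, 0.9), c(0.25, 0.75), c(0, 1), c(1 / 3, 2 / 3),
                c(0.4, 0.6))[[((r - 1) %% 5) + 1]]
  resp <- matrix(0, n, G + as.integer(noise))
  if (G == 1) {
    resp[, 1] <- 1
  } else {
    mu0 <- stats::quantile(x, probs, names = FALSE)
    assign1 <- abs(x - mu0[1]) <= abs(x - mu0[2])
    resp[cbind(seq_len(n), ifelse(assign1, 1L, 2L))] <- 1
  }
  if (noise) {
    inband <- x > cfg$noise_band[1] & x < cfg$noise_band[2]
    resp[inband, ] <- 0
    resp[inband, G + 1] <- 1
  }
  resp
}

#' Fit the per-study score mixture
#'
#' Fits 1- and 2-component unequal-variance Gaussian mixtures (each from
#' `n_restarts` deterministic initializations, best penalized objective kept)
#' to a study's sample sex scores; a uniform noise component on \[0, 1\] is
#' included iff any score falls in `noise_band` and the in-band fraction is
#' at most `noise_disable_frac`, initialized to exactly the in-band samples.
#' BIC (`k ln n - 2 lnL`) selects the component count. One-component fits are
#' discarded (`single_component`), as are two-component fits whose means are
#' closer than `min_separation` (`low_separation`).
#'
#' @param scores data.frame with `sample_id`, `score`, and optionally
#'   `study_id` (single study).
#' @param config a [cluster_config()].
#' @param seed integer seed (initializations are deterministic given it).
#' @return object of class `study_cluster_fit`.
#' @export
fit_study_mixture <- function(scores, config = cluster_config(), seed = 1L) {
  x <- scores$score
  stopifnot(all(x >= 0 & x <= 1))
  if (length(x) < 4) stop("need at least 4 scored samples", call. = FALSE)
  inband <- x > config$noise_band[1] & x < config$noise_band[2]
  noise <- any(inband) && mean(inband) <= config$noise_disable_frac

  fits <- lapply(1:2, function(G) {
    runs <- lapply(seq_len(config$n_restarts), function(r) {
      em_run(x, em_init_resp(x, G, noise, config, r), noise, config)
    })
    runs[[which.max(vapply(runs, function(f)
      utils::tail(f$objective_trace, 1), numeric(1)))]]
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]

  discarded <- FALSE; reason <- NA_character_
  if (!best$converged) {
    discarded <- TRUE; reason <- "non_convergence"
  } else if (best$G == 1) {
    discarded <- TRUE; reason <- "single_component"
  } else if (abs(diff(best$means)) < config$min_separation) {
    discarded <- TRUE; reason <- "low_separation"
  }
  structure(list(
    study_id = scores$study_id[1] %||% NA_character_,
    sample_id = scores$sample_id,
    n_components = best$G, noise = best$noise,
    means = best$means, variances = best$variances, weights = best$weights,
    posteriors = best$posteriors, loglik = best$loglik, bic = best$bic,
    bic_by_g = vapply(fits, `[[`, numeric(1), "bic"),
    objective_trace = best$objective_trace,
    objective_traces = lapply(fits, `[[`, "objective_trace"),
    n_params = best$n_params,
    discarded = discarded, reason = reason, config = config, seed = seed),
    class = "study_cluster_fit")
}

#' @export
print.study_cluster_fit <- function(x, ...) {
  cat(sprintf("study_cluster_fit: %d samples, %d component(s)%s, BIC %.2f%s\n",
              length(x$sample_id), x$n_components,
              if (x$noise) " + noise" else "", x$bic,
              if (x$discarded) paste0(" [discarded: ", x$reason, "]") else ""))
  invisible(x)
}

#' Flag high-confidence swaps from a study mixture fit
#'
#' Clusters are oriented by mean score (higher mean = male). A sample whose
#' posterior for some cluster exceeds `posterior_cutoff` is a `mismatch` if
#' that cluster's sex contradicts the metadata sex, else a `match`; a sample
#' whose largest posterior belongs to the noise term is `unclassified`;
#' anything else is `unclear`. Samples without metadata sex get NA.
#'
#' @param fit a non-discarded `study_cluster_fit`.
#' @param metadata_sex character vector aligned with `fit$sample_id`
#'   ("female"/"male"/other).
#' @param config a [cluster_config()].
#' @return data.frame sample_id, flag, posterior, component.
#' @export
flag_swaps <- function(fit, metadata_sex, config = cluster_config()) {
  stopifnot(inherits(fit, "study_cluster_fit"))
  if (fit$discarded) stop("fit was discarded: ", fit$reason, call. = FALSE)
  stopifnot(length(metadata_sex) == length(fit$sample_id))
  ord <- order(fit$means)                     # low mean first -> female
  cluster_sex <- character(fit$n_components)
  cluster_sex[ord] <- c("female", "male")
  post <- fit$posteriors
  G <- fit$n_components
  flags <- character(length(fit$sample_id))
  best_p <- numeric(length(flags)); best_k <- integer(length(flags))
  for (i in seq_along(flags)) {
    pi <- post[i, ]
    k <- which.max(pi)
    best_p[i] <- pi[k]; best_k[i] <- k
    if (fit$noise && k == G + 1) {
      flags[i] <- "unclassified"
    } else if (pi[k] > config$posterior_cutoff) {
      if (!metadata_sex[i] %in% c("female", "male")) {
        flags[i] <- NA_character_
      } else {
        flags[i] <- if (cluster_sex[k] == metadata_sex[i]) "match"
                    else "mismatch"
      }
    } else {
      flags[i] <- "unclear"
    }
  }
  data.frame(sample_id = fit$sample_id, flag = flags, posterior = best_p,
             component = ifelse(fit$noise & best_k == G + 1, "noise",
                                cluster_sex[pmin(best_k, G)]),
             stringsAsFactors = FALSE)
}

#' Cluster-and-flag across all studies of a score table
#'
#' @param scores data.frame with `sample_id`, `study_id`, `score`,
#'   `metadata_sex`.
#' @param config a [cluster_config()].
#' @param seed integer seed.
#' @param min_samples studies with fewer scored samples are skipped.
#' @return list `flags` (per-sample) and `studies` (per-study fit summary).
#' @export
flag_swaps_all <- function(scores, config = cluster_config(), seed = 1L,
                           min_samples = 4L) {
  res_f <- list(); res_s <- list()
  for (sid in unique(scores$study_id)) {
    df <- scores[scores$study_id == sid, ]
    if (nrow(df) < min_samples) next
    fit <- fit_study_mixture(df, config, seed)
    res_s[[sid]] <- data.frame(
      study_id = sid, n = nrow(df), n_components = fit$n_components,
      mean1 = fit$means[1], mean2 = fit$means[2][1] %||% NA_real_,
      noise = fit$noise, discarded = fit$discarded, reason = fit$reason,
      stringsAsFactors = FALSE)
    if (!fit$discarded) {
      fl <- flag_swaps(fit, df$metadata_sex, config)
      fl$study_id <- sid
      res_f[[sid]] <- fl
    }
  }
  list(flags = if (length(res_f)) do.call(rbind, res_f) else NULL,
       studies = if (length(res_s)) do.call(rbind, res_s) else NULL)
}

#' Mismatch rates in large single- vs mixed-sex studies
#'
#' A sample mismatch is a metadata female/male label contradicted by the
#' expression label (unlabeled samples leave the denominator); a mismatched
#' study contains at least one such sample. Strata are single-sex
#' (female-only/male-only) vs mixed studies of at least `min_study_size`
#' samples; "mostly-" categories are excluded as ambiguous.
#'
#' @param labels data.frame with `sample_id`, `study_id`, `metadata_sex`,
#'   `expr_label`.
#' @param categories data.frame with `study_id`, `category`, `n_samples`.
#' @param min_study_size default 10.
#' @return list with `sample_rates`, `study_rates` (per-stratum data.frames)
#'   and `chisq` (htest or NULL when a stratum is empty).
#' @export
simple_mismatch_rates <- function(labels, categories, min_study_size = 10L) {
  cats <- categories[categories$n_samples >= min_study_size, ]
  stratum <- ifelse(cats$category %in% c("female-only", "male-only"),
                    "single", ifelse(cats$category == "mixed", "mixed", NA))
  cats$stratum <- stratum
  cats <- cats[!is.na(cats$stratum), ]
  df <- merge(labels, cats[, c("study_id", "stratum")], by = "study_id")
  df <- df[df$metadata_sex %in% c("female", "male") &
             df$expr_label %in% c("female", "male"), ]
  df$mismatch <- df$metadata_sex != df$expr_label

  per_stratum <- function(f) do.call(rbind, lapply(split(df, df$stratum), f))
  sample_rates <- per_stratum(function(d)
    data.frame(stratum = d$stratum[1], n = nrow(d),
               n_mismatch = sum(d$mismatch), rate = mean(d$mismatch)))
  study_rates <- per_stratum(function(d) {
    by_study <- tapply(d$mismatch, d$study_id, any)
    data.frame(stratum = d$stratum[1], n_studies = length(by_study),
               n_mismatched = sum(by_study), rate = mean(by_study))
  })
  chisq <- NULL
  if (length(unique(df$stratum)) == 2 && all(sample_rates$n > 0)) {
    tab <- cbind(sample_rates$n_mismatch,
                 sample_rates$n - sample_rates$n_mismatch)
    if (any(colSums(tab) == 0)) {
      # identical proportions (e.g. zero mismatches in both strata)
      chisq <- structure(list(statistic = c("X-squared" = 0),
                              parameter = c(df = 1), p.value = 1,
                              method = paste("Pearson's Chi-squared test",
                                             "(degenerate margin)")),
                         class = "htest")
    } else {
      chisq <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    }
  }
  rownames(sample_rates) <- rownames(study_rates) <- NULL
  list(sample_rates = sample_rates, study_rates = study_rates,
       chisq = chisq)
}

#' Conservative consensus mismatch over several expression-based labelers
#'
#' In studies with at least `min_per_sex` metadata males and females, a
#' sample is a `mismatch` only if every non-abstaining method disagrees with
#' its metadata sex and at least one method voted; `match` if any method
#' agrees; `insufficient` otherwise.
#'
#' @param metadata data.frame with `sample_id`, `study_id`, `metadata_sex`.
#' @param method_labels list of >= 2 data.frames, each `sample_id`, `label`
#'   ("female"/"male"/"unlabeled").
#' @param min_per_sex eligibility threshold (default 5).
#' @return data.frame sample_id, study_id, flag, n_votes.
#' @export
consensus_mismatch <- function(metadata, method_labels, min_per_sex = 5L) {
  stopifnot(length(method_labels) >= 2)
  by_study <- split(metadata, metadata$study_id)
  eligible <- names(by_study)[vapply(by_study, function(d)
    sum(d$metadata_sex == "female") >= min_per_sex &&
      sum(d$metadata_sex == "male") >= min_per_sex, logical(1))]
  df <- metadata[metadata$study_id %in% eligible &
                   metadata$metadata_sex %in% c("female", "male"), ]
  if (!nrow(df)) {
    return(data.frame(sample_id = character(), study_id = character(),
                      flag = character(), n_votes = integer(),
                      stringsAsFactors = FALSE))
  }
  votes <- sapply(method_labels, function(m)
    m$label[match(df$sample_id, m$sample_id)])
  votes <- matrix(votes, nrow = nrow(df))
  flag <- vapply(seq_len(nrow(df)), function(i) {
    v <- votes[i, ]
    v <- v[!is.na(v) & v %in% c("female", "male")]
    if (!length(v)) return("insufficient")
    if (all(v != df$metadata_sex[i])) "mismatch" else "match"
  }, character(1))
  n_votes <- rowSums(matrix(votes %in% c("female", "male"),
                            nrow = nrow(df)))
  data.frame(sample_id = df$sample_id, study_id = df$study_id,
             flag = flag, n_votes = n_votes, stringsAsFactors = FALSE)
}

#' Baseline two-cluster sex labeler on Y-gene expression
#'
#' Stand-in for external clustering-based labelers used in consensus calls:
#' 2-means on per-sample mean Y-gene expression, higher-mean cluster labeled
#' male. Abstains (all "unlabeled") on < 4 samples, constant input, or tied
#' cluster means.
#'
#' @param y_expr samples x Y-genes matrix.
#' @return data.frame sample_id, label.
#' @export
baseline_cluster_labeler <- function(y_expr) {
  stopifnot(is.matrix(y_expr))
  ids <- rownames(y_expr) %||% as.character(seq_len(nrow(y_expr)))
  abstain <- data.frame(sample_id = ids, label = "unlabeled",
                        stringsAsFactors = FALSE)
  if (nrow(y_expr) < 4) return(abstain)
  m <- rowMeans(y_expr)
  if (max(m) - min(m) < 1e-12) return(abstain)
  km <- stats::kmeans(m, centers = matrix(c(min(m), max(m))))
  if (abs(diff(km$centers[, 1])) < 1e-12) return(abstain)
  male_cluster <- which.max(km$centers[, 1])
  data.frame(sample_id = ids,
             label = ifelse(km$cluster == male_cluster, "male", "female"),
             stringsAsFactors = FALSE)
}
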