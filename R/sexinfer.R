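# Expression-based sex inference.
#
# A logistic regression with elastic-net penalty (female = 0, male = 1) over
# X/Y-chromosome genes, with hyperparameters (alpha, lambda) selected by
# study-stratified nested cross-validation: for each of six outer folds and
# each alpha, lambda-1se is chosen by CV on the other five folds and the
# validation error recorded on the held-out fold; the alpha with the lowest
# median validation error wins (ties -> largest alpha, the sparser model) and
# its lambda is the median of the per-fold lambda-1se values — the percentile
# (50th) rule extended to both hyperparameters. The fitted model emits a
# "sample sex score", the predicted probability P(male).

#' Build study groups from sample-study membership
#'
#' Studies sharing one or more samples with more than `max_shared_studies`
#' other studies are removed first; the remaining studies are grouped by
#' connected components of the shared-sample graph, so any two studies
#' sharing a sample land in the same group.
#'
#' @param membership data.frame with columns `sample_id`, `study_id`.
#' @param max_shared_studies removal threshold (default 5).
#' @return list of class `study_group_map`: `groups` (data.frame study_id,
#'   group_id) and `removed_studies` (character).
#' @export
build_study_groups <- function(membership, max_shared_studies = 5L) {
  stopifnot(nrow(membership) > 0,
            all(c("sample_id", "study_id") %in% names(membership)))
  membership <- unique(membership[, c("sample_id", "study_id")])
  by_sample <- split(membership$study_id, membership$sample_id)
  edges <- unique(do.call(rbind, lapply(by_sample, function(st) {
    st <- unique(st)
    if (length(st) < 2) return(NULL)
    t(utils::combn(sort(st), 2))
  })))
  studies <- sort(unique(membership$study_id))
  degree <- setNames(integer(length(studies)), studies)
  if (!is.null(edges) && nrow(edges)) {
    tab <- table(c(edges[, 1], edges[, 2]))
    degree[names(tab)] <- as.integer(tab)
  }
  removed <- names(degree)[degree > max_shared_studies]
  keep <- setdiff(studies, removed)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(keep)
  if (!is.null(edges) && nrow(edges)) {
    e <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    if (nrow(e)) g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)
  groups <- data.frame(study_id = keep,
                       group_id = paste0("G", comp$membership[keep]),
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  structure(list(groups = groups, removed_studies = removed),
            class = "study_group_map")
}

#' Construct leakage-free train/test sets
#'
#' Samples at most `max_per_study` labeled samples per study, downsamples
#' the majority sex so the candidate pool is balanced, then assigns whole
#' study groups to train or test (no group spans both) with a greedy
#' randomized search targeting `test_frac` of samples in test and an
#' overall male proportion within `balance_range` in both splits.
#'
#' @param samples data.frame with `sample_id`, `study_id`, `metadata_sex`
#'   (only "female"/"male" rows are used).
#' @param groups a [build_study_groups()] result.
#' @param max_per_study maximum samples drawn per study (default 5).
#' @param test_frac target fraction of sampled samples in the test set.
#' @param balance_range allowed male proportion per split.
#' @param seed integer seed.
#' @param max_tries random restarts before giving up.
#' @return list with data.frames `train` and `test` (sample_id, study_id,
#'   group_id, metadata_sex) and the `seed`.
#' @export
construct_train_test <- function(samples, groups, max_per_study = 5L,
                                 test_frac = 0.2,
                                 balance_range = c(0.45, 0.55),
                                 seed = 1L, max_tries = 200L) {
  stopifnot(inherits(groups, "study_group_map"))
  lab <- samples[samples$metadata_sex %in% c("female", "male"), ]
  lab <- merge(lab, groups$groups, by = "study_id")
  if (!nrow(lab)) stop("no labeled samples in grouped studies", call. = FALSE)
  with_rng_seed(seed, {
    picked <- do.call(rbind, lapply(split(lab, lab$study_id), function(df) {
      if (nrow(df) > max_per_study) df[sample.int(nrow(df), max_per_study), ]
      else df
    }))
    picked <- picked[!duplicated(picked$sample_id), ]
    # balance the pool by downsampling the majority sex
    n_m <- sum(picked$metadata_sex == "male")
    n_f <- sum(picked$metadata_sex == "female")
    if (min(n_m, n_f) == 0) {
      stop("labeled pool contains a single sex", call. = FALSE)
    }
    maj <- if (n_m > n_f) "male" else "female"
    excess <- abs(n_m - n_f)
    if (excess > 0) {
      maj_idx <- which(picked$metadata_sex == maj)
      drop_idx <- maj_idx[sample.int(length(maj_idx), excess)]
      picked <- picked[-drop_idx, ]
    }
    for (i in seq_len(max_tries)) {
      gids <- sample(unique(picked$group_id))
      gsize <- table(picked$group_id)[gids]
      target <- test_frac * nrow(picked)
      cum <- cumsum(as.numeric(gsize))
      n_test_groups <- max(1L, which.min(abs(cum - target)))
      test_g <- gids[seq_len(n_test_groups)]
      te <- picked[picked$group_id %in% test_g, ]
      tr <- picked[!picked$group_id %in% test_g, ]
      pm <- function(df) mean(df$metadata_sex == "male")
      ok <- nrow(tr) > 0 && nrow(te) > 0 &&
        pm(tr) >= balance_range[1] && pm(tr) <= balance_range[2] &&
        pm(te) >= balance_range[1] && pm(te) <= balance_range[2]
      if (ok) {
        rownames(tr) <- rownames(te) <- NULL
        return(list(train = tr[order(tr$sample_id), ],
                    test = te[order(te$sample_id), ], seed = seed))
      }
    }
  })
  stop(sprintf(paste0("could not build a balanced split in %d tries ",
                      "(%d labeled samples: %d female, %d male)"),
               max_tries, nrow(lab), sum(lab$metadata_sex == "female"),
               sum(lab$metadata_sex == "male")), call. = FALSE)
}

#' Restrict a matrix to the X/Y feature set
#'
#' @param expr samples x genes matrix.
#' @param genes data.frame with `gene_id`, `chromosome`, `xi_status`.
#' @return list `x` (restricted matrix) and `annotation` (the X/Y subset).
#' @export
feature_set <- function(expr, genes) {
  ann <- genes[genes$chromosome %in% c("X", "Y") &
                 genes$gene_id %in% colnames(expr), ]
  if (!nrow(ann)) stop("no X/Y genes present in the matrix", call. = FALSE)
  list(x = expr[, ann$gene_id, drop = FALSE], annotation = ann)
}

# Greedy balanced partition of study groups into k folds by sample count.
partition_groups <- function(group_sizes, k) {
  ord <- order(group_sizes, decreasing = TRUE)
  fold_tot <- numeric(k)
  fold <- integer(length(group_sizes))
  for (i in ord) {
    j <- which.min(fold_tot)
    fold[i] <- j
    fold_tot[j] <- fold_tot[j] + group_sizes[i]
  }
  setNames(fold, names(group_sizes))
}

#' Fit the sex model by study-stratified nested cross-validation
#'
#' @param x training matrix restricted to X/Y features (samples x genes).
#' @param y labels, "female"/"male" or 0/1 (female = 0, male = 1).
#' @param group_id study group per sample (character), used to build outer
#'   folds that partition study groups.
#' @param n_folds outer folds (default 6).
#' @param alpha_grid elastic-net mixing values (default 0.1..1 by 0.1).
#' @param threshold_high labeling threshold stored in the model (default 0.7).
#' @param seed integer seed.
#' @return object of class `sex_model`: coefficients (standardized scale),
#'   intercept, alpha, lambda, thresholds, feature means/sds, the per-fold CV
#'   table, fold assignment, and a training manifest.
#' @export
nested_cv_fit <- function(x, y, group_id, n_folds = 6L,
                          alpha_grid = seq(0.1, 1, by = 0.1),
                          threshold_high = 0.7, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(group_id))
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    stopifnot(all(y %in% c("female", "male")))
    y <- as.integer(y == "male")
  }
  if (length(unique(y)) < 2) {
    stop("training data contain a single class", call. = FALSE)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  xs <- scale(x, center = mu, scale = sdv)

  gsize <- table(group_id)
  if (length(gsize) < n_folds) {
    stop("need at least as many study groups as folds", call. = FALSE)
  }
  fold_of_group <- partition_groups(as.numeric(gsize), n_folds)
  names(fold_of_group) <- names(gsize)
  fold <- fold_of_group[group_id]
  for (f in seq_len(n_folds)) {
    if (length(unique(y[fold == f])) < 2) {
      stop(sprintf("outer fold %d lacks both classes", f), call. = FALSE)
    }
  }

  cv_table <- expand.grid(fold = seq_len(n_folds), alpha = alpha_grid)
  cv_table$lambda_1se <- NA_real_
  cv_table$error <- NA_real_
  with_rng_seed(seed, {
    for (f in seq_len(n_folds)) {
      inner <- fold != f
      inner_fold <- match(fold[inner], setdiff(seq_len(n_folds), f))
      for (a in alpha_grid) {
        # inner lambda-1se on the cross-validated deviance (glmnet's mean
        # CV error for logistic models); classification error with a
        # label-noise floor gives a flat curve whose wide 1-SE band
        # over-shrinks the model. The outer metric stays class error.
        cvfit <- glmnet::cv.glmnet(xs[inner, , drop = FALSE], y[inner],
                                   family = "binomial", alpha = a,
                                   foldid = inner_fold,
                                   type.measure = "deviance",
                                   standardize = FALSE)
        lam <- cvfit$lambda.1se
        pr <- stats::predict(cvfit, newx = xs[!inner, , drop = FALSE],
                             s = lam, type = "response")
        err <- mean((pr[, 1] >= 0.5) != (y[!inner] == 1))
        i <- which(cv_table$fold == f & cv_table$alpha == a)
        cv_table$lambda_1se[i] <- lam
        cv_table$error[i] <- err
      }
    }
  })
  med_err <- vapply(alpha_grid, function(a)
    stats::median(cv_table$error[cv_table$alpha == a]), numeric(1))
  best <- max(alpha_grid[med_err == min(med_err)])  # tie -> sparsest
  lambda <- stats::median(cv_table$lambda_1se[cv_table$alpha == best])

  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = best,
                        standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = lambda))
  model <- structure(list(
    genes = colnames(x),
    coefficients = setNames(beta[-1], colnames(x)),
    intercept = beta[1],
    alpha = best, lambda = lambda,
    threshold_high = threshold_high, threshold_low = 1 - threshold_high,
    feature_means = setNames(as.numeric(mu), colnames(x)),
    feature_sds = setNames(as.numeric(sdv), colnames(x)),
    cv_table = cv_table, median_errors = setNames(med_err, alpha_grid),
    fold_of_group = fold_of_group, seed = seed,
    manifest = list(n_samples = nrow(x), n_male = sum(y == 1),
                    n_groups = length(gsize), seed = seed)),
    class = "sex_model")
  model
}

#' @export
print.sex_model <- function(x, ...) {
  cat(sprintf(paste0("sex_model: %d X/Y genes (%d nonzero), alpha = %.1f, ",
                     "lambda = %.4g\n  trained on %d samples, %d study ",
                     "groups; thresholds %.2f/%.2f\n"),
              length(x$genes), sum(x$coefficients != 0), x$alpha, x$lambda,
              x$manifest$n_samples, x$manifest$n_groups,
              x$threshold_low, x$threshold_high))
  invisible(x)
}

#' Score samples with a fitted sex model
#'
#' Model genes missing from the matrix are imputed with their training means
#' (zero on the standardized scale). Errors if no model gene overlaps.
#'
#' @param model a `sex_model`.
#' @param expr samples x genes matrix.
#' @return data.frame `sample_id`, `score` (P(male) in \[0, 1\]).
#' @export
predict_scores <- function(model, expr) {
  stopifnot(inherits(model, "sex_model"), is.matrix(expr))
  present <- intersect(model$genes, colnames(expr))
  if (!length(present)) {
    stop("no overlap between model genes and matrix columns", call. = FALSE)
  }
  xs <- matrix(0, nrow(expr), length(model$genes),
               dimnames = list(rownames(expr), model$genes))
  xs[, present] <- sweep(
    sweep(expr[, present, drop = FALSE], 2, model$feature_means[present]),
    2, model$feature_sds[present], "/")
  eta <- model$intercept + as.numeric(xs %*% model$coefficients)
  data.frame(sample_id = rownames(expr) %||% seq_len(nrow(expr)),
             score = logistic(eta), stringsAsFactors = FALSE)
}

#' Assign sex labels from scores at a calibrated threshold
#'
#' Scores >= `threshold_high` are male, scores <= `1 - threshold_high` are
#' female (boundaries inclusive: the unclassified band is the open interval),
#' everything in between is unlabeled.
#'
#' @param scores data.frame with `sample_id`, `score`.
#' @param threshold_high default 0.7.
#' @return `scores` with a `label` column.
#' @export
assign_labels <- function(scores, threshold_high = 0.7) {
  stopifnot(all(scores$score >= 0 & scores$score <= 1))
  scores$label <- ifelse(scores$score >= threshold_high, "male",
                  ifelse(scores$score <= 1 - threshold_high, "female",
                         "unlabeled"))
  scores
}

#' Concordance / coverage trade-off across thresholds
#'
#' @param scores data.frame with `score` and `metadata_sex`
#'   ("female"/"male"; other values are ignored for concordance).
#' @param thresholds grid (default 0.5 to 0.99 by 0.01).
#' @return data.frame threshold, concordance (over labeled samples with
#'   metadata sex), fraction_labeled (over all samples).
#' @export
threshold_sweep <- function(scores, thresholds = seq(0.5, 0.99, by = 0.01)) {
  has_meta <- scores$metadata_sex %in% c("female", "male")
  if (!any(has_meta)) stop("no samples with metadata sex", call. = FALSE)
  do.call(rbind, lapply(thresholds, function(th) {
    lab <- assign_labels(scores, th)
    labeled <- lab$label != "unlabeled"
    ev <- labeled & has_meta
    data.frame(threshold = th,
               concordance = if (any(ev))
                 mean(lab$label[ev] == lab$metadata_sex[ev]) else NA_real_,
               fraction_labeled = mean(labeled))
  }))
}

#' Per-platform concordance QC
#'
#' Platforms whose labeled-sample concordance with metadata sex falls below
#' `floor` (with at least `min_n` evaluable samples) are listed for
#' exclusion; platforms with fewer evaluable samples are flagged
#' insufficient, not excluded.
#'
#' @param scores data.frame with `score`, `metadata_sex`, `platform`.
#' @param threshold_high labeling threshold (default 0.7).
#' @param floor concordance floor (default 0.70).
#' @param min_n minimum evaluable samples (default 20).
#' @return list `table` (platform, n_evaluable, concordance, status) and
#'   `excluded` (character vector of platform ids).
#' @export
platform_qc <- function(scores, threshold_high = 0.7, floor = 0.70,
                        min_n = 20L) {
  stopifnot("platform" %in% names(scores))
  lab <- assign_labels(scores, threshold_high)
  tab <- do.call(rbind, lapply(split(lab, lab$platform), function(df) {
    ev <- df$label != "unlabeled" & df$metadata_sex %in% c("female", "male")
    n <- sum(ev)
    conc <- if (n > 0) mean(df$label[ev] == df$metadata_sex[ev]) else NA_real_
    status <- if (n < min_n) "insufficient"
              else if (conc < floor) "excluded" else "ok"
    data.frame(platform = df$platform[1], n_evaluable = n,
               concordance = conc, status = status,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab, excluded = tab$platform[tab$status == "excluded"])
}

#' Serialize / deserialize a sex model as JSON
#'
#' @param model a `sex_model`.
#' @param path output file.
#' @return `path` (write) or a `sex_model` (read).
#' @export
write_sex_model <- function(model, path) {
  stopifnot(inherits(model, "sex_model"))
  obj <- model[c("genes", "coefficients", "intercept", "alpha", "lambda",
                 "threshold_high", "threshold_low", "feature_means",
                 "feature_sds", "seed", "manifest")]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sex_model
#' @export
read_sex_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- setNames(as.numeric(obj$coefficients), obj$genes)
  obj$feature_means <- setNames(as.numeric(obj$feature_means), obj$genes)
  obj$feature_sds <- setNames(as.numeric(obj$feature_sds), obj$genes)
  structure(obj, class = "sex_model")
}
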