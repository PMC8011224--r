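# End-to-end pipeline driver: configuration, deterministic per-stage
# seeding, structured logging, and a run manifest. Stage order: preprocess ->
# metadata labels -> sex inference (train/predict/QC) -> misannotation ->
# entity mapping -> bias summaries.

#' Pipeline configuration
#'
#' All tunables of the individual stages plus a single global seed; per-stage
#' seeds are derived as `seed + stage index` and logged. Unknown arguments
#' are rejected. Serializable to/from JSON.
#'
#' @param corpus_dir directory with corpus tables (as written by
#'   [write_corpus()]); `NULL` to simulate in memory from `sim`.
#' @param out_dir run directory for all outputs.
#' @param sim a [sim_config()] used when `corpus_dir` is NULL.
#' @param data_type "microarray" or "rnaseq".
#' @param min_read_counts RNA-seq low-count filter.
#' @param category a [category_config()].
#' @param threshold_high sex-label threshold.
#' @param test_frac,max_per_study split construction parameters.
#' @param n_folds,alpha_grid nested-CV parameters.
#' @param platform_floor,platform_min_n platform QC parameters.
#' @param cluster a [cluster_config()].
#' @param enrichment an [enrichment_config()].
#' @param stages character vector of stages to run.
#' @param seed global integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus_dir = NULL, out_dir = tempfile("run"),
                            sim = sim_config(),
                            data_type = c("microarray", "rnaseq"),
                            min_read_counts = 100000,
                            category = category_config(),
                            threshold_high = 0.7,
                            test_frac = 0.2, max_per_study = 5L,
                            n_folds = 6L,
                            alpha_grid = seq(0.1, 1, by = 0.1),
                            platform_floor = 0.70, platform_min_n = 20L,
                            cluster = cluster_config(),
                            enrichment = enrichment_config(),
                            stages = c("preprocess", "meta_labels",
                                       "sexinfer", "mislabel", "entities",
                                       "bias"),
                            seed = 1L) {
  data_type <- match.arg(data_type)
  if (!is.numeric(threshold_high) || threshold_high <= 0.5 ||
      threshold_high >= 1) {
    stop("threshold_high must be in (0.5, 1)", call. = FALSE)
  }
  stopifnot(inherits(category, "category_config"),
            inherits(cluster, "cluster_config"),
            inherits(enrichment, "enrichment_config"),
            all(stages %in% c("preprocess", "meta_labels", "sexinfer",
                              "mislabel", "entities", "bias")))
  structure(list(corpus_dir = corpus_dir, out_dir = out_dir, sim = sim,
                 data_type = data_type, min_read_counts = min_read_counts,
                 category = category, threshold_high = threshold_high,
                 test_frac = test_frac,
                 max_per_study = as.integer(max_per_study),
                 n_folds = as.integer(n_folds), alpha_grid = alpha_grid,
                 platform_floor = platform_floor,
                 platform_min_n = as.integer(platform_min_n),
                 cluster = cluster, enrichment = enrichment,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("sim", "category", "cluster", "enrichment")) {
    if (!is.null(obj[[nm]])) {
      obj[[nm]] <- do.call(paste0(sub("sim", "sim_config",
                                      sub("category", "category_config",
                                          sub("cluster", "cluster_config",
                                              sub("enrichment",
                                                  "enrichment_config",
                                                  nm)))), ""),
                           as.list(obj[[nm]]))
    }
  }
  do.call(pipeline_config, obj)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- config
  ser$out_dir <- NULL  # run location must not change the hash
  jsonlite::write_json(lapply(ser, unclass), tmp, digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

log_stage <- function(stage, t0, msg) {
  message(sprintf("[%s] %5.1fs %s", stage,
                  as.numeric(Sys.time()) - t0, msg))
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return run manifest (list): config hash, seed, per-stage seeds and row
#'   counts, output files. All tables are written under `config$out_dir`
#'   with the config hash in a header comment; the manifest is written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  hash <- config_hash(config)
  hdr <- paste0("config_hash: ", hash)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(i) config$seed + i
  manifest <- list(config_hash = hash, seed = config$seed, stages = list())
  note <- function(stage, seed, ...) {
    manifest$stages[[stage]] <<- c(list(seed = seed), list(...))
  }

  ## -- inputs ----------------------------------------------------------------
  if (is.null(config$corpus_dir)) {
    sim_args <- unclass(config$sim)
    sim_args$data_type <- config$data_type
    sim_args$seed <- stage_seed(0L)
    corpus <- generate_corpus(do.call(sim_config, sim_args))
    expr <- corpus$expr
    meta <- corpus$meta
    studies <- corpus$studies
    genes <- corpus$genes
  } else {
    p <- config$corpus_dir
    f <- file.path(p, "expr.tsv")
    expr <- read_expression(if (file.exists(f)) f else
                              file.path(p, "expr.mtx"))
    meta <- read_tsv(file.path(p, "meta.tsv"))
    studies <- read_tsv(file.path(p, "studies.tsv"))
    genes <- read_tsv(file.path(p, "genes.tsv"))
  }
  for (col in c("sample_id", "study_id", "key", "value")) {
    if (!col %in% names(meta)) {
      stop("metadata table lacks column ", col, call. = FALSE)
    }
  }
  sample_info <- unique(meta[, c("sample_id", "study_id", "platform")])
  log_stage("input", t0, sprintf("%d samples, %d studies", nrow(expr),
                                 nrow(studies)))

  ## -- preprocess ------------------------------------------------------------
  if ("preprocess" %in% config$stages && config$data_type == "rnaseq") {
    pp <- preprocess_expression(
      expr, filter_config(config$min_read_counts, "rnaseq"))
    expr <- pp$expr
    write_tsv(pp$lambdas, file.path(config$out_dir, "boxcox_lambdas.tsv"),
              hdr)
    note("preprocess", NA, rows_out = nrow(expr))
    log_stage("preprocess", t0, sprintf("%d samples kept", nrow(expr)))
  }

  ## -- metadata labels -------------------------------------------------------
  ml <- label_metadata_sex(meta, config$category)
  write_tsv(ml$samples, file.path(config$out_dir, "metadata_sex.tsv"), hdr)
  write_tsv(ml$studies, file.path(config$out_dir, "study_categories.tsv"),
            hdr)
  note("meta_labels", NA, samples = nrow(ml$samples),
       studies = nrow(ml$studies))
  log_stage("meta_labels", t0,
            sprintf("%d labeled of %d",
                    sum(ml$samples$metadata_sex != "unlabeled"),
                    nrow(ml$samples)))
  if (!any(c("sexinfer", "mislabel", "entities", "bias") %in%
             config$stages)) {
    manifest$outputs <- list.files(config$out_dir)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
    return(invisible(manifest))
  }

  ## -- sex inference ---------------------------------------------------------
  fs <- feature_set(expr, genes)
  groups <- build_study_groups(meta[, c("sample_id", "study_id")])
  labeled <- merge(ml$samples, sample_info[, c("sample_id", "platform")],
                   by = "sample_id")
  split_ <- construct_train_test(labeled, groups,
                                 max_per_study = config$max_per_study,
                                 test_frac = config$test_frac,
                                 seed = stage_seed(1L))
  tr <- split_$train
  model <- nested_cv_fit(fs$x[tr$sample_id, , drop = FALSE],
                         tr$metadata_sex, tr$group_id,
                         n_folds = config$n_folds,
                         alpha_grid = config$alpha_grid,
                         threshold_high = config$threshold_high,
                         seed = stage_seed(2L))
  write_sex_model(model, file.path(config$out_dir, "model.json"))
  scores <- predict_scores(model, fs$x)
  scores <- merge(scores, labeled, by = "sample_id", all.x = TRUE)
  scores$metadata_sex[is.na(scores$metadata_sex)] <- "unlabeled"
  scores <- assign_labels(scores, config$threshold_high)
  qc <- platform_qc(scores, config$threshold_high,
                    config$platform_floor, config$platform_min_n)
  scores$label[scores$platform %in% qc$excluded] <- "unlabeled"
  write_tsv(scores[, c("sample_id", "score", "label")],
            file.path(config$out_dir, "scores.tsv"), hdr)
  write_tsv(qc$table, file.path(config$out_dir, "platforms.tsv"), hdr)
  note("sexinfer", stage_seed(2L), alpha = model$alpha,
       lambda = model$lambda, n_train = nrow(tr),
       n_test = nrow(split_$test),
       excluded_platforms = length(qc$excluded))
  log_stage("sexinfer", t0,
            sprintf("alpha %.1f lambda %.4g, %d/%d labeled", model$alpha,
                    model$lambda, sum(scores$label != "unlabeled"),
                    nrow(scores)))

  ## -- misannotation ---------------------------------------------------------
  if ("mislabel" %in% config$stages) {
    mixed_ids <- ml$studies$study_id[ml$studies$category == "mixed"]
    sc_mixed <- scores[scores$study_id %in% mixed_ids, ]
    sw <- flag_swaps_all(sc_mixed, config$cluster, seed = stage_seed(3L))
    if (!is.null(sw$flags)) {
      write_tsv(sw$flags, file.path(config$out_dir, "swap_flags.tsv"), hdr)
    }
    if (!is.null(sw$studies)) {
      write_tsv(sw$studies, file.path(config$out_dir, "swap_studies.tsv"),
                hdr)
    }
    rates <- simple_mismatch_rates(
      data.frame(sample_id = scores$sample_id, study_id = scores$study_id,
                 metadata_sex = scores$metadata_sex,
                 expr_label = scores$label, stringsAsFactors = FALSE),
      ml$studies)
    write_tsv(rates$sample_rates,
              file.path(config$out_dir, "mismatch_rates.tsv"), hdr)
    note("mislabel", stage_seed(3L),
         n_flagged = sum(sw$flags$flag == "mismatch", na.rm = TRUE))
    log_stage("mislabel", t0,
              sprintf("%d studies clustered",
                      length(unique(sw$studies$study_id))))
  }

  ## -- entities --------------------------------------------------------------
  cellmap <- NULL; drug_labels <- NULL
  if ("entities" %in% config$stages) {
    fx <- generate_lexicon_fixtures(seed = stage_seed(4L))
    cl_lex <- build_cell_line_lexicon(fx$cell_lines)
    dr_lex <- build_drug_lexicon(fx$drugs, fx$control_terms)
    cellmap <- map_all_samples_to_cell_lines(meta, cl_lex)
    if (nrow(cellmap)) {
      cellmap <- merge(cellmap,
                       unique(meta[, c("sample_id", "study_id")]),
                       by = "sample_id")
      write_tsv(cellmap, file.path(config$out_dir, "cellmap.tsv"), hdr)
    }
    trt <- meta[norm_string(meta$key) %in% c("treatment", "compound",
                                             "title"), ]
    drug_labels <- label_drug_studies(
      studies, data.frame(sample_id = trt$sample_id,
                          study_id = trt$study_id, value = trt$value,
                          stringsAsFactors = FALSE), dr_lex)
    write_tsv(drug_labels$mention,
              file.path(config$out_dir, "drug_mention.tsv"), hdr)
    write_tsv(drug_labels$exposure,
              file.path(config$out_dir, "drug_exposure.tsv"), hdr)
    note("entities", stage_seed(4L), n_cell_mapped = nrow(cellmap),
         n_mention = nrow(drug_labels$mention),
         n_exposure = nrow(drug_labels$exposure))
    log_stage("entities", t0,
              sprintf("%d cell hits, %d drug-mention pairs",
                      nrow(cellmap), nrow(drug_labels$mention)))
    attr(drug_labels, "lexicon") <- dr_lex
    attr(cellmap, "acc_info") <- cl_lex$acc_info
  }

  ## -- bias ------------------------------------------------------------------
  if ("bias" %in% config$stages) {
    bd <- sex_breakdown(scores)
    write_tsv(bd, file.path(config$out_dir, "breakdown.tsv"), hdr)
    expr_cat <- do.call(rbind, lapply(split(scores, scores$study_id),
      function(d) data.frame(
        study_id = d$study_id[1],
        category = categorize_study(
          ifelse(d$label %in% c("female", "male"), d$label, "unlabeled"),
          nrow(d), config$category),
        stringsAsFactors = FALSE)))
    if (!is.null(drug_labels) && nrow(drug_labels$exposure)) {
      dr_lex <- attr(drug_labels, "lexicon")
      pairs <- drug_labels$exposure
      prof <- drug_sex_profiles(pairs, expr_cat)
      write_tsv(prof, file.path(config$out_dir, "drug_profiles.tsv"), hdr)
      atc_pairs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        cls <- dr_lex$atc[[pairs$drug_id[i]]]
        if (!length(cls)) return(NULL)
        data.frame(study_id = pairs$study_id[i],
                   atc_class = substr(cls, 1, 1),
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(atc_pairs)) {
        enr <- atc_enrichment(unique(atc_pairs), expr_cat,
                              config$enrichment)
        write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"), hdr)
      }
    }
    if (!is.null(cellmap) && nrow(cellmap)) {
      conc <- cell_line_concordance(
        cellmap, stats::setNames(
          attr(cellmap, "acc_info")[, c("accession", "donor_sex")],
          c("accession", "donor_sex")),
        scores[, c("sample_id", "label", "score")])
      write_tsv(conc$switch_rates,
                file.path(config$out_dir, "switches.tsv"), hdr)
    }
    note("bias", NA, n_strata = nrow(bd))
    log_stage("bias", t0, "summaries written")
  }

  manifest$outputs <- sort(list.files(config$out_dir))
  manifest$elapsed_s <- as.numeric(Sys.time()) - t0
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = 6, auto_unbox = TRUE, force = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --out DIR --seed N`, `run --config config.json`,
#' `predict --model model.json --expr expr.tsv --out scores.tsv`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sexlabelr <simulate|run|predict> [options]",
    "  simulate --out DIR [--seed N]",
    "  run --config config.json",
    "  predict --model model.json --expr expr.tsv --out scores.tsv",
    sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  switch(cmd,
    simulate = {
      seed <- as.integer(opt("--seed", "1"))
      out <- opt("--out") %||% stop("--out required", call. = FALSE)
      write_corpus(generate_corpus(sim_config(seed = seed)), out)
      write_lexicon_fixtures(out, seed)
    },
    run = {
      cfgp <- opt("--config") %||% stop("--config required", call. = FALSE)
      run_pipeline(read_pipeline_config(cfgp))
    },
    predict = {
      model <- read_sex_model(opt("--model"))
      expr <- read_expression(opt("--expr"))
      sc <- assign_labels(predict_scores(model, expr),
                          model$threshold_high)
      write_tsv(sc, opt("--out"))
    },
    { cat(usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}
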