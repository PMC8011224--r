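# Synthetic corpus generator.
#
# Emulates the statistical structure that the sex-labeling pipeline assumes in
# large public expression compendia: bimodal Y-gene expression between the
# sexes, elevated X-inactivation-escape expression in females, per-study batch
# shifts, platform groups, pooled (mixed-sex) samples, cell lines with Y
# chromosome loss, heterogeneous/missing metadata sex labels and injected
# label swaps. Ground truth is carried separately so tests can score every
# downstream stage.

#' Simulation configuration
#'
#' Defaults describe the stated world used throughout the test-suite: about
#' 200 studies of 10-20 samples (~3000 samples), a strong Y-gene effect
#' (4 log2 units) against within-sample noise of 0.5 and between-study batch
#' SD of 0.5, 3% metadata sex swaps and 30% missing sex labels.
#'
#' @param n_studies number of studies.
#' @param samples_per_study length-2 integer range (inclusive) of study sizes.
#' @param frac_single_sex proportion of studies that are single-sex.
#' @param frac_female_only_of_single proportion of single-sex studies that are
#'   female-only.
#' @param n_y_genes,n_xescape_genes,n_xinactive_genes,n_autosomal_genes gene
#'   panel sizes; two pseudoautosomal (PAR) X genes are always added.
#' @param y_effect mean log2 shift of Y genes in males.
#' @param xescape_effect mean log2 shift of X-escape genes in females.
#' @param study_sd between-study batch SD (per study x gene).
#' @param noise_sd within-sample SD.
#' @param swap_rate proportion of sexed samples whose metadata sex is flipped.
#' @param missing_rate proportion of samples with no metadata sex attribute.
#' @param frac_pooled proportion of mixed-study samples that are pooled
#'   male+female material, with mixing coefficient u ~ Uniform(0.2, 0.8).
#' @param n_platforms number of platforms (assigned per study).
#' @param zero_effect_platforms integer platform indices generated with zero
#'   sex effect (used to exercise platform QC).
#' @param data_type "microarray" (log2-like continuous values) or "rnaseq"
#'   (Poisson-sampled integer counts).
#' @param seq_depth_factor multiplier on 2^value Poisson rates in rnaseq mode.
#' @param frac_low_depth proportion of rnaseq samples sequenced at 1% depth
#'   (to exercise the low-count filter).
#' @param frac_cellline_studies proportion of studies drawn from a cell line.
#' @param n_celllines number of distinct cell lines sampled from the bundled
#'   synthetic line table.
#' @param frac_yloss_lines proportion of male-donor lines that carry Y loss.
#' @param cellline_yloss_rate per-sample probability that a Y-loss line's
#'   sample has silenced Y genes.
#' @param frac_drug_studies proportion of studies whose metadata mentions a
#'   drug (with sample-level treatment/control fields).
#' @param seed integer seed; the same config + seed reproduces the corpus
#'   byte-for-byte.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_studies = 200L,
                       samples_per_study = c(10L, 20L),
                       frac_single_sex = 0.3,
                       frac_female_only_of_single = 0.5,
                       n_y_genes = 12L,
                       n_xescape_genes = 10L,
                       n_xinactive_genes = 30L,
                       n_autosomal_genes = 20L,
                       y_effect = 4,
                       xescape_effect = 1,
                       study_sd = 0.5,
                       noise_sd = 0.5,
                       swap_rate = 0.03,
                       missing_rate = 0.3,
                       frac_pooled = 0.01,
                       n_platforms = 3L,
                       zero_effect_platforms = integer(),
                       data_type = c("microarray", "rnaseq"),
                       seq_depth_factor = 100,
                       frac_low_depth = 0,
                       frac_cellline_studies = 0.1,
                       n_celllines = 10L,
                       frac_yloss_lines = 0.5,
                       cellline_yloss_rate = 0.5,
                       frac_drug_studies = 0.3,
                       seed = 1L) {
  data_type <- match.arg(data_type)
  for (nm in c("frac_single_sex", "frac_female_only_of_single", "swap_rate",
               "missing_rate", "frac_pooled", "frac_cellline_studies",
               "frac_yloss_lines", "cellline_yloss_rate", "frac_drug_studies",
               "frac_low_depth")) {
    check_proportion(get(nm), nm)
  }
  check_count(n_studies, "n_studies")
  check_count(n_platforms, "n_platforms")
  check_count(n_celllines, "n_celllines")
  for (nm in c("n_y_genes", "n_xescape_genes", "n_xinactive_genes")) {
    check_count(get(nm), nm)
  }
  check_count(n_autosomal_genes, "n_autosomal_genes", min = 0L)
  stopifnot(length(samples_per_study) == 2L,
            samples_per_study[1] >= 1L,
            samples_per_study[2] >= samples_per_study[1],
            y_effect >= 0, study_sd >= 0, noise_sd >= 0)
  cfg <- list(
    n_studies = as.integer(n_studies),
    samples_per_study = as.integer(samples_per_study),
    frac_single_sex = frac_single_sex,
    frac_female_only_of_single = frac_female_only_of_single,
    n_y_genes = as.integer(n_y_genes),
    n_xescape_genes = as.integer(n_xescape_genes),
    n_xinactive_genes = as.integer(n_xinactive_genes),
    n_autosomal_genes = as.integer(n_autosomal_genes),
    y_effect = y_effect, xescape_effect = xescape_effect,
    study_sd = study_sd, noise_sd = noise_sd,
    swap_rate = swap_rate, missing_rate = missing_rate,
    frac_pooled = frac_pooled,
    n_platforms = as.integer(n_platforms),
    zero_effect_platforms = as.integer(zero_effect_platforms),
    data_type = data_type,
    seq_depth_factor = seq_depth_factor,
    frac_low_depth = frac_low_depth,
    frac_cellline_studies = frac_cellline_studies,
    n_celllines = as.integer(n_celllines),
    frac_yloss_lines = frac_yloss_lines,
    cellline_yloss_rate = cellline_yloss_rate,
    frac_drug_studies = frac_drug_studies,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Bundled synthetic cell-line table (accession, name, donor sex). Names are
# invented but shaped like real line names; they are also present in the
# lexicon fixtures so corpus metadata maps back to these accessions.
base_cell_lines <- function() {
  data.frame(
    accession = sprintf("SYN-CVCL-%04d", 1:12),
    name = c("helx", "kg-7", "mframe-2", "lncx", "a5673", "vero-s",
             "jurkat-s", "hepg-s", "u2os-s", "mcf-s", "ht29-s", "pc3-s"),
    donor_sex = c("female", "male", "male", "male", "female", "female",
                  "male", "male", "female", "female", "female", "male"),
    stringsAsFactors = FALSE)
}

# Bundled synthetic drug table (real drug names, synthetic ids) with ATC
# top-level classes; used by drug-study generation and the lexicon fixtures.
base_drugs <- function() {
  data.frame(
    drug_id = sprintf("SYNDB%05d", 1:10),
    name = c("tamoxifen", "haloperidol", "doxorubicin", "metformin",
             "fluoxetine", "cisplatin", "atorvastatin", "sildenafil",
             "letrozole", "finasteride"),
    atc = c("L", "N", "L", "A", "N", "L", "C", "G", "L", "G"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic expression + metadata corpus with known ground truth
#'
#' @param config a [sim_config()].
#' @return A list of class `syn_corpus` with elements:
#'   \describe{
#'     \item{expr}{numeric matrix, samples x genes, with dimnames.}
#'     \item{samples}{wide per-sample table: sample_id, study_id, platform,
#'       data_type.}
#'     \item{meta}{long metadata table: sample_id, study_id, platform, key,
#'       value (what pipeline stages are allowed to see).}
#'     \item{studies}{study_id, title, description, platform, data_type.}
#'     \item{genes}{gene_id, chromosome (X/Y/autosome), xi_status
#'       (escape/inactive/PAR/unknown).}
#'     \item{truth}{per-sample ground truth (true_sex, pooled mixing u,
#'       metadata_sex as written, swap, cell_line, y_silenced) — never read by
#'       pipeline stages.}
#'     \item{study_truth}{study_id, true_category, is_single_sex, cell_line,
#'       drug_id.}
#'     \item{cell_lines}{accession, donor_sex, yloss (line-level truth).}
#'   }
#' @export
generate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_rng_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  lines <- utils::head(base_cell_lines(), cfg$n_celllines)
  male_lines <- lines$accession[lines$donor_sex == "male"]
  yloss_lines <- male_lines[stats::runif(length(male_lines)) < cfg$frac_yloss_lines]
  lines$yloss <- lines$accession %in% yloss_lines
  drugs <- base_drugs()

  ## -- studies ---------------------------------------------------------------
  ns <- cfg$n_studies
  study_id <- sprintf("S%04d", seq_len(ns))
  size_range <- seq(cfg$samples_per_study[1], cfg$samples_per_study[2])
  n_per <- size_range[sample.int(length(size_range), ns, replace = TRUE)]
  platform <- paste0("P", sample.int(cfg$n_platforms, ns, replace = TRUE))
  single <- stats::runif(ns) < cfg$frac_single_sex
  single_female <- single & (stats::runif(ns) < cfg$frac_female_only_of_single)
  is_cl <- stats::runif(ns) < cfg$frac_cellline_studies
  cl_acc <- ifelse(is_cl, sample(lines$accession, ns, replace = TRUE), NA)
  is_drug <- stats::runif(ns) < cfg$frac_drug_studies
  drug_idx <- sample.int(nrow(drugs), ns, replace = TRUE)
  study_drug <- ifelse(is_drug, drugs$drug_id[drug_idx], NA)

  ## -- samples ---------------------------------------------------------------
  sid <- rep(study_id, n_per)
  n <- length(sid)
  sample_id <- sprintf("SAMP%06d", seq_len(n))
  s_platform <- rep(platform, n_per)
  s_single <- rep(single, n_per)
  s_single_f <- rep(single_female, n_per)
  s_cl <- rep(cl_acc, n_per)

  true_sex <- ifelse(s_single, ifelse(s_single_f, "female", "male"),
                     ifelse(stats::runif(n) < 0.5, "female", "male"))
  cl_row <- match(s_cl, lines$accession)
  true_sex[!is.na(cl_row)] <- lines$donor_sex[cl_row[!is.na(cl_row)]]
  pooled <- !s_single & is.na(s_cl) & stats::runif(n) < cfg$frac_pooled
  u <- ifelse(pooled, stats::runif(n, 0.2, 0.8), NA)
  true_sex[pooled] <- "pooled"

  y_silenced <- !is.na(cl_row) & lines$yloss[ifelse(is.na(cl_row), 1L, cl_row)] &
    stats::runif(n) < cfg$cellline_yloss_rate

  ## -- genes -----------------------------------------------------------------
  genes <- rbind(
    data.frame(gene_id = sprintf("YG%03d", seq_len(cfg$n_y_genes)),
               chromosome = "Y", xi_status = "unknown"),
    data.frame(gene_id = sprintf("XESC%03d", seq_len(cfg$n_xescape_genes)),
               chromosome = "X", xi_status = "escape"),
    data.frame(gene_id = sprintf("XINA%03d", seq_len(cfg$n_xinactive_genes)),
               chromosome = "X", xi_status = "inactive"),
    data.frame(gene_id = c("XPAR001", "XPAR002"),
               chromosome = "X", xi_status = "PAR"),
    if (cfg$n_autosomal_genes > 0)
      data.frame(gene_id = sprintf("AUT%03d", seq_len(cfg$n_autosomal_genes)),
                 chromosome = "autosome", xi_status = "unknown"))
  g <- nrow(genes)

  ## -- expression ------------------------------------------------------------
  # maleness m in [0,1] drives Y genes (0 if Y silenced); femaleness 1 - m
  # drives X-escape genes. Zero-effect platforms carry no sex signal.
  m_eff <- ifelse(pooled, u, ifelse(true_sex == "male", 1, 0))
  m_eff[y_silenced] <- 0
  f_eff <- ifelse(pooled, 1 - u, ifelse(true_sex == "female", 1, 0))
  null_plat <- paste0("P", cfg$zero_effect_platforms)
  on_null <- s_platform %in% null_plat
  m_eff[on_null] <- 0
  f_eff[on_null] <- 0

  base <- ifelse(genes$chromosome == "Y", 1, 6)
  eff <- matrix(0, n, g)
  is_y <- genes$chromosome == "Y"
  is_xe <- genes$xi_status == "escape"
  eff[, is_y] <- cfg$y_effect * m_eff
  eff[, is_xe] <- cfg$xescape_effect * f_eff

  batch <- matrix(stats::rnorm(ns * g, sd = cfg$study_sd), ns, g)
  study_row <- match(sid, study_id)
  expr <- matrix(rep(base, each = n), n, g) + eff + batch[study_row, ] +
    matrix(stats::rnorm(n * g, sd = cfg$noise_sd), n, g)
  dimnames(expr) <- list(sample_id, genes$gene_id)

  if (cfg$data_type == "rnaseq") {
    depth <- rep(cfg$seq_depth_factor, n)
    depth[stats::runif(n) < cfg$frac_low_depth] <-
      cfg$seq_depth_factor * 0.01
    lam <- pmin(2^expr, 2^20) * depth
    expr <- matrix(stats::rpois(n * g, lam), n, g,
                   dimnames = dimnames(expr))
  }

  ## -- metadata sex labels (with swaps and missingness) ----------------------
  swap <- true_sex != "pooled" & stats::runif(n) < cfg$swap_rate
  missing <- stats::runif(n) < cfg$missing_rate
  meta_sex <- true_sex
  meta_sex[swap] <- ifelse(true_sex[swap] == "male", "female", "male")
  meta_sex[missing] <- NA

  sex_keys <- c("sex", "Sex", "gender", "characteristics: sex")
  f_vals <- c("female", "F", "f", "Female", "woman")
  m_vals <- c("male", "M", "m", "Male", "man")
  key <- sample(sex_keys, n, replace = TRUE)
  val <- character(n)
  idx_f <- which(!is.na(meta_sex) & meta_sex == "female")
  idx_m <- which(!is.na(meta_sex) & meta_sex == "male")
  val[idx_f] <- sample(f_vals, length(idx_f), replace = TRUE)
  val[idx_m] <- sample(m_vals, length(idx_m), replace = TRUE)
  val[!is.na(meta_sex) & meta_sex == "pooled"] <- "pooled male and female"

  keep <- !is.na(meta_sex)
  meta <- data.frame(sample_id = sample_id[keep], study_id = sid[keep],
                     platform = s_platform[keep], key = key[keep],
                     value = val[keep], stringsAsFactors = FALSE)

  # source attributes: cell-line studies expose the line name, others a tissue
  cl_name <- lines$name[cl_row]
  src_key <- ifelse(is.na(s_cl), "tissue", "cell line")
  src_val <- ifelse(is.na(s_cl),
                    sample(c("liver", "brain", "blood", "kidney"), n,
                           replace = TRUE),
                    cl_name)
  meta <- rbind(meta, data.frame(sample_id = sample_id, study_id = sid,
                                 platform = s_platform, key = src_key,
                                 value = src_val, stringsAsFactors = FALSE))

  # drug studies: half treated samples, half controls
  s_drug <- rep(study_drug, n_per)
  has_drug <- !is.na(s_drug)
  drug_name <- drugs$name[match(s_drug, drugs$drug_id)]
  treated <- has_drug & stats::runif(n) < 0.5
  ctrl_terms <- c("dmso", "vehicle", "untreated", "control")
  trt_val <- ifelse(treated, paste(drug_name, "1 um"),
                    sample(ctrl_terms, n, replace = TRUE))
  if (any(has_drug)) {
    meta <- rbind(meta, data.frame(sample_id = sample_id[has_drug],
                                   study_id = sid[has_drug],
                                   platform = s_platform[has_drug],
                                   key = "treatment",
                                   value = trt_val[has_drug],
                                   stringsAsFactors = FALSE))
  }
  meta <- meta[order(meta$sample_id, meta$key, meta$value), ]
  rownames(meta) <- NULL

  studies <- data.frame(
    study_id = study_id,
    title = ifelse(is.na(study_drug),
                   paste("Expression profiling study", study_id),
                   paste("Effect of", drugs$name[drug_idx],
                         "on gene expression")),
    description = ifelse(is.na(study_drug),
                         "Synthetic transcriptome profiling.",
                         paste("Samples treated with",
                               drugs$name[drug_idx], "or vehicle control.")),
    platform = platform, data_type = cfg$data_type,
    stringsAsFactors = FALSE)

  ## -- truth -----------------------------------------------------------------
  truth <- data.frame(sample_id = sample_id, study_id = sid,
                      true_sex = true_sex, pooled_u = u,
                      metadata_sex = meta_sex, swap = swap,
                      cell_line = s_cl, y_silenced = y_silenced,
                      platform = s_platform, stringsAsFactors = FALSE)

  true_cat <- vapply(split(true_sex, sid), function(ts) {
    mf <- ts[ts %in% c("female", "male")]
    if (!length(mf)) return("mixed")
    pf <- mean(mf == "female")
    if (pf == 1) "female-only" else if (pf == 0) "male-only"
    else if (pf > 0.8) "mostly-female" else if (pf < 0.2) "mostly-male"
    else "mixed"
  }, character(1))
  study_truth <- data.frame(study_id = study_id,
                            true_category = true_cat[study_id],
                            is_single_sex = single,
                            cell_line = cl_acc, drug_id = study_drug,
                            stringsAsFactors = FALSE)

  samples <- data.frame(sample_id = sample_id, study_id = sid,
                        platform = s_platform, data_type = cfg$data_type,
                        stringsAsFactors = FALSE)

  structure(list(expr = expr, samples = samples, meta = meta,
                 studies = studies, genes = genes, truth = truth,
                 study_truth = study_truth,
                 cell_lines = lines[, c("accession", "name", "donor_sex",
                                        "yloss")],
                 config = cfg),
            class = "syn_corpus")
}

#' @export
print.syn_corpus <- function(x, ...) {
  cat(sprintf("syn_corpus: %d samples, %d studies, %d genes (%s)\n",
              nrow(x$expr), nrow(x$studies), ncol(x$expr),
              x$config$data_type))
  invisible(x)
}

#' Write a corpus to disk as plain-text tables
#'
#' Expression goes to `expr.tsv` (first column `sample_id`, genes as columns)
#' or, with `format = "mtx"`, to MatrixMarket `expr.mtx` plus row/column name
#' sidecars. Ground truth is written to separate files (`truth.tsv`,
#' `study_truth.tsv`, `cell_lines.tsv`) that pipeline stages never read.
#'
#' @param corpus a `syn_corpus`.
#' @param dir output directory (created if needed).
#' @param format "tsv" or "mtx" for the expression matrix.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, format = c("tsv", "mtx")) {
  stopifnot(inherits(corpus, "syn_corpus"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(corpus$expr),
                     corpus$expr, check.names = FALSE)
    write_tsv(df, file.path(dir, "expr.tsv"))
  } else {
    Matrix::writeMM(Matrix::Matrix(corpus$expr, sparse = TRUE),
                    file.path(dir, "expr.mtx"))
    writeLines(rownames(corpus$expr), file.path(dir, "expr.rownames.txt"))
    writeLines(colnames(corpus$expr), file.path(dir, "expr.colnames.txt"))
  }
  write_tsv(corpus$meta, file.path(dir, "meta.tsv"))
  write_tsv(corpus$studies, file.path(dir, "studies.tsv"))
  write_tsv(corpus$genes, file.path(dir, "genes.tsv"))
  write_tsv(corpus$truth, file.path(dir, "truth.tsv"))
  write_tsv(corpus$study_truth, file.path(dir, "study_truth.tsv"))
  write_tsv(corpus$cell_lines, file.path(dir, "cell_lines.tsv"))
  invisible(dir)
}

#' Read an expression matrix written by [write_corpus()]
#'
#' @param path path to `expr.tsv` or `expr.mtx`.
#' @return numeric matrix, samples x genes.
#' @export
read_expression <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".rownames.txt"))
    colnames(m) <- readLines(paste0(stem, ".colnames.txt"))
    return(m)
  }
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Generate lexicon fixtures emulating cell-line and drug references
#'
#' The fixtures deliberately include the edge cases the normalization rules
#' must handle: accessions sharing one name, punctuation variants, a synonym
#' colliding with another line's name, an all-numeric synonym, names shorter
#' than 3 characters, a mouse-strain synonym, drugs with <= 3-character
#' synonyms, multi-word drug names (2- and 3-grams), and the full 18-term
#' control vocabulary.
#'
#' @param seed integer seed (fixtures are fully deterministic; the seed only
#'   fixes row order).
#' @return list with data.frames `cell_lines` (accession, name, synonyms,
#'   donor_sex, recorded_sex, parent_id), `drugs` (drug_id, name, synonyms,
#'   atc_codes) and character vector `control_terms`.
#' @export
generate_lexicon_fixtures <- function(seed = 1L) {
  bl <- base_cell_lines()
  cells <- data.frame(
    accession = c(bl$accession,
                  "SYN-CVCL-9001", "SYN-CVCL-9002",  # duplicated name "kg-1"
                  "SYN-CVCL-9003",                   # punctuation variant
                  "SYN-CVCL-9004",                   # synonym collides with
                                                     # helx's canonical name
                  "SYN-CVCL-9005", "SYN-CVCL-9006",  # same name, same parent
                  "SYN-CVCL-9007",                   # the parent line
                  "SYN-CVCL-9008",                   # short + numeric terms
                  "SYN-CVCL-9009"),                  # punct-variant of u2os-s
    name = c(bl$name,
             "kg-1", "kg-1",
             "kyse-30",
             "sidera",
             "dupline", "dupline",
             "parentline",
             "zx",
             "u2os.s"),
    synonyms = c("hela-x", "kg7", "", "lncap-x", "", "", "", "", "", "",
                 "", "",
                 "", "",
                 "kyse30|k.y.s.e-30",
                 "helx|c57bl/6",
                 "", "",
                 "",
                 "1234|zx9",
                 ""),
    donor_sex = c(bl$donor_sex,
                  "male", "male", "male", "female", "male", "male", "male",
                  "female", "male"),
    recorded_sex = c(bl$donor_sex,
                     "male", "male", "male", "female", "male", "male", "male",
                     "female", "male"),
    parent_id = c(rep("", nrow(bl)),
                  "", "", "", "", "SYN-CVCL-9007", "SYN-CVCL-9007", "", "",
                  ""),
    stringsAsFactors = FALSE)

  bd <- base_drugs()
  drugs <- data.frame(
    drug_id = c(bd$drug_id, "SYNDB09001", "SYNDB09002", "SYNDB09003"),
    name = c(bd$name, "retinoic acid", "all-trans retinoic acid",
             "acetylsalicylic acid"),
    synonyms = c("nolvadex", "haldol", "adriamycin", "glucophage",
                 "prozac", "cddp|ace", "lipitor", "viagra", "femara",
                 "propecia",
                 "ra", "atra|tretinoin", "aspirin|asa"),
    atc_codes = c(paste0(bd$atc, "01"),
                  "D10", "L01|D10", "N02|B01"),
    stringsAsFactors = FALSE)

  control_terms <- c("none", "control", "untreated", "dmso", "na", "placebo",
                     "saline", "pbs", "mock", "baseline", "unstimulated",
                     "etoh", "ethanol", "ctrl", "non-treated", "vehicle",
                     "ctl", "no treatment")

  with_rng_seed(seed, {
    cells <- cells[order(cells$accession), ]
    drugs <- drugs[order(drugs$drug_id), ]
  })
  rownames(cells) <- rownames(drugs) <- NULL
  list(cell_lines = cells, drugs = drugs, control_terms = control_terms)
}

#' Write lexicon fixtures as TSV files
#'
#' @param dir output directory.
#' @param seed passed to [generate_lexicon_fixtures()].
#' @return `dir`, invisibly.
#' @export
write_lexicon_fixtures <- function(dir, seed = 1L) {
  fx <- generate_lexicon_fixtures(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(fx$cell_lines, file.path(dir, "cell_lines_lexicon.tsv"))
  write_tsv(fx$drugs, file.path(dir, "drugs_lexicon.tsv"))
  writeLines(fx$control_terms, file.path(dir, "control_terms.txt"))
  invisible(dir)
}
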