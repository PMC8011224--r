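# Metadata entity normalization: cell-line and drug lexicons, tiered
# attribute mapping, sample source-type classification, and drug-mention /
# drug-exposure study labeling.
#
# Lexicon terms are lowercased; a punctuation-stripped variant of every term
# is indexed alongside the exact form so names differing only in punctuation
# match. Tokenization keeps internal hyphens ("kyse-30", "non-treated").

#' Default stop words excluded from lexicon terms
#' @return character vector.
#' @export
default_stop_words <- function() {
  c("cell", "line", "cells", "lines", "culture", "human", "mouse",
    "tissue", "sample", "samples", "control", "normal", "primary",
    "type", "strain", "with", "from")
}

#' Default mouse-strain names excluded from the cell-line lexicon
#' @return character vector.
#' @export
default_mouse_strains <- function() {
  c("c57bl/6", "c57bl", "balb/c", "balb", "dba/2", "129sv", "fvb", "nod",
    "cd-1", "c3h")
}

#' The 18-term control vocabulary for treatment fields
#' @return character vector.
#' @export
control_vocabulary <- function() {
  c("none", "control", "untreated", "dmso", "na", "placebo", "saline",
    "pbs", "mock", "baseline", "unstimulated", "etoh", "ethanol", "ctrl",
    "non-treated", "vehicle", "ctl", "no treatment")
}

cell_term_ok <- function(term, stop_words, strains) {
  banned <- unique(c(stop_words, strip_punct(stop_words),
                     strains, strip_punct(strains)))
  nzchar(term) & nchar(term) >= 3 & !grepl("^[0-9]+$", term) &
    !term %in% banned
}

add_term <- function(env, term, acc) {
  if (!nzchar(term)) return(invisible())
  cur <- env[[term]]
  env[[term]] <- sort(unique(c(cur, acc)))
  invisible()
}

#' Build a normalized cell-line lexicon
#'
#' Rules: duplicate names (exact or punctuation-stripped) map to all their
#' accessions; a synonym colliding with another line's name is dropped in
#' favor of the name's own accession; identically named lines sharing a
#' parent are collapsed to the parent accession; terms shorter than 3
#' characters, all-numeric terms, stop words and mouse-strain names are
#' removed.
#'
#' @param records data.frame with `accession`, `name`, `synonyms`
#'   (pipe-separated), `donor_sex`, `recorded_sex`, `parent_id`.
#' @param stop_words,mouse_strains term exclusion lists.
#' @return object of class `cell_line_lexicon`: `term2acc` (named list),
#'   `acc_info` (data.frame), `collisions` (list of data.frames).
#' @export
build_cell_line_lexicon <- function(records,
                                    stop_words = default_stop_words(),
                                    mouse_strains = default_mouse_strains()) {
  empty <- structure(list(term2acc = list(),
                          acc_info = data.frame(),
                          collisions = list()),
                     class = "cell_line_lexicon")
  if (!nrow(records)) return(empty)
  rec <- records
  rec$name <- norm_string(rec$name)
  rec$parent_id <- trimws(as.character(records$parent_id %||%
                                         rep("", nrow(records))))
  rec$parent_id[is.na(rec$parent_id)] <- ""
  rec$synonyms <- as.character(records$synonyms %||%
                                 rep("", nrow(records)))
  rec$synonyms[is.na(rec$synonyms)] <- ""

  # identically named lines sharing one parent collapse to the parent
  rec$eff_acc <- rec$accession
  for (nm in unique(rec$name[duplicated(rec$name)])) {
    grp <- rec$name == nm
    par <- unique(rec$parent_id[grp])
    if (length(par) == 1 && nzchar(par)) rec$eff_acc[grp] <- par
  }

  env <- new.env(parent = emptyenv())
  name_key <- rec$name
  name_key_p <- strip_punct(rec$name)
  # accession sets owning each name (exact / punct-stripped)
  owner <- function(keys) {
    sp <- split(rec$eff_acc, keys)
    lapply(sp, function(a) sort(unique(a)))
  }
  own_exact <- owner(name_key)
  own_punct <- owner(name_key_p)

  same_name <- names(own_exact)[vapply(own_exact, length, 1L) > 1]
  same_name_punct <- setdiff(
    names(own_punct)[vapply(own_punct, length, 1L) > 1],
    strip_punct(same_name))

  for (i in seq_len(nrow(rec))) {
    accs <- own_exact[[name_key[i]]]
    accs_p <- own_punct[[name_key_p[i]]]
    add_term(env, name_key[i], union(accs, accs_p))
    add_term(env, name_key_p[i], union(accs, accs_p))
  }

  syn_conflicts <- list()
  for (i in seq_len(nrow(rec))) {
    syns <- strsplit(rec$synonyms[i], "\\|")[[1]]
    syns <- norm_string(syns[nzchar(trimws(syns))])
    for (s in syns) {
      sp <- strip_punct(s)
      owner_accs <- union(own_exact[[s]] %||% character(),
                          own_punct[[sp]] %||% character())
      if (length(owner_accs) && !rec$eff_acc[i] %in% owner_accs) {
        # synonym collides with another line's canonical name: keep the name
        syn_conflicts[[length(syn_conflicts) + 1L]] <-
          data.frame(term = s, synonym_of = rec$accession[i],
                     name_of = paste(owner_accs, collapse = "|"),
                     stringsAsFactors = FALSE)
        next
      }
      add_term(env, s, rec$eff_acc[i])
      add_term(env, sp, rec$eff_acc[i])
    }
  }

  term2acc <- as.list(env)
  keep <- cell_term_ok(names(term2acc), stop_words, mouse_strains)
  term2acc <- term2acc[keep]

  acc_info <- rec[, c("accession", "name", "donor_sex", "recorded_sex",
                      "parent_id")]
  rownames(acc_info) <- NULL
  structure(list(
    term2acc = term2acc, acc_info = acc_info,
    collisions = list(
      same_name = data.frame(term = same_name,
                             accessions = vapply(own_exact[same_name],
                                                 paste, "", collapse = "|"),
                             stringsAsFactors = FALSE),
      same_name_punct = data.frame(
        term = same_name_punct,
        accessions = vapply(own_punct[same_name_punct], paste, "",
                            collapse = "|"),
        stringsAsFactors = FALSE),
      synonym_vs_name = if (length(syn_conflicts))
        do.call(rbind, syn_conflicts)
      else data.frame(term = character(), synonym_of = character(),
                      name_of = character()))),
    class = "cell_line_lexicon")
}

lookup_terms <- function(lexicon, terms) {
  hits <- unlist(lapply(unique(terms), function(t)
    lexicon$term2acc[[t]]), use.names = FALSE)
  sort(unique(hits))
}

value_ngram_hits <- function(lexicon, value) {
  if (nchar(norm_string(value)) <= 3) return(character())
  toks <- tokenize(value)
  if (!length(toks)) return(character())
  grams <- character()
  for (n in 1:3) {
    if (length(toks) < n) break
    for (i in seq_len(length(toks) - n + 1)) {
      g <- paste(toks[i:(i + n - 1)], collapse = " ")
      grams <- c(grams, g, strip_punct(g))
    }
  }
  lookup_terms(lexicon, grams)
}

#' Map one sample's attributes to cell-line accessions
#'
#' Three attribute tiers of decreasing specificity are tried in order:
#' (1) keys containing both "cell" and "line", (2) values containing both,
#' (3) attribute pairs mentioning "cell" at all. Within a tier, whole-value
#' exact matches (terms of >= 3 characters) are tried before n-gram
#' (n = 1..3) matches over values longer than 3 characters; the first tier
#' with a hit wins and later tiers are never consulted.
#'
#' @param attributes data.frame with `key`, `value`.
#' @param lexicon a `cell_line_lexicon`.
#' @return list `accessions` (character), `tier` (1/2/3 or NA),
#'   `tiers_consulted` (integer vector, for instrumentation).
#' @export
map_sample_to_cell_lines <- function(attributes, lexicon) {
  keys <- norm_string(attributes$key)
  vals <- as.character(attributes$value)
  tier_rows <- list(
    which(contains_all_words(keys, c("cell", "line"))),
    which(contains_all_words(vals, c("cell", "line"))),
    which(grepl("cell", keys, fixed = TRUE) |
            grepl("cell", tolower(vals), fixed = TRUE)))
  consulted <- integer()
  for (tier in 1:3) {
    rows <- tier_rows[[tier]]
    if (!length(rows)) next
    consulted <- c(consulted, tier)
    v <- vals[rows]
    exact <- lookup_terms(lexicon,
                          c(norm_string(v), strip_punct(v)))
    if (length(exact)) {
      return(list(accessions = exact, tier = tier,
                  tiers_consulted = consulted))
    }
    ng <- sort(unique(unlist(lapply(v, value_ngram_hits,
                                    lexicon = lexicon))))
    if (length(ng)) {
      return(list(accessions = ng, tier = tier,
                  tiers_consulted = consulted))
    }
  }
  list(accessions = character(), tier = NA_integer_,
       tiers_consulted = consulted)
}

#' Classify a sample's source type from its attributes
#'
#' Exact lexical keyword tests applied in fixed precedence:
#' xenograft > stem cell > primary cell > cancer cell > cell line
#' (named when a cell-line accession is attached, unnamed otherwise) >
#' tissue > other.
#'
#' @param attributes data.frame with `key`, `value`.
#' @param cell_accessions accessions from [map_sample_to_cell_lines()].
#' @return one of "xenograft", "stem_cell", "primary_cell", "cancer_cell",
#'   "cell_line_named", "cell_line_unnamed", "tissue", "other".
#' @export
classify_source_type <- function(attributes, cell_accessions = character()) {
  text <- norm_string(paste(attributes$key, attributes$value,
                            collapse = " "))
  has <- function(terms) any(vapply(terms, grepl, logical(1), x = text,
                                    fixed = TRUE))
  if (has(c("xenograft", "pdx"))) return("xenograft")
  if (has(c("stem cell", "stem-cell", "ipsc", "embryonic stem",
            "ips cell"))) return("stem_cell")
  if (has(c("primary cell", "primary culture"))) return("primary_cell")
  if (has(c("cancer cell", "tumor cell", "tumour cell",
            "carcinoma cell"))) return("cancer_cell")
  if (has(c("cell line", "cell-line", "cellline")) ||
      length(cell_accessions)) {
    return(if (length(cell_accessions)) "cell_line_named"
           else "cell_line_unnamed")
  }
  if (has(c("tissue", "biopsy"))) return("tissue")
  "other"
}

#' Build a normalized drug lexicon
#'
#' Names and synonyms of 3 or fewer characters and stop words are discarded;
#' terms are lowercased and punctuation-stripped variants indexed. The
#' control vocabulary is stored verbatim.
#'
#' @param records data.frame with `drug_id`, `name`, `synonyms`
#'   (pipe-separated), `atc_codes` (pipe-separated).
#' @param control_terms control vocabulary (default the 18 bundled terms).
#' @param stop_words excluded terms.
#' @return object of class `drug_lexicon`: `term2drug` (named list),
#'   `atc` (named list drug_id -> codes), `names` (named character),
#'   `control_terms`.
#' @export
build_drug_lexicon <- function(records,
                               control_terms = control_vocabulary(),
                               stop_words = default_stop_words()) {
  env <- new.env(parent = emptyenv())
  syn_col <- as.character(records$synonyms %||% rep("", nrow(records)))
  syn_col[is.na(syn_col)] <- ""
  for (i in seq_len(nrow(records))) {
    terms <- norm_string(c(records$name[i],
                           strsplit(syn_col[i], "\\|")[[1]]))
    terms <- terms[nzchar(terms)]
    terms <- terms[nchar(terms) > 3 & !terms %in% stop_words]
    for (t in unique(c(terms, strip_punct(terms)))) {
      if (nchar(t) > 3 && !t %in% stop_words) {
        add_term(env, t, records$drug_id[i])
      }
    }
  }
  atc_col <- as.character(records$atc_codes %||% rep("", nrow(records)))
  atc_col[is.na(atc_col)] <- ""
  atc <- lapply(strsplit(atc_col, "\\|"), function(a) a[nzchar(a)])
  names(atc) <- records$drug_id
  structure(list(term2drug = as.list(env), atc = atc,
                 names = setNames(records$name, records$drug_id),
                 control_terms = norm_string(control_terms)),
            class = "drug_lexicon")
}

# n-gram scan with longest-match shadowing: a span wholly covered by an
# earlier (longer) hit is skipped.
ngram_scan <- function(toks, is_hit) {
  covered <- rep(FALSE, length(toks))
  hits <- character()
  for (n in 3:1) {
    if (length(toks) < n) next
    for (i in seq_len(length(toks) - n + 1)) {
      span <- i:(i + n - 1)
      if (all(covered[span])) next
      g <- paste(toks[span], collapse = " ")
      if (is_hit(g)) {
        hits <- c(hits, g)
        covered[span] <- TRUE
      }
    }
  }
  unique(hits)
}

#' Map free text to drug ids and the control vocabulary
#'
#' n-grams (n = 1..3) over normalized tokens are matched against lexicon
#' terms and control terms; a longer hit shadows its sub-grams. A text may
#' map to both drugs and a control term.
#'
#' @param text character scalar (may be empty).
#' @param lexicon a `drug_lexicon`.
#' @return list `drug_ids` (character), `control` (logical).
#' @export
map_text_to_drugs <- function(text, lexicon) {
  if (is.na(text) || !nzchar(trimws(text))) {
    return(list(drug_ids = character(), control = FALSE))
  }
  toks <- tokenize(text)
  if (!length(toks)) return(list(drug_ids = character(), control = FALSE))
  drug_hits <- ngram_scan(toks, function(g)
    !is.null(lexicon$term2drug[[g]]) ||
      !is.null(lexicon$term2drug[[strip_punct(g)]]))
  ids <- sort(unique(unlist(lapply(drug_hits, function(g)
    c(lexicon$term2drug[[g]], lexicon$term2drug[[strip_punct(g)]])))))
  ctrl_hits <- ngram_scan(toks, function(g) g %in% lexicon$control_terms)
  list(drug_ids = ids %||% character(), control = length(ctrl_hits) > 0)
}

#' Label drug-mention and drug-exposure studies
#'
#' A *drug-mention* study's title + description maps to at least one drug; a
#' *drug-exposure* study additionally has a sample-level treatment field
#' mapping to one of the same drugs. Output pairs are restricted to the
#' study-sample drug intersection.
#'
#' @param studies data.frame with `study_id`, `title`, `description`.
#' @param sample_fields data.frame with `sample_id`, `study_id`, `value`
#'   (treatment / compound / sample-title strings).
#' @param lexicon a `drug_lexicon`.
#' @return list `mention` and `exposure` (data.frames study_id, drug_id) and
#'   `sample_drugs` (sample_id, study_id, drug_id, control).
#' @export
label_drug_studies <- function(studies, sample_fields, lexicon) {
  study_map <- lapply(seq_len(nrow(studies)), function(i)
    map_text_to_drugs(paste(studies$title[i], studies$description[i]),
                      lexicon)$drug_ids)
  names(study_map) <- studies$study_id
  mention <- do.call(rbind, lapply(studies$study_id, function(s) {
    d <- study_map[[s]]
    if (!length(d)) return(NULL)
    data.frame(study_id = s, drug_id = d, stringsAsFactors = FALSE)
  }))

  samp <- do.call(rbind, lapply(seq_len(nrow(sample_fields)), function(i) {
    m <- map_text_to_drugs(sample_fields$value[i], lexicon)
    if (!length(m$drug_ids) && !m$control) return(NULL)
    data.frame(sample_id = sample_fields$sample_id[i],
               study_id = sample_fields$study_id[i],
               drug_id = if (length(m$drug_ids)) m$drug_ids else
                 NA_character_,
               control = m$control, stringsAsFactors = FALSE)
  }))

  exposure <- NULL
  if (!is.null(samp)) {
    samp_drugs <- samp[!is.na(samp$drug_id), ]
    by_study <- split(samp_drugs$drug_id, samp_drugs$study_id)
    exposure <- do.call(rbind, lapply(names(by_study), function(s) {
      overlap <- intersect(unique(by_study[[s]]),
                           study_map[[s]] %||% character())
      if (!length(overlap)) return(NULL)
      data.frame(study_id = s, drug_id = overlap, stringsAsFactors = FALSE)
    }))
  }
  list(mention = mention %||%
         data.frame(study_id = character(), drug_id = character()),
       exposure = exposure %||%
         data.frame(study_id = character(), drug_id = character()),
       sample_drugs = samp %||%
         data.frame(sample_id = character(), study_id = character(),
                    drug_id = character(), control = logical()))
}

#' Map every sample of a metadata table to cell lines
#'
#' @param meta long metadata data.frame (`sample_id`, `key`, `value`).
#' @param lexicon a `cell_line_lexicon`.
#' @return data.frame sample_id, accession (one row per hit), tier.
#' @export
map_all_samples_to_cell_lines <- function(meta, lexicon) {
  out <- lapply(split(meta, meta$sample_id), function(df) {
    hit <- map_sample_to_cell_lines(df[, c("key", "value")], lexicon)
    if (!length(hit$accessions)) return(NULL)
    data.frame(sample_id = df$sample_id[1], accession = hit$accessions,
               tier = hit$tier, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(sample_id = character(), accession = character(),
                      tier = integer()))
  }
  rownames(res) <- NULL
  res
}
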