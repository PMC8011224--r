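# Curated entity-mapping cases (expected outputs written by hand); shared
# between the entities unit tests and the acceptance suite.

cell_cases <- function() {
  # key | value | expected accessions (comma-sep, "" = none) | expected tier
  m <- matrix(c(
    "cell line", "helx",                      "0001",      "1",
    "cell line", "HELX",                      "0001",      "1",
    "cell line", "  helx  ",                  "0001",      "1",
    "cell line", "kg-1",                      "9001,9002", "1",
    "cell line", "kg1",                       "9001,9002", "1",
    "cell line", "kyse30",                    "9003",      "1",
    "cell line", "k.y.s.e-30",                "9003",      "1",
    "cell line", "u2os.s",                    "0009,9009", "1",
    "cell line", "u2os-s",                    "0009,9009", "1",
    "cell line", "dupline",                   "9007",      "1",
    "cell line", "parentline",                "9007",      "1",
    "cell line", "1234",                      "",          "NA",
    "cell line", "zx",                        "",          "NA",
    "cell line", "zx9",                       "9008",      "1",
    "cell line", "c57bl/6",                   "",          "NA",
    "cell line", "sidera",                    "9004",      "1",
    "cell line", "hela-x",                    "0001",      "1",
    "cell line", "lncap-x",                   "0004",      "1",
    "cell line", "mframe-2",                  "0003",      "1",
    "cell line", "jurkat-s",                  "0007",      "1",
    "cell line", "pc3-s",                     "0012",      "1",
    "cell line", "mcf-s",                     "0010",      "1",
    "cell line", "totally unknown xyz",       "",          "NA",
    "source",    "helx cell line, cervix",    "0001",      "2",
    "source",    "vero-s cells from cell line bank", "0006", "2",
    "cell type", "grown from kyse30 cells",   "9003",      "3",
    "tissue",    "liver",                     "",          "NA",
    "description", "primary cells",           "",          "NA"
  ), ncol = 4, byrow = TRUE)
  data.frame(key = m[, 1], value = m[, 2], accessions = m[, 3],
             tier = m[, 4], stringsAsFactors = FALSE)
}

source_cases <- function() {
  m <- matrix(c(
    "source", "xenograft model",        "0", "xenograft",
    "model",  "PDX passage 2",          "0", "xenograft",
    "source", "stem cell derived",      "0", "stem_cell",
    "source", "iPSC clone 4",           "0", "stem_cell",
    "source", "primary culture",        "0", "primary_cell",
    "source", "cancer cell isolate",    "0", "cancer_cell",
    "source", "cell line sample",       "1", "cell_line_named",
    "source", "cell line sample",       "0", "cell_line_unnamed",
    "source", "liver tissue biopsy",    "0", "tissue",
    "note",   "unremarkable",           "0", "other",
    "source", "xenograft from cell line", "1", "xenograft",
    "source", "stem cell line",         "0", "stem_cell"
  ), ncol = 4, byrow = TRUE)
  data.frame(key = m[, 1], value = m[, 2], has_acc = m[, 3] == "1",
             expected = m[, 4], stringsAsFactors = FALSE)
}

drug_cases <- function() {
  m <- matrix(c(
    "treated with dmso",            "",                      "1",
    "tamoxifen 1 um in dmso",       "SYNDB00001",            "1",
    "",                             "",                      "0",
    "ace",                          "",                      "0",
    "asa",                          "",                      "0",
    "aspirin 100mg",                "SYNDB09003",            "0",
    "acetylsalicylic acid",         "SYNDB09003",            "0",
    "all-trans retinoic acid",      "SYNDB09002",            "0",
    "retinoic acid",                "SYNDB09001",            "0",
    "tretinoin",                    "SYNDB09002",            "0",
    "nolvadex and haldol",          "SYNDB00001,SYNDB00002", "0",
    "Prozac",                       "SYNDB00005",            "0",
    "no treatment",                 "",                      "1",
    "non-treated",                  "",                      "1",
    "vehicle (pbs)",                "",                      "1",
    "cddp",                         "SYNDB00006",            "0",
    "na",                           "",                      "1",
    "letrozole vs placebo",         "SYNDB00009",            "1",
    "glucophage 500 mg",            "SYNDB00004",            "0",
    "viagra",                       "SYNDB00008",            "0",
    "finasteride treatment",        "SYNDB00010",            "0",
    "doxorubicin + cisplatin",      "SYNDB00003,SYNDB00006", "0",
    "Atorvastatin daily",           "SYNDB00007",            "0",
    "mock transfection",            "",                      "1"
  ), ncol = 3, byrow = TRUE)
  data.frame(text = m[, 1], drugs = m[, 2], control = m[, 3] == "1",
             stringsAsFactors = FALSE)
}
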