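# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are deterministic
#' under their `seed` argument without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single proportion in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Lowercase, trim, collapse internal whitespace.
norm_string <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Strip everything that is not a letter, digit or space (punctuation-free key).
strip_punct <- function(x) {
  gsub("[[:space:]]+", " ", trimws(gsub("[^a-z0-9 ]", "", norm_string(x))))
}

# Tokenize on whitespace/punctuation but keep internal hyphens
# ("kyse-30", "non-treated" stay single tokens).
tokenize <- function(x) {
  x <- norm_string(x)
  toks <- strsplit(gsub("(?<![a-z0-9])-|-(?![a-z0-9])", " ",
                        gsub("[^a-z0-9-]+", " ", x), perl = TRUE),
                   "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# Does any element of `keys` contain all of `words` (case-insensitive)?
contains_all_words <- function(x, words) {
  x <- norm_string(x)
  vapply(x, function(v) all(vapply(words, grepl, logical(1), x = v,
                                   fixed = TRUE)), logical(1))
}

logistic <- function(z) 1 / (1 + exp(-z))

# Write a data.frame as TSV with an optional "# key: value" comment header.
write_tsv <- function(df, path, header_comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
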