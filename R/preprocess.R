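# Expression pre-processing: low-count RNA-seq sample filtering and a
# per-gene Box-Cox transform toward normality (microarray compendia arrive
# already normalized and are passed through untouched).

#' Filtering configuration
#'
#' @param min_read_counts samples with a total count strictly below this are
#'   removed (default 1e5; removal is "fewer than", so the boundary is kept).
#' @param data_type "rnaseq" or "microarray".
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_read_counts = 100000,
                          data_type = c("rnaseq", "microarray")) {
  stopifnot(is.numeric(min_read_counts), min_read_counts >= 0)
  structure(list(min_read_counts = min_read_counts,
                 data_type = match.arg(data_type)),
            class = "filter_config")
}

#' Remove low-count RNA-seq samples
#'
#' @param expr numeric matrix of nonnegative counts, samples x genes.
#' @param config a [filter_config()].
#' @return the matrix restricted to samples with total count
#'   >= `min_read_counts`; gene set unchanged. Microarray input is returned
#'   unchanged with a warning.
#' @export
filter_low_count_samples <- function(expr, config = filter_config()) {
  stopifnot(is.matrix(expr))
  if (config$data_type == "microarray") {
    warning("count filter is a no-op for microarray data")
    return(expr)
  }
  if (any(expr < 0)) stop("count matrix must be nonnegative", call. = FALSE)
  keep <- rowSums(expr) >= config$min_read_counts
  expr[keep, , drop = FALSE]
}

# Box-Cox profile log-likelihood for a strictly positive vector.
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  z <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  s2 <- mean((z - mean(z))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

#' Box-Cox transform a nonnegative vector
#'
#' The power parameter lambda is chosen by maximum likelihood over
#' `[-2, 2]` (golden-section search on the profile log-likelihood; tests
#' cross-check against a brute-force grid). Vectors containing zeros receive
#' `offset` first. The transform `(x^lambda - 1)/lambda` (log at lambda = 0)
#' is strictly increasing. A constant vector is returned unchanged with
#' `lambda = NA` — there is no normality to improve.
#'
#' @param x numeric vector, nonnegative.
#' @param offset added when any value is <= 0 (default 0.5).
#' @param interval search interval for lambda.
#' @return list with `transformed`, `lambda`, `offset_used`.
#' @export
boxcox_transform <- function(x, offset = 0.5, interval = c(-2, 2)) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x >= 0))
  off <- if (any(x <= 0)) offset else 0
  xs <- x + off
  if (max(xs) - min(xs) < 1e-12) {
    return(list(transformed = x, lambda = NA_real_, offset_used = off))
  }
  opt <- stats::optimize(function(l) boxcox_loglik(xs, l), interval,
                         maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  z <- if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
  list(transformed = z, lambda = lambda, offset_used = off)
}

#' Preprocess an expression matrix for modeling
#'
#' RNA-seq: low-count samples are dropped, then each gene (column) is Box-Cox
#' transformed across samples. Microarray: pass-through.
#'
#' @param expr numeric matrix, samples x genes.
#' @param config a [filter_config()].
#' @return list with `expr` (transformed matrix) and `lambdas` (per-gene
#'   data.frame, NA for untransformed genes).
#' @export
preprocess_expression <- function(expr, config = filter_config()) {
  if (config$data_type == "microarray") {
    return(list(expr = expr,
                lambdas = data.frame(gene_id = colnames(expr),
                                     lambda = NA_real_)))
  }
  expr <- filter_low_count_samples(expr, config)
  lambdas <- numeric(ncol(expr))
  out <- expr
  for (j in seq_len(ncol(expr))) {
    bc <- boxcox_transform(expr[, j])
    out[, j] <- bc$transformed
    lambdas[j] <- bc$lambda
  }
  list(expr = out,
       lambdas = data.frame(gene_id = colnames(expr), lambda = lambdas))
}
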