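#' Construct a validated correlation matrix object
#'
#' @param values p x p numeric matrix; must be symmetric within 1e-12,
#'   have a unit diagonal, and all entries in \[-1, 1\]. Positive
#'   semi-definiteness is checked where it matters, in
#'   [pca_from_correlation()], with a small negative tolerance: matrices
#'   transcribed from rounded print can carry eigenvalues a hair below
#'   zero without being data errors.
#' @param labels ordered variable names (defaults to `colnames(values)`).
#' @param method correlation type, `"spearman"` or `"pearson"`.
#' @return An `hv_corr` with elements `values`, `labels`, `method`.
#' @export
correlation_matrix <- function(values,
                               labels = colnames(values),
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  p <- nrow(values)
  if (ncol(values) != p) {
    stop("correlation matrix must be square", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("v", seq_len(p))
  if (length(labels) != p) {
    stop("labels length does not match matrix dimension", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-12) {
    stop("fixture-integrity error: matrix asymmetric beyond 1e-12",
         call. = FALSE)
  }
  if (max(abs(diag(values) - 1)) > 1e-12) {
    stop("fixture-integrity error: diagonal entries differ from 1",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(abs(values) > 1 + 1e-12)) {
    stop("correlation entries must be finite and in [-1, 1]",
         call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 1
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, method = method),
            class = "hv_corr")
}

#' @export
print.hv_corr <- function(x, ...) {
  cat(nrow(x$values), "x", ncol(x$values), x$method,
      "correlation matrix\n")
  print(round(x$values, 2))
  invisible(x)
}

check_degenerate <- function(v) {
  sds <- apply(v, 2, sd)
  if (any(sds == 0)) {
    stop("degenerate-variable error: constant column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  }
}

#' Spearman rank correlation matrix of an indicator table
#'
#' Computes the tie-aware Spearman matrix: each column is replaced by its
#' average (mid-) ranks — tied values receive the mean of the ranks they
#' span — and the Pearson product-moment correlation of the ranked
#' columns is returned. Invariant under strictly increasing per-column
#' transforms of the data. This matrix is used for reporting and for
#' comparison against the packaged reference matrices; factor scoring
#' uses [pearson_matrix()].
#'
#' @param table an [indicator_table()], n >= 3 rows, no constant column.
#' @return An `hv_corr` with `method = "spearman"`.
#' @export
spearman_matrix <- function(table) {
  stopifnot(inherits(table, "hv_table"))
  v <- table$values
  if (nrow(v) < 3) stop("need at least 3 counties", call. = FALSE)
  check_degenerate(v)
  r <- apply(v, 2, rank)  # average ranks for ties
  m <- stats::cor(r, method = "pearson")
  diag(m) <- 1
  correlation_matrix(m, labels = colnames(v), method = "spearman")
}

#' Pearson correlation matrix of an indicator table
#'
#' Standard product-moment correlations of the raw indicator columns;
#' identical to the covariance of the column-standardized table. This is
#' the conventional PCA input for vulnerability indices built from raw
#' data, and the matrix inverted by the regression factor-scoring step.
#'
#' @inheritParams spearman_matrix
#' @return An `hv_corr` with `method = "pearson"`.
#' @export
pearson_matrix <- function(table) {
  stopifnot(inherits(table, "hv_table"))
  v <- table$values
  if (nrow(v) < 3) stop("need at least 3 counties", call. = FALSE)
  check_degenerate(v)
  m <- stats::cor(v, method = "pearson")
  diag(m) <- 1
  correlation_matrix(m, labels = colnames(v), method = "pearson")
}

#' Write a correlation matrix in the fixture layout
#'
#' Same delimited layout as the packaged reference matrices (a `variable`
#' label column followed by one column per variable), so computed
#' matrices can be diffed against the transcriptions.
#'
#' @param corr an `hv_corr`.
#' @param path output path.
#' @param digits decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(corr, path, digits = 6) {
  stopifnot(inherits(corr, "hv_corr"))
  df <- data.frame(variable = corr$labels,
                   round(corr$values, digits),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a correlation matrix written in the fixture layout
#'
#' @param path path to a matrix file with a `variable` label column.
#' @param method correlation type recorded on the result.
#' @return An `hv_corr`.
#' @export
read_correlation_matrix <- function(path,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df$variable
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(labels, colnames(m))) {
    stop("fixture-integrity error: row and column labels disagree in ",
         path, call. = FALSE)
  }
  correlation_matrix(m, labels = labels, method = method)
}
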