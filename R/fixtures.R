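#' Packaged reference Spearman correlation matrix
#'
#' Loads the 10 x 10 Spearman correlation matrix for one population
#' stratum, transcribed from the published summary table of the
#' 73-county study the package's defaults are calibrated to. The
#' transcription records each printed cell verbatim (one entry is printed
#' with three decimals and one without a leading zero; both are kept as
#' printed); the lower triangle was mirrored to form the full matrix.
#' Every cell, with its printed form, significance star and any
#' transcription note, is listed in the manifest returned by
#' [fixture_manifest()].
#'
#' @param stratum `"urban"` or `"rural"`.
#' @return An `hv_corr` with `method = "spearman"`.
#' @examples
#' fixture_correlation("urban")$values["low_income", "low_income_households"]
#' @export
fixture_correlation <- function(stratum = c("urban", "rural")) {
  stratum <- match.arg(stratum)
  path <- system.file("extdata",
                      paste0("spearman_", stratum, ".csv"),
                      package = "heatvuln", mustWork = TRUE)
  corr <- read_correlation_matrix(path, method = "spearman")
  if (!identical(corr$labels, hv_variables())) {
    stop("fixture-integrity error: variable set in ", path,
         " does not match the indicator schema", call. = FALSE)
  }
  corr
}

#' Transcription manifest for the reference correlation matrices
#'
#' One row per lower-triangle cell of each stratum's matrix: the printed
#' string, the numeric value recorded, the significance star as printed,
#' and a note where the printed form needed a transcription decision
#' (including one rural cell whose significance star is inconsistent with
#' its printed magnitude and is flagged as a suspected misprint).
#'
#' @return Data frame with columns `stratum`, `row_var`, `col_var`,
#'   `printed`, `value`, `significance`, `note`.
#' @export
fixture_manifest <- function() {
  path <- system.file("extdata", "spearman_transcription_manifest.csv",
                      package = "heatvuln", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, na.strings = NULL)
}

#' Reference marginal moments of the ten indicators
#'
#' Mean, standard deviation, minimum and maximum of each indicator in the
#' source study's 73 counties, per stratum. These are the default
#' calibration targets of the synthetic county generator
#' ([synthetic_config()]).
#'
#' @param stratum `"urban"`, `"rural"`, or `NULL` for both.
#' @return Data frame with columns `stratum`, `variable`, `mean`, `sd`,
#'   `min`, `max` (variables in schema order).
#' @export
fixture_moments <- function(stratum = NULL) {
  path <- system.file("extdata", "indicator_moments.csv",
                      package = "heatvuln", mustWork = TRUE)
  mom <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, c("urban", "rural"))
    mom <- mom[mom$stratum == stratum, , drop = FALSE]
    mom <- mom[match(hv_variables(), mom$variable), , drop = FALSE]
    rownames(mom) <- NULL
  }
  mom
}

#' Published rotated factor loadings (reference only)
#'
#' The rotated loading matrices reported by the source study for urban
#' and rural residents (10 variables x 4 factors). These were estimated
#' from census microdata that is not publicly available; they are shipped
#' for cross-validation of the factor engine (e.g. congruence with
#' loadings recovered from the reference correlation matrices), never as
#' an input to the pipeline.
#'
#' @param stratum `"urban"` or `"rural"`.
#' @return 10 x 4 numeric matrix, rows in schema order.
#' @export
fixture_published_loadings <- function(stratum = c("urban", "rural")) {
  stratum <- match.arg(stratum)
  path <- system.file("extdata", "published_loadings.csv",
                      package = "heatvuln", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$stratum == stratum, , drop = FALSE]
  df <- df[match(hv_variables(), df$variable), , drop = FALSE]
  m <- as.matrix(df[, paste0("factor_", 1:4)])
  rownames(m) <- df$variable
  colnames(m) <- paste0("factor_", 1:4)
  m
}
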