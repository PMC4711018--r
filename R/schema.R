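#' Indicator schema for heat vulnerability tables
#'
#' The index is built from ten county-level indicators, all expressed as
#' percentages in \[0, 100\] and coded so that higher values mean higher
#' vulnerability to extreme heat. The variable set and order are fixed:
#'
#' \describe{
#'   \item{age_ge60}{percent population aged 60 or older}
#'   \item{loss_labor_ability}{percent population having lost labor ability
#'     through physical or mental disease}
#'   \item{illiterate}{percent population (15+) illiterate; the census
#'     word-count threshold differs between the urban and rural strata}
#'   \item{living_alone}{percent population living alone}
#'   \item{age_ge60_living_alone}{percent population aged 60+ living alone}
#'   \item{low_income}{percent population receiving minimum living
#'     allowances}
#'   \item{low_income_seniors}{percent elderly receiving minimum living
#'     allowances}
#'   \item{low_income_households}{percent households receiving minimum
#'     living allowances}
#'   \item{households_one_room}{percent households with a single room}
#'   \item{households_le8m2}{percent households with under 8 m2 gross
#'     floor area}
#' }
#'
#' @param stratum population stratum, `"urban"` or `"rural"`. The split
#'   follows the Chinese census definition (city districts and towns vs
#'   villages); each county contributes a row to each stratum's table.
#' @return An object of class `hv_schema` with elements `variables`
#'   (ordered character vector of length 10), `units` (`"percent"`) and
#'   `stratum`.
#' @examples
#' hv_schema("urban")$variables
#' @export
hv_schema <- function(stratum = c("urban", "rural")) {
  stratum <- match.arg(stratum)
  structure(
    list(variables = hv_variables(), units = "percent", stratum = stratum),
    class = "hv_schema"
  )
}

#' Canonical indicator variable names, in schema order
#'
#' @return Character vector of the 10 indicator names.
#' @export
hv_variables <- function() {
  c("age_ge60", "loss_labor_ability", "illiterate", "living_alone",
    "age_ge60_living_alone", "low_income", "low_income_seniors",
    "low_income_households", "households_one_room", "households_le8m2")
}

#' Construct a validated county indicator table
#'
#' @param values numeric matrix or data frame, counties in rows, the 10
#'   indicators in columns (any column order; they are reordered to schema
#'   order). All values must be finite percentages in \[0, 100\]; missing
#'   cells are rejected, never imputed.
#' @param county_ids unique county identifiers, one per row.
#' @param schema an [hv_schema()].
#' @param area_ids optional grouping label per county (e.g. the
#'   prefecture-level area), used by [summarize_index()].
#' @return An `hv_table` with elements `county_ids`, `area_ids`, `values`
#'   (n x 10 matrix, schema column order) and `schema`.
#' @export
indicator_table <- function(values, county_ids, schema = hv_schema(),
                            area_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("indicator values must be numeric", call. = FALSE)
  }
  vars <- schema$variables
  if (is.null(colnames(values))) {
    if (ncol(values) != length(vars)) {
      stop("expected ", length(vars), " indicator columns, got ",
           ncol(values), call. = FALSE)
    }
    colnames(values) <- vars
  }
  missing_cols <- setdiff(vars, colnames(values))
  if (length(missing_cols) > 0) {
    stop("schema error: missing indicator column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  values <- values[, vars, drop = FALSE]
  county_ids <- as.character(county_ids)
  n <- nrow(values)
  if (length(county_ids) != n) {
    stop("county_ids length (", length(county_ids),
         ") does not match row count (", n, ")", call. = FALSE)
  }
  dup <- county_ids[duplicated(county_ids)]
  if (length(dup) > 0) {
    stop("validation error: duplicate county id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!is.null(area_ids)) {
    area_ids <- as.character(area_ids)
    if (length(area_ids) != n) {
      stop("area_ids length does not match row count", call. = FALSE)
    }
  }
  bad <- which(!is.finite(values) | values < 0 | values > 100,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("validation error: value ", format(values[i, j]),
         " for county '", county_ids[i], "', variable '",
         vars[j], "' is missing or outside [0, 100] (",
         nrow(bad), " offending cell(s))", call. = FALSE)
  }
  rownames(values) <- county_ids
  structure(
    list(county_ids = county_ids, area_ids = area_ids,
         values = values, schema = schema),
    class = "hv_table"
  )
}

#' @export
print.hv_table <- function(x, ...) {
  cat("County indicator table (", x$schema$stratum, " stratum): ",
      nrow(x$values), " counties x ", ncol(x$values), " indicators\n",
      sep = "")
  invisible(x)
}

#' Read a county indicator table from delimited text
#'
#' Expects a UTF-8 header row naming a `county_id` column, optionally an
#' `area_id` column, and all 10 schema variables (in any order); one row
#' per county. Values must be percentages in \[0, 100\] with no missing
#' cells.
#'
#' @param path path to the delimited file.
#' @param schema an [hv_schema()] giving the variable set and stratum.
#' @param sep field separator: `","` (default) or `"\t"`.
#' @return An [indicator_table()].
#' @seealso [write_indicator_table()]
#' @export
load_indicator_table <- function(path, schema = hv_schema(), sep = ",") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (!"county_id" %in% names(df)) {
    stop("schema error: missing column 'county_id' in ", path,
         call. = FALSE)
  }
  missing_cols <- setdiff(schema$variables, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing indicator column(s): ",
         paste(missing_cols, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  vals <- df[, schema$variables, drop = FALSE]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    stop("validation error: non-numeric values in column(s): ",
         paste(non_num, collapse = ", "), call. = FALSE)
  }
  indicator_table(as.matrix(vals), df$county_id, schema = schema,
                  area_ids = if ("area_id" %in% names(df)) df$area_id)
}

#' Write a county indicator table to delimited text
#'
#' Values are written at a fixed decimal precision so that a
#' write-then-load round trip reproduces the table exactly.
#'
#' @param table an [indicator_table()].
#' @param path output path.
#' @param sep field separator.
#' @param digits decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(table, path, sep = ",", digits = 6) {
  stopifnot(inherits(table, "hv_table"))
  vals <- round(table$values, digits)
  df <- data.frame(county_id = table$county_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(table$area_ids)) df$area_id <- table$area_ids
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-variable summary statistics of an indicator table
#'
#' Mean, standard deviation (sample convention, n - 1 denominator),
#' minimum and maximum per indicator, in schema order.
#'
#' @param table an [indicator_table()].
#' @return Data frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_indicators <- function(table) {
  stopifnot(inherits(table, "hv_table"))
  v <- table$values
  data.frame(
    variable = colnames(v),
    mean = apply(v, 2, mean),
    sd = apply(v, 2, sd),
    min = apply(v, 2, min),
    max = apply(v, 2, max),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
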