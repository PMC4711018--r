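#' Six-category integer score of a standardized factor score
#'
#' Maps a standardized score to an integer category by its
#' standard-deviation distance from the mean:
#'
#' | category | range |
#' |---|---|
#' | 1 | z <= -2 (2 or more SD below the mean) |
#' | 2 | -2 < z <= -1 |
#' | 3 | -1 < z < 0 |
#' | 4 | 0 <= z < 1 |
#' | 5 | 1 <= z < 2 |
#' | 6 | z >= 2 (2 or more SD above the mean) |
#'
#' The outer categories are closed at +/-2 by definition; the inner
#' boundary convention (negative boundaries assigned outward, zero and
#' positive boundaries assigned upward) is symmetric at +/-2 and places
#' the mean in category 4. Counties landing exactly on a boundary are
#' counted in the `"boundary_hits"` attribute.
#'
#' @param z numeric vector of standardized scores; must be finite.
#' @return Integer vector of categories in 1..6, with attribute
#'   `boundary_hits` (count of inputs exactly on a category boundary).
#' @export
bin_score <- function(z) {
  if (any(!is.finite(z))) {
    stop("validation error: non-finite standardized score", call. = FALSE)
  }
  cat <- ifelse(z <= -2, 1L,
         ifelse(z <= -1, 2L,
         ifelse(z < 0, 3L,
         ifelse(z < 1, 4L,
         ifelse(z < 2, 5L, 6L)))))
  structure(as.integer(cat),
            boundary_hits = sum(z %in% c(-2, -1, 0, 1, 2)))
}

#' Cumulative heat vulnerability index from factor scores
#'
#' Applies [bin_score()] to every standardized factor score and sums the
#' integer categories per county. With four retained factors the
#' cumulative index lies in \[4, 24\], both bounds attainable.
#'
#' @param scores an `hv_scores` from [factor_scores()]; must carry the
#'   standardized contract (each column mean 0, sample SD 1).
#' @param stratum population stratum label recorded on the result.
#' @param check verify the mean-0 / SD-1 contract numerically (default
#'   TRUE; a column of exact zeros — every county at the mean — is
#'   accepted). Set FALSE only for constructed score matrices in
#'   boundary experiments.
#' @return An `hv_index` with elements `county_ids`, `categories`
#'   (n x k integer matrix), `cumulative` (integer row sums), `stratum`,
#'   `boundary_hits`.
#' @export
build_index <- function(scores, stratum = c("urban", "rural"),
                        check = TRUE) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(scores, "hv_scores"))
  if (!isTRUE(scores$standardized)) {
    stop("contract error: factor scores must be standardized before ",
         "binning", call. = FALSE)
  }
  m <- scores$scores
  if (check) {
    chk <- apply(m, 2, function(x) c(mean(x), sd(x)))
    sd_ok <- abs(chk[2, ] - 1) <= 1e-8 | chk[2, ] == 0
    if (max(abs(chk[1, ])) > 1e-8 || !all(sd_ok)) {
      stop("contract error: score columns are not mean-0 / SD-1",
           call. = FALSE)
    }
  }
  binned <- bin_score(as.vector(m))
  categories <- matrix(as.integer(binned), nrow(m), ncol(m),
                       dimnames = dimnames(m))
  structure(
    list(county_ids = scores$county_ids, categories = categories,
         cumulative = as.integer(rowSums(categories)),
         stratum = stratum,
         boundary_hits = attr(binned, "boundary_hits")),
    class = "hv_index"
  )
}

#' @export
print.hv_index <- function(x, ...) {
  cat("Heat vulnerability index (", x$stratum, "): ",
      length(x$cumulative), " counties, ", ncol(x$categories),
      " factors; cumulative range [", min(x$cumulative), ", ",
      max(x$cumulative), "], median ", median(x$cumulative), "\n",
      sep = "")
  invisible(x)
}

#' Write a vulnerability index as delimited text
#'
#' @param index an `hv_index`.
#' @param path output path.
#' @param area_ids optional area label per county.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path, area_ids = NULL) {
  stopifnot(inherits(index, "hv_index"))
  df <- data.frame(county_id = index$county_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(area_ids)) df$area_id <- area_ids
  cats <- index$categories
  colnames(cats) <- paste0("category_", colnames(cats))
  df <- cbind(df, cats)
  df$cumulative <- index$cumulative
  df$stratum <- index$stratum
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified summary of urban and rural vulnerability indices
#'
#' Reproduces the structure of the study-level results: per-stratum
#' median and range of the cumulative index, the count of counties
#' scoring above the mean (score > 0, the mean of a standardized score)
#' on every factor, per-area mean cumulative index, and the counties
#' whose urban and rural cumulative values are equal.
#'
#' @param urban,rural `hv_index` objects for the two strata.
#' @param urban_scores,rural_scores the `hv_scores` the indices were
#'   built from (for the above-mean counts).
#' @param area_ids optional named vector or data frame column mapping
#'   `county_id` to an area label; when supplied, per-area means are
#'   computed per stratum.
#' @param join `"strict"` (default) errors when the two strata cover
#'   different county sets; `"outer"` compares the intersection and
#'   reports counties present in only one stratum.
#' @return An `hv_summary` list: `per_stratum` (median, min, max,
#'   above-mean-all-factors count), `area_means` (or NULL),
#'   `matched_counties` (ids with equal cumulative values), `match_count`,
#'   `unmatched` (ids in only one stratum).
#' @export
summarize_index <- function(urban, rural, urban_scores, rural_scores,
                            area_ids = NULL,
                            join = c("strict", "outer")) {
  join <- match.arg(join)
  stopifnot(inherits(urban, "hv_index"), inherits(rural, "hv_index"),
            inherits(urban_scores, "hv_scores"),
            inherits(rural_scores, "hv_scores"))
  only_u <- setdiff(urban$county_ids, rural$county_ids)
  only_r <- setdiff(rural$county_ids, urban$county_ids)
  if (join == "strict" && (length(only_u) > 0 || length(only_r) > 0)) {
    stop("alignment error: county sets differ between strata (",
         length(only_u), " urban-only, ", length(only_r),
         " rural-only); use join = \"outer\" to compare the overlap",
         call. = FALSE)
  }
  per_stratum <- do.call(rbind, lapply(
    list(urban = list(urban, urban_scores),
         rural = list(rural, rural_scores)),
    function(z) {
      idx <- z[[1]]; sc <- z[[2]]
      data.frame(
        median = median(idx$cumulative),
        min = min(idx$cumulative),
        max = max(idx$cumulative),
        above_mean_all_factors = sum(apply(sc$scores > 0, 1, all))
      )
    }))
  per_stratum <- cbind(stratum = rownames(per_stratum), per_stratum)
  rownames(per_stratum) <- NULL

  area_means <- NULL
  if (!is.null(area_ids)) {
    area_means <- do.call(rbind, lapply(
      list(urban = urban, rural = rural), function(idx) {
        a <- area_ids[idx$county_ids]
        agg <- tapply(idx$cumulative, a, mean)
        data.frame(stratum = idx$stratum, area = names(agg),
                   mean_cumulative = as.numeric(agg),
                   stringsAsFactors = FALSE)
      }))
    rownames(area_means) <- NULL
  }

  common <- intersect(urban$county_ids, rural$county_ids)
  cu <- urban$cumulative[match(common, urban$county_ids)]
  cr <- rural$cumulative[match(common, rural$county_ids)]
  matched <- common[cu == cr]
  structure(
    list(per_stratum = per_stratum, area_means = area_means,
         matched_counties = matched, match_count = length(matched),
         unmatched = c(only_u, only_r)),
    class = "hv_summary"
  )
}

#' @export
print.hv_summary <- function(x, ...) {
  cat("Cross-stratum vulnerability summary\n")
  print(x$per_stratum)
  cat("Counties with equal urban and rural cumulative index:",
      x$match_count, "\n")
  if (length(x$unmatched) > 0) {
    cat("Counties present in one stratum only:",
        paste(x$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Join the cumulative index onto GeoJSON county features
#'
#' Reads a GeoJSON FeatureCollection, matches each feature to a county
#' by a property key, adds the cumulative index as an `"hvi"` property
#' and writes the result. Features without a matching county keep a
#' null `"hvi"` and are counted in a warning. No polygon data is bundled
#' with the package; supply your own boundaries.
#'
#' @param index an `hv_index`.
#' @param geojson_path input FeatureCollection path.
#' @param out_path output path.
#' @param key_property feature property holding the county identifier
#'   (default `"county_id"`).
#' @return `out_path`, invisibly.
#' @export
export_geojson <- function(index, geojson_path, out_path,
                           key_property = "county_id") {
  stopifnot(inherits(index, "hv_index"))
  gj <- jsonlite::fromJSON(geojson_path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  unmatched <- 0L
  gj$features <- lapply(gj$features, function(f) {
    key <- f$properties[[key_property]]
    i <- if (is.null(key)) integer(0) else
      which(index$county_ids == as.character(key))
    if (length(i) == 1) {
      f$properties$hvi <- index$cumulative[i]
    } else {
      f$properties$hvi <- NULL
      unmatched <<- unmatched + 1L
    }
    f
  })
  if (unmatched > 0) {
    warning(unmatched, " feature(s) had no matching county id")
  }
  jsonlite::write_json(gj, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(out_path)
}
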