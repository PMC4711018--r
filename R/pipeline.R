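#' Configure an end-to-end vulnerability-index run
#'
#' Exactly one input mode must be chosen:
#' \describe{
#'   \item{tables}{named list with `urban` and/or `rural` paths to
#'     county indicator files; the full pipeline runs per stratum.}
#'   \item{fixture}{`TRUE`: analyze the packaged reference correlation
#'     matrices. Only the correlation/eigenvalue/loading stages run —
#'     factor scores need county-level microdata, which the reference
#'     tables do not provide, and the pipeline refuses to fabricate
#'     them.}
#'   \item{synthetic}{list of [synthetic_config()] arguments (less
#'     `stratum` and `seed`); counties are generated per stratum from
#'     `seed` and the full pipeline runs.}
#' }
#'
#' @param tables,fixture,synthetic input mode, see above.
#' @param pca_input correlation fed to the PCA: `"pearson"` (default for
#'   table and synthetic runs; the conventional PCA of standardized raw
#'   data) or `"spearman"`. Fixture runs always use the packaged
#'   Spearman matrices.
#' @param kaiser_normalize,tol,max_iter varimax settings, see
#'   [varimax_rotate()].
#' @param n_factors optional fixed factor count overriding the
#'   eigenvalue-one rule (recorded in the manifest when used).
#' @param output_dir directory for the report bundle (created if
#'   needed).
#' @param seed integer seed for synthetic mode.
#' @param sep field separator for table input.
#' @return An `hv_config` list.
#' @export
run_config <- function(tables = NULL, fixture = FALSE, synthetic = NULL,
                       pca_input = c("pearson", "spearman"),
                       kaiser_normalize = TRUE, tol = 1e-6,
                       max_iter = 1000, n_factors = NULL,
                       output_dir = tempfile("hvi_run_"), seed = 1L,
                       sep = ",") {
  pca_input <- match.arg(pca_input)
  modes <- c(tables = !is.null(tables), fixture = isTRUE(fixture),
             synthetic = !is.null(synthetic))
  if (sum(modes) != 1) {
    stop("configuration error: exactly one input mode required, got ",
         if (sum(modes) == 0) "none" else
           paste(names(modes)[modes], collapse = " + "),
         call. = FALSE)
  }
  if (!is.null(tables)) {
    bad <- setdiff(names(tables), c("urban", "rural"))
    if (length(bad) > 0 || length(tables) == 0) {
      stop("configuration error: tables must be a named list with ",
           "elements 'urban' and/or 'rural'", call. = FALSE)
    }
  }
  stopifnot(tol > 0, max_iter >= 1)
  structure(
    list(mode = names(modes)[modes], tables = tables,
         synthetic = synthetic, pca_input = pca_input,
         kaiser_normalize = kaiser_normalize, tol = tol,
         max_iter = max_iter, n_factors = n_factors,
         output_dir = output_dir, seed = as.integer(seed), sep = sep),
    class = "hv_config"
  )
}

#' Run the stratified vulnerability-index pipeline
#'
#' For each stratum: computes (or loads) the correlation matrices,
#' extracts and rotates the factor solution, writes the eigenvalue
#' table and the rotated-loading report with salience flags, and — when
#' county-level data is present — computes standardized factor scores,
#' builds the six-category cumulative index and writes it. When both
#' strata carry indices, a cross-stratum summary is written. A JSON run
#' manifest records the configuration, seed, package version, every
#' convention invocation that could alter results (sign flips, factor
#' reordering, retention overrides, PSD clipping, category-boundary
#' hits) and every file produced, and is sufficient to re-execute the
#' run; outputs carry no timestamps, so a re-run with the same
#' configuration reproduces the bundle byte for byte.
#'
#' @param config an [run_config()].
#' @return Invisibly, a list with per-stratum results (`correlation`,
#'   `pca`, `solution`, and for data-bearing runs `scores`, `index`),
#'   `summary` (or NULL), and `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hv_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  files <- character(0)
  log <- list()
  strata <- if (config$mode == "tables") names(config$tables) else
    c("urban", "rural")
  results <- list()

  for (stratum in strata) {
    res <- list()
    table <- NULL
    if (config$mode == "tables") {
      table <- load_indicator_table(config$tables[[stratum]],
                                    schema = hv_schema(stratum),
                                    sep = config$sep)
    } else if (config$mode == "synthetic") {
      args <- c(list(stratum = stratum,
                     seed = config$seed + match(stratum,
                                                c("urban", "rural"))),
                config$synthetic)
      gen <- generate_counties(do.call(synthetic_config, args))
      table <- gen$table
      res$true_loadings <- gen$true_loadings
      write_indicator_table(table, out(paste0(stratum, "_table.csv")))
      files <- c(files, paste0(stratum, "_table.csv"))
    }

    if (is.null(table)) {                      # fixture mode
      corr <- fixture_correlation(stratum)
      pca_corr <- corr
    } else {
      corr <- spearman_matrix(table)
      pearson <- pearson_matrix(table)
      pca_corr <- if (config$pca_input == "pearson") pearson else corr
      write_correlation_matrix(pearson,
                               out(paste0(stratum, "_pearson.csv")))
      files <- c(files, paste0(stratum, "_pearson.csv"))
    }
    write_correlation_matrix(corr, out(paste0(stratum, "_spearman.csv")))
    files <- c(files, paste0(stratum, "_spearman.csv"))

    sol <- factor_solution(pca_corr, n_factors = config$n_factors,
                           kaiser_normalize = config$kaiser_normalize,
                           tol = config$tol, max_iter = config$max_iter)
    pca <- attr(sol, "pca")
    eig <- data.frame(component = seq_along(pca$eigenvalues),
                      eigenvalue = pca$eigenvalues,
                      variance_share = pca$variance_shares,
                      retained = seq_along(pca$eigenvalues) <= sol$k)
    write.csv(eig, out(paste0(stratum, "_eigenvalues.csv")),
              row.names = FALSE, quote = FALSE)
    write_loading_report(sol, out(paste0(stratum, "_loadings.csv")))
    files <- c(files, paste0(stratum, "_eigenvalues.csv"),
               paste0(stratum, "_loadings.csv"))
    log[[stratum]] <- list(
      pca_input = if (is.null(table)) "fixture_spearman" else
        config$pca_input,
      k = sol$k,
      retention = if (is.null(config$n_factors)) "eigenvalue_gt_one"
        else paste0("fixed_k_", config$n_factors),
      sign_flips = as.integer(sol$sign_flips),
      factor_order = as.integer(sol$order),
      varimax_converged = sol$converged,
      varimax_iterations = sol$iterations
    )
    res$correlation <- corr
    res$pca <- pca
    res$solution <- sol

    if (!is.null(table)) {
      scores <- factor_scores(table, sol)
      index <- build_index(scores, stratum = stratum)
      sc <- data.frame(county_id = scores$county_ids,
                       scores$scores, check.names = FALSE)
      write.csv(sc, out(paste0(stratum, "_scores.csv")),
                row.names = FALSE, quote = FALSE)
      write_index(index, out(paste0(stratum, "_index.csv")),
                  area_ids = table$area_ids)
      files <- c(files, paste0(stratum, "_scores.csv"),
                 paste0(stratum, "_index.csv"))
      log[[stratum]]$boundary_hits <- index$boundary_hits
      res$table <- table
      res$scores <- scores
      res$index <- index
    } else {
      log[[stratum]]$score_stages <-
        "skipped: no county-level data in fixture mode"
    }
    results[[stratum]] <- res
  }

  summary <- NULL
  if (all(c("urban", "rural") %in% names(results)) &&
      !is.null(results$urban$index) && !is.null(results$rural$index)) {
    area_ids <- NULL
    t_u <- results$urban$table
    if (!is.null(t_u$area_ids)) {
      area_ids <- stats::setNames(t_u$area_ids, t_u$county_ids)
    }
    summary <- summarize_index(results$urban$index,
                               results$rural$index,
                               results$urban$scores,
                               results$rural$scores,
                               area_ids = area_ids, join = "outer")
    sm <- summary$per_stratum
    sm$match_count <- summary$match_count
    write.csv(sm, out("cross_stratum_summary.csv"),
              row.names = FALSE, quote = FALSE)
    files <- c(files, "cross_stratum_summary.csv")
  }

  manifest <- list(
    package = "heatvuln",
    version = as.character(packageVersion("heatvuln")),
    config = config[setdiff(names(config), "output_dir")],
    seed = config$seed,
    log = log,
    files = sort(files)
  )
  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(results, list(summary = summary,
                            manifest_path = manifest_path)))
}

#' Rebuild a run configuration from a manifest
#'
#' Reads the JSON manifest written by [run_pipeline()] and reconstructs
#' the `hv_config`, so a recorded run can be re-executed (into a fresh
#' output directory).
#'
#' @param manifest_path path to `manifest.json`.
#' @param output_dir output directory for the re-run.
#' @return An `hv_config`.
#' @export
config_from_manifest <- function(manifest_path,
                                 output_dir = tempfile("hvi_rerun_")) {
  m <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  cfg <- m$config
  run_config(
    tables = if (!is.null(cfg$tables)) as.list(cfg$tables),
    fixture = identical(cfg$mode, "fixture"),
    synthetic = if (identical(cfg$mode, "synthetic"))
      as.list(cfg$synthetic) %||% list(),
    pca_input = cfg$pca_input,
    kaiser_normalize = cfg$kaiser_normalize,
    tol = cfg$tol, max_iter = cfg$max_iter,
    n_factors = cfg$n_factors,
    output_dir = output_dir, seed = cfg$seed, sep = cfg$sep
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
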