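#' Preset true loading matrices for the synthetic generator
#'
#' Encodes the four-block structure observed in the source study's
#' rotated solutions. Both presets share a poverty block (the three
#' low-income measures), a social-isolation pair (living alone, seniors
#' living alone), an elderly/fragile-health pair (age 60+, loss of labor
#' ability) and a small-dwelling pair (one-room and under-8 m2
#' households); illiteracy joins the elderly block in the urban preset
#' and the dwelling block in the rural preset — the one structural
#' difference the study found between strata.
#'
#' @param stratum `"urban"` or `"rural"`.
#' @param salient loading value given to each variable on its block
#'   factor (default 0.8; off-block loadings are 0).
#' @return 10 x 4 numeric matrix, rows in schema order, columns named
#'   after the blocks.
#' @export
preset_loadings <- function(stratum = c("urban", "rural"),
                            salient = 0.8) {
  stratum <- match.arg(stratum)
  vars <- hv_variables()
  blocks <- list(
    poverty = c("low_income", "low_income_seniors",
                "low_income_households"),
    elderly = c("age_ge60", "loss_labor_ability"),
    isolation = c("living_alone", "age_ge60_living_alone"),
    dwelling = c("households_one_room", "households_le8m2")
  )
  if (stratum == "urban") {
    blocks$elderly <- c(blocks$elderly, "illiterate")
  } else {
    blocks$dwelling <- c(blocks$dwelling, "illiterate")
  }
  L <- matrix(0, 10, 4, dimnames = list(vars, names(blocks)))
  for (b in names(blocks)) L[blocks[[b]], b] <- salient
  L
}

#' Configuration of the synthetic county generator
#'
#' Describes a latent-factor model calibrated to the source study's
#' published marginals: four independent standard-normal latent factors,
#' a 10 x 4 loading matrix (block presets via [preset_loadings()]),
#' independent normal uniqueness (residual) noise, and per-variable
#' target means/SDs used to map standardized values onto percentage
#' scales.
#'
#' @param n_counties number of counties (default 73, the study size).
#' @param stratum `"urban"` or `"rural"`; selects the preset loading
#'   block structure and the default marginal targets.
#' @param true_loadings optional 10 x 4 loading matrix overriding the
#'   preset; row communalities must not exceed 1.
#' @param uniqueness_sd residual SD per variable (default 0.3).
#' @param target_means,target_sds length-10 vectors (defaults: the
#'   published per-stratum means/SDs, see [fixture_moments()]).
#' @param seed integer seed; generation is fully reproducible from it.
#' @param clip_to_percent clip generated values to \[0, 100\]. Off by
#'   default: clipping distorts correlations, so recovery experiments
#'   leave it off, while runs feeding the \[0, 100\]-validated I/O layer
#'   turn it on.
#' @return An `hv_synth_config`.
#' @export
synthetic_config <- function(n_counties = 73,
                             stratum = c("urban", "rural"),
                             true_loadings = NULL,
                             uniqueness_sd = 0.3,
                             target_means = NULL, target_sds = NULL,
                             seed = 1L, clip_to_percent = FALSE) {
  stratum <- match.arg(stratum)
  if (n_counties < 10) {
    stop("config error: n_counties must be at least 10", call. = FALSE)
  }
  if (is.null(true_loadings)) true_loadings <- preset_loadings(stratum)
  true_loadings <- as.matrix(true_loadings)
  if (!all(dim(true_loadings) == c(10, 4))) {
    stop("config error: true_loadings must be 10 x 4", call. = FALSE)
  }
  if (is.null(rownames(true_loadings))) {
    rownames(true_loadings) <- hv_variables()
  }
  h2 <- rowSums(true_loadings^2)
  if (any(h2 > 1)) {
    stop("config error: row communality exceeds 1 for: ",
         paste(rownames(true_loadings)[h2 > 1], collapse = ", "),
         call. = FALSE)
  }
  mom <- fixture_moments(stratum)
  if (is.null(target_means)) target_means <- mom$mean
  if (is.null(target_sds)) target_sds <- mom$sd
  stopifnot(length(target_means) == 10, length(target_sds) == 10)
  if (any(target_sds <= 0)) {
    stop("config error: target_sds must be positive", call. = FALSE)
  }
  if (uniqueness_sd < 0) {
    stop("config error: uniqueness_sd must be non-negative",
         call. = FALSE)
  }
  structure(
    list(n_counties = as.integer(n_counties), stratum = stratum,
         true_loadings = true_loadings, uniqueness_sd = uniqueness_sd,
         target_means = target_means, target_sds = target_sds,
         seed = as.integer(seed), clip_to_percent = clip_to_percent),
    class = "hv_synth_config"
  )
}

#' Generate a synthetic county indicator table
#'
#' Draws latent factor scores F (n x 4, independent standard normal)
#' and residuals E (n x 10, independent normal with SD
#' `uniqueness_sd`), forms standardized values Z = F L' + E rescaled to
#' unit population variance per variable, and maps them to percentages
#' as `target_means + target_sds * Z`. Latent factors are orthogonal in
#' expectation only — their sample correlations are whatever the draw
#' produces, as in real census data. The true latent scores and the true
#' loadings are returned alongside the table so factor-recovery
#' experiments can score the pipeline against ground truth.
#'
#' @param config an [synthetic_config()].
#' @return A list with `table` (an [indicator_table()]), `latent_scores`
#'   (n x 4 matrix of true factor scores), `true_loadings`, and
#'   `n_clipped` (cells clipped to \[0, 100\]; always 0 unless
#'   `clip_to_percent`).
#' @export
generate_counties <- function(config) {
  stopifnot(inherits(config, "hv_synth_config"))
  n <- config$n_counties
  L <- config$true_loadings
  set.seed(config$seed)
  F_lat <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, colnames(L)))
  E <- matrix(rnorm(n * 10, sd = config$uniqueness_sd), n, 10)
  Z <- F_lat %*% t(L) + E
  # rescale to unit population variance: var_j = h2_j + uniqueness_sd^2
  total_sd <- sqrt(rowSums(L^2) + config$uniqueness_sd^2)
  if (any(total_sd == 0)) {
    stop("config error: variable(s) with zero loading and zero ",
         "uniqueness have no variance", call. = FALSE)
  }
  Z <- sweep(Z, 2, total_sd, `/`)
  vals <- sweep(sweep(Z, 2, config$target_sds, `*`),
                2, config$target_means, `+`)
  n_clipped <- 0L
  if (config$clip_to_percent) {
    n_clipped <- sum(vals < 0 | vals > 100)
    vals <- pmin(pmax(vals, 0), 100)
    if (n_clipped > 0) {
      message(n_clipped, " cell(s) clipped to [0, 100]")
    }
  } else if (any(vals < 0 | vals > 100)) {
    # tables entering the validated I/O layer need clip_to_percent
    message(sum(vals < 0 | vals > 100),
            " generated cell(s) fall outside [0, 100] (unclipped)")
  }
  colnames(vals) <- rownames(L)
  ids <- sprintf("C%03d", seq_len(n))
  areas <- paste0("A", rep_len(1:7, n))
  table <- if (config$clip_to_percent || all(vals >= 0 & vals <= 100)) {
    indicator_table(vals, ids, schema = hv_schema(config$stratum),
                    area_ids = areas)
  } else {
    # bypass the percent bound for unclipped recovery runs
    structure(
      list(county_ids = ids, area_ids = areas,
           values = structure(vals, dimnames = list(ids, colnames(vals))),
           schema = hv_schema(config$stratum)),
      class = "hv_table"
    )
  }
  list(table = table, latent_scores = F_lat, true_loadings = L,
       n_clipped = n_clipped)
}

#' Matched mean Tucker congruence between two loading matrices
#'
#' The Tucker congruence of two loading columns is their cosine
#' similarity phi(x, y) = sum(x y) / sqrt(sum(x^2) sum(y^2)). Because a
#' recovered factor solution is only identified up to column order and
#' sign, this computes |phi| for every column pair and searches all
#' column permutations (exhaustive for k <= 6) for the matching that
#' maximizes the mean |phi|; that maximum is returned. A value of 1
#' means the recovered factors span the true ones exactly (up to
#' permutation and sign); 0 means orthogonality.
#'
#' @param true_loadings,estimated_loadings p x k matrices, same shape,
#'   no zero columns.
#' @return Scalar in \[0, 1\]: the matched mean absolute congruence,
#'   with attributes `perm` (column of `estimated_loadings` matched to
#'   each true column) and `per_factor` (the matched |phi| values).
#' @export
congruence <- function(true_loadings, estimated_loadings) {
  x <- as.matrix(true_loadings); y <- as.matrix(estimated_loadings)
  if (!all(dim(x) == dim(y))) {
    stop("loading matrices must have the same shape", call. = FALSE)
  }
  k <- ncol(x)
  if (k > 6) stop("exhaustive matching supported for k <= 6",
                  call. = FALSE)
  nx <- sqrt(colSums(x^2)); ny <- sqrt(colSums(y^2))
  if (any(nx == 0) || any(ny == 0)) {
    stop("undefined-congruence error: zero loading column",
         call. = FALSE)
  }
  phi <- abs(crossprod(x, y) / outer(nx, ny))
  perms <- permutations(k)
  means <- apply(perms, 1, function(pr) {
    mean(phi[cbind(seq_len(k), pr)])
  })
  best <- which.max(means)
  pr <- as.integer(perms[best, ])
  structure(means[best], perm = pr,
            per_factor = phi[cbind(seq_len(k), pr)])
}

# all permutations of 1..k, one per row
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
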