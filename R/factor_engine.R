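#' Principal components of a correlation matrix
#'
#' Full eigendecomposition of a validated correlation matrix, with the
#' conventions used throughout the package: eigenvalues in descending
#' order; component loadings are eigenvectors scaled by the square root
#' of their eigenvalue (so squared loadings are variance contributions);
#' each eigenvector's sign is fixed by making its largest-magnitude
#' component positive, which makes the decomposition deterministic.
#' Because the input has a unit diagonal, the eigenvalues sum to the
#' number of variables.
#'
#' Matrices transcribed from print at two decimals can fail positive
#' semi-definiteness by rounding noise alone; eigenvalues down to -1e-6
#' are accepted and clipped to zero for variance shares, with a warning.
#' Anything more negative is treated as a corrupt input.
#'
#' @param corr an `hv_corr` (see [correlation_matrix()]).
#' @return An `hv_pca` with elements `eigenvalues` (descending),
#'   `loadings` (p x p, column j scaled by sqrt(eigenvalue j)),
#'   `variance_shares` (eigenvalues / p, negatives clipped to 0),
#'   `variables`.
#' @export
pca_from_correlation <- function(corr) {
  stopifnot(inherits(corr, "hv_corr"))
  p <- nrow(corr$values)
  e <- eigen(corr$values, symmetric = TRUE)
  values <- e$values           # descending by eigen() contract
  vectors <- e$vectors
  if (min(values) < -1e-6) {
    stop("non-PSD error: smallest eigenvalue ", format(min(values)),
         " is below the -1e-6 tolerance; input is not a valid ",
         "correlation matrix", call. = FALSE)
  }
  if (min(values) < 0) {
    warning("eigenvalue(s) slightly negative (min ",
            format(min(values)),
            "); clipped to 0 for variance shares (rounded-print noise)")
  }
  clipped <- pmax(values, 0)
  # deterministic sign: largest-|component| entry of each eigenvector > 0
  for (j in seq_len(p)) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  loadings <- vectors %*% diag(sqrt(clipped), p)
  dimnames(loadings) <- list(corr$labels,
                             paste0("PC", seq_len(p)))
  structure(
    list(eigenvalues = values, loadings = loadings,
         variance_shares = clipped / p, variables = corr$labels),
    class = "hv_pca"
  )
}

#' @export
print.hv_pca <- function(x, ...) {
  cat("Principal components of a", length(x$eigenvalues),
      "-variable correlation matrix\n")
  cat("Eigenvalues:", paste(round(x$eigenvalues, 3), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of components retained by the eigenvalue-one rule
#'
#' Kaiser criterion: retain components whose eigenvalue is strictly
#' greater than 1, i.e. that explain more variance than one standardized
#' variable. The rule is strict; an eigenvalue of exactly 1 (the identity
#' matrix spectrum) does not qualify.
#'
#' @param pca an `hv_pca` from [pca_from_correlation()].
#' @return Integer count `k >= 1`.
#' @export
retain_factors <- function(pca) {
  stopifnot(inherits(pca, "hv_pca"))
  k <- sum(pca$eigenvalues > 1)
  if (k == 0) {
    stop("retention error: no eigenvalue strictly exceeds 1; ",
         "nothing to retain under the Kaiser rule", call. = FALSE)
  }
  k
}

#' Varimax criterion of a loading matrix
#'
#' The quantity maximized by [varimax_rotate()]: the sum over factors of
#' the variance of squared loadings,
#' V = sum_j \[ sum_i L_ij^4 / p - (sum_i L_ij^2 / p)^2 \].
#'
#' @param loadings p x k numeric matrix.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  p <- nrow(loadings)
  L2 <- loadings^2
  sum(colSums(L2^2) / p - (colSums(L2) / p)^2)
}

# optimal planar rotation angle for one column pair (Kaiser's formula)
varimax_pair_angle <- function(x, y) {
  p <- length(x)
  u <- x^2 - y^2
  v <- 2 * x * y
  A <- sum(u); B <- sum(v)
  C <- sum(u^2 - v^2); D <- sum(2 * u * v)
  num <- D - 2 * A * B / p
  den <- C - (A^2 - B^2) / p
  atan2(num, den) / 4
}

#' Varimax rotation of retained component loadings
#'
#' Orthogonal rotation maximizing the varimax simple-structure criterion
#' (see [varimax_criterion()]) by cyclic pairwise planar rotations: each
#' sweep visits every column pair and applies the angle that maximizes
#' the pair's contribution, so the criterion is non-decreasing across
#' iterations. Iteration stops when a full sweep improves the criterion
#' by less than `tol`, or at `max_iter` sweeps (then the result carries
#' `converged = FALSE` with a warning, not an error).
#'
#' With `kaiser_normalize = TRUE` (the default, the norm in the
#' vulnerability-index literature) loading rows are divided by the square
#' roots of their communalities before optimization and rescaled after,
#' so every variable contributes equally to the criterion. A row of
#' zeros cannot be normalized and is an error.
#'
#' Two presentation conventions are then applied and recorded on the
#' result: each factor column is sign-flipped so its largest-magnitude
#' loading is positive (all ten indicators are coded so higher = more
#' vulnerable, so this orients every factor with vulnerability), and
#' factors are reordered by descending post-rotation variance.
#'
#' @param loadings p x k matrix of retained component loadings
#'   (typically `pca$loadings[, 1:k]`), p > k >= 1.
#' @param kaiser_normalize logical; normalize rows before rotating.
#' @param tol convergence threshold on the criterion improvement per
#'   sweep (default 1e-6).
#' @param max_iter sweep cap (default 1000).
#' @param explained_total optional share of total variance carried by the
#'   k retained components (sum of retained eigenvalues / p); recorded on
#'   the result when supplied. Invariant under the rotation.
#' @param salient_cutoff absolute loading above which a cell is flagged
#'   salient (default 0.5).
#' @return An `hv_factors` with elements `k`, `rotated_loadings` (p x k),
#'   `rotation` (k x k orthogonal), `per_factor_variance` (column sums of
#'   squared rotated loadings / p, descending), `explained_total`,
#'   `salient_mask`, `sign_flips`, `order`, `converged`, `iterations`,
#'   `criterion_path` (criterion after each sweep, on the normalized
#'   loadings when Kaiser normalization is on), `kaiser_normalize`.
#' @export
varimax_rotate <- function(loadings, kaiser_normalize = TRUE,
                           tol = 1e-6, max_iter = 1000,
                           explained_total = NULL,
                           salient_cutoff = 0.5) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings); k <- ncol(loadings)
  if (k < 1 || p <= k) {
    stop("need p > k >= 1 (got p = ", p, ", k = ", k, ")",
         call. = FALSE)
  }
  vars <- rownames(loadings)
  if (is.null(vars)) vars <- paste0("v", seq_len(p))

  h2 <- rowSums(loadings^2)          # communalities, rotation-invariant
  if (kaiser_normalize && any(h2 == 0)) {
    stop("degenerate-row error: zero-communality row(s): ",
         paste(vars[h2 == 0], collapse = ", "),
         "; cannot Kaiser-normalize", call. = FALSE)
  }
  L <- if (kaiser_normalize) loadings / sqrt(h2) else loadings
  rot <- diag(k)
  crit_path <- varimax_criterion(L)
  converged <- TRUE
  iter <- 0
  if (k > 1) {
    converged <- FALSE
    pairs <- combn(k, 2)
    for (iter in seq_len(max_iter)) {
      for (q in seq_len(ncol(pairs))) {
        i <- pairs[1, q]; j <- pairs[2, q]
        theta <- varimax_pair_angle(L[, i], L[, j])
        if (theta != 0) {
          cs <- cos(theta); sn <- sin(theta)
          G <- matrix(c(cs, -sn, sn, cs), 2, 2, byrow = TRUE)
          L[, c(i, j)] <- L[, c(i, j)] %*% G
          rot[, c(i, j)] <- rot[, c(i, j)] %*% G
        }
      }
      crit_path <- c(crit_path, varimax_criterion(L))
      n_it <- length(crit_path)
      if (crit_path[n_it] - crit_path[n_it - 1] < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warning("varimax did not converge in ", max_iter, " sweeps")
    }
  }
  if (kaiser_normalize) L <- L * sqrt(h2)

  # sign orientation: largest-|loading| entry of each column positive
  sign_flips <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) -1 else 1
  }, numeric(1))
  L <- sweep(L, 2, sign_flips, `*`)
  rot <- sweep(rot, 2, sign_flips, `*`)

  # order factors by descending post-rotation variance
  pf_var <- colSums(L^2) / p
  ord <- order(pf_var, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  rot <- rot[, ord, drop = FALSE]
  pf_var <- pf_var[ord]

  dimnames(L) <- list(vars, paste0("factor_", seq_len(k)))
  names(pf_var) <- colnames(L)
  if (is.null(explained_total)) explained_total <- sum(pf_var)
  structure(
    list(k = k, rotated_loadings = L, rotation = rot,
         per_factor_variance = pf_var,
         explained_total = explained_total,
         salient_mask = abs(L) > salient_cutoff,
         sign_flips = sign_flips, order = ord,
         converged = converged, iterations = iter,
         criterion_path = crit_path,
         kaiser_normalize = kaiser_normalize),
    class = "hv_factors"
  )
}

#' @export
print.hv_factors <- function(x, digits = 2, ...) {
  cat("Varimax-rotated factor solution: ", nrow(x$rotated_loadings),
      " variables x ", x$k, " factors (",
      round(100 * x$explained_total, 1), "% of total variance)\n",
      sep = "")
  L <- round(x$rotated_loadings, digits)
  disp <- matrix(paste0(format(L), ifelse(x$salient_mask, "*", " ")),
                 nrow(L), ncol(L), dimnames = dimnames(L))
  print(disp, quote = FALSE)
  cat("(* |loading| >", 0.5, "— salient)\n")
  invisible(x)
}

#' Extract, retain and rotate in one call
#'
#' Convenience wrapper: [pca_from_correlation()], then
#' [retain_factors()] (unless `n_factors` overrides the eigenvalue-one
#' rule), then [varimax_rotate()] with `explained_total` filled in from
#' the retained eigenvalues.
#'
#' @param corr an `hv_corr`.
#' @param n_factors optional fixed number of factors to retain instead
#'   of the eigenvalue-one rule (e.g. a component count established by a
#'   prior analysis of the full data).
#' @param ... passed to [varimax_rotate()].
#' @return An `hv_factors`; the underlying `hv_pca` is attached as
#'   attribute `"pca"`.
#' @export
factor_solution <- function(corr, n_factors = NULL, ...) {
  pca <- pca_from_correlation(corr)
  k <- if (is.null(n_factors)) retain_factors(pca) else {
    stopifnot(n_factors >= 1, n_factors < length(pca$eigenvalues))
    as.integer(n_factors)
  }
  sol <- varimax_rotate(pca$loadings[, seq_len(k), drop = FALSE],
                        explained_total =
                          sum(pca$variance_shares[seq_len(k)]), ...)
  attr(sol, "pca") <- pca
  sol
}

#' Standardized regression (Thurstone) factor scores
#'
#' Scores each county on the retained rotated factors by the regression
#' method: weights W = R^-1 L, where R is the Pearson correlation matrix
#' of the same table and L the rotated loadings; raw scores are Z W with
#' Z the column-standardized table (mean 0, sample SD 1). Each score
#' column is then re-standardized to mean 0, SD 1 exactly, matching the
#' index construction's "standardized scores" contract. Higher scores
#' mean higher vulnerability under the sign orientation applied by
#' [varimax_rotate()].
#'
#' @param table an [indicator_table()] with more counties than factors.
#' @param solution an `hv_factors` over the same variable set.
#' @param scoring_corr Pearson `hv_corr` of `table`; computed if omitted.
#'   Must be well-conditioned (2-norm condition number below
#'   `max_condition`).
#' @param max_condition conditioning cap on the scoring matrix inverse
#'   (default 1e8).
#' @return An `hv_scores` with elements `county_ids`, `scores` (n x k),
#'   `standardized = TRUE`, `weights`.
#' @export
factor_scores <- function(table, solution, scoring_corr = NULL,
                          max_condition = 1e8) {
  stopifnot(inherits(table, "hv_table"),
            inherits(solution, "hv_factors"))
  L <- solution$rotated_loadings
  if (!identical(rownames(L), colnames(table$values))) {
    stop("solution and table cover different variable sets",
         call. = FALSE)
  }
  n <- nrow(table$values)
  if (n < solution$k + 1) {
    stop("need more counties (", n, ") than retained factors (",
         solution$k, ")", call. = FALSE)
  }
  if (is.null(scoring_corr)) scoring_corr <- pearson_matrix(table)
  stopifnot(inherits(scoring_corr, "hv_corr"))
  if (!identical(scoring_corr$labels, rownames(L))) {
    stop("scoring correlation matrix covers a different variable set",
         call. = FALSE)
  }
  R <- scoring_corr$values
  kap <- kappa(R, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop("conditioning error: scoring correlation matrix has condition ",
         "number ", format(kap), " (cap ", format(max_condition),
         "); inspect near-collinear indicator variables", call. = FALSE)
  }
  W <- solve(R, L)
  Z <- scale(table$values)          # sample-SD standardization
  raw <- Z %*% W
  scores <- apply(raw, 2, function(x) {
    s <- sd(x)
    if (s == 0) stop("degenerate factor score column (zero variance)",
                     call. = FALSE)
    (x - mean(x)) / s
  })
  dimnames(scores) <- list(table$county_ids, colnames(L))
  structure(
    list(county_ids = table$county_ids, scores = scores,
         standardized = TRUE, weights = W),
    class = "hv_scores"
  )
}

#' @export
print.hv_scores <- function(x, ...) {
  cat("Standardized factor scores:", nrow(x$scores), "counties x",
      ncol(x$scores), "factors (mean 0, SD 1 per factor)\n")
  invisible(x)
}

#' Write a rotated-loading report
#'
#' Delimited text in the layout of a published loading table: one row
#' per variable, one column per factor, plus `salient_*` flag columns
#' marking |loading| above the salience cutoff.
#'
#' @param solution an `hv_factors`.
#' @param path output path.
#' @param digits decimal places (default 3).
#' @return `path`, invisibly.
#' @export
write_loading_report <- function(solution, path, digits = 3) {
  stopifnot(inherits(solution, "hv_factors"))
  L <- round(solution$rotated_loadings, digits)
  df <- data.frame(variable = rownames(L), L, check.names = FALSE)
  sal <- solution$salient_mask
  colnames(sal) <- paste0("salient_", colnames(L))
  df <- cbind(df, sal)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
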