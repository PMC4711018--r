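test_that("pca of a correlation matrix has the expected spectrum", {
  idm <- correlation_matrix(diag(10), labels = hv_variables(),
                            method = "pearson")
  pca <- pca_from_correlation(idm)
  expect_equal(pca$eigenvalues, rep(1, 10))
  expect_equal(pca$variance_shares, rep(0.1, 10))
  # strict Kaiser rule: eigenvalue exactly 1 is not retained
  expect_error(retain_factors(pca), "retention error")

  # closed form for a 2x2 with off-diagonal r: eigenvalues 1 +/- r
  m2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  p2 <- pca_from_correlation(correlation_matrix(m2, labels = c("a", "b"),
                                                method = "pearson"))
  expect_equal(p2$eigenvalues, c(1.6, 0.4))

  # trace conservation and descending order on arbitrary valid input
  set.seed(31)
  for (i in 1:5) {
    g <- suppressMessages(generate_counties(
      synthetic_config(n_counties = 50, seed = 31 + i)))
    pc <- pca_from_correlation(pearson_matrix(g$table))
    expect_lt(abs(sum(pc$eigenvalues) - 10), 1e-9)
    expect_true(all(diff(pc$eigenvalues) <= 1e-12))
    # sign convention: largest-|entry| of each loading column positive
    for (j in 1:10) {
      col <- pc$loadings[, j]
      expect_gte(col[which.max(abs(col))], 0)
    }
  }
})

test_that("non-PSD input beyond the rounding tolerance is refused", {
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.9; m[2, 3] <- m[3, 2] <- -0.9
  corr <- correlation_matrix(m, labels = c("a", "b", "c"),
                             method = "pearson")
  expect_error(pca_from_correlation(corr), "non-PSD")
})

test_that("varimax leaves nothing-to-rotate cases alone", {
  set.seed(41)
  L1 <- matrix(rnorm(10), 10, 1, dimnames = list(hv_variables(), NULL))
  s1 <- varimax_rotate(L1)
  expect_equal(dim(s1$rotation), c(1, 1))
  expect_equal(abs(s1$rotation[1, 1]), 1)
  expect_equal(abs(unname(s1$rotated_loadings[, 1])),
               abs(unname(L1[, 1])))

  # perfect simple structure is a fixed point of the criterion
  L2 <- cbind(c(rep(0.8, 5), rep(0, 5)), c(rep(0, 5), rep(0.6, 5)))
  s2 <- varimax_rotate(L2, kaiser_normalize = FALSE)
  expect_equal(varimax_criterion(s2$rotated_loadings),
               varimax_criterion(L2), tolerance = 1e-10)
  expect_equal(abs(s2$rotation), diag(2), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("varimax matches the exhaustive angle-grid oracle for k = 2", {
  for (s in 1:5) {
    set.seed(s)
    L <- matrix(rnorm(20), 10, 2)
    sol <- varimax_rotate(L, kaiser_normalize = FALSE)
    expect_lt(abs(grid_varimax_max(L, step = 1e-4) -
                  varimax_criterion(sol$rotated_loadings)), 1e-6)
  }
})

test_that("varimax agrees with an independent implementation for k = 3", {
  for (s in 1:5) {
    set.seed(100 + s)
    L <- matrix(rnorm(30), 10, 3)
    mine <- varimax_criterion(
      varimax_rotate(L, kaiser_normalize = FALSE,
                     tol = 1e-10)$rotated_loadings)
    ref <- varimax_criterion(
      unclass(stats::varimax(L, normalize = FALSE, eps = 1e-10)$loadings))
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("rotation is orthogonal and conserves communalities", {
  for (stratum in c("urban", "rural")) {
    sol <- factor_solution(fixture_correlation(stratum), n_factors = 4)
    pca <- attr(sol, "pca")
    R <- sol$rotation
    expect_lt(max(abs(crossprod(R) - diag(4))), 1e-10)
    h_pre <- rowSums(pca$loadings[, 1:4]^2)
    h_post <- rowSums(sol$rotated_loadings^2)
    expect_lt(max(abs(h_pre - h_post)), 1e-10)
    # explained variance invariant under rotation
    expect_lt(abs(sum(sol$per_factor_variance) - sol$explained_total),
              1e-10)
    expect_equal(sol$explained_total, sum(pca$eigenvalues[1:4]) / 10,
                 tolerance = 1e-12)
    # criterion path is non-decreasing, factor variances descending
    expect_true(all(diff(sol$criterion_path) >= -1e-12))
    expect_true(all(diff(sol$per_factor_variance) <= 1e-12))
  }
})

test_that("varimax flags non-convergence instead of failing", {
  set.seed(77)
  L <- matrix(rnorm(40), 10, 4)
  expect_warning(s <- varimax_rotate(L, max_iter = 1), "converge")
  expect_false(s$converged)
})

test_that("kaiser normalization refuses zero-communality rows", {
  L <- rbind(matrix(rnorm(18), 9, 2), c(0, 0))
  rownames(L) <- hv_variables()
  expect_error(varimax_rotate(L, kaiser_normalize = TRUE),
               "households_le8m2")
  expect_silent(varimax_rotate(L, kaiser_normalize = FALSE))
})

test_that("factor scores are standardized and row-local", {
  g <- generate_counties(synthetic_config(n_counties = 73, seed = 55,
                                          clip_to_percent = TRUE))
  sol <- factor_solution(pearson_matrix(g$table))
  sc <- factor_scores(g$table, sol)
  expect_lt(max(abs(colMeans(sc$scores))), 1e-10)
  expect_lt(max(abs(apply(sc$scores, 2, sd) - 1)), 1e-10)

  # duplicating every county leaves each county's scores unchanged
  dup_vals <- rbind(g$table$values, g$table$values)
  dup <- indicator_table(dup_vals,
                         c(g$table$county_ids,
                           paste0(g$table$county_ids, "b")))
  sc2 <- factor_scores(dup, sol)
  expect_equal(unname(sc2$scores[1:73, ]), unname(sc2$scores[74:146, ]),
               tolerance = 1e-12)
})

test_that("regression scores recover known latent factors", {
  # two-factor model, near-zero uniqueness
  L <- preset_loadings("urban")[, 1:2]
  L4 <- cbind(L, 0, 0)
  # give the unloaded variables a little variance of their own
  cfg <- synthetic_config(n_counties = 300, true_loadings = L4,
                          uniqueness_sd = 0.05, seed = 66)
  g <- suppressMessages(generate_counties(cfg))
  sol <- factor_solution(pearson_matrix(g$table), n_factors = 2)
  sc <- factor_scores(g$table, sol)
  cmat <- abs(cor(g$latent_scores[, 1:2], sc$scores))
  # after column matching, each true factor is recovered almost exactly
  best <- apply(cmat, 1, max)
  expect_true(all(best > 0.99))
})

test_that("near-singular scoring matrices raise a conditioning error", {
  g <- generate_counties(synthetic_config(n_counties = 40, seed = 67,
                                          clip_to_percent = TRUE))
  v <- g$table$values
  v[, 2] <- v[, 1]  # exact collinearity
  tab <- g$table; tab$values <- v
  sol <- factor_solution(fixture_correlation("urban"), n_factors = 4)
  expect_error(factor_scores(tab, sol), "conditioning error")
})

test_that("fixture solutions are congruent with the published loadings", {
  # The published rotated loadings come from the raw county microdata;
  # our fixture runs only see the rounded printed Spearman matrices, so
  # agreement is strong but not exact (the rural fourth factor is the
  # most sensitive to the rounding).
  for (stratum in c("urban", "rural")) {
    sol <- factor_solution(fixture_correlation(stratum), n_factors = 4)
    cg <- as.numeric(congruence(fixture_published_loadings(stratum),
                                sol$rotated_loadings))
    expect_gt(cg, if (stratum == "urban") 0.95 else 0.85)
  }
})
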