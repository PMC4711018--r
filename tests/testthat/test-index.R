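test_that("binning matches the hand-written piecewise oracle", {
  z <- seq(-3, 3, by = 0.1)  # 61-point grid
  expect_identical(as.integer(bin_score(z)), bin_oracle(z))
  # documented boundary convention
  expect_equal(as.integer(bin_score(c(-2, -1, -0.5, 0, 1, 2))),
               c(1L, 2L, 3L, 4L, 5L, 6L))
  expect_error(bin_score(c(0, NA)), "non-finite")
  expect_error(bin_score(Inf), "non-finite")
})

test_that("binning is a monotone step partition of the real line", {
  set.seed(17)
  z <- sort(c(rnorm(500, sd = 1.5), -2, -1, 0, 1, 2))
  cats <- bin_score(z)
  expect_true(all(cats %in% 1:6))
  expect_true(all(diff(as.integer(cats)) >= 0))   # monotone
  expect_equal(attr(cats, "boundary_hits"), 5)
})

test_that("the cumulative index is the row sum of categories", {
  sc <- make_scores(matrix(0, 5, 4))
  idx <- build_index(sc, "urban")
  expect_true(all(idx$categories == 4L))
  expect_true(all(idx$cumulative == 16L))

  sc1 <- make_scores(rbind(c(-2.5, -1.5, 0.5, 2.5)))
  idx1 <- build_index(sc1, "urban", check = FALSE)
  expect_equal(unname(idx1$categories[1, ]), c(1L, 2L, 4L, 6L))
  expect_equal(idx1$cumulative, 13L)

  # real pipeline scores stay within the attainable [4, 24] band
  g <- generate_counties(synthetic_config(n_counties = 73, seed = 9,
                                          clip_to_percent = TRUE))
  sc73 <- factor_scores(g$table, factor_solution(pearson_matrix(g$table),
                                                 n_factors = 4))
  idx73 <- build_index(sc73, "urban")
  expect_true(all(idx73$cumulative >= 4 & idx73$cumulative <= 24))
  expect_identical(idx73$cumulative,
                   as.integer(rowSums(idx73$categories)))

  # both bounds are attainable by constructed score matrices
  lo <- build_index(make_scores(matrix(-3, 3, 4)), "urban",
                    check = FALSE)
  hi <- build_index(make_scores(matrix(3, 3, 4)), "urban",
                    check = FALSE)
  expect_true(all(lo$cumulative == 4L))
  expect_true(all(hi$cumulative == 24L))
})

test_that("non-standardized scores are refused", {
  raw <- make_scores(matrix(rnorm(20, mean = 3), 5, 4))
  expect_error(build_index(raw, "urban"), "contract error")
  flagless <- raw; flagless$standardized <- FALSE
  expect_error(build_index(flagless, "urban", check = FALSE),
               "contract error")
})

test_that("cumulative index is permutation-equivariant", {
  g <- generate_counties(synthetic_config(n_counties = 40, seed = 23,
                                          clip_to_percent = TRUE))
  sol <- factor_solution(pearson_matrix(g$table), n_factors = 4)
  idx <- build_index(factor_scores(g$table, sol), "urban")
  set.seed(1); perm <- sample(40)
  tabp <- indicator_table(g$table$values[perm, ],
                          g$table$county_ids[perm])
  idxp <- build_index(factor_scores(tabp, sol), "urban")
  expect_identical(idxp$cumulative, idx$cumulative[perm])
  expect_identical(idxp$county_ids, idx$county_ids[perm])
})

test_that("the index is invariant to a constant shift of all indicators", {
  g <- generate_counties(synthetic_config(n_counties = 73, seed = 29,
                                          clip_to_percent = TRUE))
  run <- function(tab) {
    sol <- factor_solution(pearson_matrix(tab), n_factors = 4)
    build_index(factor_scores(tab, sol), "urban")
  }
  base <- run(g$table)
  shifted <- g$table
  shifted$values <- g$table$values + 7.5   # leaves correlations alone
  expect_identical(run(shifted)$cumulative, base$cumulative)
})

test_that("cross-stratum summaries count matches and above-mean counties", {
  g <- generate_counties(synthetic_config(n_counties = 30, seed = 35,
                                          clip_to_percent = TRUE))
  sol <- factor_solution(pearson_matrix(g$table), n_factors = 4)
  sc <- factor_scores(g$table, sol)
  idx <- build_index(sc, "urban")
  idxr <- idx; idxr$stratum <- "rural"
  s <- summarize_index(idx, idxr, sc, sc)
  expect_equal(s$match_count, 30)                  # self-comparison
  expect_equal(s$per_stratum$median[1], s$per_stratum$median[2])
  # above-mean-on-all-factors requires strict positivity everywhere
  expect_equal(s$per_stratum$above_mean_all_factors[1],
               sum(apply(sc$scores > 0, 1, all)))
  two <- make_scores(rbind(c(0.1, 0.1, 0.1, 0.1),
                           c(0.1, -0.1, 0.1, 0.1)))
  itwo <- build_index(two, "urban", check = FALSE)
  stwo <- summarize_index(itwo, itwo, two, two)
  expect_equal(stwo$per_stratum$above_mean_all_factors[1], 1)

  # brute-force recount of cross-stratum matches on distinct strata
  g2 <- generate_counties(synthetic_config(n_counties = 30,
                                           stratum = "rural", seed = 36,
                                           clip_to_percent = TRUE))
  sol2 <- factor_solution(pearson_matrix(g2$table), n_factors = 4)
  sc2 <- factor_scores(g2$table, sol2)
  idx2 <- build_index(sc2, "rural")
  s2 <- summarize_index(idx, idx2, sc, sc2)
  brute <- sum(vapply(seq_len(30), function(i) {
    idx$cumulative[i] ==
      idx2$cumulative[match(idx$county_ids[i], idx2$county_ids)]
  }, logical(1)))
  expect_equal(s2$match_count, brute)
})

test_that("county-set mismatches need an explicit join policy", {
  g <- generate_counties(synthetic_config(n_counties = 12, seed = 44,
                                          clip_to_percent = TRUE))
  sol <- factor_solution(pearson_matrix(g$table), n_factors = 4)
  sc <- factor_scores(g$table, sol)
  idx <- build_index(sc, "urban")
  # drop one county from the rural side
  keep <- 1:11
  tab2 <- indicator_table(g$table$values[keep, ],
                          g$table$county_ids[keep])
  sc2 <- factor_scores(tab2, sol)
  idx2 <- build_index(sc2, "rural")
  expect_error(summarize_index(idx, idx2, sc, sc2), "alignment error")
  s <- summarize_index(idx, idx2, sc, sc2, join = "outer")
  expect_identical(s$unmatched, g$table$county_ids[12])
})

test_that("per-area means stay within member county ranges", {
  g <- generate_counties(synthetic_config(n_counties = 21, seed = 47,
                                          clip_to_percent = TRUE))
  sol <- factor_solution(pearson_matrix(g$table), n_factors = 4)
  sc <- factor_scores(g$table, sol)
  idx <- build_index(sc, "urban")
  areas <- stats::setNames(g$table$area_ids, g$table$county_ids)
  s <- summarize_index(idx, idx, sc, sc, area_ids = areas)
  for (i in seq_len(nrow(s$area_means))) {
    a <- s$area_means$area[i]
    members <- idx$cumulative[areas[idx$county_ids] == a]
    expect_gte(s$area_means$mean_cumulative[i], min(members))
    expect_lte(s$area_means$mean_cumulative[i], max(members))
  }
})

test_that("geojson export joins the index onto features by key", {
  g <- generate_counties(synthetic_config(n_counties = 12, seed = 51,
                                          clip_to_percent = TRUE))
  sol <- factor_solution(pearson_matrix(g$table), n_factors = 4)
  idx <- build_index(factor_scores(g$table, sol), "urban")
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         properties = list(county_id = "C001", name = "first"),
         geometry = list(type = "Point", coordinates = c(91.1, 29.6))),
    list(type = "Feature",
         properties = list(county_id = "ZZZ"),
         geometry = list(type = "Point", coordinates = c(0, 0)))
  ))
  inp <- withr::local_tempfile(fileext = ".geojson")
  outp <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, inp, auto_unbox = TRUE, digits = NA)
  expect_warning(export_geojson(idx, inp, outp), "no matching")
  back <- jsonlite::fromJSON(outp, simplifyVector = FALSE)
  expect_equal(back$features[[1]]$properties$hvi, idx$cumulative[1])
  expect_null(back$features[[2]]$properties$hvi)
})
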