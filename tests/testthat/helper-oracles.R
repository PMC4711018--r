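# Independent oracles used across the test suite. These deliberately do
# not share code with the implementation they check.

# Exhaustive rotation-angle grid maximum of the varimax criterion for a
# two-column loading matrix: every orthogonal 2x2 rotation is a planar
# rotation by some angle, and the criterion has period pi/2 in it.
grid_varimax_max <- function(L, step = 1e-5) {
  stopifnot(ncol(L) == 2)
  th <- seq(0, pi / 2, by = step)
  x <- L[, 1]; y <- L[, 2]
  X <- outer(x, cos(th)) + outer(y, sin(th))
  Y <- -outer(x, sin(th)) + outer(y, cos(th))
  p <- nrow(L)
  crit <- colSums(X^4) / p - (colSums(X^2) / p)^2 +
          colSums(Y^4) / p - (colSums(Y^2) / p)^2
  max(crit)
}

# Hand-written piecewise table for the six SD categories, written in
# descending order (the implementation works upward from z <= -2).
bin_oracle <- function(z) {
  vapply(z, function(zi) {
    if (zi >= 2) 6L
    else if (zi >= 1) 5L
    else if (zi >= 0) 4L
    else if (zi > -1) 3L
    else if (zi > -2) 2L
    else 1L
  }, integer(1))
}

# A small valid indicator table whose first columns are set explicitly;
# remaining columns are filled with distinct in-range values.
make_table <- function(..., n = NULL, stratum = "urban") {
  cols <- list(...)
  if (is.null(n)) n <- length(cols[[1]])
  vars <- heatvuln::hv_variables()
  m <- matrix(NA_real_, n, 10, dimnames = list(NULL, vars))
  for (i in seq_along(cols)) m[, i] <- cols[[i]]
  for (j in seq_len(10)) {
    if (anyNA(m[, j])) m[, j] <- seq(1, 50, length.out = n) + j
  }
  heatvuln::indicator_table(m, sprintf("C%03d", seq_len(n)),
                            schema = heatvuln::hv_schema(stratum))
}

# Standardized hv_scores wrapper around a raw matrix (for constructed
# binning/summary cases; bypass numeric checks with check = FALSE).
make_scores <- function(m, ids = sprintf("C%03d", seq_len(nrow(m)))) {
  structure(list(county_ids = ids, scores = m, standardized = TRUE),
            class = "hv_scores")
}
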